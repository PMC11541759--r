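# Synthetic video generator: trajectories, rendering, dataset layout,
# determinism, and class separability.

test_that("trajectories are deterministic given the seed and stay inside the frame", {
  set.seed(31); t1 <- make_trajectory(100, 1, 224)
  set.seed(31); t2 <- make_trajectory(100, 1, 224)
  expect_identical(t1, t2)
  expect_true(all(t1 >= 0 & t1 <= 223))
  expect_error(make_trajectory(1, 1, 224), "at least 2")
})

test_that("novice jitter raises the discrete-acceleration statistic", {
  # degenerate amplitude: both classes share the smoothness statistics
  set.seed(32); te <- make_trajectory(200, 1, 224, jitter_amplitude = 0)
  set.seed(32); tn <- make_trajectory(200, 0, 224, jitter_amplitude = 0)
  expect_identical(te, tn)
  # amplitude 5: the novice trajectory is strictly rougher at the same seed
  set.seed(33); sm <- make_trajectory(200, 1, 224, jitter_amplitude = 5)
  set.seed(33); jk <- make_trajectory(200, 0, 224, jitter_amplitude = 5)
  expect_gt(trajectory_roughness(jk), trajectory_roughness(sm))
})

test_that("ground-truth smoothness separates the classes on 40 videos", {
  set.seed(34)
  labels <- rep(c(1, 0), each = 20)
  stat <- vapply(labels, function(l) {
    trajectory_roughness(make_trajectory(sample(140:200, 1), l, 64,
                                         jitter_amplitude = 2.5))
  }, numeric(1))
  # brute-force pairwise-ordering AUC (novices should be rougher)
  pairs <- outer(stat[labels == 0], stat[labels == 1], ">")
  auc <- mean(pairs + 0.5 * outer(stat[labels == 0], stat[labels == 1],
                                  "=="))
  expect_gt(auc, 0.95)
})

test_that("rendered tips peak at their positions and support multiple tips", {
  set.seed(35)
  img <- render_frame(matrix(c(31.5, 31.5), 1), 64, label = 1)
  expect_equal(dim(img), c(64, 64, 3))
  expect_true(all(img >= 0 & img <= 1))
  peak <- which(img[, , 1] == max(img[, , 1]), arr.ind = TRUE)[1, ]
  expect_lte(sqrt((peak[2] - 1 - 31.5)^2 + (peak[1] - 1 - 31.5)^2), 2)
  # two tips: a brute-force local-maximum scan finds two separated peaks
  img2 <- render_frame(rbind(c(16, 16), c(48, 48)), 64, label = 1)
  ch <- img2[, , 1]
  is_peak <- matrix(FALSE, 64, 64)
  for (r in 5:60) {
    for (c in 5:60) {
      w <- ch[(r - 2):(r + 2), (c - 2):(c + 2)]
      if (ch[r, c] == max(w) && ch[r, c] > 0.9) is_peak[r, c] <- TRUE
    }
  }
  pk <- which(is_peak, arr.ind = TRUE)
  near <- function(p, q) sqrt(sum((p - q)^2)) < 4
  expect_true(any(apply(pk, 1, function(p) near(p, c(17, 17)))))
  expect_true(any(apply(pk, 1, function(p) near(p, c(49, 49)))))
  expect_error(render_frame(matrix(c(300, 10), 1), 64, 1), "inside")
})

test_that("the corner cue is absent when its strength is zero", {
  pos <- matrix(c(40, 40), 1)
  set.seed(36); f0 <- render_frame(pos, 64, label = 0,
                                   spurious_cue_strength = 0)
  set.seed(36); f1 <- render_frame(pos, 64, label = 1,
                                   spurious_cue_strength = 0)
  # corner region independent of label (identical under the same noise)
  expect_identical(f0[1:8, 1:8, ], f1[1:8, 1:8, ])
  # with positive strength, expert frames in the source domain carry the
  # marker more often than novice frames
  n_marker <- function(lbl) {
    sum(vapply(1:40, function(i) {
      f <- render_frame(pos, 64, label = lbl, domain = "source",
                        spurious_cue_strength = 0.8)
      f[4, 4, 1] > 0.9 && f[4, 4, 2] < 0.3
    }, logical(1)))
  }
  set.seed(37)
  expect_gt(n_marker(1), n_marker(0) + 10)
})

test_that("generated datasets follow the configured structure", {
  dir <- file.path(tempdir(), "gen-structure")
  on.exit(unlink(dir, recursive = TRUE))
  cfg <- synthetic_config(frame_size = 32, n_videos_source = 10,
                          n_videos_target = 2,
                          length_range_source = c(100, 100),
                          length_range_target = c(300, 300),
                          expert_fraction_source = 0.5,
                          annotation_interval = 12, rng_seed = 38)
  man <- generate_dataset(cfg, dir)
  src <- man[man$domain == "source", ]
  expect_equal(nrow(src), 10)
  expect_equal(sum(src$label), 5)
  # frames on disk match the manifest
  expect_equal(length(list_frames(src$frame_dir[1])), src$n_frames[1])
  # keypoints exactly at annotated indices: frames 0, 12, ..., 96 (9 rows)
  kp <- read_keypoints(src$keypoint_file[1])
  expect_equal(sort(unique(kp$frame_index)), seq(0, 96, by = 12))
  expect_equal(nrow(kp), 9)
  # annotation consistency: keypoints equal the rendered tip position
  trj <- attr(man, "trajectories")[[src$video_id[1]]][[1]]
  expect_lt(max(abs(kp$x - trj[kp$frame_index + 1, 1])), 0.5)
  expect_lt(max(abs(kp$y - trj[kp$frame_index + 1, 2])), 0.5)
  # manifest round-trips through the TSV dialect
  man2 <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(man2$video_id, man$video_id)
  expect_equal(man2$n_frames, man$n_frames)
})

test_that("generation is bit-identical for equal configs and seeds", {
  cfg <- synthetic_config(frame_size = 32, n_videos_source = 2,
                          n_videos_target = 1,
                          length_range_source = c(30, 40),
                          length_range_target = c(90, 120), rng_seed = 39)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  m1 <- generate_dataset(cfg, d1)
  m2 <- generate_dataset(cfg, d2)
  expect_equal(m1$n_frames, m2$n_frames)
  expect_equal(m1$label, m2$label)
  f1 <- list_frames(m1$frame_dir[1]); f2 <- list_frames(m2$frame_dir[1])
  expect_identical(readBin(f1[5], "raw", file.size(f1[5])),
                   readBin(f2[5], "raw", file.size(f2[5])))
  expect_identical(readLines(m1$keypoint_file[2]),
                   readLines(m2$keypoint_file[2]))
})

test_that("target videos are about three times longer than source videos", {
  dir <- file.path(tempdir(), "gen-ratio")
  on.exit(unlink(dir, recursive = TRUE))
  cfg <- synthetic_config(frame_size = 16, n_videos_source = 20,
                          n_videos_target = 20,
                          length_range_source = c(14, 20),
                          length_range_target = c(42, 60), rng_seed = 40)
  man <- generate_dataset(cfg, dir)
  ratio <- mean(man$n_frames[man$domain == "target"]) /
    mean(man$n_frames[man$domain == "source"])
  expect_gt(ratio, 3 * 0.8)
  expect_lt(ratio, 3 * 1.2)
  # label skew: the target domain is scarce in experts
  expect_equal(sum(man$label[man$domain == "target"]),
               round(5 / 51 * 20))
})

test_that("invalid generator configurations are rejected", {
  expect_error(synthetic_config(n_videos_source = 0))
  expect_error(synthetic_config(expert_fraction_source = 1.2))
  expect_error(synthetic_config(annotation_interval = 0))
  expect_error(synthetic_config(spurious_cue_strength = -0.1))
})
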