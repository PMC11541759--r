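# Clip sampling, keypoint attachment, and clip-consistent augmentation.

test_that("clip indices are strided windows with uniformly sampled starts", {
  set.seed(41)
  starts <- integer(0)
  for (i in 1:50) {
    idx <- sample_clip_indices(30000, 256, 8)
    expect_length(idx, 256)
    expect_true(all(diff(idx) == 8))
    expect_gte(idx[1], 0)
    expect_lte(idx[1], 27959)
    expect_lt(max(idx), 30000)
    starts <- c(starts, idx[1])
  }
  expect_gt(length(unique(starts)), 1)  # different draws, different starts
  # unique feasible start when the window exactly fits
  idx <- sample_clip_indices((256 - 1) * 8 + 1, 256, 8)
  expect_equal(idx[1], 0)
  expect_equal(idx[256], 2040)
})

test_that("short videos fall back to a reduced stride or padding", {
  set.seed(42)
  # reduced stride: largest stride >= 1 that fits
  idx <- sample_clip_indices(1000, 256, 8)
  expect_length(idx, 256)
  expect_true(all(diff(idx) == 3))  # (1000-1) %/% 255 = 3
  expect_lt(max(idx), 1000)
  # shorter than the clip even at stride 1: pad with the last frame
  idx2 <- sample_clip_indices(100, 256, 8)
  expect_length(idx2, 256)
  expect_true(all(idx2 < 100))
  expect_equal(idx2[1:100], 0:99)
  expect_true(all(idx2[101:256] == 99))
})

test_that("repeated sampling sparsely covers the whole video", {
  set.seed(43)
  used <- integer(0)
  for (i in 1:200) used <- union(used, sample_clip_indices(30000, 256, 8))
  bins <- unique(used %/% 8)
  expect_gt(length(bins) / (30000 / 8), 0.9)
})

test_that("sampled frames receive keypoints of the nearest annotated frame", {
  kp <- data.frame(video_id = "v", frame_index = rep(seq(0, 96, 12), each = 1),
                   instrument_id = 0,
                   x = seq(0, 96, 12) + 0.5, y = seq(0, 96, 12) * 2)
  # exact hit: frame 24 keeps its own annotation
  got <- assign_keypoints_to_frames(c(24), kp, 12)
  expect_equal(got[[1]]$x, 24.5)
  # frame 8: donor is frame 12 (distance 4 < 8)
  got <- assign_keypoints_to_frames(c(8), kp, 12)
  expect_equal(got[[1]]$x, 12.5)
  # tie at the midpoint goes to the earlier frame
  got <- assign_keypoints_to_frames(c(6), kp, 12)
  expect_equal(got[[1]]$x, 0.5)
  # donor distance never exceeds half the interval (interior frames)
  for (i in 0:90) {
    g <- assign_keypoints_to_frames(i, kp, 12)[[1]]
    expect_lte(abs(g$x - 0.5 - i), ceiling(12 / 2))
  }
  # empty table: every frame gets an empty list and an all-zero heat map
  got <- assign_keypoints_to_frames(c(0, 5, 10), kp[0, ], 12)
  expect_true(all(vapply(got, nrow, integer(1)) == 0L))
  expect_equal(sum(build_trajectory_heatmap(got[[1]], 64, 8)), 0)
})

make_test_clip <- function(n = 3, fs = 32, kp_xy = c(10, 20)) {
  frames <- replicate(n, array(runif(fs * fs * 3), c(fs, fs, 3)),
                      simplify = FALSE)
  kps <- replicate(n, data.frame(instrument_id = 0L, x = kp_xy[1],
                                 y = kp_xy[2]), simplify = FALSE)
  structure(list(video_id = "v", source_indices = seq_len(n) - 1L,
                 frames = frames, keypoints = kps, label = 1L),
            class = "clip_sample")
}

test_that("identity augmentation leaves frames and keypoints unchanged", {
  set.seed(44)
  clip <- make_test_clip()
  out <- augment_clip(clip, augmentation_params(max_rotate = 0,
                                                hflip_prob = 0,
                                                brightness = 0,
                                                contrast = 0))
  expect_equal(out$frames[[1]], clip$frames[[1]], tolerance = 1e-12)
  expect_equal(out$keypoints[[2]], clip$keypoints[[2]], tolerance = 1e-12)
})

test_that("horizontal flip reflects keypoints to W-1-x", {
  set.seed(45)
  clip <- make_test_clip(fs = 32, kp_xy = c(10, 20))
  out <- augment_clip(clip, augmentation_params(max_rotate = 0,
                                                hflip_prob = 1,
                                                brightness = 0,
                                                contrast = 0))
  expect_equal(out$keypoints[[1]]$x, 32 - 1 - 10)
  expect_equal(out$keypoints[[1]]$y, 20)
  # image columns are reversed
  expect_equal(out$frames[[1]][, , 1], clip$frames[[1]][, 32:1, 1],
               tolerance = 1e-9)
})

test_that("rotation moves keypoints by the same affine map as the image", {
  set.seed(46)
  clip <- make_test_clip(fs = 33, kp_xy = c(8, 14))
  out <- augment_clip(clip, augmentation_params(max_rotate = 25,
                                                hflip_prob = 0,
                                                brightness = 0,
                                                contrast = 0))
  aug <- attr(out, "augment")
  # independent oracle: rotate the point about the center directly
  theta <- aug$theta; cx <- (33 - 1) / 2
  x0 <- 8 - cx; y0 <- 14 - cx
  expx <- cos(theta) * x0 - sin(theta) * y0 + cx
  expy <- sin(theta) * x0 + cos(theta) * y0 + cx
  expect_lt(abs(out$keypoints[[1]]$x - expx), 0.5)
  expect_lt(abs(out$keypoints[[1]]$y - expy), 0.5)
})

test_that("augmented keypoints stay on the rendered blob", {
  set.seed(47)
  tip <- c(24.0, 40.0)
  img <- render_frame(matrix(tip, 1), 64, label = 1)
  clip <- structure(list(video_id = "v", source_indices = 0L,
                         frames = list(img),
                         keypoints = list(data.frame(instrument_id = 0L,
                                                     x = tip[1],
                                                     y = tip[2])),
                         label = 1L), class = "clip_sample")
  for (i in 1:5) {
    out <- augment_clip(clip, augmentation_params(max_rotate = 20,
                                                  hflip_prob = 0.5,
                                                  brightness = 0,
                                                  contrast = 0))
    kp <- out$keypoints[[1]]
    if (nrow(kp) == 0) next
    ch <- out$frames[[1]][, , 1]
    ctr <- ch[max(1, round(kp$y) - 8):min(64, round(kp$y) + 8),
              max(1, round(kp$x) - 8):min(64, round(kp$x) + 8)]
    peak <- which(ctr == max(ctr), arr.ind = TRUE)[1, ]
    # the local maximum of the warped blob lies within ~1 px of the
    # transformed keypoint (quantized to the pixel grid)
    py <- max(1, round(kp$y) - 8) + peak[1] - 1
    px <- max(1, round(kp$x) - 8) + peak[2] - 1
    expect_lte(sqrt((px - 1 - kp$x)^2 + (py - 1 - kp$y)^2), 1.8)
  }
})

test_that("keypoints leaving the crop are dropped and big crops error", {
  set.seed(48)
  clip <- make_test_clip(fs = 32, kp_xy = c(2, 2))
  out <- augment_clip(clip, augmentation_params(crop_size = 16,
                                                max_rotate = 0,
                                                hflip_prob = 0,
                                                brightness = 0,
                                                contrast = 0))
  expect_equal(dim(out$frames[[1]]), c(16, 16, 3))
  for (kp in out$keypoints) {
    if (nrow(kp) > 0) {
      expect_true(all(kp$x >= 0 & kp$x <= 15 & kp$y >= 0 & kp$y <= 15))
    }
  }
  expect_error(augment_clip(clip, augmentation_params(crop_size = 64)),
               "exceeds")
})

test_that("clips load from disk with attached keypoints", {
  fx <- small_dataset()
  rec <- fx$manifest[1, ]
  set.seed(49)
  clip <- load_clip(rec, clip_len = 8, stride = 4)
  expect_s3_class(clip, "clip_sample")
  expect_length(clip$frames, 8)
  expect_equal(dim(clip$frames[[1]]), c(64, 64, 3))
  expect_length(clip$keypoints, 8)
  expect_true(all(clip$source_indices < rec$n_frames))
})
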