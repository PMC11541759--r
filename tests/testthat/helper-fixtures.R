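# Shared fixtures built in code, generated lazily once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Small synthetic dataset: 20 source videos (90-130 frames), 8 target
# videos (270-390 frames), 64-px frames, written to a per-run temp dir.
small_dataset <- function() {
  if (!is.null(.fixture_env$small)) return(.fixture_env$small)
  dir <- file.path(tempdir(), "surgskill-fixture")
  cfg <- synthetic_config(frame_size = 64, n_videos_source = 20,
                          n_videos_target = 8,
                          length_range_source = c(90, 130),
                          length_range_target = c(270, 390),
                          jitter_amplitude_novice = 2.5,
                          rng_seed = 424L)
  manifest <- generate_dataset(cfg, dir)
  .fixture_env$small <- list(cfg = cfg, dir = dir, manifest = manifest,
                             trajectories = attr(manifest, "trajectories"))
  .fixture_env$small
}

# tiny-encoder features for the small dataset's source videos
small_features <- function() {
  if (!is.null(.fixture_env$feats)) return(.fixture_env$feats)
  fx <- small_dataset()
  enc <- frame_encoder("tiny", seed = 424L)
  src <- fx$manifest[fx$manifest$domain == "source", ]
  .fixture_env$feats <- list(encoder = enc,
                             source = encode_videos(src, enc))
  .fixture_env$feats
}

# finite-difference gradient check against the tape's analytic gradients.
# fn() must rebuild the forward pass from the leaves' current values and
# return the loss (node under a tape, numeric otherwise).
expect_fd_grads <- function(fn, leaves, n_checks = 4, h = 1e-6,
                            tol = 1e-3) {
  surgskill:::ag_zero_grad(leaves)
  surgskill:::tape_begin()
  loss <- fn()
  surgskill:::ag_backward(loss)
  surgskill:::tape_end()
  for (nm in names(leaves)) {
    l <- leaves[[nm]]
    ga <- l$g
    if (is.null(ga)) ga <- l$v * 0
    idx <- sample(length(l$v), min(n_checks, length(l$v)))
    for (i in idx) {
      orig <- l$v[i]
      l$v[i] <- orig + h
      fp <- surgskill:::vof(fn())
      l$v[i] <- orig - h
      fm <- surgskill:::vof(fn())
      l$v[i] <- orig
      num <- (fp - fm) / (2 * h)
      an <- ga[i]
      rel <- abs(num - an) / max(1e-6, abs(num), abs(an))
      expect_lt(rel, tol, label = sprintf(
        "relative FD mismatch for %s[%d] (analytic %.6g, numeric %.6g)",
        nm, i, an, num))
    }
  }
  invisible(NULL)
}

leafify <- function(lst) lapply(lst, surgskill:::ag_leaf)
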