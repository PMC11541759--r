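# Synthetic surgical-like video generator with tool-tip annotations and
# controllable source/target domain shift.
#
# The generator emulates the structure of the real capsulorhexis datasets
# that motivated this package without claiming visual realism: clips of RGB
# frames showing a textured circular field (the surgical field under the
# microscope) with one or more moving bright tool-tip blobs; expert tips
# follow smooth low-curvature paths while novice tips add high-frequency
# jitter; tips are annotated every k-th frame; a target domain has roughly
# three-times-longer videos, a strong novice label skew, and an optional
# spurious corner cue that is label-correlated only in the source domain.
# The skill-informative cue is deliberately local to the tip (blob
# ellipticity differs by class) so that spatial attention supervised toward
# the tip has access to the class signal: this is a generator guarantee.

#' Configuration of the synthetic video generator
#'
#' Defaults encode the emulated study conditions: square frames, a tip
#' annotated every 12th frame, target-domain videos with roughly 3x the
#' source mean length, a source expert fraction near 51/99 and a target
#' expert fraction near 5/51.
#'
#' @param frame_size square frame size in pixels.
#' @param n_videos_source,n_videos_target videos per domain.
#' @param length_range_source,length_range_target inclusive frame-count
#'   ranges (uniform); the target default mean is 3x the source default
#'   mean.
#' @param expert_fraction_source,expert_fraction_target fraction of videos
#'   labeled expert per domain (in \[0, 1\]).
#' @param annotation_interval annotate tips every this many frames (>= 1).
#' @param n_tips number of instrument tips per video.
#' @param jitter_amplitude_novice pixel standard deviation of the novice
#'   high-frequency jitter.
#' @param spurious_cue_strength in \[0, 1\]: 0 disables the corner marker;
#'   1 makes it perfectly label-correlated in the source domain.  In the
#'   target domain the marker is always label-independent.
#' @param rng_seed integer seed; equal seeds give bit-identical datasets.
#' @return validated config of class `"synthetic_config"`.
#' @export
synthetic_config <- function(frame_size = 224,
                             n_videos_source = 20,
                             n_videos_target = 10,
                             length_range_source = c(600, 1200),
                             length_range_target = c(1800, 3600),
                             expert_fraction_source = 51 / 99,
                             expert_fraction_target = 5 / 51,
                             annotation_interval = 12,
                             n_tips = 1,
                             jitter_amplitude_novice = 8,
                             spurious_cue_strength = 0.8,
                             rng_seed = 1L) {
  cfg <- list(frame_size = as.integer(frame_size),
              n_videos_source = as.integer(n_videos_source),
              n_videos_target = as.integer(n_videos_target),
              length_range_source = as.integer(length_range_source),
              length_range_target = as.integer(length_range_target),
              expert_fraction_source = expert_fraction_source,
              expert_fraction_target = expert_fraction_target,
              annotation_interval = as.integer(annotation_interval),
              n_tips = as.integer(n_tips),
              jitter_amplitude_novice = jitter_amplitude_novice,
              spurious_cue_strength = spurious_cue_strength,
              rng_seed = as.integer(rng_seed))
  with(cfg, {
    stopifnot(frame_size > 0, n_videos_source > 0, n_videos_target > 0,
              all(length_range_source > 0), all(length_range_target > 0),
              expert_fraction_source >= 0, expert_fraction_source <= 1,
              expert_fraction_target >= 0, expert_fraction_target <= 1,
              annotation_interval >= 1, n_tips > 0,
              jitter_amplitude_novice >= 0,
              spurious_cue_strength >= 0, spurious_cue_strength <= 1)
  })
  structure(cfg, class = "synthetic_config")
}

#' Desk-scale generator profile
#'
#' The configuration used by the package's scaled-down end-to-end
#' experiments: 64-px frames, 40 source and 20 target videos, source
#' lengths 140-200 frames, target lengths 420-600 frames (3x mean), novice
#' jitter 2.5 px (the 224-px default scaled to 64 px).
#'
#' @param rng_seed integer seed.
#' @return a `"synthetic_config"`.
#' @export
synthetic_profile_desk <- function(rng_seed = 1L) {
  synthetic_config(frame_size = 64,
                   n_videos_source = 40, n_videos_target = 20,
                   length_range_source = c(140, 200),
                   length_range_target = c(420, 600),
                   jitter_amplitude_novice = 2.5,
                   rng_seed = rng_seed)
}

#' Simulate an instrument-tip trajectory
#'
#' Experts follow a smooth path (cubic spline through a few random control
#' points); novices follow the same kind of path plus zero-mean white
#' positional jitter of standard deviation `jitter_amplitude`, realizing
#' the smooth-versus-jerky motion contrast between skill classes.  All
#' positions are clamped inside the frame.  Positions are drawn from the
#' current RNG state; seed with `set.seed()` for reproducibility.
#'
#' @param n_frames number of frames (>= 2).
#' @param label 1 = expert (smooth), 0 = novice (jittered).
#' @param frame_size frame size in pixels.
#' @param jitter_amplitude novice jitter standard deviation in pixels.
#' @param n_control number of spline control points.
#' @return `n_frames x 2` matrix of (x, y) positions (0-based pixels).
#' @export
make_trajectory <- function(n_frames, label, frame_size,
                            jitter_amplitude = 8, n_control = 5) {
  if (n_frames < 2) stop("n_frames must be at least 2")
  lo <- 0.12 * frame_size
  hi <- 0.88 * frame_size
  tc <- seq(1, n_frames, length.out = n_control)
  cx <- stats::runif(n_control, lo, hi)
  cy <- stats::runif(n_control, lo, hi)
  x <- stats::spline(tc, cx, xout = seq_len(n_frames))$y
  y <- stats::spline(tc, cy, xout = seq_len(n_frames))$y
  if (label == 0 && jitter_amplitude > 0) {
    x <- x + stats::rnorm(n_frames, 0, jitter_amplitude)
    y <- y + stats::rnorm(n_frames, 0, jitter_amplitude)
  }
  lim <- c(2, frame_size - 3)
  cbind(x = pmin(pmax(x, lim[1]), lim[2]),
        y = pmin(pmax(y, lim[1]), lim[2]))
}

#' Mean discrete acceleration magnitude of a trajectory
#'
#' The mean Euclidean norm of the second difference of the position
#' sequence; the brute-force smoothness statistic separating expert from
#' novice trajectories.
#'
#' @param pos `n x 2` position matrix.
#' @return scalar.
#' @export
trajectory_roughness <- function(pos) {
  if (nrow(pos) < 3) return(0)
  d2 <- diff(pos, differences = 2)
  mean(sqrt(rowSums(d2^2)))
}

#' Render one synthetic frame
#'
#' Draws a textured circular field, a bright compact blob at each tip
#' position, a class-informative local cue at the tip (expert blobs are
#' round, novice blobs elliptical), and optionally a corner marker whose
#' presence is label-correlated in the source domain (with strength
#' `spurious_cue_strength`) and label-independent in the target domain.
#' Per-frame pixel noise and the marker draw come from the current RNG
#' state.
#'
#' @param tip_positions `n_tips x 2` matrix of (x, y) positions (0-based
#'   pixels, inside the frame).
#' @param frame_size frame size in pixels.
#' @param label 0/1 skill class.
#' @param domain `"source"` or `"target"`.
#' @param spurious_cue_strength in \[0, 1\].
#' @return `frame_size x frame_size x 3` array in \[0, 1\].
#' @export
render_frame <- function(tip_positions, frame_size, label,
                         domain = "source", spurious_cue_strength = 0) {
  fs <- frame_size
  tip_positions <- matrix(tip_positions, ncol = 2)
  if (any(tip_positions < 0 | tip_positions > fs - 1)) {
    stop("tip positions must lie inside the frame")
  }
  ys <- matrix(0:(fs - 1), fs, fs)
  xs <- matrix(0:(fs - 1), fs, fs, byrow = TRUE)
  cx <- (fs - 1) / 2
  r <- sqrt((xs - cx)^2 + (ys - cx)^2) / fs
  ang <- atan2(ys - cx, xs - cx)
  disk <- r < 0.46
  base <- 0.18 + disk * (0.25 + 0.08 * sin(8 * ang) + 0.10 * cos(2 * pi * r * 6))
  img <- array(0, c(fs, fs, 3))
  img[, , 1] <- base * 0.9
  img[, , 2] <- base * 0.75
  img[, , 3] <- base * 1.05
  # tool-tip blobs; the local class cue is the blob's shape and tint
  # (expert: round, warm; novice: elongated, cool).  The tint survives
  # the coarse cell pooling of downstream feature grids, so the cue is
  # recoverable at any sub-cell tip position (a generator guarantee).
  if (label == 1) {
    sx <- 0.035 * fs; sy <- 0.035 * fs
    tip_col <- c(1.0, 0.95, 0.8)
  } else {
    sx <- 0.055 * fs; sy <- 0.022 * fs
    tip_col <- c(0.78, 0.95, 1.0)
  }
  th <- 35 * pi / 180  # fixed instrument orientation
  for (k in seq_len(nrow(tip_positions))) {
    tx <- tip_positions[k, 1]; ty <- tip_positions[k, 2]
    u <- (xs - tx) * cos(th) + (ys - ty) * sin(th)
    v <- -(xs - tx) * sin(th) + (ys - ty) * cos(th)
    blob <- exp(-0.5 * ((u / sx)^2 + (v / sy)^2))
    for (c in 1:3) img[, , c] <- img[, , c] * (1 - blob) + blob * tip_col[c]
  }
  # spurious corner marker
  if (spurious_cue_strength > 0 || domain == "target") {
    show <- if (spurious_cue_strength == 0) {
      FALSE
    } else if (domain == "source") {
      agree <- stats::runif(1) < (1 + spurious_cue_strength) / 2
      if (agree) label == 1 else label == 0
    } else {
      stats::runif(1) < 0.5
    }
    if (isTRUE(show)) {
      ms <- max(4L, round(0.04 * fs))
      sel <- 3:(2 + ms)
      img[sel, sel, 1] <- 1
      img[sel, sel, 2] <- 0.1
      img[sel, sel, 3] <- 0.8
    }
  }
  img <- img + array(stats::rnorm(fs * fs * 3, 0, 0.02), c(fs, fs, 3))
  pmin(pmax(img, 0), 1)
}

#' Generate a labeled synthetic video dataset
#'
#' Writes, for each video, a directory of zero-padded numbered PNG frames
#' and a keypoint CSV (header `video_id,frame_index,instrument_id,x,y`)
#' with rows exactly at frame indices divisible by the annotation interval,
#' plus a dataset manifest TSV (header
#' `video_id,domain,label,n_frames,frame_dir,keypoint_file`).  Per-domain
#' video counts, length distributions, and expert fractions follow the
#' config; generation is bit-identical for equal configs and seeds.
#'
#' @param cfg a [synthetic_config()].
#' @param out_dir writable output directory (created if missing).
#' @param return_trajectories attach the ground-truth per-frame tip
#'   trajectories as attribute `"trajectories"` of the manifest.
#' @return the manifest data frame, invisibly.
#' @export
generate_dataset <- function(cfg, out_dir, return_trajectories = TRUE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  set.seed(cfg$rng_seed)
  rows <- list()
  trajs <- list()
  for (domain in c("source", "target")) {
    nv <- if (domain == "source") cfg$n_videos_source else cfg$n_videos_target
    lr <- if (domain == "source") cfg$length_range_source else cfg$length_range_target
    ef <- if (domain == "source") cfg$expert_fraction_source else cfg$expert_fraction_target
    n_exp <- round(ef * nv)
    labels <- sample(c(rep(1L, n_exp), rep(0L, nv - n_exp)))
    for (v in seq_len(nv)) {
      vid <- sprintf("%s_%03d", domain, v)
      n_frames <- lr[1] + sample.int(lr[2] - lr[1] + 1L, 1L) - 1L
      label <- labels[v]
      tips <- lapply(seq_len(cfg$n_tips), function(k) {
        make_trajectory(n_frames, label, cfg$frame_size,
                        jitter_amplitude = cfg$jitter_amplitude_novice)
      })
      frame_dir <- file.path(out_dir, vid)
      dir.create(frame_dir, showWarnings = FALSE)
      for (i in seq_len(n_frames)) {
        pos <- do.call(rbind, lapply(tips, function(tp) tp[i, ]))
        img <- render_frame(pos, cfg$frame_size, label, domain,
                            cfg$spurious_cue_strength)
        png::writePNG(img, file.path(frame_dir,
                                     sprintf("frame_%06d.png", i - 1L)))
      }
      ann <- seq(0L, n_frames - 1L, by = cfg$annotation_interval)
      kp <- do.call(rbind, lapply(seq_along(tips), function(k) {
        data.frame(video_id = vid, frame_index = ann,
                   instrument_id = k - 1L,
                   x = round(tips[[k]][ann + 1L, 1], 4),
                   y = round(tips[[k]][ann + 1L, 2], 4))
      }))
      kp <- kp[order(kp$frame_index, kp$instrument_id), ]
      kp_file <- file.path(out_dir, paste0(vid, "_keypoints.csv"))
      utils::write.csv(kp, kp_file, row.names = FALSE, quote = FALSE)
      rows[[vid]] <- data.frame(video_id = vid, domain = domain,
                                label = label, n_frames = n_frames,
                                frame_dir = frame_dir,
                                keypoint_file = kp_file)
      if (return_trajectories) trajs[[vid]] <- tips
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  if (return_trajectories) attr(manifest, "trajectories") <- trajs
  invisible(manifest)
}
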