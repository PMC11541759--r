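# Clip sampling: fixed-length strided clips, keypoint attachment, and
# clip-consistent augmentation of frames and keypoints together.

#' Sample strided frame indices for one clip
#'
#' Draws a uniformly random starting frame and returns `clip_len` indices
#' `start, start + stride, ...` (0-based).  When the strided window does
#' not fit the video, the stride is reduced to the largest value >= 1 that
#' fits; if the video is shorter than `clip_len` even at stride 1, the
#' last frame index is repeated to pad the clip (the fixed-length contract
#' is preserved for the temporal models).
#'
#' @param video_length number of frames in the video (>= 1).
#' @param clip_len clip length in frames (default 256).
#' @param stride subsampling stride (default 8).
#' @return integer vector of `clip_len` 0-based frame indices.
#' @export
sample_clip_indices <- function(video_length, clip_len = 256, stride = 8) {
  stopifnot(video_length >= 1, clip_len >= 1, stride >= 1)
  span <- (clip_len - 1) * stride
  if (span > video_length - 1) {
    stride <- max(1L, (video_length - 1L) %/% max(1L, clip_len - 1L))
    span <- (clip_len - 1) * stride
  }
  if (span <= video_length - 1) {
    start <- sample.int(video_length - span, 1L) - 1L
    seq(start, by = stride, length.out = clip_len)
  } else {
    idx <- seq_len(video_length) - 1L
    c(idx, rep(video_length - 1L, clip_len - video_length))
  }
}

#' Attach keypoints to sampled frames
#'
#' Annotations exist only every `annotation_interval` frames; each sampled
#' frame receives the keypoints of the nearest annotated frame (ties go to
#' the earlier frame), so the donor distance never exceeds
#' `ceiling(annotation_interval / 2)` away from the annotation grid
#' boundaries.  An empty keypoint table yields empty per-frame lists.
#'
#' @param source_indices 0-based sampled frame indices.
#' @param keypoints keypoint table (`frame_index`, `instrument_id`, `x`,
#'   `y`), as from [read_keypoints()].
#' @param annotation_interval annotation spacing in frames.
#' @return list (one entry per sampled frame) of data frames with columns
#'   `instrument_id`, `x`, `y` (possibly zero rows).
#' @export
assign_keypoints_to_frames <- function(source_indices, keypoints,
                                       annotation_interval = 12) {
  empty <- data.frame(instrument_id = integer(), x = numeric(),
                      y = numeric())
  if (is.null(keypoints) || nrow(keypoints) == 0L) {
    return(rep(list(empty), length(source_indices)))
  }
  ann_max <- max(keypoints$frame_index)
  by_frame <- split(keypoints[c("instrument_id", "x", "y")],
                    keypoints$frame_index)
  lapply(source_indices, function(i) {
    lower <- annotation_interval * (i %/% annotation_interval)
    upper <- lower + annotation_interval
    donor <- if (i - lower <= upper - i) lower else upper
    donor <- min(donor, ann_max)
    rows <- by_frame[[as.character(donor)]]
    if (is.null(rows)) empty else rows
  })
}

#' Load one sampled clip of a video
#'
#' Reads the sampled frames from disk and attaches per-frame keypoints.
#'
#' @param record one manifest row (`video_id`, `label`, `n_frames`,
#'   `frame_dir`, `keypoint_file`).
#' @param indices 0-based frame indices; defaults to a fresh
#'   [sample_clip_indices()] draw.
#' @param clip_len,stride clip sampling parameters.
#' @param annotation_interval annotation spacing for keypoint attachment.
#' @return a `clip_sample`: list with `video_id`, `source_indices`,
#'   `frames` (list of `h x w x 3` arrays), `keypoints` (per-frame data
#'   frames), `label`.
#' @export
load_clip <- function(record, indices = NULL, clip_len = 256, stride = 8,
                      annotation_interval = 12) {
  if (is.null(indices)) {
    indices <- sample_clip_indices(record$n_frames, clip_len, stride)
  }
  files <- file.path(record$frame_dir,
                     sprintf("frame_%06d.png", indices))
  frames <- lapply(files, read_frame)
  kp <- read_keypoints(record$keypoint_file)
  structure(list(video_id = record$video_id,
                 source_indices = indices,
                 frames = frames,
                 keypoints = assign_keypoints_to_frames(indices, kp,
                                                        annotation_interval),
                 label = record$label),
            class = "clip_sample")
}

#' Augmentation parameter ranges
#'
#' One geometric parameter set is drawn per clip and applied identically
#' to every frame, preserving temporal coherence; keypoints undergo the
#' identical geometric transform.  Color jitter perturbs pixel values only
#' and leaves keypoints unchanged.
#'
#' @param crop_size output crop size in pixels (`NULL` = no crop).
#' @param max_rotate maximal rotation magnitude in degrees.
#' @param hflip_prob probability of a horizontal flip.
#' @param brightness,contrast maximal brightness shift / contrast
#'   log-factor.
#' @return list of ranges for [augment_clip()].
#' @export
augmentation_params <- function(crop_size = NULL, max_rotate = 10,
                                hflip_prob = 0.5, brightness = 0.1,
                                contrast = 0.1) {
  list(crop_size = crop_size, max_rotate = max_rotate,
       hflip_prob = hflip_prob, brightness = brightness,
       contrast = contrast)
}

# 3x3 affine for a point transform p' = M [x, y, 1]'
affine_rotation <- function(theta, cx, cy) {
  ct <- cos(theta); st <- sin(theta)
  rbind(c(ct, -st, cx - ct * cx + st * cy),
        c(st, ct, cy - st * cx - ct * cy),
        c(0, 0, 1))
}

# bilinear warp of an image under point transform M (output <- input)
warp_image <- function(img, M, out_h, out_w) {
  Minv <- solve(M)
  xo <- rep(0:(out_w - 1), each = out_h)
  yo <- rep(0:(out_h - 1), times = out_w)
  xs <- Minv[1, 1] * xo + Minv[1, 2] * yo + Minv[1, 3]
  ys <- Minv[2, 1] * xo + Minv[2, 2] * yo + Minv[2, 3]
  h <- dim(img)[1]; w <- dim(img)[2]
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  out <- array(0, c(out_h, out_w, dim(img)[3]))
  gather <- function(ch, yy, xx) {
    ok <- xx >= 0 & xx <= w - 1 & yy >= 0 & yy <= h - 1
    v <- numeric(length(xx))
    v[ok] <- ch[cbind(yy[ok] + 1L, xx[ok] + 1L)]
    v
  }
  for (c in seq_len(dim(img)[3])) {
    ch <- img[, , c]
    v <- (1 - fx) * (1 - fy) * gather(ch, y0, x0) +
      fx * (1 - fy) * gather(ch, y0, x0 + 1) +
      (1 - fx) * fy * gather(ch, y0 + 1, x0) +
      fx * fy * gather(ch, y0 + 1, x0 + 1)
    out[, , c] <- matrix(v, out_h, out_w)
  }
  out
}

#' Augment a clip (frames and keypoints together)
#'
#' Draws one parameter set (rotation angle, crop offset, flip, color
#' jitter) from the current RNG state and applies it to all frames of the
#' clip; keypoints are mapped through the identical affine transform and
#' dropped if they leave the output frame.
#'
#' @param clip a `clip_sample`.
#' @param params ranges from [augmentation_params()].
#' @return the augmented `clip_sample`.
#' @export
augment_clip <- function(clip, params = augmentation_params()) {
  h <- dim(clip$frames[[1]])[1]
  w <- dim(clip$frames[[1]])[2]
  cs <- params$crop_size
  if (is.null(cs)) cs <- min(h, w)
  if (cs > min(h, w)) stop("crop size exceeds frame size")
  theta <- stats::runif(1, -params$max_rotate, params$max_rotate) * pi / 180
  off_x <- sample.int(w - cs + 1L, 1L) - 1L
  off_y <- sample.int(h - cs + 1L, 1L) - 1L
  flip <- stats::runif(1) < params$hflip_prob
  bshift <- stats::runif(1, -params$brightness, params$brightness)
  cfac <- exp(stats::runif(1, -params$contrast, params$contrast))
  M <- affine_rotation(theta, (w - 1) / 2, (h - 1) / 2)
  Mcrop <- rbind(c(1, 0, -off_x), c(0, 1, -off_y), c(0, 0, 1))
  M <- Mcrop %*% M
  if (flip) M <- rbind(c(-1, 0, cs - 1), c(0, 1, 0), c(0, 0, 1)) %*% M
  clip$frames <- lapply(clip$frames, function(f) {
    out <- warp_image(f, M, cs, cs)
    pmin(pmax((out - 0.5) * cfac + 0.5 + bshift, 0), 1)
  })
  clip$keypoints <- lapply(clip$keypoints, function(kp) {
    if (nrow(kp) == 0L) return(kp)
    p <- M %*% rbind(kp$x, kp$y, 1)
    kp$x <- p[1, ]; kp$y <- p[2, ]
    kp[kp$x >= 0 & kp$x <= cs - 1 & kp$y >= 0 & kp$y <= cs - 1, ,
       drop = FALSE]
  })
  attr(clip, "augment") <- list(theta = theta, off = c(off_x, off_y),
                                flip = flip, matrix = M)
  clip
}
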