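# Frame encoders: map an RGB frame to an H x W x C_e feature grid.
#
# The encoder is consumed as a component behind a fixed contract
# (deterministic given weights and input); any function frame -> grid can
# be plugged in (e.g. features exported from a pretrained network).  Two
# built-in randomly initialized convolutional stacks are provided:
#   tiny : 64-px frames -> 8 x 8 grid, C_e = 64 (4 conv blocks); the
#          desk-scale test encoder.
#   deep : 224-px frames -> 7 x 7 grid, C_e = 2048 (6 blocks); the
#          reference interface shape.
# All blocks except the last are always frozen; the last block (a 1x1
# convolution, i.e. a per-cell dense map) is unfrozen under the
# selection-scheme training policy.

# cached im2col index map
.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(h, w, c, k, stride, pad) {
  key <- paste(h, w, c, k, stride, pad, sep = ",")
  got <- .im2col_cache[[key]]
  if (!is.null(got)) return(got)
  out_h <- (h + 2L * pad - k) %/% stride + 1L
  out_w <- (w + 2L * pad - k) %/% stride + 1L
  hp <- h + 2L * pad
  # position of each patch element in the zero-padded image, column-major
  oy <- rep(seq_len(out_h), times = out_w)
  ox <- rep(seq_len(out_w), each = out_h)
  y0 <- (oy - 1L) * stride
  x0 <- (ox - 1L) * stride
  n_pos <- out_h * out_w
  idx <- integer(n_pos * k * k * c)
  p <- 1L
  for (ci in seq_len(c)) {
    zoff <- (ci - 1L) * hp * (w + 2L * pad)
    for (kx in seq_len(k)) {
      for (ky in seq_len(k)) {
        idx[p:(p + n_pos - 1L)] <- zoff + (x0 + kx - 1L) * hp + (y0 + ky)
        p <- p + n_pos
      }
    }
  }
  res <- list(idx = idx, out_h = out_h, out_w = out_w, n_pos = n_pos,
              hp = hp, wp = w + 2L * pad)
  .im2col_cache[[key]] <- res
  res
}

im2col <- function(img, k, stride, pad) {
  d <- dim(img)
  map <- im2col_index(d[1], d[2], d[3], k, stride, pad)
  z <- array(0, c(map$hp, map$wp, d[3]))
  z[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), ] <- img
  matrix(z[map$idx], nrow = map$n_pos)
}

conv_block_forward <- function(img, kernel, bias, stride = 2L) {
  k <- round(sqrt(nrow(kernel) / dim(img)[3]))
  cols <- im2col(img, k, stride, 1L)
  pre <- cols %*% kernel + rep(bias, each = nrow(cols))
  out <- pre * (pre > 0)
  d <- dim(img)
  map <- im2col_index(d[1], d[2], d[3], k, stride, 1L)
  array(out, c(map$out_h, map$out_w, ncol(kernel)))
}

#' Create a frame encoder
#'
#' @param type `"tiny"` (64-px frames, 8x8x64 grid), `"deep"` (224-px
#'   frames, 7x7x2048 grid), or `"custom"`.
#' @param seed integer seed for weight initialization.
#' @param fn for `type = "custom"`: a function `frame -> H x W x C_e`
#'   array; the penultimate and final features coincide and the last
#'   block is not trainable.
#' @param frame_size,H,W,C_e shape metadata for `type = "custom"`.
#' @return a `frame_encoder` object.
#' @export
frame_encoder <- function(type = c("tiny", "deep", "custom"), seed = 1L,
                          fn = NULL, frame_size = NULL, H = NULL, W = NULL,
                          C_e = NULL) {
  type <- match.arg(type)
  if (type == "custom") {
    stopifnot(is.function(fn), !is.null(frame_size), !is.null(H),
              !is.null(W), !is.null(C_e))
    return(structure(list(type = type, fn = fn, frame_size = frame_size,
                          H = H, W = W, C_e = C_e, C_penult = C_e,
                          last = NULL),
                     class = "frame_encoder"))
  }
  set.seed(seed)
  spec <- if (type == "tiny") {
    list(frame_size = 64L, chans = c(3L, 8L, 16L, 32L), C_e = 64L,
         H = 8L, W = 8L)
  } else {
    list(frame_size = 224L, chans = c(3L, 16L, 32L, 64L, 128L, 256L),
         C_e = 2048L, H = 7L, W = 7L)
  }
  nb <- length(spec$chans) - 1L
  blocks <- lapply(seq_len(nb), function(i) {
    cin <- spec$chans[i]; cout <- spec$chans[i + 1L]
    list(K = matrix(stats::rnorm(9L * cin * cout, sd = sqrt(2 / (9 * cin))),
                    9L * cin, cout),
         b = numeric(cout))
  })
  Cp <- spec$chans[length(spec$chans)]
  last <- list(W = matrix(stats::rnorm(Cp * spec$C_e, sd = sqrt(2 / Cp)),
                          Cp, spec$C_e),
               b = numeric(spec$C_e))
  structure(list(type = type, frame_size = spec$frame_size,
                 H = spec$H, W = spec$W, C_e = spec$C_e, C_penult = Cp,
                 blocks = blocks, last = last),
            class = "frame_encoder")
}

#' Encode one frame to a feature grid
#'
#' @param encoder a [frame_encoder()].
#' @param img `h x w x 3` array matching the encoder's frame size.
#' @param stage `"final"` for the `(H*W) x C_e` cell matrix after the last
#'   block, `"penult"` for the cell matrix before it.
#' @return `(H*W) x C` cell matrix (row-major cells).
#' @export
encode_frame <- function(encoder, img, stage = c("final", "penult")) {
  stage <- match.arg(stage)
  if (encoder$type == "custom") {
    return(grid_to_cells(encoder$fn(img)))
  }
  d <- dim(img)
  if (d[1] != encoder$frame_size || d[2] != encoder$frame_size) {
    stop("frame size ", d[1], "x", d[2], " does not match encoder input ",
         encoder$frame_size)
  }
  x <- img
  for (b in encoder$blocks) x <- conv_block_forward(x, b$K, b$b)
  P <- grid_to_cells(x)
  if (stage == "penult") return(P)
  encoder_last_block(P, encoder$last$W, encoder$last$b)
}

# last encoder block: per-cell dense + ReLU; autograd-compatible so it can
# be trained when the selection-scheme policy unfreezes it
encoder_last_block <- function(P, W, b) {
  ag_dense(P, W, b, "relu")
}

#' Precompute per-frame encoder features for a set of videos
#'
#' Encodes every frame of every video once (the convolutional stack is
#' frozen, so features are reusable across epochs) and returns a cache
#' used by the training and prediction routines.  Features are stored at
#' the penultimate stage so the trainable last block can still be applied.
#'
#' @param records manifest data frame.
#' @param encoder a [frame_encoder()].
#' @param verbose print progress.
#' @return an environment mapping video_id to a `frames x cells x C`
#'   array.
#' @export
encode_videos <- function(records, encoder, verbose = FALSE) {
  cache <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(records))) {
    rec <- records[r, ]
    files <- list_frames(rec$frame_dir)
    arr <- array(0, c(length(files), encoder$H * encoder$W,
                      encoder$C_penult))
    for (i in seq_along(files)) {
      arr[i, , ] <- encode_frame(encoder, read_frame(files[i]), "penult")
    }
    cache[[rec$video_id]] <- arr
    if (verbose) message("encoded ", rec$video_id, " (", length(files),
                         " frames)")
  }
  cache
}
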