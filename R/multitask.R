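# Multi-task keypoint-localization branch: a transposed-convolution decoder
# on the attention-weighted feature map, trained against Gaussian heat-map
# targets with mean squared error.

#' Gaussian target heat map for keypoint supervision
#'
#' The target value at pixel q is `max_k exp(-||q - tip_k||^2 / (2 sigma^2))`
#' (peak 1 at each keypoint, isotropic Gaussian falloff, maximum taken
#' across tips).  No keypoints give an all-zero map.
#'
#' @param keypoints matrix or data frame with columns `x`, `y` (0-based
#'   pixels at the output resolution); `NULL`/empty allowed.
#' @param out_size output size in pixels: scalar or `c(h, w)`.
#' @param sigma Gaussian scale in pixels (> 0; default 6 at 224-px frames).
#' @return `h x w` matrix with values in \[0, 1\].
#' @export
gaussian_target_heatmap <- function(keypoints, out_size, sigma = 6) {
  if (sigma <= 0) stop("sigma must be positive")
  if (length(out_size) == 1L) out_size <- c(out_size, out_size)
  h <- out_size[1]; w <- out_size[2]
  M <- matrix(0, h, w)
  if (is.null(keypoints) || NROW(keypoints) == 0L) return(M)
  kp <- as.data.frame(keypoints)
  ys <- matrix(0:(h - 1), h, w)
  xs <- matrix(0:(w - 1), h, w, byrow = TRUE)
  for (i in seq_len(nrow(kp))) {
    d2 <- (xs - kp$x[i])^2 + (ys - kp$y[i])^2
    M <- pmax(M, exp(-d2 / (2 * sigma^2)))
  }
  M
}

#' Create keypoint-decoder parameters
#'
#' A stack of `n_layers` transposed convolutions (kernel 2, stride 2), each
#' doubling the spatial resolution, mapping the attention-weighted feature
#' map to a one-channel nonnegative heat map.  The reference channel
#' schedule for a 2048-channel input is 2048 -> 256 -> 128 -> 64 -> 32 -> 1.
#'
#' @param C_in input channel count (`C_e`).
#' @param n_layers number of 2x upsampling stages (reference 5:
#'   7x7 -> 224x224).
#' @param channels output channels per stage (last must be 1); defaults to
#'   the reference schedule truncated/scaled to `n_layers`.
#' @param seed integer seed.
#' @return decoder parameter list.
#' @export
make_decoder_params <- function(C_in, n_layers = 5L, channels = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(channels)) {
    full <- c(256L, 128L, 64L, 32L, 1L)
    channels <- if (n_layers == 5L) full else {
      c(pmin(rev(2L^(seq_len(n_layers - 1L) + 2L)), C_in), 1L)
    }
  }
  if (length(channels) != n_layers) stop("channels must have n_layers entries")
  if (channels[n_layers] != 1L) stop("last decoder stage must have 1 channel")
  cin <- c(C_in, channels[-n_layers])
  layers <- lapply(seq_len(n_layers), function(i) {
    list(K = matrix(stats::rnorm(cin[i] * 4L * channels[i],
                                 sd = sqrt(2 / (cin[i] * 4))),
                    cin[i], 4L * channels[i]),
         b = numeric(4L * channels[i]))
  })
  structure(list(C_in = C_in, n_layers = n_layers, channels = channels,
                 layers = layers), class = "decoder_params")
}

# cache of pixel-shuffle index maps keyed by "H,W,Co"
.ps_cache <- new.env(parent = emptyenv())

# Index map turning an (H*W) x (4*Co) matrix (cells row-major, columns
# ordered [sub-position q = dm*2+dn][channel]) into a (2H*2W) x Co matrix.
pixelshuffle_index <- function(H, W, Co) {
  key <- paste(H, W, Co, sep = ",")
  if (!is.null(.ps_cache[[key]])) return(.ps_cache[[key]])
  H2 <- 2L * H; W2 <- 2L * W
  # for each output element (cell2 row-major, co), find source flat index
  co <- rep(seq_len(Co) - 1L, each = H2 * W2)
  cell2 <- rep(seq_len(H2 * W2) - 1L, times = Co)
  r2 <- cell2 %/% W2
  c2 <- cell2 %% W2
  m <- r2 %/% 2L; dm <- r2 %% 2L
  n <- c2 %/% 2L; dn <- c2 %% 2L
  q <- dm * 2L + dn
  cell1 <- m * W + n
  col1 <- q * Co + co
  idx <- col1 * (H * W) + cell1 + 1L  # column-major flat index of input
  .ps_cache[[key]] <- idx
  idx
}

# one transposed-conv stage (kernel 2, stride 2) on cell-matrix input
decoder_stage <- function(X, K, b, H, W, Co, final) {
  Y <- ag_dense(X, K, b, if (final) "none" else "relu")
  out <- ag_reindex(Y, pixelshuffle_index(H, W, Co), c(4L * H * W, Co))
  if (final) ag_relu(out) else out
}

#' Keypoint decoder forward pass
#'
#' Upsamples an attention-weighted `H x W x C_e` feature map through the
#' transposed-convolution stack to a one-channel nonnegative heat map of
#' size `(2^L * H) x (2^L * W)`.
#'
#' @param fmap `H x W x C_e` array or `(H*W) x C_e` cell matrix (row-major
#'   cells); in the latter case supply `grid` as `c(H, W)`.
#' @param params from [make_decoder_params()].
#' @param grid grid size `c(H, W)` when `fmap` is a cell matrix.
#' @return predicted heat map matrix at the upsampled resolution.
#' @export
keypoint_decoder_forward <- function(fmap, params, grid = NULL) {
  if (length(dim(vof(fmap))) == 3L) {
    grid <- dim(fmap)[1:2]
    X <- grid_to_cells(fmap)
  } else {
    if (is.null(grid)) stop("grid = c(H, W) required for cell-matrix input")
    X <- fmap
  }
  if (ncol(vof(X)) != params$C_in) {
    stop("feature channels ", ncol(vof(X)), " do not match decoder C_in ",
         params$C_in)
  }
  res <- decoder_run(X, params, grid[1], grid[2])
  cells_to_grid(as.vector(vof(res$X)), res$H, res$W)
}

# core decoder loop; X may be a node (training) or plain matrix; `pget`
# optionally overrides per-layer parameters with autograd leaf nodes
# (names "dec.l<i>.K" / "dec.l<i>.b").
# Returns list(X = cells x 1 output, H, W) at the final resolution.
decoder_run <- function(X, params, H, W, pget = NULL) {
  layer_params <- function(i, part) {
    if (!is.null(pget)) {
      nd <- pget(paste0("dec.l", i, ".", part))
      if (!is.null(nd)) return(nd)
    }
    params$layers[[i]][[part]]
  }
  for (i in seq_len(params$n_layers)) {
    Co <- params$channels[i]
    X <- decoder_stage(X, layer_params(i, "K"), layer_params(i, "b"),
                       H, W, Co, final = i == params$n_layers)
    H <- 2L * H; W <- 2L * W
  }
  list(X = X, H = H, W = W)
}

#' Combined multi-task loss
#'
#' Adds the keypoint-localization mean-squared-error term to the combined
#' classification/supervision loss: `L + mu * MSE(pred, target)`.
#'
#' @param L combined loss from [combined_loss()].
#' @param pred predicted heat map.
#' @param target Gaussian target heat map (same shape).
#' @param mu nonnegative task weight (default 1).
#' @return scalar loss.
#' @export
multitask_loss <- function(L, pred, target, mu = 1) {
  p <- vof(pred); t <- vof(target)
  if (!identical(dim(p), dim(t))) stop("prediction and target shapes differ")
  L + mu * mean((p - t)^2)
}
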