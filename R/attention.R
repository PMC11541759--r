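# Spatial attention over per-frame feature grids, trajectory heat-map
# targets, Dice supervision, and the two attending schemes.
#
# Grid convention: a frame's feature grid is an H x W x C array; internally
# cells are flattened row-major (cell index = (row-1)*W + col) into a
# (H*W) x C matrix.  Image coordinates are 0-based, x rightward (columns),
# y downward (rows), pixel units, origin at the top-left pixel.

# flatten H x W x C grid to (H*W) x C cell matrix, row-major cells
grid_to_cells <- function(x) {
  stopifnot(length(dim(x)) == 3L)
  d <- dim(x)
  matrix(aperm(x, c(2L, 1L, 3L)), nrow = d[1] * d[2], ncol = d[3])
}

# inverse of grid_to_cells for a single channel (vector of H*W weights)
cells_to_grid <- function(v, H, W) {
  t(matrix(v, nrow = W, ncol = H))
}

#' Create spatial-attention scoring parameters
#'
#' The attention scorer maps each cell's appearance feature (length `C_e`)
#' and, optionally, the temporal model's previous hidden state (length
#' `C_h`) to a scalar score through a shared hidden layer of width `C_att`
#' with a ReLU activation.  Reference dimensions are `C_e = 2048`,
#' `C_att = 1024`, `C_h = 1024`.
#'
#' @param C_e appearance feature length per grid cell.
#' @param C_att width of the attention hidden layer.
#' @param C_h hidden-state length of the temporal model, or `NULL` when the
#'   scorer takes no temporal input (e.g. with a transformer backbone).
#' @param seed integer seed for weight initialization.
#' @return a list with matrices `Ma` (`C_e x C_att`), `Ms`
#'   (`C_h x C_att` or `NULL`) and vector `Mo` (length `C_att`).
#' @export
make_attention_params <- function(C_e, C_att, C_h = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(
    Ma = matrix(stats::rnorm(C_e * C_att, sd = sqrt(2 / C_e)), C_e, C_att),
    Ms = if (!is.null(C_h)) {
      matrix(stats::rnorm(C_h * C_att, sd = sqrt(2 / C_h)), C_h, C_att)
    },
    Mo = stats::rnorm(C_att, sd = sqrt(2 / C_att))
  )
}

check_attention_shapes <- function(features, params, hidden_state) {
  if (ncol(features) != nrow(params$Ma)) {
    stop("feature length ", ncol(features), " does not match attention C_e ",
         nrow(params$Ma))
  }
  if (!is.null(hidden_state)) {
    if (is.null(params$Ms)) {
      stop("hidden state supplied but attention parameters have no Ms map")
    }
    if (length(hidden_state) != nrow(params$Ms)) {
      stop("hidden state length ", length(hidden_state),
           " does not match attention C_h ", nrow(params$Ms))
    }
  }
  invisible(TRUE)
}

#' Spatial attention weights for one frame
#'
#' Scores every cell of a frame's feature grid and softmax-normalizes the
#' scores over the grid, producing nonnegative weights that sum to 1.  The
#' score of cell (m, n) with feature p is `Mo' relu(Ma' p + Ms' h)`;
#' the hidden-state term is dropped when `hidden_state` is `NULL`.
#'
#' @param features `H x W x C_e` array (one frame's feature grid), or an
#'   `(H*W) x C_e` cell matrix.
#' @param params attention parameters from [make_attention_params()].
#' @param hidden_state optional temporal hidden state (length `C_h`).
#' @return `H x W` matrix of attention weights summing to 1 (or a vector of
#'   cell weights if `features` was given as a cell matrix).
#' @export
spatial_attention_scores <- function(features, params, hidden_state = NULL) {
  as_grid <- length(dim(features)) == 3L
  P <- if (as_grid) grid_to_cells(features) else features
  check_attention_shapes(P, params, hidden_state)
  att <- ag_attention_step(P, hidden_state, params$Ma, params$Ms, params$Mo)
  if (as_grid) cells_to_grid(att, dim(features)[1], dim(features)[2]) else att
}

#' Binary trajectory heat map for one frame
#'
#' Marks each cell of an `H x W` grid with 1 if at least one instrument tip
#' falls inside it, else 0.  The image is partitioned into `H x W` equal
#' cells and a tip at pixel (x, y) maps to cell
#' (`floor(y / (image_h/H))`, `floor(x / (image_w/W))`) (0-based rows and
#' columns).  Multiple tips in a cell still yield 1.  Out-of-bounds
#' keypoints are dropped with a warning.  An all-zero map (no instrument in
#' the frame) is legal.
#'
#' @param keypoints matrix or data frame with columns `x`, `y` (0-based
#'   pixel coordinates); `NULL` or zero rows give an all-zero map.
#' @param image_size image size in pixels: scalar (square) or `c(h, w)`.
#' @param grid_size grid size: scalar or `c(H, W)`.
#' @return `H x W` binary matrix.
#' @export
build_trajectory_heatmap <- function(keypoints, image_size, grid_size) {
  if (length(image_size) == 1L) image_size <- c(image_size, image_size)
  if (length(grid_size) == 1L) grid_size <- c(grid_size, grid_size)
  H <- grid_size[1]; W <- grid_size[2]
  B <- matrix(0, H, W)
  if (is.null(keypoints) || NROW(keypoints) == 0L) return(B)
  kp <- as.data.frame(keypoints)
  x <- kp$x; y <- kp$y
  ok <- x >= 0 & x < image_size[2] & y >= 0 & y < image_size[1] &
    !is.na(x) & !is.na(y)
  if (any(!ok)) {
    warning(sum(!ok), " keypoint(s) out of image bounds dropped")
  }
  if (!any(ok)) return(B)
  col <- floor(x[ok] / (image_size[2] / W))
  row <- floor(y[ok] / (image_size[1] / H))
  B[cbind(row + 1L, col + 1L)] <- 1
  B
}

#' Soft Dice loss between attention maps and trajectory heat maps
#'
#' `1 - (2 * sum(A*B) + eps) / (sum(A) + sum(B) + eps)`, computed jointly
#' over all cells of all frames (one Dice coefficient per clip, not a
#' per-frame average).  The attention map is continuous, so the Dice
#' coefficient is "soft"; the smoothing constant `eps` keeps the loss
#' defined when the target is all-zero.
#'
#' @param attention numeric array of attention weights (any shape).
#' @param target binary array of the same shape.
#' @param eps smoothing constant (default 1).
#' @return scalar loss in \[0, 1\].
#' @export
soft_dice_loss <- function(attention, target, eps = 1) {
  a <- vof(attention); b <- vof(target)
  if (!identical(dim(a), dim(b)) || length(a) != length(b)) {
    stop("attention and target shapes differ")
  }
  inter <- sum(a * b)
  1 - (2 * inter + eps) / (sum(a) + sum(b) + eps)
}

#' Combined classification and attention-supervision loss
#'
#' `L = L_BCE + lambda * L_Dice`.  `lambda = 0` disables the attention
#' supervision (the unsupervised-attention variants); the reference value
#' is 0.5.
#'
#' @param l_bce binary cross-entropy loss (scalar).
#' @param l_dice soft Dice loss (scalar).
#' @param lambda nonnegative supervision weight.
#' @return scalar combined loss.
#' @export
combined_loss <- function(l_bce, l_dice, lambda = 0.5) {
  stopifnot(is.finite(l_bce), is.finite(l_dice), lambda >= 0)
  l_bce + lambda * l_dice
}

#' Attend by aggregation
#'
#' The attention-weighted cell features are summed over the grid:
#' `x_att = sum_{m,n} att[m,n] * p[m,n]`.  With uniform attention this is
#' the arithmetic mean of the cell features (average pooling).
#'
#' @param attention `H x W` weight matrix (or vector of cell weights).
#' @param features `H x W x C_e` array (or `(H*W) x C_e` cell matrix in the
#'   same cell order as `attention`).
#' @return attended feature vector of length `C_e`.
#' @export
attend_aggregate <- function(attention, features) {
  P <- if (length(dim(features)) == 3L) grid_to_cells(features) else features
  a <- if (is.matrix(attention)) as.vector(t(attention)) else attention
  if (length(a) != nrow(P)) stop("attention and feature grid sizes differ")
  as.vector(crossprod(P, a))
}

#' Attend by selection
#'
#' Returns the feature vector of the single cell with maximal attention.
#' Ties are broken row-major (first occurrence).  Equals
#' [attend_aggregate()] when the attention is one-hot.
#'
#' @inheritParams attend_aggregate
#' @return attended feature vector of length `C_e` with attribute `cell`
#'   (0-based row-major index of the selected cell).
#' @export
attend_select <- function(attention, features) {
  P <- if (length(dim(features)) == 3L) grid_to_cells(features) else features
  a <- if (is.matrix(attention)) as.vector(t(attention)) else attention
  if (length(a) != nrow(P)) stop("attention and feature grid sizes differ")
  i <- which.max(a)
  out <- P[i, ]
  attr(out, "cell") <- i - 1L
  out
}

# weighted feature map x~ = att * P (rows of P scaled by attention weights);
# used by the multitask decoder branch
ag_rowscale <- function(P, att) {
  Pv <- vof(P); av <- vof(att)
  out <- Pv * av
  if (!tape_active() || !node_args(P, att)) return(out)
  new_node(out, function(g) {
    if (is_node(P)) accum(P, g * av)
    if (is_node(att)) accum(att, rowSums(g * Pv))
  })
}
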