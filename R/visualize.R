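# Export of attention maps as grayscale images and colormap overlays.

jet_colors <- function(v) {
  ramp <- grDevices::colorRamp(c("#00007F", "blue", "cyan", "yellow",
                                 "red", "#7F0000"))
  ramp(pmin(pmax(v, 0), 1)) / 255
}

#' Overlay a spatial attention map on a frame
#'
#' Upsamples the `H x W` attention map to the frame resolution (nearest
#' neighbour), maps it through a jet colormap, and alpha-blends it over
#' the frame.
#'
#' @param frame `h x w x 3` array in \[0, 1\].
#' @param attention `H x W` attention weight matrix.
#' @param alpha blend weight of the colormap layer.
#' @return `h x w x 3` array.
#' @export
attention_overlay <- function(frame, attention, alpha = 0.45) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  a <- attention / max(attention, 1e-12)
  ry <- ceiling(seq_len(h) / (h / nrow(a)))
  rx <- ceiling(seq_len(w) / (w / ncol(a)))
  up <- a[ry, rx, drop = FALSE]
  cols <- jet_colors(as.vector(up))
  out <- frame
  for (c in 1:3) {
    out[, , c] <- (1 - alpha) * frame[, , c] +
      alpha * matrix(cols[, c], h, w)
  }
  out
}

#' Save per-frame attention maps
#'
#' Writes one grayscale PNG per frame (weights rescaled to the unit
#' interval per frame) and, when frames are given, jet-colormap overlays.
#'
#' @param attention list of per-frame `H x W` matrices (or cell-weight
#'   vectors with `grid` supplied).
#' @param dir output directory.
#' @param frames optional list of frames for overlays.
#' @param grid `c(H, W)` when `attention` holds cell vectors.
#' @return output directory, invisibly.
#' @export
save_attention_maps <- function(attention, dir, frames = NULL, grid = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(attention)) {
    a <- attention[[i]]
    if (is.null(dim(a))) {
      if (is.null(grid)) stop("grid required for cell-weight vectors")
      a <- cells_to_grid(a, grid[1], grid[2])
    }
    png::writePNG(a / max(a, 1e-12),
                  file.path(dir, sprintf("attention_%06d.png", i - 1L)))
    if (!is.null(frames)) {
      png::writePNG(attention_overlay(frames[[i]], a),
                    file.path(dir, sprintf("overlay_%06d.png", i - 1L)))
    }
  }
  invisible(dir)
}
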