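# Dataset file formats: manifest TSV, keypoint CSV, numbered PNG frames.

#' Write a dataset manifest
#'
#' Tab-separated with header
#' `video_id,domain,label,n_frames,frame_dir,keypoint_file`.
#'
#' @param manifest data frame of video records.
#' @param path output TSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a dataset manifest
#'
#' @param path manifest TSV path.
#' @return data frame with one row per video.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("video_id", "domain", "label", "n_frames", "frame_dir",
            "keypoint_file")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns ", paste(need, collapse = ", "))
  }
  m
}

#' Read a keypoint annotation table
#'
#' CSV with header `video_id,frame_index,instrument_id,x,y`; coordinates
#' are 0-based pixels.  A missing or `NA` path returns an empty table
#' (legal: the target dataset carries no tip annotations).
#'
#' @param path keypoint CSV path (or `NA`).
#' @return data frame (possibly with zero rows).
#' @export
read_keypoints <- function(path) {
  empty <- data.frame(video_id = character(), frame_index = integer(),
                      instrument_id = integer(), x = numeric(),
                      y = numeric())
  if (length(path) != 1L || is.na(path) || !nzchar(path) || !file.exists(path)) {
    return(empty)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' List a video's frame files in index order
#'
#' @param frame_dir directory of zero-padded numbered PNG frames.
#' @return character vector of file paths.
#' @export
list_frames <- function(frame_dir) {
  f <- list.files(frame_dir, pattern = "\\.png$", full.names = TRUE)
  sort(f)
}

#' Read one RGB frame
#'
#' @param path PNG path.
#' @return `h x w x 3` array in \[0, 1\].
#' @export
read_frame <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE][, , 1:3]
}
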