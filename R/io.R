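# Image and table I/O: grayscale PNG with a JSON sidecar carrying the
# standardization metadata, CSV arrays, and pair-table CSV.

#' Write a standardized image as grayscale PNG with a JSON sidecar
#'
#' The image is affinely mapped from `range` to `[0, 1]` for the 8-bit PNG;
#' the sidecar (`<path>.json`) stores the mapping and the image's mean and
#' RMS so that [read_image_png()] restores the original values up to
#' quantization.
#'
#' @param image numeric matrix
#' @param path output PNG path
#' @param range intensity range mapped onto the PNG's dynamic range
#' @return invisibly, the sidecar metadata list
#' @export
write_image_png <- function(image, path, range = c(-1, 1)) {
  scaled <- (image - range[1]) / diff(range)
  scaled[scaled < 0] <- 0; scaled[scaled > 1] <- 1
  png::writePNG(scaled, path, dpi = NULL)
  meta <- list(lo = range[1], hi = range[2],
               mean = mean(image), rms = sqrt(mean((image - mean(image))^2)),
               rows = nrow(image), cols = ncol(image))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(meta)
}

#' Read a grayscale PNG written by [write_image_png()]
#'
#' @param path PNG path (sidecar `<path>.json` must exist)
#' @return numeric matrix in original units
#' @export
read_image_png <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * (meta$hi - meta$lo) + meta$lo
}

#' Read an image from a CSV array
#'
#' @param path CSV of numbers, one image row per line
#' @return numeric matrix
#' @export
read_image_csv <- function(path) {
  as.matrix(utils::read.csv(path, header = FALSE))
}

#' Write an image as a CSV array
#'
#' @param image numeric matrix
#' @param path output path
#' @export
write_image_csv <- function(image, path) {
  utils::write.table(image, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
}

#' Read a connectivity pair table from CSV
#'
#' Required columns: presyn_id, postsyn_id, connected, n_syn, co_travel_mm;
#' any additional metric columns are kept.
#'
#' @param path CSV path
#' @return validated data.frame
#' @export
read_pair_table <- function(path) {
  tab <- utils::read.csv(path)
  tab$connected <- as.logical(tab$connected)
  check_pair_table(tab)
  tab
}

#' Write a pair table to CSV
#'
#' @param table pair table data.frame
#' @param path output path
#' @export
write_pair_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
}
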