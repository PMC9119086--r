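# Raster input/output for section stacks.

#' Read a grayscale section image
#'
#' @param path a TIFF or PNG file
#' @return height x width numeric matrix in \[0, 1\]
#' @export
readSectionImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Read a serial-section stack
#'
#' Accepts a multipage TIFF or a character vector of numbered
#' single-section files.
#'
#' @param paths one multipage TIFF path or several image paths
#' @return h x w x n array
#' @export
readSectionStack <- function(paths) {
  if (length(paths) == 1 &&
      tolower(tools::file_ext(paths)) %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(paths, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
    return(simplify2array(pages))
  }
  simplify2array(lapply(paths, readSectionImage))
}

#' Write a serial-section stack
#'
#' @param stack h x w x n array (values clamped to \[0, 1\])
#' @param path output multipage TIFF path
#' @export
writeSectionStack <- function(stack, path) {
  stack <- asStackArray(stack)
  pages <- lapply(seq_len(dim(stack)[3]), function(z)
    pmin(pmax(stack[, , z], 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}
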