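#' Read / write RGB images
#'
#' Thin wrappers over the png and tiff packages dispatching on the file
#' extension. Images are arrays (height x width x 3) with values in
#' \[0,1\].
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @param img RGB array.
#' @rdname read_image
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, path),
         tif = ,
         tiff = tiff::writeTIFF(img, path),
         stop("unsupported image format: ", ext))
  invisible(path)
}
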