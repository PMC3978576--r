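#' Grayscale section image with physical pixel size
#'
#' A `section_image` wraps a 2-D grayscale pixel matrix together with the
#' physical pixel size in millimetres, the patellar region the section was
#' taken from (lateral, central or medial facet) and its position in the
#' 1-mm slide series. All lengths reported downstream are converted to mm
#' through `pixel_size_mm`; the pixel grid is row-major with origin at the
#' top-left corner.
#'
#' @param pixels numeric matrix of grayscale values (0-255 scale).
#' @param pixel_size_mm physical edge length of one pixel, in mm.
#' @param region one of `"lateral"`, `"central"`, `"medial"`.
#' @param slide_index position of the section in the 1-mm slide series
#'   (integer, >= 1).
#' @return An object of class `section_image`.
#' @examples
#' img <- section_image(matrix(runif(64, 0, 255), 8, 8), pixel_size_mm = 0.05)
#' dim(img$pixels)
#' @export
section_image <- function(pixels, pixel_size_mm, region = "central", slide_index = 1L) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || any(dim(pixels) < 1L))
    stop_param("pixels must be a non-empty numeric matrix")
  check_scalar_pos(pixel_size_mm, "pixel_size_mm")
  check_region(region)
  if (slide_index < 1) stop_param("slide_index must be >= 1")
  structure(
    list(pixels = pixels, pixel_size_mm = pixel_size_mm,
         region = region, slide_index = as.integer(slide_index)),
    class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("<section_image> %d x %d px, %.4g mm/px (%.2f x %.2f mm), region %s, slide %d\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_mm,
              nrow(x$pixels) * x$pixel_size_mm, ncol(x$pixels) * x$pixel_size_mm,
              x$region, x$slide_index))
  invisible(x)
}

#' Binary trabeculae/marrow mask
#'
#' Boolean grid on the same pixel lattice as its source [section_image()];
#' `TRUE` marks trabecular bone, `FALSE` marrow.
#'
#' @param bits logical matrix (`TRUE` = bone).
#' @param pixel_size_mm physical pixel size inherited from the source image.
#' @param region region label inherited from the source image.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(bits, pixel_size_mm, region = "central") {
  if (!is.matrix(bits) || !is.logical(bits) || any(dim(bits) < 1L))
    stop_param("bits must be a non-empty logical matrix")
  check_scalar_pos(pixel_size_mm, "pixel_size_mm")
  check_region(region)
  structure(list(bits = bits, pixel_size_mm = pixel_size_mm, region = region),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %.4g mm/px, bone fraction %.3f\n",
              nrow(x$bits), ncol(x$bits), x$pixel_size_mm, mean(x$bits)))
  invisible(x)
}

#' Read a section image from a TIFF or PNG file
#'
#' Grayscale TIFF/PNG pixels are rescaled to the 0-255 range; RGB input is
#' averaged to gray. The physical pixel size is not stored in either format
#' by this package, so it must be supplied.
#'
#' @inheritParams section_image
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @return A [section_image()].
#' @export
read_section_image <- function(path, pixel_size_mm, region = "central", slide_index = 1L) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop_param("unsupported image format: .", ext))
  if (length(dim(arr)) == 3L) arr <- apply(arr[, , seq_len(min(3L, dim(arr)[3])), drop = FALSE], c(1, 2), mean)
  section_image(arr * 255, pixel_size_mm, region, slide_index)
}

#' Write a section image or mask to TIFF or PNG
#'
#' Images are written as 8-bit grayscale; masks as black/white.
#'
#' @param x a [section_image()] or [binary_mask()].
#' @param path output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_section_image <- function(x, path) {
  g <- if (inherits(x, "binary_mask")) x$bits * 1.0 else pmin(pmax(x$pixels / 255, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(g, path, bits.per.sample = 8L),
    png = png::writePNG(g, path),
    stop_param("unsupported image format: .", ext))
  invisible(path)
}
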