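# Separable convolution helpers for the Marr-Hildreth chain.
#
# The LoG kernel factors as L(x, y) = g''(x) g(y) + g(x) g''(y), so the 2-D
# convolution is done as two separable passes. Kernels are sampled from the
# analytic Gaussian and its second derivative, truncated at 4 sigma; the
# second-derivative samples are recentred to sum exactly to zero so a
# constant image maps to an exactly zero response.

log_kernels <- function(sigma_px) {
  r <- max(1L, ceiling(4 * sigma_px))
  x <- seq(-r, r)
  e <- exp(-x^2 / (2 * sigma_px^2))
  g <- e / sum(e)
  g2 <- (x^2 - sigma_px^2) / sigma_px^4 * e / sum(e)
  g2 <- g2 - mean(g2)
  list(g = g, g2 = g2, radius = r)
}

# convolve each column of m with symmetric kernel k, replicating edges
conv_cols <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  mp <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(nrow(m), r), , drop = FALSE])
  out <- stats::filter(mp, k, method = "convolution", sides = 2)
  matrix(out[(r + 1L):(r + nrow(m)), ], nrow(m), ncol(m))
}

sep_conv <- function(m, k_row, k_col) {
  t(conv_cols(t(conv_cols(m, k_row)), k_col))
}

# full 2-D LoG response; exported through log_filter()
log_response <- function(m, sigma_px) {
  k <- log_kernels(sigma_px)
  sep_conv(m, k$g2, k$g) + sep_conv(m, k$g, k$g2)
}

# plain Gaussian smoothing (shared with the random-field generator)
gaussian_smooth <- function(m, sigma_px) {
  k <- log_kernels(max(sigma_px, 0.5))
  sep_conv(m, k$g, k$g)
}

#' Laplacian-of-Gaussian filtering of a section image
#'
#' Convolves the image with the Laplacian-of-Gaussian (Marr-Hildreth) kernel
#' at physical scale `sigma_mm`: Gaussian smoothing combined with the
#' second-derivative operator in one filter. The response is negative inside
#' regions brighter than their surround and positive inside darker regions;
#' its zero crossings trace intensity edges. A constant image maps to an
#' exactly zero response.
#'
#' @param image a [section_image()].
#' @param sigma_mm Gaussian scale in mm; must be at least one pixel.
#' @return A numeric matrix of the signed filter response, same size as the
#'   image.
#' @seealso [zero_crossing_binarize()]
#' @export
log_filter <- function(image, sigma_mm = 3 * image$pixel_size_mm) {
  stopifnot(inherits(image, "section_image"))
  check_scalar_pos(sigma_mm, "sigma_mm")
  if (sigma_mm < image$pixel_size_mm)
    stop_param("sigma_mm (", sigma_mm, ") is below the pixel size (",
               image$pixel_size_mm, " mm): filter scale unresolvable")
  log_response(image$pixels, sigma_mm / image$pixel_size_mm)
}

#' Binarize a LoG response at its zero crossings
#'
#' The zero-crossing contours of the LoG response partition the image into
#' sign regions; the binary trabeculae/marrow image is the two-colouring of
#' that partition by local brightness. Each connected sign region is
#' classified from its mean source intensity against an Otsu threshold on
#' the image: with the default `polarity = "bright"`, regions brighter than
#' the threshold become bone (the scanner convention where light regions
#' are trabeculae and dark regions marrow). `polarity = "dark"` inverts
#' the convention for stains where bone is dark. Classifying whole sign
#' regions rather than single pixels keeps noise-induced sign flips deep
#' inside homogeneous pools from fragmenting the mask.
#'
#' @param filtered signed LoG response from [log_filter()].
#' @param reference the source [section_image()], used to resolve which
#'   regions are bone.
#' @param polarity `"bright"` (bone is the brighter phase) or `"dark"`.
#' @return A [binary_mask()] on the same grid.
#' @export
zero_crossing_binarize <- function(filtered, reference, polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(reference, "section_image"))
  if (!is.matrix(filtered) || !all(dim(filtered) == dim(reference$pixels)))
    stop_param("filtered response and reference image must have the same shape")
  px <- reference$pixels
  rng <- range(px)
  neg <- filtered < 0
  if (all(neg) || !any(neg)) {
    warning("LoG response has a single sign: no zero crossings; returning a uniform mask")
    bone_all <- mean(px) > (rng[1] + rng[2]) / 2
    if (polarity == "dark") bone_all <- !bone_all
    return(binary_mask(matrix(bone_all, nrow(neg), ncol(neg)),
                       reference$pixel_size_mm, reference$region))
  }
  # label connected sign regions (negative and positive separately)
  lab_neg <- EBImage::bwlabel(neg)
  lab_pos <- EBImage::bwlabel(!neg)
  labels <- ifelse(neg, lab_neg, -lab_pos)
  # threshold separating the two intensity populations
  u <- if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
  thr <- rng[1] + diff(rng) * EBImage::otsu(EBImage::Image(u))
  comp_sum <- rowsum(as.vector(px), group = as.vector(labels))
  comp_n <- rowsum(rep(1, length(labels)), group = as.vector(labels))
  comp_bright <- (comp_sum / comp_n) > thr
  bone <- matrix(comp_bright[match(as.vector(labels), as.numeric(rownames(comp_sum)))],
                 nrow(px), ncol(px))
  if (polarity == "dark") bone <- !bone
  binary_mask(bone, reference$pixel_size_mm, reference$region)
}

#' Detect the cortical shell and the trabecular region of interest
#'
#' Scanned patellar sections carry a thin, nearly solid cortical shell at
#' the tissue margin. The boundary between that shell and the underlying
#' trabecular bone is found by sliding a band of width `band_mm` inwards
#' from each image edge and peeling rows/columns while the band's bone
#' fraction exceeds `shell_threshold`. The trabecular ROI is the interior
#' rectangle left after peeling. If no side shows a shell the full image is
#' returned as ROI with `shell_found = FALSE`.
#'
#' @param mask a [binary_mask()].
#' @param shell_threshold bone fraction above which a band is considered
#'   cortical shell.
#' @param band_mm width of the sliding band in mm.
#' @return An object of class `cortical_boundary`: list with `roi_rows`,
#'   `roi_cols` (index ranges of the trabecular ROI), `polyline` (ROI
#'   outline in pixel coordinates, closed), `depths_px` (peeled depth per
#'   side) and `shell_found`.
#' @export
detect_cortical_boundary <- function(mask, shell_threshold = 0.85, band_mm = 1) {
  stopifnot(inherits(mask, "binary_mask"))
  check_fraction(shell_threshold, "shell_threshold")
  bits <- mask$bits
  w <- max(1L, round(band_mm / mask$pixel_size_mm))

  peel <- function(line_frac) {
    n <- length(line_frac)
    w <- min(w, n)
    cs <- cumsum(line_frac)
    d <- 0L
    for (i in w:min(n, floor(0.4 * n) + w)) {
      frac <- (cs[i] - if (i > w) cs[i - w] else 0) / w
      if (frac > shell_threshold) d <- i else break
    }
    min(d, floor(0.4 * n))
  }

  rf <- rowMeans(bits); cf <- colMeans(bits)
  d_top <- peel(rf); d_bot <- peel(rev(rf))
  d_left <- peel(cf); d_right <- peel(rev(cf))
  depths <- c(top = d_top, bottom = d_bot, left = d_left, right = d_right)
  shell_found <- any(depths > 0)
  if (!shell_found) {
    warning("no cortical shell detected; using the full image as trabecular ROI")
    depths[] <- 0L
  }
  roi_rows <- (depths["top"] + 1L):(nrow(bits) - depths["bottom"])
  roi_cols <- (depths["left"] + 1L):(ncol(bits) - depths["right"])
  r0 <- min(roi_rows); r1 <- max(roi_rows); c0 <- min(roi_cols); c1 <- max(roi_cols)
  structure(list(
    roi_rows = roi_rows, roi_cols = roi_cols,
    polyline = cbind(row = c(r0, r0, r1, r1, r0), col = c(c0, c1, c1, c0, c0)),
    depths_px = depths, shell_found = shell_found),
    class = "cortical_boundary")
}

#' @export
print.cortical_boundary <- function(x, ...) {
  cat(sprintf("<cortical_boundary> ROI rows %d-%d, cols %d-%d; shell %s (depths px: %s)\n",
              min(x$roi_rows), max(x$roi_rows), min(x$roi_cols), max(x$roi_cols),
              if (x$shell_found) "found" else "not found",
              paste(x$depths_px, collapse = "/")))
  invisible(x)
}

#' Segment a section image into a trabeculae/marrow mask
#'
#' Convenience wrapper chaining [log_filter()] and
#' [zero_crossing_binarize()].
#'
#' @inheritParams log_filter
#' @inheritParams zero_crossing_binarize
#' @return A [binary_mask()].
#' @export
segment_trabeculae <- function(image, sigma_mm = 3 * image$pixel_size_mm,
                               polarity = c("bright", "dark")) {
  zero_crossing_binarize(log_filter(image, sigma_mm), image, match.arg(polarity))
}
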