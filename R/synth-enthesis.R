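# Synthetic annotated enthesis cross-sections.
#
# Coordinate frame: x runs across the attachment width (mm), y is the
# perpendicular direction with the tendon on the +y side of the tidemark and
# calcified tissue / bone on the -y side.

# unit normals of a polyline pointing to the tendon (+y) side, tangents by
# central differences
polyline_normals <- function(pts) {
  n <- nrow(pts)
  ip <- pmin(seq_len(n) + 1L, n)
  im <- pmax(seq_len(n) - 1L, 1L)
  tx <- pts[ip, 1] - pts[im, 1]
  ty <- pts[ip, 2] - pts[im, 2]
  len <- sqrt(tx^2 + ty^2)
  cbind(-ty / len, tx / len)
}

#' Generate a synthetic annotated enthesis section
#'
#' Constructs a section annotation with known ground truth: a tidemark
#' polyline (flat, or a sinusoid emulating the undulating mineralization
#' front), a calcified-zone outer boundary offset `cf_mm` from the tidemark
#' along the inward normal (so the true calcified-fibrocartilage thickness
#' is `cf_mm` everywhere), and chondrocyte positions on the tendon side
#' whose furthest member in each of the five measurement bands lies exactly
#' `uf_mm` from the tidemark (the uncalcified-fibrocartilage ground truth).
#'
#' The sinusoid amplitude and wavelength are chosen so the offset curve at
#' distances up to ~1.5 mm stays simple (offset below the minimum radius of
#' curvature).
#'
#' @param region `"lateral"`, `"central"` or `"medial"`.
#' @param cf_mm true calcified-fibrocartilage thickness, mm (> 0).
#' @param uf_mm true uncalcified-fibrocartilage thickness, mm (> 0).
#' @param tidemark_shape `"flat"` or `"sinusoid"`.
#' @param seed integer RNG seed (chondrocyte scatter); fixed seed gives an
#'   identical annotation.
#' @param width_mm attachment width, mm.
#' @param slide_index position in the 1-mm slide series.
#' @param amplitude_mm,wavelength_mm sinusoid parameters.
#' @param n_bands number of measurement bands seeded with chondrocytes.
#' @return An object of class `annotated_section`: list with `region`,
#'   `slide_index`, `tidemark` (k x 2 matrix, mm), `calcified_outer_boundary`
#'   (k x 2), `chondrocytes` (m x 2), `width_mm`, and the ground-truth
#'   `cf_mm`, `uf_mm`.
#' @examples
#' sec <- gen_enthesis_section("central", cf_mm = 1.21, uf_mm = 0.62,
#'                             tidemark_shape = "flat", seed = 1)
#' range(sec$calcified_outer_boundary[, 2])
#' @export
gen_enthesis_section <- function(region, cf_mm, uf_mm,
                                 tidemark_shape = c("flat", "sinusoid"),
                                 seed = 1L, width_mm = 5, slide_index = 1L,
                                 amplitude_mm = 0.1, wavelength_mm = 3,
                                 n_bands = 5L) {
  check_region(region)
  check_scalar_pos(cf_mm, "cf_mm")
  check_scalar_pos(uf_mm, "uf_mm")
  tidemark_shape <- match.arg(tidemark_shape)
  check_scalar_pos(width_mm, "width_mm")

  x <- seq(0, width_mm, length.out = 401L)
  y <- if (tidemark_shape == "flat") rep(0, length(x))
       else amplitude_mm * sin(2 * pi * x / wavelength_mm)
  tidemark <- cbind(x = x, y = y)
  nrm <- polyline_normals(tidemark)
  boundary <- tidemark - cf_mm * nrm

  # chondrocytes: in each band one cell at exactly uf_mm (the furthest
  # recognizable chondrocyte), the rest scattered closer to the tidemark
  chondrocytes <- with_seed(seed, {
    pts <- NULL
    for (b in seq_len(n_bands)) {
      lo <- (b - 1) / n_bands * width_mm
      hi <- b / n_bands * width_mm
      n_extra <- sample(3:6, 1L)
      xs <- stats::runif(n_extra + 1L, lo + 0.02 * width_mm, hi - 0.02 * width_mm)
      ds <- c(uf_mm, stats::runif(n_extra, 0.15 * uf_mm, 0.9 * uf_mm))
      idx <- vapply(xs, function(x0) which.min(abs(tidemark[, 1] - x0)), integer(1))
      pts <- rbind(pts, tidemark[idx, , drop = FALSE] + ds * nrm[idx, , drop = FALSE])
    }
    pts
  })
  colnames(chondrocytes) <- c("x", "y")

  structure(list(region = region, slide_index = as.integer(slide_index),
                 tidemark = tidemark, calcified_outer_boundary = boundary,
                 chondrocytes = chondrocytes, width_mm = width_mm,
                 cf_mm = cf_mm, uf_mm = uf_mm, tidemark_shape = tidemark_shape),
            class = "annotated_section")
}

#' @export
print.annotated_section <- function(x, ...) {
  cat(sprintf("<annotated_section> region %s, slide %d, %s tidemark over %.1f mm, %d chondrocytes\n",
              x$region, x$slide_index, x$tidemark_shape, x$width_mm, nrow(x$chondrocytes)))
  invisible(x)
}
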