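#' Specification of a synthetic trabecular texture
#'
#' Describes a binary trabecular/marrow texture with a controllable bone
#' area fraction and strut thickness, plus the grayscale rendering noise.
#' These stand in for scanned histological bone sections: bone is rendered
#' bright (gray level 200), marrow dark (gray level 50), and additive
#' Gaussian noise emulates scanner noise.
#'
#' @param kind texture family: `"stripes"` (parallel struts),
#'   `"checkerboard"`, `"disk"` (single bone disk), `"gaussian_random_field"`
#'   (thresholded smooth random field, the most histology-like) or
#'   `"plate_lattice"` (orthogonal strut grid).
#' @param target_ba target bone area fraction, strictly in (0, 1).
#' @param strut_thickness_mm strut (trabecula) thickness in mm; must be at
#'   least two pixels so struts are resolvable.
#' @param pixel_size_mm physical pixel size in mm.
#' @param noise_sd standard deviation of additive grayscale noise (0-255
#'   scale), >= 0.
#' @param seed integer RNG seed; a fixed seed gives bit-identical output.
#' @param size_px image side length in pixels (square image).
#' @return An object of class `texture_spec`.
#' @seealso [gen_trabecular_image()]
#' @export
texture_spec <- function(kind = c("gaussian_random_field", "stripes", "checkerboard",
                                  "disk", "plate_lattice"),
                         target_ba = 0.5, strut_thickness_mm = 0.2,
                         pixel_size_mm = 0.025, noise_sd = 10, seed = 1L,
                         size_px = 256L) {
  kind <- match.arg(kind)
  check_fraction(target_ba, "target_ba")
  check_scalar_pos(strut_thickness_mm, "strut_thickness_mm")
  check_scalar_pos(pixel_size_mm, "pixel_size_mm")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop_param("noise_sd must be >= 0")
  if (strut_thickness_mm < 2 * pixel_size_mm)
    stop_param("strut_thickness_mm must be at least 2 pixels (",
               2 * pixel_size_mm, " mm) to be resolvable")
  if (size_px < 8) stop_param("size_px must be at least 8")
  structure(list(kind = kind, target_ba = target_ba,
                 strut_thickness_mm = strut_thickness_mm,
                 pixel_size_mm = pixel_size_mm, noise_sd = noise_sd,
                 seed = as.integer(seed), size_px = as.integer(size_px)),
            class = "texture_spec")
}

# gray levels used when rendering a mask to a grayscale section
GRAY_BONE <- 200
GRAY_MARROW <- 50

#' Generate a synthetic trabecular section with known ground truth
#'
#' Builds the noise-free ground-truth binary texture for the requested
#' family, renders it to a noisy grayscale section image, and returns both
#' together with the ground-truth morphometry of the binary texture. The
#' ground-truth bone area fraction is the exact bone-pixel count fraction of
#' the returned mask.
#'
#' @param spec a [texture_spec()].
#' @param region region label attached to the outputs.
#' @return A list with components `image` ([section_image()]), `mask`
#'   (ground-truth [binary_mask()]) and `truth` (a `morphometry_result`
#'   computed on the ground-truth mask over the full image).
#' @examples
#' out <- gen_trabecular_image(texture_spec("stripes", target_ba = 0.5,
#'   strut_thickness_mm = 0.2, pixel_size_mm = 0.025, noise_sd = 0, size_px = 64))
#' out$truth$BA
#' @export
gen_trabecular_image <- function(spec, region = "central") {
  stopifnot(inherits(spec, "texture_spec"))
  check_region(region)
  n <- spec$size_px
  strut_px <- spec$strut_thickness_mm / spec$pixel_size_mm
  ba <- spec$target_ba

  bits <- with_seed(spec$seed, switch(spec$kind,
    stripes = {
      b <- max(2L, round(strut_px))
      p <- round(b / ba)
      if (p <= b) stop_param("target_ba ", ba, " unreachable for stripes with this strut thickness")
      col_bone <- (seq_len(n) - 1L) %% p < b
      matrix(rep(col_bone, each = n), n, n)
    },
    checkerboard = {
      if (abs(ba - 0.5) > 1e-9)
        stop_param("checkerboard textures have bone fraction 0.5; target_ba ", ba, " unreachable")
      cell <- max(2L, round(strut_px))
      ij <- outer((seq_len(n) - 1L) %/% cell, (seq_len(n) - 1L) %/% cell, "+")
      ij %% 2L == 0L
    },
    disk = {
      r <- sqrt(ba * n^2 / pi)
      if (2 * r < strut_px) stop_param("target_ba too small: disk thinner than strut_thickness")
      if (r > n / 2) stop_param("target_ba ", ba, " unreachable: disk does not fit in the image")
      ctr <- (n + 1) / 2
      d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")
      d2 <= r^2
    },
    gaussian_random_field = {
      field <- gaussian_smooth(matrix(stats::rnorm(n * n), n, n), sigma_px = strut_px / 2)
      field > stats::quantile(field, 1 - ba, type = 1)
    },
    plate_lattice = {
      t_px <- max(2L, round(strut_px))
      p <- round(t_px / (1 - sqrt(1 - ba)))
      if (p <= t_px) stop_param("target_ba ", ba, " unreachable for plate_lattice with this strut thickness")
      on_i <- (seq_len(n) - 1L) %% p < t_px
      outer(on_i, on_i, "|")
    }))

  gray <- ifelse(bits, GRAY_BONE, GRAY_MARROW)
  if (spec$noise_sd > 0)
    gray <- gray + with_seed(spec$seed + 1L,
                             matrix(stats::rnorm(n * n, sd = spec$noise_sd), n, n))

  mask <- binary_mask(bits, spec$pixel_size_mm, region)
  img <- section_image(gray, spec$pixel_size_mm, region)
  list(image = img, mask = mask, truth = morphometry(mask))
}
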