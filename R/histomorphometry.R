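# resolve an ROI argument (NULL, cortical_boundary, or list with
# roi_rows/roi_cols) to the submatrix index ranges of a mask
roi_indices <- function(mask, roi) {
  if (is.null(roi))
    return(list(rows = seq_len(nrow(mask$bits)), cols = seq_len(ncol(mask$bits))))
  if (inherits(roi, "cortical_boundary") ||
      (is.list(roi) && all(c("roi_rows", "roi_cols") %in% names(roi))))
    return(list(rows = roi$roi_rows, cols = roi$roi_cols))
  stop_param("roi must be NULL or a cortical_boundary")
}

#' Apparent bone area
#'
#' The fraction of the trabecular region of interest occupied by bone: the
#' bone-pixel count divided by the total pixel count of the ROI. This is
#' the two-dimensional analogue of bone volume over tissue volume (BV/TV).
#' Computed in integer arithmetic; exact for any mask.
#'
#' @param mask a [binary_mask()].
#' @param roi a `cortical_boundary` from [detect_cortical_boundary()], or
#'   `NULL` for the full image.
#' @return Bone area fraction in `[0, 1]`.
#' @export
compute_ba <- function(mask, roi = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  idx <- roi_indices(mask, roi)
  sub <- mask$bits[idx$rows, idx$cols, drop = FALSE]
  if (length(sub) == 0L) stop_param("ROI is empty")
  sum(sub) / length(sub)
}

# run lengths of one phase along a single scan line, optionally dropping
# runs censored by the line ends
line_runs <- function(line, phase_val, drop_censored = TRUE) {
  r <- rle(line)
  keep <- r$values == phase_val
  if (drop_censored && length(keep) > 0L) {
    keep[1L] <- FALSE                 # runs touching the line ends are censored
    keep[length(keep)] <- FALSE
  }
  r$lengths[keep]
}

#' Mean intercept length of a phase
#'
#' Stereological intercept estimator: scan lines are drawn through the ROI
#' in the requested directions (horizontal and/or vertical) and the lengths
#' of maximal same-phase runs are averaged, in mm. Runs truncated by the
#' ROI border are excluded (censored runs bias the mean downward); if every
#' run is censored the censored runs are used with a warning. With
#' `phase = "marrow"` this is the trabecular separation estimate (Tb.Sp);
#' with `phase = "bone"` the intercept-based trabecular thickness.
#'
#' @inheritParams compute_ba
#' @param phase `"bone"` or `"marrow"`.
#' @param directions any subset of `c("horizontal", "vertical")`.
#' @return Mean intercept length in mm.
#' @export
mean_intercept_length <- function(mask, roi = NULL, phase = c("marrow", "bone"),
                                  directions = c("horizontal", "vertical")) {
  stopifnot(inherits(mask, "binary_mask"))
  phase <- match.arg(phase)
  directions <- match.arg(directions, several.ok = TRUE)
  idx <- roi_indices(mask, roi)
  sub <- mask$bits[idx$rows, idx$cols, drop = FALSE]
  phase_val <- phase == "bone"
  if (!any(sub == phase_val)) stop_param("phase '", phase, "' absent from the ROI")

  collect <- function(drop_censored) {
    runs <- integer(0)
    if ("horizontal" %in% directions)
      for (i in seq_len(nrow(sub)))
        runs <- c(runs, line_runs(sub[i, ], phase_val, drop_censored))
    if ("vertical" %in% directions)
      for (j in seq_len(ncol(sub)))
        runs <- c(runs, line_runs(sub[, j], phase_val, drop_censored))
    runs
  }
  runs <- collect(TRUE)
  if (length(runs) == 0L) {
    warning("all '", phase, "' runs are censored by the ROI border; using censored runs")
    runs <- collect(FALSE)
  }
  mean(runs) * mask$pixel_size_mm
}

#' Apparent trabecular thickness indices
#'
#' Two derived thickness indices from the bone area fraction and the
#' trabecular separation. `TH_printed` is the index
#' \eqn{2 / (Tb.Sp / BA)} = \eqn{2\,BA / Tb.Sp}; note its units are 1/mm
#' (see the package vignette for the dimensional caveat). `TH_plate_mm` is
#' the parallel-plate model thickness \eqn{Tb.Sp \cdot BA / (1 - BA)}, in
#' mm, which equals the mean bone intercept length for ideal plate
#' geometry.
#'
#' @param ba bone area fraction, strictly in (0, 1).
#' @param tb_sp trabecular separation (mean marrow intercept), mm, > 0.
#' @return List with `TH_printed` and `TH_plate_mm`.
#' @examples
#' compute_th(0.5, 2.0) # TH_printed = 0.5
#' @export
compute_th <- function(ba, tb_sp) {
  check_fraction(ba, "ba")
  check_scalar_pos(tb_sp, "tb_sp")
  list(TH_printed = 2 * ba / tb_sp,
       TH_plate_mm = tb_sp * ba / (1 - ba))
}

#' Full two-dimensional morphometry of a binary mask
#'
#' Computes, over the trabecular ROI: the apparent bone area `BA`
#' ([compute_ba()]), the trabecular separation `Tb_Sp` (mean marrow
#' intercept, mm), the derived thickness indices `TH` (printed formula,
#' 1/mm) and `TH_plate` (plate model, mm) from [compute_th()], and the
#' directly measured mean bone intercept `TH_intercept` (mm). Degenerate
#' masks (no bone, or no marrow) report `NA` for the indices that need the
#' missing phase.
#'
#' @inheritParams compute_ba
#' @return An object of class `morphometry_result`.
#' @export
morphometry <- function(mask, roi = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  idx <- roi_indices(mask, roi)
  ba <- compute_ba(mask, roi)
  quiet_mil <- function(phase)
    tryCatch(suppressWarnings(mean_intercept_length(mask, roi, phase)),
             error = function(e) NA_real_)
  tb_sp <- quiet_mil("marrow")
  th_int <- quiet_mil("bone")
  th <- if (is.finite(tb_sp) && ba > 0 && ba < 1) compute_th(ba, tb_sp)
        else list(TH_printed = NA_real_, TH_plate_mm = NA_real_)
  structure(list(region = mask$region, BA = ba, Tb_Sp = tb_sp,
                 TH = th$TH_printed, TH_plate = th$TH_plate_mm,
                 TH_intercept = th_int,
                 n_pixels_roi = length(idx$rows) * length(idx$cols)),
            class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf(paste0("<morphometry_result> region %s: BA %.3f, Tb.Sp %.3f mm, ",
                     "TH %.3f (printed), %.3f mm (plate), %.3f mm (intercept), ROI %d px\n"),
              x$region, x$BA, x$Tb_Sp, x$TH, x$TH_plate, x$TH_intercept, x$n_pixels_roi))
  invisible(x)
}

#' @export
as.data.frame.morphometry_result <- function(x, ...) {
  data.frame(region = x$region, BA = x$BA, Tb_Sp = x$Tb_Sp, TH = x$TH,
             TH_plate = x$TH_plate, TH_intercept = x$TH_intercept,
             n_pixels_roi = x$n_pixels_roi, stringsAsFactors = FALSE)
}

#' Aggregate morphometry results by region
#'
#' Per-region mean and sample standard deviation (n-1 denominator) of each
#' numeric morphometry variable. Regions with fewer than two results are
#' excluded with a warning.
#'
#' @param results list of `morphometry_result` objects, or a data frame
#'   with a `region` column and numeric columns.
#' @return Data frame with one row per region and `<var>_mean`, `<var>_sd`
#'   columns, plus `n`.
#' @export
aggregate_regions <- function(results) {
  df <- if (is.data.frame(results)) results
        else do.call(rbind, lapply(results, as.data.frame))
  if (is.null(df$region)) stop_param("results carry no region labels")
  counts <- table(df$region)
  drop <- names(counts)[counts < 2]
  if (length(drop) > 0) {
    warning("excluding region(s) with fewer than 2 results: ", paste(drop, collapse = ", "))
    df <- df[!df$region %in% drop, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop_param("no region has >= 2 results")
  num <- names(df)[vapply(df, is.numeric, logical(1))]
  num <- setdiff(num, "n_pixels_roi")
  out <- lapply(split(df, df$region), function(d) {
    stats_row <- lapply(num, function(v) {
      c(stats::setNames(mean(d[[v]]), paste0(v, "_mean")),
        stats::setNames(stats::sd(d[[v]]), paste0(v, "_sd")))
    })
    data.frame(region = d$region[1], n = nrow(d),
               as.list(unlist(stats_row)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(match(out$region, REGIONS)), , drop = FALSE]
}
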