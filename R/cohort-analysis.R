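#' Individual muscle contributions to total quadriceps volume
#'
#' Each muscle's volume divided by the total quadriceps volume, expressed
#' in percent. By default the total is the component sum, so the four
#' percentages sum to exactly 100; a published (rounded) total can be
#' supplied instead via `total`, in which case the sum may differ from 100
#' by the rounding of the total.
#'
#' @param vm,rf,vi,vl muscle volumes in cm^3 (vastus medialis, rectus
#'   femoris, vastus intermedialis, vastus lateralis); all > 0. Vectors are
#'   accepted elementwise.
#' @param total optional explicit total volume (cm^3).
#' @return Named list of percentage vectors `vm`, `rf`, `vi`, `vl`.
#' @examples
#' muscle_contributions(152, 78, 204, 247)
#' @export
muscle_contributions <- function(vm, rf, vi, vl, total = vm + rf + vi + vl) {
  if (any(c(vm, rf, vi, vl) <= 0)) stop_param("all muscle volumes must be > 0")
  if (any(total <= 0)) stop_param("total volume must be > 0")
  list(vm = 100 * vm / total, rf = 100 * rf / total,
       vi = 100 * vi / total, vl = 100 * vl / total)
}

#' VL/VM volume ratio
#'
#' The vastus lateralis to vastus medialis volume ratio, the muscle-balance
#' index correlated with patellofemoral cartilage status.
#'
#' @param vl,vm volumes in cm^3; `vm` must be > 0.
#' @return `vl / vm` (vectorized).
#' @export
vl_vm_ratio <- function(vl, vm) {
  if (any(vm <= 0)) stop_param("vm must be > 0")
  vl / vm
}

#' Consensus ICRS grade from independent graders
#'
#' Each grader scores every cartilage defect and, when multiple defects are
#' present, the highest grade is taken as that grader's knee grade. If the
#' two primary graders agree, their grade is the consensus; on disagreement
#' a third grade (adjudicator) decides by majority, falling back to the
#' median when all three differ.
#'
#' @param grader1,grader2 integer vector(s) of per-defect grades (0..4) for
#'   the two primary graders.
#' @param grader3 optional adjudicator grades (or `NA` when not called).
#' @return A single consensus grade in 0..4.
#' @examples
#' consensus_icrs(c(1, 3), 3)        # max over defects, then agreement
#' consensus_icrs(2, 3, grader3 = 3) # majority
#' @export
consensus_icrs <- function(grader1, grader2, grader3 = NULL) {
  per_grader <- function(g, name) {
    g <- g[!is.na(g)]
    if (length(g) == 0L) stop_param(name, " has no grades")
    if (any(g < 0 | g > 4 | g != round(g))) stop_param("ICRS grades must be integers in 0..4")
    max(g)
  }
  g1 <- per_grader(grader1, "grader1")
  g2 <- per_grader(grader2, "grader2")
  if (g1 == g2) return(g1)
  if (!is.null(grader3) && !all(is.na(grader3))) {
    g3 <- per_grader(grader3, "grader3")
    grades <- c(g1, g2, g3)
    tab <- table(grades)
    if (max(tab) >= 2) return(as.numeric(names(tab)[which.max(tab)]))
    return(stats::median(grades))
  }
  stats::median(c(g1, g2))
}

#' Lateral-to-medial ratio of a regional measurement
#'
#' @param lateral,medial measurement at the lateral and medial facet;
#'   `medial` must be > 0 (non-positive medial values yield `NA` so the
#'   record can be flagged and excluded from correlation).
#' @return `lateral / medial`, with `NA` where `medial <= 0`.
#' @export
lateral_medial_ratio <- function(lateral, medial) {
  out <- lateral / medial
  bad <- !is.finite(medial) | medial <= 0
  if (any(bad, na.rm = TRUE)) {
    warning(sum(bad), " record(s) with non-positive medial value flagged as NA")
    out[bad] <- NA_real_
  }
  out
}

#' Kolmogorov-Smirnov normality gate
#'
#' One-sample KS test of the values against a normal distribution with the
#' sample mean and SD (the plug-in form commonly used as a pre-test before
#' choosing nonparametric statistics). `is_normal` is `p >= alpha` and
#' drives the nonparametric analysis path.
#'
#' @param values numeric vector, n >= 5.
#' @param alpha significance level of the gate.
#' @return List with `statistic`, `p`, `is_normal`, `degenerate`.
#' @export
ks_normality <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 5L) stop_param("need at least 5 values")
  if (stats::sd(values) == 0)
    return(list(statistic = NA_real_, p = 0, is_normal = FALSE, degenerate = TRUE))
  kt <- suppressWarnings(stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
  list(statistic = unname(kt$statistic), p = kt$p.value,
       is_normal = kt$p.value >= alpha, degenerate = FALSE)
}

#' Wilcoxon tests for the cohort comparisons
#'
#' `wilcoxon_paired()` is the signed-rank test for within-knee region
#' comparisons (exact null for n <= 25 non-zero differences when ties
#' permit, normal approximation otherwise); `wilcoxon_unpaired()` is the
#' rank-sum test for between-group comparisons such as male vs female
#' totals. Both report a two-sided p-value.
#'
#' @param x,y paired numeric vectors (equal length) for the signed-rank
#'   test; independent samples for the rank-sum test.
#' @return List with `statistic`, `p`, `n` (non-zero differences for the
#'   paired test) and `method`.
#' @export
wilcoxon_paired <- function(x, y) {
  if (length(x) != length(y)) stop_param("x and y must have equal length")
  d <- x - y
  d <- d[!is.na(d)]
  nz <- sum(d != 0)
  if (nz == 0L) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p = 1, n = 0L, method = "signed-rank (degenerate)"))
  }
  if (nz < 5L) stop_param("need at least 5 non-zero paired differences")
  exact <- nz <= 25L && !any(duplicated(abs(d[d != 0])))
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE, exact = exact,
                                            correct = !exact))
  list(statistic = unname(wt$statistic), p = wt$p.value, n = nz,
       method = if (exact) "signed-rank (exact)" else "signed-rank (normal approx.)")
}

#' @rdname wilcoxon_paired
#' @export
wilcoxon_unpaired <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop_param("need at least 2 values per group")
  exact <- length(x) + length(y) <= 50 && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n = length(x) + length(y),
       method = if (exact) "rank-sum (exact)" else "rank-sum (normal approx.)")
}

#' Spearman correlation with strength categories
#'
#' Spearman's rank correlation (Pearson correlation of average ranks, so
#' ties are handled by midranks) with the strength map used throughout the
#' cohort analysis: |r| >= 0.8 very strong, 0.60 <= |r| < 0.80 moderate,
#' 0.30 <= |r| < 0.60 fair, |r| < 0.30 weak (half-open intervals make the
#' map total on [-1, 1]). The p-value is exact (AS 89) for n <= 10 without
#' ties and the t approximation otherwise.
#'
#' @param x,y numeric vectors of equal length, n >= 5, no missing values
#'   (use [build_table2()] for listwise deletion over a table).
#' @return An object of class `correlation_result`: list with `r`, `p`,
#'   `n`, `strength`, `direction`.
#' @examples
#' r <- spearman_strength(1:10, (1:10)^3)
#' r$r        # 1: rank correlation is invariant to monotone transforms
#' @export
spearman_strength <- function(x, y) {
  if (length(x) != length(y)) stop_param("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop_param("missing values not allowed; filter first")
  n <- length(x)
  if (n < 5L) stop_param("need at least 5 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_param("constant input: Spearman correlation undefined")
  r <- stats::cor(rank(x), rank(y))
  ties <- any(duplicated(x)) || any(duplicated(y))
  exact <- n <= 10L && !ties
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = exact))
  structure(list(r = r, p = ct$p.value, n = n,
                 strength = strength_label(r),
                 direction = if (r >= 0) "positive" else "inverse"),
            class = "correlation_result")
}

#' Strength category of a correlation coefficient
#'
#' @param r correlation coefficient(s) in `[-1, 1]`.
#' @return Character vector: `"very strong"`, `"moderate"`, `"fair"` or
#'   `"weak"` based on |r|.
#' @export
strength_label <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) > 1 + 1e-12)) stop_param("r must lie in [-1, 1]")
  a <- abs(r)
  ifelse(a >= 0.8, "very strong",
         ifelse(a >= 0.6, "moderate",
                ifelse(a >= 0.3, "fair", "weak")))
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman r = %.2f (%s, %s), p = %.3g, n = %d\n",
              x$r, x$strength, x$direction, x$p, x$n))
  invisible(x)
}

#' Per-knee ratio records from a cohort table
#'
#' Derives the ratio-level analysis variables from raw knee records: the
#' VL/VM volume ratio, the lateral/medial ratio of each regional
#' measurement (UF, CF, BA, TH) and the consensus ICRS grade from the
#' grader columns. Knees with non-positive medial values are flagged `NA`.
#'
#' @param cohort data frame in the layout produced by [gen_cohort()].
#' @return Data frame with columns `donor_id`, `leg`, `vl_vm`, `uf_ratio`,
#'   `cf_ratio`, `ba_ratio`, `th_ratio`, `icrs`.
#' @export
knee_ratios <- function(cohort) {
  need <- c("vol_vm", "vol_vl", "icrs_g1", "icrs_g2",
            paste0(rep(c("ba", "th", "cf", "uf"), each = 2), "_",
                   c("lateral", "medial")))
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0)
    stop_param("cohort table lacks columns: ", paste(missing_cols, collapse = ", "))
  icrs <- vapply(seq_len(nrow(cohort)), function(i) {
    g3 <- if ("icrs_g3" %in% names(cohort)) cohort$icrs_g3[i] else NULL
    consensus_icrs(cohort$icrs_g1[i], cohort$icrs_g2[i], g3)
  }, numeric(1))
  data.frame(
    donor_id = if (!is.null(cohort$donor_id)) cohort$donor_id else seq_len(nrow(cohort)),
    leg = if (!is.null(cohort$leg)) cohort$leg else NA_character_,
    vl_vm = vl_vm_ratio(cohort$vol_vl, cohort$vol_vm),
    uf_ratio = lateral_medial_ratio(cohort$uf_lateral, cohort$uf_medial),
    cf_ratio = lateral_medial_ratio(cohort$cf_lateral, cohort$cf_medial),
    ba_ratio = lateral_medial_ratio(cohort$ba_lateral, cohort$ba_medial),
    th_ratio = lateral_medial_ratio(cohort$th_lateral, cohort$th_medial),
    icrs = icrs, stringsAsFactors = FALSE)
}

#' Pairwise Spearman matrix of the ratio-level variables
#'
#' All pairwise Spearman correlations among `{VL/VM, UF, CF, BA, TH, ICRS}`
#' lateral/medial ratio variables, with strength marks, in the layout of
#' the published ratio correlation table. Records with any missing ratio
#' are excluded listwise; the number used is reported.
#'
#' @param ratios data frame from [knee_ratios()].
#' @param unit `"knee"` (each knee is an observation) or `"donor"`
#'   (within-donor average first).
#' @return An object of class `ratio_correlation_table`: list with the
#'   correlation matrix `r`, p-value matrix `p`, `strength` matrix,
#'   `n_used`, `n_excluded`, `unit`.
#' @export
build_table2 <- function(ratios, unit = c("knee", "donor")) {
  unit <- match.arg(unit)
  vars <- RATIO_VARS
  missing_cols <- setdiff(vars, names(ratios))
  if (length(missing_cols) > 0)
    stop_param("ratio table lacks columns: ", paste(missing_cols, collapse = ", "))
  d <- ratios[, c("donor_id", vars)]
  complete <- stats::complete.cases(d[, vars])
  n_excluded <- sum(!complete)
  d <- d[complete, , drop = FALSE]
  if (unit == "donor") {
    d <- stats::aggregate(d[vars], by = list(donor_id = d$donor_id), FUN = mean)
  }
  if (nrow(d) < 5L) stop_param("need at least 5 complete records")
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    sr <- tryCatch(spearman_strength(d[[vars[i]]], d[[vars[j]]]),
                   enthesomorph_parameter_error = function(e) {
                     warning("Spearman undefined for ", vars[i], "-", vars[j],
                             " (constant variable); reported as NA", call. = FALSE)
                     list(r = NA_real_, p = NA_real_)
                   })
    r[i, j] <- r[j, i] <- sr$r
    p[i, j] <- p[j, i] <- sr$p
  }
  strength <- matrix("", k, k, dimnames = dimnames(r))
  ok <- is.finite(r) & row(r) != col(r)
  strength[ok] <- strength_label(r[ok])
  structure(list(r = r, p = p, strength = strength,
                 n_used = nrow(d), n_excluded = n_excluded, unit = unit),
            class = "ratio_correlation_table")
}

#' @export
print.ratio_correlation_table <- function(x, digits = 2, ...) {
  cat(sprintf("Spearman correlations of lateral/medial ratios (%d %ss%s)\n",
              x$n_used, x$unit,
              if (x$n_excluded > 0) sprintf(", %d excluded", x$n_excluded) else ""))
  marks <- ifelse(x$strength == "very strong", "*",
                  ifelse(x$strength == "moderate", "+", " "))
  diag(marks) <- " "
  m <- matrix(paste0(formatC(x$r, digits = digits, format = "f"), marks),
              nrow(x$r), dimnames = dimnames(x$r))
  diag(m) <- "1"
  print(m, quote = FALSE)
  cat("  * very strong (|r| >= 0.8), + moderate (0.60 <= |r| < 0.80)\n")
  invisible(x)
}
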