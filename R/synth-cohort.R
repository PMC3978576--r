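# Synthetic donor cohort with a controlled Spearman dependence structure.
#
# The dependence is specified on the ratio-level variables
# {VL/VM, UF ratio, CF ratio, BA ratio, TH ratio, ICRS} and realized by a
# latent Gaussian copula. For continuous margins the latent Pearson
# correlation is the classical rank-to-latent map rho = 2 sin(pi * r_s / 6);
# for pairs involving the ordinal ICRS margin the midrank-tie attenuation is
# inverted numerically so the population Spearman (computed with average
# ranks) still hits the target.

RATIO_VARS <- c("vl_vm", "uf_ratio", "cf_ratio", "ba_ratio", "th_ratio", "icrs")

# ICRS grade probabilities on grades 0..4 with mean 2.35 and SD 0.55 exactly
# (closed form: support {1,2,3,4}, p1 = p4 = eps with 0.2275 + 4*eps = 0.55^2)
icrs_default_probs <- function() c(0, 0.01875, 0.63125, 0.33125, 0.01875)

#' Specification of a synthetic knee cohort
#'
#' Defines the donor count, sex split, marginal distributions and the
#' target Spearman dependence among the ratio-level variables. Defaults
#' are calibrated to the printed cohort tables: individual quadriceps
#' muscle volumes by sex, regional bone-area / trabecular-thickness /
#' fibrocartilage marginals, an ICRS grade distribution with mean 2.35 and
#' SD 0.55, and the published lateral/medial-ratio correlation matrix.
#'
#' Lateral facet values are derived as `medial * ratio` so the ratio-level
#' dependence structure is exact; central values get independent marginals.
#' Ratio dispersions are delta-method propagations of the printed facet
#' means and SDs (the source tables print no ratio SDs).
#'
#' @param n_donors number of donors (two knees each), >= 4.
#' @param sex_split integer vector `c(male, female)` summing to `n_donors`.
#' @param target_spearman 6 x 6 symmetric matrix with unit diagonal over
#'   `c("vl_vm", "uf_ratio", "cf_ratio", "ba_ratio", "th_ratio", "icrs")`.
#' @param means_sds named list of `c(mean, sd)` pairs for the marginals;
#'   see `cohort_default_marginals()` for the full set of names.
#' @param icrs_probs probabilities of ICRS grades 0..4.
#' @param leg_correlation within-donor leg-to-leg latent correlation.
#' @param grader_disagreement probability that the two graders disagree on
#'   a knee (a third grader then adjudicates).
#' @param seed integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @seealso [gen_cohort()]
#' @export
cohort_spec <- function(n_donors = 12L,
                        sex_split = NULL,
                        target_spearman = table2_target(),
                        means_sds = cohort_default_marginals(),
                        icrs_probs = icrs_default_probs(),
                        leg_correlation = 0.8,
                        grader_disagreement = 0.2,
                        seed = 1L) {
  if (n_donors < 4) stop_param("n_donors must be >= 4")
  if (is.null(sex_split)) sex_split <- c(ceiling(n_donors / 2), floor(n_donors / 2))
  if (length(sex_split) != 2L || sum(sex_split) != n_donors)
    stop_param("sex_split must be c(male, female) summing to n_donors")
  m <- as.matrix(target_spearman)
  if (!isTRUE(all.equal(dim(m), c(6L, 6L))) || !isTRUE(all.equal(m, t(m))) ||
      any(abs(diag(m) - 1) > 1e-12) || any(abs(m) > 1))
    stop_param("target_spearman must be a symmetric 6x6 matrix with unit diagonal and entries in [-1, 1]")
  dimnames(m) <- list(RATIO_VARS, RATIO_VARS)
  if (abs(sum(icrs_probs) - 1) > 1e-9 || length(icrs_probs) != 5L || any(icrs_probs < 0))
    stop_param("icrs_probs must be 5 nonnegative probabilities over grades 0..4 summing to 1")
  check_fraction(leg_correlation, "leg_correlation", open = FALSE)
  check_fraction(grader_disagreement, "grader_disagreement", open = FALSE)
  structure(list(n_donors = as.integer(n_donors), sex_split = as.integer(sex_split),
                 target_spearman = m, means_sds = means_sds, icrs_probs = icrs_probs,
                 leg_correlation = leg_correlation,
                 grader_disagreement = grader_disagreement, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Published lateral/medial-ratio correlation matrix
#'
#' The Spearman correlation matrix among `{VL/VM, UF, CF, BA, TH, ICRS}`
#' lateral/medial ratios used as the default dependence target for
#' [cohort_spec()].
#'
#' @return A named 6 x 6 symmetric matrix.
#' @export
table2_target <- function() {
  m <- matrix(c(
    1.00, 0.80, 0.72, 0.81, 0.56, 0.65,
    0.80, 1.00, 0.64, 0.69, 0.52, 0.49,
    0.72, 0.64, 1.00, 0.55, 0.49, 0.41,
    0.81, 0.69, 0.55, 1.00, 0.78, 0.74,
    0.56, 0.52, 0.49, 0.78, 1.00, 0.67,
    0.65, 0.49, 0.41, 0.74, 0.67, 1.00), 6, 6, byrow = TRUE)
  dimnames(m) <- list(RATIO_VARS, RATIO_VARS)
  m
}

#' Default marginal calibration for the synthetic cohort
#'
#' Named `c(mean, sd)` pairs: sex-specific muscle volumes (cm^3), medial
#' and central facet morphometry (BA fraction, TH mm, CF mm, UF mm),
#' ratio-level variables, and donor age (years).
#'
#' @return Named list of length-2 numeric vectors.
#' @export
cohort_default_marginals <- function() {
  list(
    vm_male = c(175, 18), rf_male = c(81, 12), vi_male = c(220, 28),
    vm_female = c(129, 19), rf_female = c(74, 14), vi_female = c(187, 27),
    age = c(75, 5),
    ba_medial = c(0.28, 0.07), ba_central = c(0.49, 0.06),
    th_medial = c(0.07, 0.03), th_central = c(0.19, 0.06),
    cf_medial = c(0.63, 0.21), cf_central = c(1.21, 0.14),
    uf_medial = c(0.37, 0.09), uf_central = c(0.62, 0.15),
    # ratio dispersions: delta-method from the facet means/SDs above
    vl_vm = c(247 / 152, 0.28),
    uf_ratio = c(0.55 / 0.37, 0.40),
    cf_ratio = c(0.81 / 0.63, 0.51),
    ba_ratio = c(0.41 / 0.28, 0.39),
    th_ratio = c(0.16 / 0.07, 1.03))
}

# population Spearman between a continuous margin and the ordinal ICRS
# margin under a latent bivariate normal with correlation rho, using
# average ranks for the tie groups
spearman_cont_ordinal <- function(rho, probs) {
  cum <- cumsum(probs)
  cuts <- stats::qnorm(c(0, cum))
  mid <- c(0, cum[-length(cum)]) + probs / 2   # midrank scores on [0,1]
  scale <- rho / sqrt(2 - rho^2)
  cov <- 0
  for (g in seq_along(probs)) {
    if (probs[g] <= 0) next
    I <- stats::integrate(function(z) stats::dnorm(z) * stats::pnorm(scale * z),
                          cuts[g], cuts[g + 1], rel.tol = 1e-9)$value
    cov <- cov + mid[g] * I
  }
  cov <- cov - 0.25
  sd_s <- sqrt(sum(probs * mid^2) - 0.25)
  cov / (sqrt(1 / 12) * sd_s)
}

# latent Pearson correlation achieving a target population Spearman
latent_rho <- function(target, ordinal = FALSE, probs = NULL, pair = "") {
  if (!ordinal) return(2 * sin(pi * target / 6))
  if (abs(target) < 1e-12) return(0)
  max_s <- spearman_cont_ordinal(0.999999, probs)
  if (abs(target) >= max_s)
    stop_param("target Spearman ", target, " for pair ", pair,
               " exceeds the maximum ", round(max_s, 3),
               " attainable with the tied ICRS margin")
  stats::uniroot(function(r) spearman_cont_ordinal(r, probs) - target,
                 lower = -0.999999, upper = 0.999999, tol = 1e-8)$root
}

# build the 6x6 latent correlation matrix, erroring on non-PSD
latent_matrix <- function(target, probs) {
  L <- diag(6)
  dimnames(L) <- dimnames(target)
  for (i in 1:5) for (j in (i + 1):6) {
    ord <- RATIO_VARS[j] == "icrs" || RATIO_VARS[i] == "icrs"
    L[i, j] <- L[j, i] <- latent_rho(target[i, j], ordinal = ord, probs = probs,
                                     pair = paste(RATIO_VARS[i], RATIO_VARS[j], sep = "-"))
  }
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    off <- abs(L); diag(off) <- 0
    worst <- which(off == max(off), arr.ind = TRUE)[1, ]
    stop_param("latent correlation matrix is not positive semidefinite ",
               "(most extreme pair: ", RATIO_VARS[worst[1]], "-", RATIO_VARS[worst[2]], ")")
  }
  L
}

# draw n_donors x 2 knees of latent N(0,1) variables with cross-variable
# correlation L and within-donor leg correlation rho_leg
draw_latent <- function(n_donors, L, rho_leg) {
  k <- nrow(L)
  ch <- chol(L + diag(1e-10, k))
  zd <- matrix(stats::rnorm(n_donors * k), n_donors) %*% ch
  z1 <- matrix(stats::rnorm(n_donors * k), n_donors) %*% ch
  z2 <- matrix(stats::rnorm(n_donors * k), n_donors) %*% ch
  a <- sqrt(rho_leg); b <- sqrt(1 - rho_leg)
  z <- rbind(a * zd + b * z1, a * zd + b * z2)  # knees: donors x leg L then leg R
  colnames(z) <- rownames(L)
  z
}

#' Generate a synthetic knee cohort
#'
#' Draws `2 * n_donors` knee records whose ratio-level variables follow a
#' latent Gaussian copula calibrated so the population Spearman matrix
#' equals `spec$target_spearman` (tie-corrected for the ordinal ICRS
#' margin). Muscle volumes use sex-specific log-normal marginals; the VL
#' volume is `VM * (VL/VM ratio)` and lateral facet values are
#' `medial * ratio`, so the published ratio dependence is carried by
#' construction. ICRS consensus grades are discretized from the latent
#' normal; two grader columns (plus a third where they disagree) are
#' emitted so the consensus rule is exercised downstream.
#'
#' @param spec a [cohort_spec()].
#' @return A data frame with one row per knee: `donor_id`, `leg`, `sex`,
#'   `age`, `vol_vm`, `vol_rf`, `vol_vi`, `vol_vl`, `icrs_g1`, `icrs_g2`,
#'   `icrs_g3` (`NA` when the first two agree), and
#'   `ba_/th_/cf_/uf_{lateral,central,medial}`.
#' @examples
#' coh <- gen_cohort(cohort_spec(n_donors = 6, seed = 42))
#' nrow(coh)  # 12 knees
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ms <- spec$means_sds
  L <- latent_matrix(spec$target_spearman, spec$icrs_probs)
  nd <- spec$n_donors

  with_seed(spec$seed, {
    z_ratio <- draw_latent(nd, L, spec$leg_correlation)
    z_ind <- draw_latent(nd, diag(9), spec$leg_correlation)
    colnames(z_ind) <- c("vm", "rf", "vi", "ba_medial", "ba_central",
                         "th_medial", "th_central", "cf_medial", "cf_central")
    # uf medial/central reuse independent draws
    z_uf <- draw_latent(nd, diag(2), spec$leg_correlation)

    sex <- rep(c(rep("M", spec$sex_split[1]), rep("F", spec$sex_split[2])), 2L)
    donor <- rep(seq_len(nd), 2L)
    leg <- rep(c("L", "R"), each = nd)
    age_d <- round(stats::rnorm(nd, ms$age[1], ms$age[2]))
    age <- age_d[donor]

    q_ln <- function(z, par) {
      p <- lnorm_pars(par[1], par[2])
      stats::qlnorm(stats::pnorm(z), p$meanlog, p$sdlog)
    }
    by_sex <- function(z, par_m, par_f) ifelse(sex == "M", q_ln(z, par_m), q_ln(z, par_f))

    vol_vm <- by_sex(z_ind[, "vm"], ms$vm_male, ms$vm_female)
    vol_rf <- by_sex(z_ind[, "rf"], ms$rf_male, ms$rf_female)
    vol_vi <- by_sex(z_ind[, "vi"], ms$vi_male, ms$vi_female)

    r <- list()
    for (v in setdiff(RATIO_VARS, "icrs"))
      r[[v]] <- q_ln(z_ratio[, v], ms[[v]])
    vol_vl <- vol_vm * r$vl_vm

    med <- list(ba = q_ln(z_ind[, "ba_medial"], ms$ba_medial),
                th = q_ln(z_ind[, "th_medial"], ms$th_medial),
                cf = q_ln(z_ind[, "cf_medial"], ms$cf_medial),
                uf = q_ln(z_uf[, 1], ms$uf_medial))
    cen <- list(ba = q_ln(z_ind[, "ba_central"], ms$ba_central),
                th = q_ln(z_ind[, "th_central"], ms$th_central),
                cf = q_ln(z_ind[, "cf_central"], ms$cf_central),
                uf = q_ln(z_uf[, 2], ms$uf_central))
    lat <- list(ba = pmin(med$ba * r$ba_ratio, 0.99),
                th = med$th * r$th_ratio,
                cf = med$cf * r$cf_ratio,
                uf = med$uf * r$uf_ratio)

    cum <- cumsum(spec$icrs_probs)
    consensus <- findInterval(stats::pnorm(z_ratio[, "icrs"]), cum[-5],
                              left.open = TRUE)  # grade 0..4
    disagree <- stats::runif(2 * nd) < spec$grader_disagreement
    step <- sample(c(-1L, 1L), 2 * nd, replace = TRUE)
    g2 <- consensus + ifelse(disagree, step, 0L)
    g2[g2 < 0L] <- 1L; g2[g2 > 4L] <- 3L
    disagree <- g2 != consensus
    icrs_g3 <- ifelse(disagree, consensus, NA_integer_)

    data.frame(donor_id = donor, leg = leg, sex = sex, age = age,
               vol_vm = vol_vm, vol_rf = vol_rf, vol_vi = vol_vi, vol_vl = vol_vl,
               icrs_g1 = consensus, icrs_g2 = g2, icrs_g3 = icrs_g3,
               ba_lateral = lat$ba, ba_central = cen$ba, ba_medial = med$ba,
               th_lateral = lat$th, th_central = cen$th, th_medial = med$th,
               cf_lateral = lat$cf, cf_central = cen$cf, cf_medial = med$cf,
               uf_lateral = lat$uf, uf_central = cen$uf, uf_medial = med$uf,
               stringsAsFactors = FALSE)
  })
}

#' Write / read a cohort table as CSV
#'
#' @param cohort data frame from [gen_cohort()].
#' @param path CSV path.
#' @return `path` (write) or the cohort data frame (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
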