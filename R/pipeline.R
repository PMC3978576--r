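# Region-level defaults used by the pipeline's synthetic stages: the
# published facet means (BA fraction, CF and UF thickness in mm).
region_defaults <- function() {
  list(ba = c(lateral = 0.41, central = 0.49, medial = 0.28),
       cf = c(lateral = 0.81, central = 1.21, medial = 0.63),
       uf = c(lateral = 0.55, central = 0.62, medial = 0.37))
}

#' Pipeline configuration
#'
#' Collects every tunable of a full synthetic pipeline run. All image
#' and geometry scales are in mm; `sigma_mm = NULL` means 3 pixels.
#'
#' @param out_dir output directory (created if absent).
#' @param seed master RNG seed; stage seeds are derived from it and
#'   recorded in the manifest.
#' @param stages subset of `c("images", "sections", "cohort")`.
#' @param n_images_per_region trabecular images per region.
#' @param image_size_px image side length.
#' @param pixel_size_mm physical pixel size.
#' @param strut_thickness_mm trabecular strut thickness for the generator.
#' @param noise_sd grayscale noise SD of the rendering.
#' @param sigma_mm LoG scale; `NULL` for 3 pixels.
#' @param shell_threshold cortical shell bone-fraction threshold.
#' @param n_slides enthesis slides per region (1-mm series).
#' @param n_sites measurement stations per slide.
#' @param n_donors cohort donors (two knees each).
#' @param correlation_unit `"knee"` or `"donor"` for the ratio correlations.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("images", "sections", "cohort"),
                            n_images_per_region = 3L, image_size_px = 192L,
                            pixel_size_mm = 0.025, strut_thickness_mm = 0.2,
                            noise_sd = 10, sigma_mm = NULL,
                            shell_threshold = 0.85,
                            n_slides = 4L, n_sites = 5L,
                            n_donors = 12L, correlation_unit = "knee") {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 n_images_per_region = n_images_per_region,
                 image_size_px = image_size_px, pixel_size_mm = pixel_size_mm,
                 strut_thickness_mm = strut_thickness_mm, noise_sd = noise_sd,
                 sigma_mm = sigma_mm, shell_threshold = shell_threshold,
                 n_slides = n_slides, n_sites = n_sites, n_donors = n_donors,
                 correlation_unit = correlation_unit),
            class = "pipeline_config")
}

write_report_csv <- function(df, path, digits = 3) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, digits))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' Runs the enabled stages end to end on synthetic inputs and writes a
#' report bundle to `config$out_dir`: per-region morphometry
#' (`morphometry_regions.csv`), per-region fibrocartilage thickness
#' (`fibrocartilage_regions.csv`), the cohort table (`cohort.csv`), a
#' cohort summary (`cohort_summary.csv`), the ratio correlation matrix
#' with strength marks (`ratio_correlations.csv`), and a JSON manifest
#' (`manifest.json`) recording package version, seeds and parameters.
#' Report CSVs are rounded to 3 decimals; `results_full.json` carries the
#' same numbers at full precision. Identical configs produce byte-identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  defs <- region_defaults()
  results <- list()
  outputs <- character(0)

  if ("images" %in% config$stages) {
    rows <- list()
    for (region in REGIONS) {
      for (i in seq_len(config$n_images_per_region)) {
        sp <- texture_spec("gaussian_random_field",
                           target_ba = defs$ba[[region]],
                           strut_thickness_mm = config$strut_thickness_mm,
                           pixel_size_mm = config$pixel_size_mm,
                           noise_sd = config$noise_sd,
                           seed = config$seed * 1000L + match(region, REGIONS) * 100L + i,
                           size_px = config$image_size_px)
        gen <- gen_trabecular_image(sp, region = region)
        sigma <- if (is.null(config$sigma_mm)) 3 * config$pixel_size_mm else config$sigma_mm
        mask <- segment_trabeculae(gen$image, sigma_mm = sigma)
        mask$region <- region
        res <- morphometry(mask)
        row <- as.data.frame(res)
        row$BA_truth <- gen$truth$BA
        rows[[length(rows) + 1L]] <- row
      }
    }
    morpho <- do.call(rbind, rows)
    agg <- aggregate_regions(morpho)
    write_report_csv(agg, file.path(config$out_dir, "morphometry_regions.csv"))
    outputs <- c(outputs, "morphometry_regions.csv")
    results$morphometry <- list(per_image = morpho, by_region = agg)
  }

  if ("sections" %in% config$stages) {
    rows <- list()
    profiles <- list()
    for (region in REGIONS) {
      secs <- lapply(seq_len(config$n_slides), function(i)
        gen_enthesis_section(region, cf_mm = defs$cf[[region]],
                             uf_mm = defs$uf[[region]],
                             tidemark_shape = "sinusoid",
                             seed = config$seed * 1000L + match(region, REGIONS) * 10L + i,
                             slide_index = i))
      pr <- suppressWarnings(profile_region(secs, n_sites = config$n_sites))
      profiles[[region]] <- pr
      rows[[region]] <- data.frame(region = region, n_slides = pr$n_slides,
                                   cf_mean = pr$cf_mean, cf_sd = pr$cf_sd,
                                   uf_mean = pr$uf_mean, uf_sd = pr$uf_sd,
                                   stringsAsFactors = FALSE)
    }
    fib <- do.call(rbind, rows)
    rownames(fib) <- NULL
    write_report_csv(fib, file.path(config$out_dir, "fibrocartilage_regions.csv"))
    outputs <- c(outputs, "fibrocartilage_regions.csv")
    results$fibrocartilage <- list(profiles = profiles, by_region = fib)
  }

  if ("cohort" %in% config$stages) {
    coh <- gen_cohort(cohort_spec(n_donors = config$n_donors,
                                  seed = config$seed + 7L))
    write_cohort_csv(coh, file.path(config$out_dir, "cohort.csv"))
    contrib <- muscle_contributions(coh$vol_vm, coh$vol_rf, coh$vol_vi, coh$vol_vl)
    summ <- data.frame(
      group = c("all", "male", "female"),
      n_knees = c(nrow(coh), sum(coh$sex == "M"), sum(coh$sex == "F")),
      do.call(rbind, lapply(list(coh, coh[coh$sex == "M", ], coh[coh$sex == "F", ]),
        function(d) {
          tot <- d$vol_vm + d$vol_rf + d$vol_vi + d$vol_vl
          c(age_mean = mean(d$age), vm_mean = mean(d$vol_vm), rf_mean = mean(d$vol_rf),
            vi_mean = mean(d$vol_vi), vl_mean = mean(d$vol_vl), total_mean = mean(tot),
            total_sd = stats::sd(tot))
        })), stringsAsFactors = FALSE)
    write_report_csv(summ, file.path(config$out_dir, "cohort_summary.csv"))
    ratios <- knee_ratios(coh)
    tab2 <- build_table2(ratios, unit = config$correlation_unit)
    tab_df <- data.frame(variable = rownames(tab2$r),
                         round(tab2$r, 3),
                         strength = apply(tab2$strength, 1, function(s)
                           paste(s[s != ""], collapse = ";")),
                         stringsAsFactors = FALSE)
    write_report_csv(tab_df, file.path(config$out_dir, "ratio_correlations.csv"))
    comparisons <- list(
      cf_central_vs_medial = wilcoxon_paired(coh$cf_central, coh$cf_medial),
      ba_central_vs_medial = wilcoxon_paired(coh$ba_central, coh$ba_medial),
      uf_lateral_vs_medial = wilcoxon_paired(coh$uf_lateral, coh$uf_medial))
    outputs <- c(outputs, "cohort.csv", "cohort_summary.csv", "ratio_correlations.csv")
    results$cohort <- list(records = coh, summary = summ, ratios = ratios,
                           correlations = tab2, comparisons = comparisons,
                           contributions = contrib)
    jsonlite::write_json(
      list(correlations = tab2$r, p_values = tab2$p,
           comparisons = lapply(comparisons, function(x) x[c("statistic", "p", "n")])),
      file.path(config$out_dir, "results_full.json"),
      auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    outputs <- c(outputs, "results_full.json")
  }

  manifest <- list(
    package = "enthesomorph",
    version = as.character(utils::packageVersion("enthesomorph")),
    seed = config$seed,
    stages = config$stages,
    parameters = config[setdiff(names(config), c("out_dir", "seed", "stages"))],
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
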