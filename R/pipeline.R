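#' Read a cohort table from delimited text
#'
#' Reads the UTF-8 comma-separated cohort schema (header
#' `participant_id, site_id, age, sex, icv`, then the 16
#' `{region}_{L|R}` volumes), validating column names/order, the sex
#' domain and numeric parsing. Empty fields become missing values; quoted
#' fields and stray whitespace are tolerated.
#'
#' @param path file path.
#' @return cohort data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE,
                         check.names = FALSE, fileEncoding = "UTF-8")
  expected <- cohort_columns()
  if (!identical(names(raw), expected)) {
    extra <- setdiff(names(raw), expected)
    miss <- setdiff(expected, names(raw))
    stop("cohort file columns do not match the schema",
         if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")),
         if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")))
  }
  out <- raw
  num_cols <- c("age", "icv", volume_columns())
  for (cl in num_cols) {
    v <- raw[[cl]]
    v[v == ""] <- NA_character_
    parsed <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(parsed)
    if (any(bad)) {
      stop("non-numeric ", cl, " in data row(s): ",
           paste(utils::head(which(bad), 10L), collapse = ", "))
    }
    out[[cl]] <- parsed
  }
  out$sex[out$sex == ""] <- NA_character_
  bad_sex <- !is.na(out$sex) & !out$sex %in% c("M", "F")
  if (any(bad_sex)) {
    stop("invalid sex value in data row(s): ",
         paste(utils::head(which(bad_sex), 10L), collapse = ", "))
  }
  check_cohort(out)
  out
}

#' Write a cohort table as delimited text
#'
#' @param table cohort data.frame.
#' @param path output file; missing values are written as empty fields.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  check_cohort(table, require_rows = FALSE)
  utils::write.csv(table[cohort_columns()], path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every stage option of [run_pipeline()] with its default. The
#' defaults reproduce the primary analysis path: complete-case filtering,
#' pooled Mahalanobis exclusion at alpha 0.001, per-site ICV adjustment,
#' joint 16-feature ComBat with a sex + cubic-age design, closed-test FP
#' selection at alpha 0.01, early/middle/late age bands with a
#' Brown-Forsythe omnibus at the 0.05/16 Bonferroni threshold, and LMS
#' centiles at levels 5/25/50/75/95 selected by GAIC with penalty 3.
#'
#' @param input path to a cohort CSV, or `NULL` to simulate the bundled
#'   synthetic cohort.
#' @param out_dir output directory for all artefacts, or `NULL` to skip
#'   writing.
#' @param sim_scale size factor of the simulated cohort relative to the
#'   reference compilation (default 12000/18605, about 12,000 rows).
#' @param icv_adjust apply the ICV adjustment stage (`FALSE` gives the
#'   ICV-unadjusted sensitivity path; outputs are flagged accordingly).
#' @param mahalanobis_alpha tail probability of the outlier threshold.
#' @param mahalanobis_per_site compute outlier distances within site.
#' @param combat_age_degree,combat_per_hemisphere harmonization options.
#' @param fp_alpha,fp_max_degree,fp_age_scale trajectory-selection options.
#' @param bands named list of age bands.
#' @param variance_method `"brown_forsythe"` or `"bartlett"`.
#' @param centile_levels centile levels in percent.
#' @param centile_df_grid data.frame of `df_mu`/`df_sigma` candidates.
#' @param centile_penalty_k GAIC penalty.
#' @param seed root seed; all stage randomness derives from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, out_dir = NULL,
                            sim_scale = 12000 / 18605,
                            icv_adjust = TRUE,
                            mahalanobis_alpha = 0.001,
                            mahalanobis_per_site = FALSE,
                            combat_age_degree = 3,
                            combat_per_hemisphere = FALSE,
                            fp_alpha = 0.01, fp_max_degree = 3,
                            fp_age_scale = 10,
                            bands = age_bands(),
                            variance_method = "brown_forsythe",
                            centile_levels = c(5, 25, 50, 75, 95),
                            centile_df_grid = expand.grid(df_mu = 3:6,
                                                          df_sigma = 2:4),
                            centile_penalty_k = 3,
                            seed = 1L) {
  stopifnot(mahalanobis_alpha >= 0, mahalanobis_alpha < 1,
            fp_alpha > 0, fp_alpha <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML mapping whose keys are [pipeline_config()] argument names;
#' unknown keys are an error.
#'
#' @param path YAML file.
#' @param ... overrides applied after the file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  if (!is.null(vals$bands)) vals$bands <- lapply(vals$bands, unlist)
  if (!is.null(vals$centile_df_grid)) {
    vals$centile_df_grid <- as.data.frame(lapply(vals$centile_df_grid, unlist))
  }
  do.call(pipeline_config, vals)
}

# stable FNV-1a hash of a config (hex string), for the manifest
config_hash <- function(config) {
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                        digits = NA, null = "null", force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Fitted FP curves on an age grid
#'
#' Tidy table of each selected trajectory evaluated on a 3-90 year grid in
#' 0.5-year steps (cross-sex reference curve).
#'
#' @param fits named list of `fp_fit` per region-hemisphere.
#' @param ages age grid.
#' @return data.frame with `region_hemisphere`, `age`, `fitted`.
#' @export
fp_curve_table <- function(fits, ages = seq(3, 90, by = 0.5)) {
  do.call(rbind, lapply(names(fits), function(nm) {
    data.frame(region_hemisphere = nm, age = ages,
               fitted = predict(fits[[nm]], ages))
  }))
}

# serialize an fp_fit to a plain list for JSON
fp_fit_dump <- function(fit) {
  list(powers = fit$spec$powers, age_scale = fit$spec$age_scale,
       degree = fit$spec$degree,
       coefficients = as.list(fit$coefficients),
       robust_se = as.list(fit$robust_se),
       rss = fit$rss, deviance = fit$deviance,
       partial_r2_age = fit$partial_r2_age,
       n = fit$n, n_sites = fit$n_sites,
       selection_trace = fit$selection_trace)
}

#' Run the full lifespan trajectory pipeline
#'
#' Executes, in order: simulate-or-read the cohort, complete-case
#' filtering, Mahalanobis outlier exclusion, per-site ICV adjustment
#' (unless disabled), ComBat harmonization, closed-test FP trajectory
#' selection for all 16 region-hemisphere series (plus sex-stratified fits
#' and age-band correlations), the 16 age-band variance reports with the
#' Bonferroni-corrected omnibus decisions and per-band meta-analysis of
#' site SDs, and LMS centile models for the 32 structure x hemisphere x
#' sex strata. All artefacts are written under `config$out_dir` together
#' with a manifest (config hash, seed, versions, stage outputs); rerunning
#' with the same config and seed regenerates identical numbers.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a result bundle: `cohort`, `qc`, `icv`, `harmonized`,
#'   `fp_fits`, `fp_by_sex`, `correlations`, `variance_reports`,
#'   `band_meta`, `lms_models`, `centiles`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  cohort <- stage("input", {
    if (is.null(config$input)) {
      generate_cohort(reference_sim_config(scale = config$sim_scale,
                                           seed = stage_seed(config$seed,
                                                             "simulate")))
    } else {
      read_cohort(config$input)
    }
  })
  fc <- stage("filter_complete", filter_complete(cohort))
  mh <- stage("mahalanobis", mahalanobis_exclude(
    fc$table, alpha = config$mahalanobis_alpha,
    per_site = config$mahalanobis_per_site))
  qc <- list(filter_complete = fc$report, mahalanobis = mh$report)
  icv <- NULL
  adjusted <- mh$table
  if (config$icv_adjust) {
    icv_res <- stage("icv_adjust", adjust_icv(adjusted))
    adjusted <- icv_res$table
    icv <- icv_res$report
  }
  harm <- stage("harmonize", harmonize_cohort(
    adjusted, age_degree = config$combat_age_degree,
    per_hemisphere = config$combat_per_hemisphere))
  tab <- harm$table

  cols <- volume_columns()
  fp_fits <- stage("trajectories", {
    out <- lapply(cols, function(cl) {
      select_fp(tab[[cl]], tab$age, tab$sex, tab$site_id,
                max_degree = config$fp_max_degree, alpha = config$fp_alpha,
                age_scale = config$fp_age_scale)
    })
    names(out) <- cols
    out
  })
  fp_by_sex <- stage("trajectories_by_sex", {
    out <- lapply(cols, function(cl) fit_fp_by_sex(
      tab, cl, max_degree = config$fp_max_degree, alpha = config$fp_alpha,
      age_scale = config$fp_age_scale))
    names(out) <- cols
    out
  })
  correlations <- stage("ageband_correlations", {
    out <- do.call(rbind, lapply(cols, function(cl) {
      cbind(region_hemisphere = cl,
            ageband_correlations(tab, cl, config$bands))
    }))
    out
  })
  corrected_alpha <- bonferroni_threshold(0.05, length(cols))
  variance_reports <- stage("variability", {
    out <- lapply(cols, function(cl) variance_report(
      tab, fp_fits[[cl]], cl, bands = config$bands,
      corrected_alpha = corrected_alpha, method = config$variance_method))
    names(out) <- cols
    out
  })
  band_meta <- stage("variability_meta", {
    out <- lapply(cols, function(cl) variability_by_band_meta(
      tab, cl, bands = config$bands))
    names(out) <- cols
    out
  })
  lms_models <- stage("centiles", {
    out <- list()
    for (cl in cols) {
      for (s in c("M", "F")) {
        idx <- tab$sex == s & tab[[cl]] > 0
        out[[paste(cl, s, sep = "_")]] <- fit_lms(
          tab[[cl]][idx], tab$age[idx], df_grid = config$centile_df_grid,
          penalty_k = config$centile_penalty_k)
      }
    }
    out
  })
  centiles <- stage("centile_tables", {
    do.call(rbind, lapply(names(lms_models), function(nm) {
      parts <- strsplit(nm, "_")[[1]]
      sex <- parts[length(parts)]
      rh <- paste(parts[-length(parts)], collapse = "_")
      centile_table(lms_models[[nm]], levels = config$centile_levels,
                    stratum = list(region_hemisphere = rh, sex = sex))
    }))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("lifespanvol")),
    r_version = R.version.string,
    seed = config$seed, config_hash = config_hash(config),
    icv_adjusted = config$icv_adjust,
    n_input = qc$filter_complete$n_input,
    n_incomplete_removed = qc$filter_complete$n_incomplete_removed,
    n_outliers_removed = qc$mahalanobis$n_outliers_removed,
    n_analyzed = nrow(tab), n_sites = length(unique(tab$site_id)),
    n_fp_fits = length(fp_fits),
    n_variance_reports = length(variance_reports),
    n_centile_tables = length(lms_models),
    outputs = character(0))

  bundle <- list(cohort = cohort, qc = qc, icv = icv, adjusted = adjusted,
                 harmonized = tab,
                 combat_model = harm$model, fp_fits = fp_fits,
                 fp_by_sex = fp_by_sex, correlations = correlations,
                 variance_reports = variance_reports, band_meta = band_meta,
                 lms_models = lms_models, centiles = centiles,
                 manifest = manifest, config = config)
  if (!is.null(config$out_dir)) {
    bundle$manifest$outputs <- write_pipeline_outputs(bundle, config)
    manifest_path <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(bundle$manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(bundle)
}

# write every stage artefact; returns the relative paths written
write_pipeline_outputs <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  tag <- if (config$icv_adjust) "" else "icv_unadjusted_"
  out <- character(0)
  put <- function(rel) { out <<- c(out, rel); file.path(config$out_dir, rel) }
  write_cohort(bundle$harmonized, put(paste0(tag, "harmonized_cohort.csv")))
  jsonlite::write_json(bundle$qc, put(paste0(tag, "qc_report.json")),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$combat_model) &&
      inherits(bundle$combat_model, "combat_model")) {
    write_combat_model(bundle$combat_model, put(paste0(tag, "combat_model.json")))
  }
  jsonlite::write_json(lapply(bundle$fp_fits, fp_fit_dump),
                       put(paste0(tag, "fp_fits.json")),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(fp_curve_table(bundle$fp_fits),
                   put(paste0(tag, "fp_curves.csv")), row.names = FALSE)
  utils::write.csv(bundle$correlations,
                   put(paste0(tag, "ageband_correlations.csv")),
                   row.names = FALSE)
  var_tab <- do.call(rbind, lapply(bundle$variance_reports, function(vr) {
    cbind(region_hemisphere = vr$region_hemisphere, vr$per_band,
          omnibus_stat = vr$omnibus_stat, omnibus_p = vr$omnibus_p,
          significant = vr$significant)
  }))
  utils::write.csv(var_tab, put(paste0(tag, "variance_reports.csv")),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(bundle$band_meta, function(bm) lapply(bm, unclass)),
    put(paste0(tag, "band_meta_sd.json")), auto_unbox = TRUE, digits = NA)
  utils::write.csv(bundle$centiles, put(paste0(tag, "centile_tables.csv")),
                   row.names = FALSE)
  out
}
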