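#' Age-band inter-individual variability statistic
#'
#' Summarizes dispersion within an age band as the natural log of the mean
#' squared residual, ln(sum(e_i^2)/n_t), where the residuals e_i come from
#' the selected fractional polynomial fit of the same region-hemisphere and
#' n_t is the number of observations in the band.
#'
#' @param residuals numeric vector of residuals (mm^3) for one band.
#' @return scalar ln mean squared residual.
#' @export
band_variance_stat <- function(residuals) {
  if (!length(residuals)) stop("empty band: no residuals")
  ms <- mean(residuals^2)
  if (ms <= 0) stop("all residuals are zero; ln mean squared residual is -Inf")
  log(ms)
}

#' Omnibus test of equal residual variance across age bands
#'
#' Brown-Forsythe test (median-centered Levene) on the absolute residuals
#' across bands, robust to non-normal residuals; Bartlett's test is
#' available for audit.
#'
#' @param residuals numeric vector of residuals.
#' @param band factor/character of band membership, same length.
#' @param method `"brown_forsythe"` (default) or `"bartlett"`.
#' @return list with `statistic`, `p`, `df`, `method`.
#' @export
omnibus_variance_test <- function(residuals, band,
                                  method = c("brown_forsythe", "bartlett")) {
  method <- match.arg(method)
  band <- factor(band)
  keep <- !is.na(band) & !is.na(residuals)
  residuals <- residuals[keep]
  band <- droplevels(band[keep])
  sizes <- table(band)
  sizes <- sizes[sizes >= 3L]
  if (length(sizes) < 2L) stop("need at least 2 bands with >= 3 members")
  use <- band %in% names(sizes)
  residuals <- residuals[use]
  band <- droplevels(band[use])
  if (method == "brown_forsythe") {
    lt <- car::leveneTest(residuals, group = band, center = stats::median)
    list(statistic = unname(lt[1, "F value"]), p = unname(lt[1, "Pr(>F)"]),
         df = c(lt[1, "Df"], lt[2, "Df"]), method = method)
  } else {
    bt <- stats::bartlett.test(residuals, g = band)
    list(statistic = unname(bt$statistic), p = bt$p.value,
         df = unname(bt$parameter), method = method)
  }
}

#' Bonferroni-corrected significance threshold
#'
#' @param family_alpha family-wise alpha.
#' @param n_tests number of tests in the family.
#' @return `family_alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 16)  # 0.003125, i.e. 0.003 at 3 decimals
#' @export
bonferroni_threshold <- function(family_alpha, n_tests) {
  if (n_tests < 1) stop("n_tests must be at least 1")
  stopifnot(family_alpha > 0, family_alpha <= 1)
  family_alpha / n_tests
}

#' Random-effects meta-analysis of per-site standard deviations
#'
#' Pools per-site SDs on the log scale using the small-sample
#' bias-corrected log-SD estimator: effect ln(sd) + 1/(2(n-1)) with
#' sampling variance 1/(2(n-1)), combined by DerSimonian-Laird random
#' effects. Sites with sd <= 0 or n < 2 are dropped with a warning.
#'
#' @param sds per-site standard deviations (mm^3).
#' @param ns per-site sample sizes.
#' @param sites optional site labels.
#' @param bias_correction include the 1/(2(n-1)) mean correction.
#' @return object of class `meta_sd_result`: `per_site` data.frame
#'   (site, n, sd, effect, var_effect), `pooled_effect`, `pooled_se`,
#'   `tau2`, `method`.
#' @export
meta_sd <- function(sds, ns, sites = NULL, bias_correction = TRUE) {
  stopifnot(length(sds) == length(ns))
  if (is.null(sites)) sites <- paste0("site", seq_along(sds))
  usable <- is.finite(sds) & sds > 0 & ns >= 2
  if (any(!usable)) {
    warning(sum(!usable), " site(s) dropped (sd <= 0 or n < 2): ",
            paste(sites[!usable], collapse = ", "))
  }
  if (sum(usable) < 2L) stop("need at least 2 usable sites for meta-analysis")
  sds <- sds[usable]; ns <- ns[usable]; sites <- sites[usable]
  vi <- 1 / (2 * (ns - 1))
  yi <- log(sds) + if (bias_correction) vi else 0
  fit <- metafor::rma(yi = yi, vi = vi, method = "DL")
  structure(list(per_site = data.frame(site = sites, n = ns, sd = sds,
                                       effect = yi, var_effect = vi),
                 pooled_effect = as.numeric(fit$beta),
                 pooled_se = fit$se, tau2 = max(fit$tau2, 0),
                 method = "DerSimonian-Laird on lnSD"),
            class = "meta_sd_result")
}

#' Per-band meta-analysis of site SDs
#'
#' Within each age band, computes each site's SD of the adjusted volume and
#' pools the log-SDs across sites with [meta_sd()], exposing the
#' early/middle/late variability comparison. Bands absent from every site
#' (or with fewer than 2 usable sites) are omitted with a warning.
#'
#' @param table cohort data.frame (adjusted/harmonized volumes).
#' @param region_hemisphere one of [volume_columns()].
#' @param bands named band list as in [age_bands()].
#' @param min_site_n minimum per-site rows within a band for that site to
#'   contribute.
#' @param bias_correction passed to [meta_sd()].
#' @return named list of `meta_sd_result`, one per retained band.
#' @export
variability_by_band_meta <- function(table, region_hemisphere,
                                     bands = age_bands(), min_site_n = 5L,
                                     bias_correction = TRUE) {
  stopifnot(region_hemisphere %in% volume_columns())
  lab <- band_assign(table$age, bands)
  out <- list()
  for (nm in names(bands)) {
    idx <- !is.na(lab) & lab == nm
    if (!any(idx)) {
      warning("band '", nm, "' has no observations; omitted")
      next
    }
    sub <- table[idx, ]
    stats_by_site <- lapply(split(sub[[region_hemisphere]], sub$site_id),
                            function(v) c(sd = stats::sd(v), n = length(v)))
    m <- do.call(rbind, stats_by_site)
    keep <- m[, "n"] >= min_site_n & is.finite(m[, "sd"]) & m[, "sd"] > 0
    if (sum(keep) < 2L) {
      warning("band '", nm, "' has fewer than 2 usable sites; omitted")
      next
    }
    out[[nm]] <- meta_sd(m[keep, "sd"], m[keep, "n"],
                         sites = rownames(m)[keep],
                         bias_correction = bias_correction)
  }
  out
}

#' Variance report for one region-hemisphere
#'
#' Assembles the age-band variability analysis for one structure: residuals
#' from the selected pooled-sex FP fit, the ln mean-squared-residual
#' statistic and SD per band, the omnibus variance test across bands and
#' the Bonferroni decision at `corrected_alpha`.
#'
#' @param table cohort data.frame the fit was estimated on.
#' @param fit the selected `fp_fit` for this region-hemisphere.
#' @param region_hemisphere one of [volume_columns()].
#' @param bands named band list.
#' @param corrected_alpha the Bonferroni-corrected alpha (default
#'   0.05 / 16).
#' @param method omnibus test, see [omnibus_variance_test()].
#' @return list of class `variance_report` with `per_band` data.frame,
#'   `omnibus_stat`, `omnibus_p`, `significant`, `corrected_alpha` and the
#'   count of rows outside every band.
#' @export
variance_report <- function(table, fit, region_hemisphere,
                            bands = age_bands(),
                            corrected_alpha = bonferroni_threshold(0.05, 16),
                            method = "brown_forsythe") {
  stopifnot(inherits(fit, "fp_fit"), region_hemisphere %in% volume_columns())
  res <- table[[region_hemisphere]] -
    predict(fit, table$age, table$sex)
  lab <- band_assign(table$age, bands)
  per_band <- do.call(rbind, lapply(names(bands), function(nm) {
    idx <- !is.na(lab) & lab == nm
    if (!any(idx)) return(NULL)
    data.frame(band = nm, n = sum(idx),
               stat = band_variance_stat(res[idx]),
               sd = stats::sd(res[idx]))
  }))
  omni <- omnibus_variance_test(res, lab, method = method)
  structure(list(region_hemisphere = region_hemisphere, per_band = per_band,
                 omnibus_stat = omni$statistic, omnibus_p = omni$p,
                 significant = omni$p < corrected_alpha,
                 corrected_alpha = corrected_alpha, method = omni$method,
                 n_outside_bands = sum(is.na(lab))),
            class = "variance_report")
}
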