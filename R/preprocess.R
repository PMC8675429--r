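#' Complete-case filtering of a cohort table
#'
#' Keeps only participants with non-missing age, sex, ICV and all 16
#' region-hemisphere volumes, mirroring the pooled-analysis convention that
#' only individuals with complete data enter the analysis.
#'
#' @param table cohort data.frame ([cohort_columns()] schema).
#' @return list with `table` (the filtered cohort) and `report`, a QC report
#'   list with counts (`n_input`, `n_incomplete_removed`) and the removed
#'   participant IDs.
#' @export
filter_complete <- function(table) {
  check_cohort(table)
  needed <- c("age", "sex", "icv", volume_columns())
  complete <- stats::complete.cases(table[needed])
  if (!any(complete)) {
    n_miss <- colSums(is.na(table[needed]))
    stop("no complete rows remain; missingness per column: ",
         paste(sprintf("%s=%d", names(n_miss)[n_miss > 0], n_miss[n_miss > 0]),
               collapse = ", "))
  }
  report <- list(n_input = nrow(table),
                 n_incomplete_removed = sum(!complete),
                 removed_ids = table$participant_id[!complete])
  list(table = table[complete, , drop = FALSE], report = report)
}

#' Multivariate outlier exclusion by Mahalanobis distance
#'
#' Computes the squared Mahalanobis distance of each participant's
#' 16-dimensional volume vector from the pooled mean and covariance and
#' removes rows exceeding the chi-square quantile at `1 - alpha` with 16
#' degrees of freedom. A small ridge (`ridge * trace(S)/p` on the diagonal)
#' stabilizes the covariance; the pooled (all-site) computation is the
#' default, with a per-site option.
#'
#' @param table complete-case cohort data.frame.
#' @param alpha upper-tail probability defining the exclusion threshold
#'   (default 0.001). `alpha = 0` disables exclusion.
#' @param per_site if `TRUE`, compute distances within each site separately.
#' @param ridge relative ridge added to the covariance diagonal.
#' @return list with `table` (rows kept) and `report` containing counts, the
#'   chi-square threshold used and the excluded IDs.
#' @export
mahalanobis_exclude <- function(table, alpha = 0.001, per_site = FALSE,
                                ridge = 1e-6) {
  check_cohort(table)
  vols <- as.matrix(table[volume_columns()])
  if (anyNA(vols)) stop("mahalanobis_exclude requires a complete-case table")
  p <- ncol(vols)
  threshold <- if (alpha <= 0) Inf else stats::qchisq(1 - alpha, df = p)
  d2_for <- function(x) {
    if (nrow(x) <= p) stop("need more rows than the ", p, " volume columns")
    S <- stats::cov(x)
    S <- S + diag(ridge * sum(diag(S)) / p, p)
    if (rcond_sym(S) < 1e-14) {
      stop("volume covariance is singular; increase the ridge or drop columns")
    }
    stats::mahalanobis(x, colMeans(x), S)
  }
  d2 <- if (per_site) {
    out <- numeric(nrow(vols))
    for (s in unique(table$site_id)) {
      idx <- table$site_id == s
      out[idx] <- d2_for(vols[idx, , drop = FALSE])
    }
    out
  } else {
    d2_for(vols)
  }
  drop <- d2 > threshold
  report <- list(n_input = nrow(table), n_outliers_removed = sum(drop),
                 outlier_ids = table$participant_id[drop],
                 mahalanobis_threshold = threshold, alpha = alpha)
  list(table = table[!drop, , drop = FALSE], report = report)
}

# reciprocal condition number of a symmetric PSD matrix
rcond_sym <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

#' Per-site ICV adjustment model for one region-hemisphere
#'
#' Within one site, regresses the raw volume of one region-hemisphere on
#' intracranial volume by ordinary least squares; the slope `b` and the
#' within-site mean ICV define the covariance-style adjustment
#' `adjusted = raw - b * (ICV - mean ICV)`.
#'
#' @param table cohort data.frame.
#' @param site_id site whose rows are used.
#' @param region_hemisphere one of [volume_columns()].
#' @return list of class `icv_adjustment` with `b`, `site_icv_mean`, `n`,
#'   plus the site and column labels.
#' @export
fit_icv_adjustment <- function(table, site_id, region_hemisphere) {
  stopifnot(region_hemisphere %in% volume_columns())
  rows <- table[table$site_id == site_id, ]
  if (nrow(rows) < 3L) stop("need at least 3 rows at site ", site_id)
  icv <- rows$icv
  y <- rows[[region_hemisphere]]
  sxx <- sum((icv - mean(icv))^2)
  if (sxx <= 0) stop("zero ICV variance at site ", site_id,
                     "; slope b is undefined")
  b <- sum((icv - mean(icv)) * (y - mean(y))) / sxx
  structure(list(site_id = site_id, region_hemisphere = region_hemisphere,
                 b = b, site_icv_mean = mean(icv), n = nrow(rows)),
            class = "icv_adjustment")
}

#' Apply an ICV adjustment to raw volumes
#'
#' @param model an `icv_adjustment` from [fit_icv_adjustment()].
#' @param raw raw volume(s) in mm^3.
#' @param icv intracranial volume(s) in mm^3.
#' @return adjusted volume(s): `raw - b * (icv - site_icv_mean)`.
#' @export
apply_icv_adjustment <- function(model, raw, icv) {
  stopifnot(inherits(model, "icv_adjustment"))
  raw - model$b * (icv - model$site_icv_mean)
}

#' ICV-adjust every region-hemisphere volume, site by site
#'
#' Fits [fit_icv_adjustment()] for each (site, region-hemisphere) and
#' replaces raw volumes with adjusted ones. Sites with fewer than
#' `min_site_n` rows inherit the pooled (all-site) slope for each column,
#' recentered at their own mean ICV; these sites are listed in the report.
#'
#' @param table complete-case cohort data.frame.
#' @param min_site_n minimum site size for a site-specific slope.
#' @return list with `table` (adjusted volumes), `models` (nested list
#'   site -> column -> `icv_adjustment`) and `report` (pooled-slope sites).
#' @export
adjust_icv <- function(table, min_site_n = 10L) {
  check_cohort(table)
  cols <- volume_columns()
  sites <- unique(table$site_id)
  icv_all <- table$icv
  sxx_all <- sum((icv_all - mean(icv_all))^2)
  pooled_b <- vapply(cols, function(cl) {
    y <- table[[cl]]
    sum((icv_all - mean(icv_all)) * (y - mean(y))) / sxx_all
  }, numeric(1))
  models <- list()
  out <- table
  small_sites <- character(0)
  for (s in sites) {
    idx <- table$site_id == s
    use_pooled <- sum(idx) < min_site_n ||
      sum((table$icv[idx] - mean(table$icv[idx]))^2) <= 0
    if (use_pooled) small_sites <- c(small_sites, s)
    site_models <- list()
    for (cl in cols) {
      m <- if (use_pooled) {
        structure(list(site_id = s, region_hemisphere = cl, b = pooled_b[[cl]],
                       site_icv_mean = mean(table$icv[idx]), n = sum(idx)),
                  class = "icv_adjustment")
      } else {
        fit_icv_adjustment(table[idx, ], s, cl)
      }
      out[idx, cl] <- apply_icv_adjustment(m, table[idx, cl], table$icv[idx])
      site_models[[cl]] <- m
    }
    models[[s]] <- site_models
  }
  list(table = out, models = models,
       report = list(pooled_slope_sites = small_sites, min_site_n = min_site_n))
}
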