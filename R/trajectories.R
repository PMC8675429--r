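#' Fractional polynomial specification
#'
#' A fractional polynomial (FP) in a positive predictor x uses powers drawn
#' from the fixed set \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}, where 0 encodes
#' ln(x). A repeated power multiplies the previous term by ln(x)
#' (the Royston-Altman convention). Age is divided by `age_scale` before
#' transformation to keep the basis well conditioned.
#'
#' @param powers numeric vector (length 0-3) of powers from the permitted
#'   set; sorted ascending internally. Length 0 encodes the age-free model.
#' @param age_scale divisor applied to age before the power transform.
#' @return object of class `fp_spec`.
#' @export
fp_spec <- function(powers = 1, age_scale = 10) {
  allowed <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)
  powers <- sort(as.numeric(powers))
  if (length(powers) > 3L) stop("fractional polynomial degree is capped at 3")
  if (length(powers) && !all(powers %in% allowed)) {
    stop("powers must come from {-2, -1, -0.5, 0, 0.5, 1, 2, 3}")
  }
  structure(list(powers = powers, age_scale = age_scale,
                 degree = length(powers)), class = "fp_spec")
}

#' Fractional polynomial basis
#'
#' Column j is `x^p_j` (`ln x` for p = 0); when p_j equals p_(j-1) the
#' column is the previous column multiplied by `ln x`.
#'
#' @param x positive numeric vector (already scaled).
#' @param powers numeric vector of powers, or an [fp_spec()].
#' @return matrix with one column per power.
#' @export
fp_basis <- function(x, powers) {
  if (inherits(powers, "fp_spec")) powers <- powers$powers
  if (any(x <= 0)) stop("fractional polynomial basis requires x > 0")
  if (!length(powers)) return(matrix(numeric(0), length(x), 0))
  lx <- log(x)
  out <- matrix(0, length(x), length(powers))
  for (j in seq_along(powers)) {
    if (j > 1L && powers[j] == powers[j - 1L]) {
      out[, j] <- out[, j - 1L] * lx
    } else if (powers[j] == 0) {
      out[, j] <- lx
    } else {
      out[, j] <- x^powers[j]
    }
  }
  colnames(out) <- paste0("fp", seq_along(powers))
  out
}

# internal: model matrix for an FP fit
fp_design <- function(age, sex, spec, include_sex) {
  X <- matrix(1, length(age), 1, dimnames = list(NULL, "intercept"))
  if (include_sex) X <- cbind(X, sex = ifelse(sex == "M", 0.5, -0.5))
  cbind(X, fp_basis(age / spec$age_scale, spec))
}

# internal: fast rss of y on X via QR least squares
rss_of <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Fit a fractional polynomial age model
#'
#' Gaussian OLS of a volume on an intercept, a sum-to-zero sex contrast
#' (+1/2 male, -1/2 female, so the intercept is the cross-sex mean) and the
#' FP basis of scaled age. Standard errors are adjusted for site clustering
#' with the cluster-robust sandwich estimator; with a single site this
#' degenerates to the heteroscedasticity-robust estimator (with a warning).
#' The partial R-squared for age is R2(full) - R2(covariates-only).
#'
#' @param y numeric vector of volumes (mm^3).
#' @param age ages in years.
#' @param sex `"M"`/`"F"` vector.
#' @param sites site label per observation.
#' @param spec an [fp_spec()].
#' @param include_sex include the sex contrast (dropped automatically when
#'   sex is constant).
#' @param robust compute cluster-robust standard errors (skippable inside
#'   selection loops).
#' @return object of class `fp_fit`: spec, named coefficients, `rss`,
#'   Gaussian `deviance` (-2 log-likelihood), `robust_se`,
#'   `partial_r2_age`, `n`, `n_sites` and an (initially empty)
#'   `selection_trace`.
#' @export
fit_fp <- function(y, age, sex, sites, spec = fp_spec(1),
                   include_sex = TRUE, robust = TRUE) {
  stopifnot(inherits(spec, "fp_spec"))
  n <- length(y)
  if (n <= spec$degree + 2L) stop("too few observations for this degree")
  include_sex <- include_sex && length(unique(sex)) > 1L
  X <- fp_design(age, sex, spec, include_sex)
  if (qr(X)$rank < ncol(X)) {
    stop("collinear fractional polynomial basis (degenerate age distribution)")
  }
  ls <- stats::lm.fit(X, y)
  rss <- sum(ls$residuals^2)
  coefs <- ls$coefficients
  tss <- sum((y - mean(y))^2)
  X0 <- X[, setdiff(colnames(X), colnames(X)[grep("^fp", colnames(X))]),
          drop = FALSE]
  rss0 <- rss_of(y, X0)
  r2_full <- if (tss > 0) 1 - rss / tss else 0
  r2_cov <- if (tss > 0) 1 - rss0 / tss else 0
  partial_r2 <- max(0, min(1, r2_full - r2_cov))
  robust_se <- NULL
  if (robust) {
    df <- data.frame(y = y, X[, -1, drop = FALSE], check.names = FALSE)
    lmfit <- stats::lm(y ~ ., data = df)
    vc <- if (length(unique(sites)) > 1L) {
      sandwich::vcovCL(lmfit, cluster = factor(sites))
    } else {
      warning("single site: using heteroscedasticity-robust SEs")
      sandwich::vcovHC(lmfit, type = "HC1")
    }
    robust_se <- sqrt(diag(vc))
    names(robust_se) <- colnames(X)
  }
  structure(list(spec = spec, coefficients = coefs, include_sex = include_sex,
                 rss = rss,
                 deviance = n * (log(2 * pi * max(rss, .Machine$double.xmin) / n) + 1),
                 robust_se = robust_se, partial_r2_age = partial_r2,
                 n = n, n_sites = length(unique(sites)),
                 selection_trace = list()),
            class = "fp_fit")
}

#' Predict the fitted mean curve of an FP fit
#'
#' @param object an `fp_fit`.
#' @param age ages in years.
#' @param sex `"M"`, `"F"` or `NULL` for the cross-sex reference curve.
#' @param ... unused.
#' @return fitted mean volumes.
#' @export
predict.fp_fit <- function(object, age, sex = NULL, ...) {
  B <- fp_basis(age / object$spec$age_scale, object$spec)
  out <- rep(object$coefficients[["intercept"]], length(age))
  if (object$include_sex) {
    s <- if (is.null(sex)) 0 else ifelse(sex == "M", 0.5, -0.5)
    out <- out + object$coefficients[["sex"]] * s
  }
  if (ncol(B)) out <- out + drop(B %*% object$coefficients[colnames(B)])
  out
}

# all power multisets of a given degree (combinations with repetition)
fp_power_sets <- function(degree) {
  p <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)
  if (degree == 1) return(lapply(p, identity))
  out <- list()
  if (degree == 2) {
    for (i in seq_along(p)) for (j in i:length(p)) {
      out[[length(out) + 1L]] <- c(p[i], p[j])
    }
  } else if (degree == 3) {
    for (i in seq_along(p)) for (j in i:length(p)) for (k in j:length(p)) {
      out[[length(out) + 1L]] <- c(p[i], p[j], p[k])
    }
  } else {
    stop("degree must be 1, 2 or 3")
  }
  out
}

#' Closed-test fractional polynomial model selection
#'
#' Finds the best-deviance FP of each degree 1..`max_degree` over the full
#' power grid (8, 36 and 120 candidate power sets), then walks the closed
#' test down from the top: best FP3 vs best FP2 by chi-square
#' likelihood-ratio test with 2 df per degree step; if not significant, FP2
#' vs FP1; then the best FP1 against the straight line by a partial F-test
#' with 1 numerator df (the power treated as fixed); finally the straight
#' line against the covariates-only null. The lowest-degree surviving model
#' is refitted with cluster-robust SEs and returned with the full selection
#' trace. The strict default cut-off `alpha = 0.01` guards against
#' over-fitting at densely sampled ages.
#'
#' @inheritParams fit_fp
#' @param max_degree highest FP degree considered (<= 3).
#' @param alpha significance cut-off of each selection test.
#' @param age_scale divisor applied to age before the power transform.
#' @return the selected `fp_fit`, with `selection_trace` listing each
#'   comparison (statistic, df, p, decision).
#' @export
select_fp <- function(y, age, sex, sites, max_degree = 3, alpha = 0.01,
                      age_scale = 10, include_sex = TRUE) {
  n <- length(y)
  include_sex <- include_sex && length(unique(sex)) > 1L
  stopifnot(max_degree >= 1, max_degree <= 3)
  null_spec <- fp_spec(numeric(0), age_scale)
  X_null <- fp_design(age, sex, null_spec, include_sex)
  rss_null <- rss_of(y, X_null)
  best <- vector("list", max_degree)
  for (m in seq_len(max_degree)) {
    best_rss <- Inf; best_powers <- NULL
    for (pw in fp_power_sets(m)) {
      X <- fp_design(age, sex, fp_spec(pw, age_scale), include_sex)
      if (qr(X)$rank < ncol(X)) next
      r <- rss_of(y, X)
      if (r < best_rss) { best_rss <- r; best_powers <- pw }
    }
    if (is.null(best_powers)) stop("no non-collinear FP basis of degree ", m)
    best[[m]] <- list(powers = best_powers, rss = best_rss)
  }
  tss <- sum((y - mean(y))^2)
  if (best[[max_degree]]$rss <= 1e-12 * max(tss, 1) || rss_null <= 0) {
    stop("(near-)zero residual variance: likelihood-ratio tests are ",
         "degenerate; add minimal noise/jitter to the response")
  }
  line_rss <- rss_of(y, fp_design(age, sex, fp_spec(1, age_scale), include_sex))
  trace <- list()
  selected <- NULL
  for (m in rev(seq_len(max_degree))) {
    if (m >= 2) {
      stat <- n * log(best[[m - 1]]$rss / best[[m]]$rss)
      p <- stats::pchisq(stat, df = 2, lower.tail = FALSE)
      trace[[length(trace) + 1L]] <- list(
        comparison = sprintf("FP%d vs FP%d", m, m - 1),
        statistic = stat, df = 2, p = p, significant = p < alpha)
      if (p < alpha) { selected <- fp_spec(best[[m]]$powers, age_scale); break }
    } else {
      p_line <- ncol(X_null) + 1L
      f_stat <- max(0, (line_rss - best[[1]]$rss)) / (best[[1]]$rss / (n - p_line))
      p <- stats::pf(f_stat, 1, n - p_line, lower.tail = FALSE)
      trace[[length(trace) + 1L]] <- list(
        comparison = "FP1 vs line", statistic = f_stat, df = 1, p = p,
        significant = p < alpha)
      if (p < alpha) { selected <- fp_spec(best[[1]]$powers, age_scale); break }
      f_lin <- max(0, (rss_null - line_rss)) / (line_rss / (n - p_line))
      p_lin <- stats::pf(f_lin, 1, n - p_line, lower.tail = FALSE)
      trace[[length(trace) + 1L]] <- list(
        comparison = "line vs null", statistic = f_lin, df = 1, p = p_lin,
        significant = p_lin < alpha)
      selected <- if (p_lin < alpha) fp_spec(1, age_scale) else null_spec
    }
  }
  fit <- fit_fp(y, age, sex, sites, selected, include_sex = include_sex)
  fit$selection_trace <- trace
  fit
}

#' Default lifespan age bands
#'
#' Early life 6-29, middle life 30-59, late life 60-90 years (closed
#' intervals). Ages 3-5 fall outside every band and are excluded from
#' band-wise analyses only.
#'
#' @return named list of `c(lo, hi)` intervals.
#' @export
age_bands <- function() {
  list(early = c(6, 29), middle = c(30, 59), late = c(60, 90))
}

# internal: band label per age (NA outside all bands); band limits are
# whole years, so membership uses the completed age floor(age)
band_assign <- function(age, bands = age_bands()) {
  yrs <- floor(age)
  out <- rep(NA_character_, length(age))
  for (nm in names(bands)) {
    b <- bands[[nm]]
    out[yrs >= b[1] & yrs <= b[2]] <- nm
  }
  factor(out, levels = names(bands))
}

#' Age-band Pearson correlations between volume and age
#'
#' Pearson's r between one region-hemisphere volume and age within each age
#' band, pooled and stratified by sex. Bands with fewer than 3 rows or zero
#' variance yield `NA`.
#'
#' @param table cohort data.frame (typically ICV-adjusted and harmonized).
#' @param region_hemisphere one of [volume_columns()].
#' @param bands named list of bands as in [age_bands()].
#' @return data.frame with columns `band`, `group` (`all`/`M`/`F`), `n`, `r`.
#' @export
ageband_correlations <- function(table, region_hemisphere,
                                 bands = age_bands()) {
  stopifnot(region_hemisphere %in% volume_columns())
  lab <- band_assign(table$age, bands)
  rows <- list()
  for (nm in names(bands)) {
    for (grp in c("all", "M", "F")) {
      idx <- !is.na(lab) & lab == nm & (grp == "all" | table$sex == grp)
      y <- table[[region_hemisphere]][idx]
      a <- table$age[idx]
      r <- if (sum(idx) >= 3 && stats::sd(y) > 0 && stats::sd(a) > 0) {
        stats::cor(y, a)
      } else {
        NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(band = nm, group = grp,
                                              n = sum(idx), r = r)
    }
  }
  do.call(rbind, rows)
}

#' Sex-stratified fractional polynomial fits
#'
#' Runs [select_fp()] separately within each sex (the sex contrast is
#' dropped from the design). A sex with fewer than `min_n` rows is skipped
#' with a warning.
#'
#' @param table cohort data.frame.
#' @param region_hemisphere one of [volume_columns()].
#' @param min_n minimum subset size for a fit.
#' @param ... passed to [select_fp()].
#' @return named list with elements `M` and `F` (each an `fp_fit` or `NULL`).
#' @export
fit_fp_by_sex <- function(table, region_hemisphere, min_n = 50L, ...) {
  stopifnot(region_hemisphere %in% volume_columns())
  out <- list(M = NULL, F = NULL)
  for (s in c("M", "F")) {
    idx <- table$sex == s
    if (sum(idx) < min_n) {
      warning("fewer than ", min_n, " rows for sex ", s, "; fit skipped")
      next
    }
    out[[s]] <- select_fp(table[[region_hemisphere]][idx], table$age[idx],
                          table$sex[idx], table$site_id[idx],
                          include_sex = FALSE, ...)
  }
  out
}
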