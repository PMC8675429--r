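#' Box-Cox Cole-Green z-score
#'
#' Converts a measurement to its z-score under the LMS (BCCG) model with
#' Box-Cox power `lambda`, median-type location `mu` and coefficient of
#' variation `sigma`:
#' z = ((y/mu)^lambda - 1)/(lambda sigma) for lambda != 0 and
#' z = ln(y/mu)/sigma at lambda = 0. The power branch is computed with
#' `expm1`, so it is continuous in lambda through 0.
#'
#' @param y measurement(s), > 0.
#' @param lambda Box-Cox power (scalar).
#' @param mu location(s), > 0.
#' @param sigma coefficient(s) of variation, > 0.
#' @return z-score(s).
#' @export
bccg_z <- function(y, lambda, mu, sigma) {
  if (any(y <= 0) || any(mu <= 0) || any(sigma <= 0)) {
    stop("bccg_z requires y, mu and sigma to be positive")
  }
  u <- log(y / mu)
  if (lambda == 0) u / sigma else expm1(lambda * u) / (lambda * sigma)
}

#' Box-Cox Cole-Green log-likelihood
#'
#' Sum over observations of
#' lambda ln(y/mu) - ln y - ln sigma - ln(sqrt(2 pi)) - z^2/2,
#' the BCCG log density (the positivity truncation term is omitted, the
#' standard LMS practice, negligible for sigma << 1). At lambda = 1 this
#' equals the Gaussian log-likelihood with mean mu and SD mu*sigma.
#'
#' @param y measurements, > 0.
#' @param lambda Box-Cox power (scalar).
#' @param mu location vector (recycled), > 0.
#' @param sigma coefficient-of-variation vector (recycled), > 0.
#' @return scalar log-likelihood.
#' @export
bccg_loglik <- function(y, lambda, mu, sigma) {
  z <- bccg_z(y, lambda, mu, sigma)
  sum(lambda * log(y / mu) - log(y) - log(sigma) - 0.5 * log(2 * pi) -
        z^2 / 2)
}

# spline design for one LMS curve: intercept only (df = 1) or
# intercept + natural spline with df-1 basis columns
lms_basis <- function(age, df) {
  stopifnot(df >= 1)
  if (df == 1L) return(list(basis = NULL, df = 1L))
  b <- splines::ns(age, df = df - 1L)
  list(basis = b, df = df)
}

lms_design <- function(bs_obj, age) {
  if (is.null(bs_obj$basis)) {
    matrix(1, length(age), 1)
  } else {
    cbind(1, stats::predict(bs_obj$basis, age))
  }
}

# negative log-likelihood and analytic gradient in
# theta = (lambda, beta_mu, beta_sigma); eta_mu = M_mu beta_mu = ln mu,
# eta_s = M_s beta_s = ln sigma
lms_objective <- function(y, M_mu, M_s) {
  ly <- log(y)
  n <- length(y)
  p_mu <- ncol(M_mu); p_s <- ncol(M_s)
  split_theta <- function(theta) {
    list(lambda = theta[1],
         bmu = theta[1 + seq_len(p_mu)],
         bs = theta[1 + p_mu + seq_len(p_s)])
  }
  # the BCCG quantile 1 + lambda*sigma*z must stay positive across the
  # centile range of interest; keep the fit inside that region
  z_lim <- stats::qnorm(0.995)
  feasible <- function(lambda, sigma) {
    m <- max(abs(lambda) * sigma)
    1 - m * z_lim > 0
  }
  fn <- function(theta) {
    th <- split_theta(theta)
    eta_mu <- drop(M_mu %*% th$bmu); eta_s <- drop(M_s %*% th$bs)
    u <- ly - eta_mu
    lu <- th$lambda * u
    if (any(abs(lu) > 200) || any(abs(eta_s) > 200)) return(1e10)
    sigma <- exp(eta_s)
    if (!feasible(th$lambda, sigma)) return(1e10)
    z <- if (abs(th$lambda) < 1e-5) {
      (u + th$lambda * u^2 / 2 + th$lambda^2 * u^3 / 6) / sigma
    } else {
      expm1(lu) / (th$lambda * sigma)
    }
    ll <- sum(lu - ly - eta_s - 0.5 * log(2 * pi) - z^2 / 2)
    if (!is.finite(ll)) 1e10 else -ll
  }
  gr <- function(theta) {
    th <- split_theta(theta)
    eta_mu <- drop(M_mu %*% th$bmu); eta_s <- drop(M_s %*% th$bs)
    u <- ly - eta_mu
    lu <- th$lambda * u
    if (any(abs(lu) > 200) || any(abs(eta_s) > 200)) return(rep(0, length(theta)))
    sigma <- exp(eta_s)
    if (!feasible(th$lambda, sigma)) return(rep(0, length(theta)))
    w <- exp(lu)
    if (abs(th$lambda) < 1e-5) {
      z <- (u + th$lambda * u^2 / 2 + th$lambda^2 * u^3 / 6) / sigma
      dzdl <- (u^2 / 2 + th$lambda * u^3 / 3) / sigma
    } else {
      z <- expm1(lu) / (th$lambda * sigma)
      dzdl <- (u * w) / (th$lambda * sigma) - z / th$lambda
    }
    d_eta_mu <- -th$lambda + z * w / sigma
    d_eta_s <- z^2 - 1
    g <- c(sum(u - z * dzdl),
           drop(crossprod(M_mu, d_eta_mu)),
           drop(crossprod(M_s, d_eta_s)))
    if (any(!is.finite(g))) rep(0, length(theta)) else -g
  }
  list(fn = fn, gr = gr)
}

#' Fit an LMS (BCCG) normative model
#'
#' Models the age-conditional distribution of a positive measurement with
#' the LMS method: a scalar Box-Cox power lambda, ln mu represented as a
#' natural-spline expansion in age with `df_mu` degrees of freedom, and
#' ln sigma as a spline with `df_sigma` degrees of freedom. Each candidate
#' (df_mu, df_sigma) pair on the grid is fitted by quasi-Newton maximum
#' likelihood with analytic gradients; the returned model minimizes
#' GAIC = -2 loglik + penalty_k * (total edf), with edf = 1 + df_mu +
#' df_sigma. With unpenalized spline bases the effective degrees of freedom
#' equal the parameter counts, so GAIC over the df grid plays the role of
#' the smoothness selection. The optimizer is constrained to the parameter
#' region where the BCCG quantile term 1 + lambda sigma z stays positive
#' over the 0.5th-99.5th centile range, so every requested centile inside
#' that range is defined.
#'
#' @param y positive measurements (mm^3).
#' @param age ages in years (span of at least 20 years required).
#' @param df_grid data.frame or list with columns/elements `df_mu` and
#'   `df_sigma`; default grid crosses df_mu in 3..6 with df_sigma in 2..4.
#' @param penalty_k GAIC penalty per edf (3 sits between AIC's 2 and BIC's
#'   ln n).
#' @param min_n minimum stratum size.
#' @return object of class `lms_model`: `lambda`, spline coefficients and
#'   basis objects for the mu and sigma curves, `edf`, `gaic`, `penalty_k`,
#'   the fitted age range and `fit_meta` (per-candidate GAIC table,
#'   convergence flags).
#' @export
fit_lms <- function(y, age,
                    df_grid = expand.grid(df_mu = 3:6, df_sigma = 2:4),
                    penalty_k = 3, min_n = 50L) {
  stopifnot(length(y) == length(age))
  if (any(y <= 0)) stop("LMS requires strictly positive measurements")
  if (length(y) < min_n) stop("need at least ", min_n, " observations")
  if (diff(range(age)) < 20) stop("ages must span at least 20 years")
  df_grid <- as.data.frame(df_grid)
  stopifnot(all(c("df_mu", "df_sigma") %in% names(df_grid)), nrow(df_grid) >= 1)
  ly <- log(y)
  best <- NULL
  meta <- list()
  for (i in seq_len(nrow(df_grid))) {
    df_mu <- df_grid$df_mu[i]; df_sigma <- df_grid$df_sigma[i]
    b_mu <- lms_basis(age, df_mu)
    b_s <- lms_basis(age, df_sigma)
    M_mu <- lms_design(b_mu, age)
    M_s <- lms_design(b_s, age)
    # start: mu from the lognormal regression, sigma from its residual SD
    bmu0 <- stats::lm.fit(M_mu, ly)$coefficients
    r <- ly - drop(M_mu %*% bmu0)
    bs0 <- c(log(max(stats::sd(r), 1e-3)), rep(0, ncol(M_s) - 1L))
    obj <- lms_objective(y, M_mu, M_s)
    # start inside the feasible BCCG region (see lms_objective)
    lambda0 <- min(0.5, 0.8 / (stats::qnorm(0.995) * exp(bs0[1])))
    theta0 <- c(lambda0, bmu0, bs0)
    opt <- stats::optim(theta0, obj$fn, obj$gr, method = "BFGS",
                        control = list(maxit = 300, reltol = 1e-10))
    edf <- 1 + df_mu + df_sigma
    ll <- -opt$value
    gaic <- -2 * ll + penalty_k * edf
    converged <- opt$convergence == 0 && is.finite(gaic)
    meta[[i]] <- data.frame(df_mu = df_mu, df_sigma = df_sigma,
                            loglik = ll, gaic = gaic, edf = edf,
                            converged = converged,
                            iterations = unname(opt$counts["gradient"]))
    if (!is.finite(gaic)) next
    if (is.null(best) || gaic < best$gaic) {
      th <- theta0
      th[] <- opt$par
      best <- list(lambda = opt$par[1],
                   beta_mu = opt$par[1 + seq_len(ncol(M_mu))],
                   beta_sigma = opt$par[1 + ncol(M_mu) + seq_len(ncol(M_s))],
                   basis_mu = b_mu, basis_sigma = b_s,
                   edf = edf, gaic = gaic, loglik = ll,
                   converged = converged)
    }
  }
  meta <- do.call(rbind, meta)
  if (is.null(best) || !any(meta$converged)) {
    stop("LMS fit failed to converge on every df-grid candidate; trace:\n",
         paste(utils::capture.output(print(meta)), collapse = "\n"))
  }
  structure(list(lambda = best$lambda, beta_mu = best$beta_mu,
                 beta_sigma = best$beta_sigma,
                 basis_mu = best$basis_mu, basis_sigma = best$basis_sigma,
                 age_range = range(age), edf = best$edf, gaic = best$gaic,
                 loglik = best$loglik, penalty_k = penalty_k,
                 fit_meta = list(grid = meta, converged = best$converged)),
            class = "lms_model")
}

# evaluate lambda/mu(age)/sigma(age); extrapolation guarded
lms_params <- function(model, age, allow_extrapolation = FALSE) {
  stopifnot(inherits(model, "lms_model"))
  if (!allow_extrapolation &&
      (any(age < model$age_range[1] - 1e-9) ||
       any(age > model$age_range[2] + 1e-9))) {
    stop("age outside the fitted range [",
         round(model$age_range[1], 2), ", ", round(model$age_range[2], 2),
         "]; set allow_extrapolation = TRUE to override")
  }
  mu <- exp(unname(drop(lms_design(model$basis_mu, age) %*% model$beta_mu)))
  sigma <- exp(unname(drop(lms_design(model$basis_sigma, age) %*%
                             model$beta_sigma)))
  list(lambda = model$lambda, mu = mu, sigma = sigma)
}

#' Centile curve of a fitted LMS model
#'
#' Value of the `level`-th centile at each age:
#' mu (1 + lambda sigma z)^(1/lambda) for lambda != 0 (an error if the
#' argument is non-positive) and mu exp(sigma z) at lambda = 0, with z the
#' standard normal quantile of `level`/100.
#'
#' @param model an `lms_model`.
#' @param ages ages in years within the fitted range.
#' @param level centile level in (0, 100).
#' @param allow_extrapolation permit ages outside the fitted range.
#' @return volumes (mm^3) at the requested centile.
#' @export
centile_curve <- function(model, ages, level, allow_extrapolation = FALSE) {
  stopifnot(level > 0, level < 100)
  p <- lms_params(model, ages, allow_extrapolation)
  z <- stats::qnorm(level / 100)
  if (p$lambda == 0) {
    p$mu * exp(p$sigma * z)
  } else {
    arg <- 1 + p$lambda * p$sigma * z
    if (any(arg <= 0)) {
      stop("centile undefined: 1 + lambda*sigma*z <= 0 at some age")
    }
    p$mu * exp(log1p(p$lambda * p$sigma * z) / p$lambda)
  }
}

#' Centile of a measurement under a fitted LMS model
#'
#' Inverse lookup of [centile_curve()] at a fixed age:
#' Phi(z(y)) * 100 with z the BCCG z-score at the model's age-specific
#' lambda, mu, sigma.
#'
#' @param model an `lms_model`.
#' @param age age(s) in years.
#' @param y measurement(s), > 0.
#' @param allow_extrapolation permit ages outside the fitted range.
#' @return centile(s) in (0, 100).
#' @export
centile_of <- function(model, age, y, allow_extrapolation = FALSE) {
  p <- lms_params(model, age, allow_extrapolation)
  unname(stats::pnorm(bccg_z(y, p$lambda, p$mu, p$sigma)) * 100)
}

#' Tidy centile table over an age grid
#'
#' @param model an `lms_model`.
#' @param ages age grid (default: the fitted range in 0.5-year steps).
#' @param levels centile levels in percent.
#' @param stratum optional named list (e.g. structure/hemisphere/sex labels)
#'   replicated into columns.
#' @return data.frame with columns from `stratum`, plus `age`, `level`,
#'   `value`; values are strictly increasing in level at every age.
#' @export
centile_table <- function(model, ages = NULL,
                          levels = c(5, 25, 50, 75, 95), stratum = NULL) {
  if (is.null(ages)) {
    ages <- seq(model$age_range[1], model$age_range[2], by = 0.5)
  }
  out <- do.call(rbind, lapply(levels, function(lv) {
    data.frame(age = ages, level = lv,
               value = centile_curve(model, ages, lv))
  }))
  if (!is.null(stratum)) {
    for (nm in rev(names(stratum))) out <- cbind(stats::setNames(
      data.frame(rep(stratum[[nm]], nrow(out))), nm), out)
  }
  rownames(out) <- NULL
  out
}
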