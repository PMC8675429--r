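#' Covariate design matrix for harmonization
#'
#' Builds the biological-covariate design preserved during site
#' harmonization: an intercept, a sum-to-zero sex contrast (+1/2 male, -1/2
#' female) and a cubic polynomial basis in age centered at 45 years and
#' scaled by 1/45, flexible enough not to bend lifespan trajectories while
#' keeping the standardization linear. Zero (degenerate) columns are pruned:
#' a constant-sex input drops the sex column with a warning, and all-equal
#' ages drop the age columns.
#'
#' @param ages numeric vector of ages in years.
#' @param sexes character vector (`"M"`/`"F"`), same length.
#' @param age_degree polynomial degree of the age basis (default 3; 0
#'   removes age columns).
#' @param age_center,age_scale centering and scaling of age before the
#'   polynomial expansion.
#' @return full-column-rank design matrix with an `"design_spec"` attribute
#'   recording the basis so it can be rebuilt at apply time.
#' @export
build_design <- function(ages, sexes, age_degree = 3, age_center = 45,
                         age_scale = 45) {
  if (length(ages) == 0L) stop("empty input")
  stopifnot(length(ages) == length(sexes))
  if (anyNA(ages) || anyNA(sexes)) stop("missing values in ages/sexes")
  X <- matrix(1, length(ages), 1, dimnames = list(NULL, "intercept"))
  if (length(unique(sexes)) > 1L) {
    X <- cbind(X, sex = ifelse(sexes == "M", 0.5, -0.5))
  } else if (!is.null(sexes)) {
    warning("constant sex; dropping the sex column from the design")
  }
  if (age_degree >= 1) {
    u <- (ages - age_center) / age_scale
    for (d in seq_len(age_degree)) {
      col <- u^d
      if (sum(col^2) > 0) {
        X <- cbind(X, col)
        colnames(X)[ncol(X)] <- paste0("age", d)
      }
    }
  }
  attr(X, "design_spec") <- list(age_degree = age_degree,
                                 age_center = age_center,
                                 age_scale = age_scale,
                                 has_sex = "sex" %in% colnames(X))
  X
}

#' Fit parametric empirical-Bayes (ComBat) site harmonization
#'
#' Implements the standard parametric ComBat location-scale model. Each
#' feature is standardized using a pooled OLS fit on batch indicators plus
#' the covariate design (batch effects constrained to a size-weighted zero
#' sum); per-batch location (gamma) and scale (delta) estimates are then
#' shrunk across features toward method-of-moments empirical-Bayes priors
#' (normal for location, inverse-gamma for scale) by iterating the
#' conditional posterior updates until the largest relative change falls
#' below `tol`.
#'
#' @param data numeric matrix, features x subjects.
#' @param batches batch (site/scanner) label per subject.
#' @param design covariate design matrix from [build_design()] (first column
#'   must be the intercept).
#' @param tol convergence tolerance of the EB iteration.
#' @param max_iter iteration cap.
#' @return an object of class `combat_model`: per-batch per-feature
#'   `gamma_star`/`delta_star`, EB hyperparameters, the pooled feature
#'   variances and covariate coefficients needed to standardize new data,
#'   and the iteration count.
#' @export
fit_combat <- function(data, batches, design, tol = 1e-4, max_iter = 100L) {
  data <- as.matrix(data)
  if (is.null(rownames(data))) rownames(data) <- paste0("f", seq_len(nrow(data)))
  batches <- as.character(batches)
  stopifnot(ncol(data) == length(batches), nrow(design) == ncol(data))
  levels_b <- unique(batches)
  n_b <- vapply(levels_b, function(b) sum(batches == b), integer(1))
  if (length(levels_b) < 2L) stop("need at least 2 batches to harmonize")
  if (any(n_b < 2L)) stop("every batch needs at least 2 subjects; too small: ",
                          paste(levels_b[n_b < 2L], collapse = ", "))
  for (b in levels_b) {
    v <- apply(data[, batches == b, drop = FALSE], 1, stats::var)
    if (any(v <= 0)) {
      stop("zero variance in batch '", b, "' for feature(s): ",
           paste(rownames(data)[v <= 0], collapse = ", "))
    }
  }
  N <- ncol(data)
  batch_design <- stats::model.matrix(~ 0 + factor(batches, levels = levels_b))
  colnames(batch_design) <- levels_b
  cov_cols <- design[, colnames(design) != "intercept", drop = FALSE]
  X <- cbind(batch_design, cov_cols)
  if (qr(X)$rank < ncol(X)) stop("design is collinear with batch indicators")
  B <- solve(crossprod(X), crossprod(X, t(data)))   # p x features
  grand_mean <- drop((n_b / N) %*% B[seq_along(levels_b), , drop = FALSE])
  resid <- data - t(X %*% B)
  var_pooled <- rowMeans(resid^2)
  if (any(var_pooled <= 0)) {
    stop("zero pooled variance for feature(s): ",
         paste(rownames(data)[var_pooled <= 0], collapse = ", "))
  }
  cov_coef <- B[-seq_along(levels_b), , drop = FALSE]
  stand_mean <- outer(grand_mean, rep(1, N)) +
    (if (ncol(cov_cols)) t(cov_cols %*% cov_coef) else 0)
  Z <- (data - stand_mean) / sqrt(var_pooled)

  G <- length(var_pooled)
  gamma_hat <- t(matrix(vapply(levels_b, function(b)
    rowMeans(Z[, batches == b, drop = FALSE]), numeric(G)), nrow = G))
  delta_hat <- t(matrix(vapply(levels_b, function(b)
    apply(Z[, batches == b, drop = FALSE], 1, stats::var), numeric(G)), nrow = G))
  dimnames(gamma_hat) <- dimnames(delta_hat) <- list(levels_b, rownames(data))

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  hyper <- list()
  n_iter <- 0L
  for (bi in seq_along(levels_b)) {
    g <- gamma_hat[bi, ]; d <- delta_hat[bi, ]; n_i <- n_b[bi]
    g_bar <- mean(g)
    t2 <- if (G > 1L) stats::var(g) else 0
    m_d <- mean(d)
    s2_d <- if (G > 1L) stats::var(d) else 0
    a_pr <- if (s2_d > 0) (2 * s2_d + m_d^2) / s2_d else Inf
    b_pr <- if (s2_d > 0) (m_d * s2_d + m_d^3) / s2_d else Inf
    Zb <- Z[, batches == levels_b[bi], drop = FALSE]
    g_old <- g; d_old <- d
    it <- 0L
    repeat {
      it <- it + 1L
      g_new <- (t2 * n_i * g + d_old * g_bar) / (t2 * n_i + d_old)
      sum2 <- rowSums((Zb - g_new)^2)
      d_new <- if (is.finite(a_pr) && is.finite(b_pr)) {
        (0.5 * sum2 + b_pr) / (n_i / 2 + a_pr - 1)
      } else {
        d_old
      }
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
      g_old <- g_new; d_old <- d_new
      if (change < tol || it >= max_iter) break
    }
    gamma_star[bi, ] <- g_old
    delta_star[bi, ] <- pmax(d_old, 1e-12)
    hyper[[levels_b[bi]]] <- list(gamma_bar = g_bar, tau2 = t2,
                                  a_prior = a_pr, b_prior = b_pr)
    n_iter <- max(n_iter, it)
  }
  structure(list(batch_labels = levels_b, batch_sizes = n_b,
                 features = rownames(data),
                 design_spec = attr(design, "design_spec"),
                 design_colnames = colnames(design),
                 grand_mean = grand_mean, cov_coef = cov_coef,
                 var_pooled = var_pooled,
                 gamma_hat = gamma_hat, delta_hat = delta_hat,
                 gamma_star = gamma_star, delta_star = delta_star,
                 hyperparams = hyper, n_iter = n_iter, tol = tol),
            class = "combat_model")
}

#' Apply a fitted ComBat model
#'
#' Standardizes the data with the model's pooled coefficients, removes the
#' empirical-Bayes batch location/scale, and restores the grand
#' location/covariate structure and pooled scale. Row/column order and shape
#' are preserved.
#'
#' @param model a [fit_combat()] model.
#' @param data features x subjects matrix with the model's feature set.
#' @param batches batch label per subject; labels unseen at fit time are an
#'   error, as are batches with a single subject.
#' @param design covariate design built with the same basis as at fit time.
#' @return harmonized matrix, same dimensions as `data`.
#' @export
apply_combat <- function(model, data, batches, design) {
  stopifnot(inherits(model, "combat_model"))
  data <- as.matrix(data)
  batches <- as.character(batches)
  if (nrow(data) != length(model$features)) {
    stop("feature set does not match the fitted model")
  }
  unseen <- setdiff(unique(batches), model$batch_labels)
  if (length(unseen)) stop("batch label(s) not seen at fit time: ",
                           paste(unseen, collapse = ", "))
  tab <- table(batches)
  if (any(tab < 2L)) stop("single-subject batch at apply time: ",
                          paste(names(tab)[tab < 2L], collapse = ", "))
  if (!identical(colnames(design), model$design_colnames)) {
    stop("design columns do not match the fitted model")
  }
  cov_cols <- design[, colnames(design) != "intercept", drop = FALSE]
  stand_mean <- outer(model$grand_mean, rep(1, ncol(data))) +
    (if (ncol(cov_cols)) t(cov_cols %*% model$cov_coef) else 0)
  Z <- (data - stand_mean) / sqrt(model$var_pooled)
  for (b in unique(batches)) {
    idx <- batches == b
    Z[, idx] <- (Z[, idx, drop = FALSE] - model$gamma_star[b, ]) /
      sqrt(model$delta_star[b, ])
  }
  Z * sqrt(model$var_pooled) + stand_mean
}

#' Harmonize a cohort table across sites
#'
#' Pivots the 16 region-hemisphere volumes to a features x subjects matrix,
#' builds the covariate design from age and sex, fits parametric ComBat with
#' the scanner/site column as the batch, and returns the harmonized cohort.
#' With a single site the table passes through unchanged with a warning so
#' single-site sensitivity paths remain runnable. Hemispheres are harmonized
#' jointly by default; `per_hemisphere = TRUE` fits each hemisphere's eight
#' features separately.
#'
#' @param table complete-case cohort data.frame.
#' @param age_degree,age_center,age_scale passed to [build_design()].
#' @param per_hemisphere harmonize L and R feature blocks separately.
#' @param tol,max_iter EB iteration controls.
#' @return list with `table` (harmonized volumes) and `model` (a
#'   `combat_model`, or list of two when `per_hemisphere`; `NULL` on the
#'   single-site pass-through).
#' @export
harmonize_cohort <- function(table, age_degree = 3, age_center = 45,
                             age_scale = 45, per_hemisphere = FALSE,
                             tol = 1e-4, max_iter = 100L) {
  check_cohort(table)
  if (length(unique(table$site_id)) < 2L) {
    warning("single site; harmonization is a pass-through")
    return(list(table = table, model = NULL))
  }
  design <- build_design(table$age, table$sex, age_degree = age_degree,
                         age_center = age_center, age_scale = age_scale)
  blocks <- if (per_hemisphere) {
    list(L = grep("_L$", volume_columns(), value = TRUE),
         R = grep("_R$", volume_columns(), value = TRUE))
  } else {
    list(all = volume_columns())
  }
  out <- table
  models <- list()
  for (nm in names(blocks)) {
    mat <- t(as.matrix(table[blocks[[nm]]]))
    model <- fit_combat(mat, table$site_id, design, tol = tol,
                        max_iter = max_iter)
    harm <- apply_combat(model, mat, table$site_id, design)
    out[blocks[[nm]]] <- t(harm)
    models[[nm]] <- model
  }
  list(table = out, model = if (per_hemisphere) models else models[[1]])
}

#' Serialize a ComBat model to JSON
#'
#' Writes hyperparameters and per-batch estimates for audit.
#'
#' @param model a `combat_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_combat_model <- function(model, path) {
  stopifnot(inherits(model, "combat_model"))
  dump <- list(batch_labels = model$batch_labels,
               batch_sizes = as.list(model$batch_sizes),
               features = model$features,
               design_spec = model$design_spec,
               grand_mean = model$grand_mean,
               var_pooled = model$var_pooled,
               gamma_star = apply(model$gamma_star, 1, identity, simplify = FALSE),
               delta_star = apply(model$delta_star, 1, identity, simplify = FALSE),
               hyperparams = model$hyperparams,
               n_iter = model$n_iter, tol = model$tol)
  jsonlite::write_json(dump, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
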