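test_that("the FP basis follows the power and repeated-power rules", {
  expect_equal(unname(fp_basis(exp(1), 0)[1, 1]), 1.0)
  expect_equal(unname(fp_basis(4, 0.5)[1, 1]), 2.0)
  expect_equal(unname(fp_basis(2, c(1, 1))[1, ]), c(2, 2 * log(2)))
  expect_equal(unname(fp_basis(2, c(0, 0))[1, ]), c(log(2), log(2)^2))
  expect_equal(unname(fp_basis(3, c(-2, -0.5))[1, ]), c(1 / 9, 1 / sqrt(3)))
  # power 1 reproduces the identity column exactly
  x <- c(0.5, 1.7, 8.2)
  expect_identical(drop(fp_basis(x, 1)), x)
  expect_error(fp_basis(c(1, -1), 1), "x > 0")
  expect_error(fp_spec(c(1, 1, 2, 3)), "degree")
  expect_error(fp_spec(0.25), "powers")
})

test_that("an exactly linear response is fitted perfectly", {
  set.seed(40)
  age <- runif(500, 5, 85)
  sex <- sample(c("M", "F"), 500, TRUE)
  y <- 1000 - 12 * age
  fit <- fit_fp(y, age, sex, rep("s1", 500), fp_spec(1), robust = FALSE)
  expect_lt(fit$rss, 1e-12 * var(y) * 500)
  # chance sex-age correlation diverts a sliver of R2 to the covariate
  expect_gt(fit$partial_r2_age, 0.95)
  # slope on the scaled axis: -12 per year = -120 per decade
  expect_equal(unname(fit$coefficients["fp1"]), -120, tolerance = 1e-8)
  # a sex covariate on sex-free truth stays at zero
  expect_lt(abs(fit$coefficients[["sex"]]), 1e-8)
})

test_that("age-independent noise yields near-zero partial R-squared", {
  set.seed(41)
  n <- 10000
  age <- runif(n, 5, 85)
  sex <- sample(c("M", "F"), n, TRUE)
  y <- 500 + 20 * (sex == "M") + rnorm(n, 0, 50)
  fit <- fit_fp(y, age, sex, rep("s1", n), fp_spec(c(-2, 1)), robust = FALSE)
  expect_lt(fit$partial_r2_age, 0.002)
})

test_that("cluster-robust SEs respond to site clustering", {
  set.seed(42)
  n <- 1200
  sites <- rep(sprintf("s%02d", 1:12), each = 100)
  shift <- rep(rnorm(12, 0, 40), each = 100)
  age <- runif(n, 5, 85)
  sex <- sample(c("M", "F"), n, TRUE)
  y <- 800 - 3 * age + shift + rnorm(n, 0, 20)
  fit <- fit_fp(y, age, sex, sites, fp_spec(1))
  iid_se <- summary(lm(y ~ I(ifelse(sex == "M", .5, -.5)) + I(age / 10)))$
    coefficients["(Intercept)", "Std. Error"]
  expect_gt(unname(fit$robust_se["intercept"]), 2 * iid_se)
  expect_warning(
    fit1 <- fit_fp(y, age, sex, rep("s1", n), fp_spec(1)),
    "single site")
  expect_true(all(is.finite(fit1$robust_se)))
})

test_that("closed-test selection finds the generating degree", {
  set.seed(43)
  n <- 2000
  age <- runif(n, 5, 85)
  sex <- sample(c("M", "F"), n, TRUE)
  sites <- sample(sprintf("s%d", 1:5), n, TRUE)
  # linear truth with small noise: straight line selected
  y_lin <- 300 + 4 * age + rnorm(n, 0, 0.01 * 4 * 80)
  fit <- select_fp(y_lin, age, sex, sites)
  expect_equal(fit$spec$powers, 1)
  expect_equal(fit$spec$degree, 1)
  expect_named(fit$selection_trace[[1]], c("comparison", "statistic", "df",
                                           "p", "significant"))
  # strong FP2 curvature recovered with degree >= 2
  x <- age / 10
  y_fp2 <- 5000 + 400 / x^2 - 150 * x + rnorm(n, 0, 60)
  fit2 <- select_fp(y_fp2, age, sex, sites, max_degree = 3)
  expect_gte(fit2$spec$degree, 2)
  truth <- 5000 + 400 / x^2 - 150 * x
  rmse <- sqrt(mean((predict(fit2, age) - truth)^2))
  expect_lt(rmse, 0.02 * diff(range(truth)))
  # noise-free input is a documented degenerate case
  expect_error(select_fp(300 + 4 * age, age, sex, sites), "jitter|degenerate")
})

test_that("deviance is non-increasing across nested best-fit degrees", {
  set.seed(44)
  n <- 800
  age <- runif(n, 5, 85)
  sex <- sample(c("M", "F"), n, TRUE)
  y <- 2000 - 5 * age + 40 * sqrt(age) + rnorm(n, 0, 30)
  devs <- sapply(1:3, function(m) {
    best <- Inf
    for (pw in lifespanvol:::fp_power_sets(m)) {
      X <- lifespanvol:::fp_design(age, sex, fp_spec(pw), TRUE)
      if (qr(X)$rank < ncol(X)) next
      best <- min(best, sum(lm.fit(X, y)$residuals^2))
    }
    n * log(best / n)
  })
  expect_true(all(diff(devs) <= 1e-8))
})

test_that("under a sex-only null an age term is rarely admitted", {
  set.seed(45)
  alpha <- 0.05
  reps <- 200
  n <- 400
  hits <- 0
  for (i in seq_len(reps)) {
    age <- runif(n, 5, 85)
    sex <- sample(c("M", "F"), n, TRUE)
    y <- 100 + 10 * (sex == "M") + rnorm(n)
    fit <- select_fp(y, age, sex, rep(c("s1", "s2"), n / 2), alpha = alpha)
    if (fit$spec$degree >= 1) hits <- hits + 1
  }
  # closed test familywise rate stays near alpha (binomial 3-sigma margin)
  expect_lt(hits / reps, alpha + 3 * sqrt(alpha * (1 - alpha) / reps) + 0.02)
})

test_that("age-band correlations behave over the bands", {
  tab <- small_cohort()
  tab$caudate_L <- tab$age
  r <- ageband_correlations(tab, "caudate_L")
  expect_true(all(abs(r$r[r$group == "all"] - 1) < 1e-12))

  set.seed(46)
  tab$caudate_L <- -tab$age + rnorm(nrow(tab), 0, 1e-6)
  r2 <- ageband_correlations(tab, "caudate_L")
  expect_true(all(r2$r[r2$group == "all"] < -0.999))

  # sampling-error bound at true rho = -0.3
  n <- 5000
  rho <- -0.3
  big <- small_cohort()[rep(1, 3 * n), ]
  big$participant_id <- sprintf("p%05d", seq_len(3 * n))
  big$age <- c(runif(n, 6, 29), runif(n, 30, 59), runif(n, 60, 90))
  z <- rnorm(3 * n)
  band_id <- rep(1:3, each = n)
  a_std <- big$age
  for (b in 1:3) {
    i <- band_id == b
    a_std[i] <- (big$age[i] - mean(big$age[i])) / sd(big$age[i])
  }
  big$caudate_L <- 1000 + 100 * (rho * a_std + sqrt(1 - rho^2) * z)
  r3 <- ageband_correlations(big, "caudate_L")
  pooled <- r3[r3$group == "all", ]
  expect_true(all(abs(pooled$r - rho) < 0.04))

  const <- small_cohort()
  const$caudate_L <- 5
  r4 <- ageband_correlations(const, "caudate_L")
  expect_true(all(is.na(r4$r)))
})

test_that("sex-stratified fits reflect the generating sex structure", {
  set.seed(47)
  cfg <- sim_config(n_sites = 4, site_sizes = rep(900, 4),
                    site_age_ranges = rep(list(c(5, 85)), 4),
                    outlier_rate = 0, seed = 60)
  trs <- default_trajectories()
  trs$putamen$sex_effect <- 0
  tab <- generate_cohort(cfg, trs)
  fits <- fit_fp_by_sex(tab, "putamen_L")
  grid <- seq(10, 80, 2)
  fM <- predict(fits$M, grid)
  fF <- predict(fits$F, grid)
  se_scale <- sd(tab$putamen_L) / sqrt(nrow(tab) / 2)
  expect_lt(max(abs(fM - fF)), 10 * se_scale)

  # a purely additive sex effect gives parallel curves
  trs$putamen$sex_effect <- 400
  tab2 <- generate_cohort(cfg, trs)
  fits2 <- fit_fp_by_sex(tab2, "putamen_L")
  dif <- predict(fits2$M, grid) - predict(fits2$F, grid)
  expect_lt(diff(range(dif)), 100)
  expect_gt(mean(dif), 300)

  allm <- tab[tab$sex == "M", ]
  expect_warning(fits3 <- fit_fp_by_sex(allm, "putamen_L"), "skipped")
  expect_null(fits3$F)
  expect_s3_class(fits3$M, "fp_fit")
})
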