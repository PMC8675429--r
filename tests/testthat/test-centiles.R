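test_that("BCCG z-scores match their closed forms", {
  expect_equal(bccg_z(100, 0.7, 100, 0.1), 0)
  expect_equal(bccg_z(100, 0, 100, 0.3), 0)
  expect_equal(bccg_z(110, 1, 100, 0.1), 1.0)
  expect_equal(bccg_z(100 * exp(0.2), 0, 100, 0.1), 2.0)
  # continuity in lambda through 0
  expect_equal(bccg_z(123, 1e-10, 100, 0.1), bccg_z(123, 0, 100, 0.1),
               tolerance = 1e-8)
  expect_error(bccg_z(-1, 1, 100, 0.1), "positive")
  expect_error(bccg_z(1, 1, 100, -0.1), "positive")
})

test_that("the BCCG log-likelihood reduces to Gaussian at lambda = 1", {
  set.seed(60)
  y <- rnorm(50, 100, 8)
  mu <- 100
  sigma <- 0.08
  expect_equal(bccg_loglik(y, 1, mu, sigma),
               sum(dnorm(y, mu, mu * sigma, log = TRUE)),
               tolerance = 1e-10)
  # the maximizing mu beats a shifted mu on a fixed sample
  ll_at <- function(m) bccg_loglik(y, 1, m, sigma)
  opt <- optimize(ll_at, c(50, 150), maximum = TRUE)$maximum
  expect_gt(ll_at(opt), ll_at(opt * 1.05))
  expect_gt(ll_at(opt), ll_at(opt * 0.95))
  # single observation at the median only contributes constants
  expect_equal(bccg_loglik(1, 1, 1, 1), -0.5 * log(2 * pi))
})

test_that("LMS fitting recovers known BCCG truth", {
  set.seed(61)
  n <- 5000
  age <- runif(n, 3, 90)
  # lognormal: lambda 0, mu 100, sigma 0.1, no age trend
  y <- rlnorm(n, log(100), 0.1)
  m <- fit_lms(y, age)
  expect_gt(m$lambda, -0.3)
  expect_lt(m$lambda, 0.3)
  grid <- seq(5, 88, 1)
  p <- lifespanvol:::lms_params(m, grid)
  expect_true(all(p$mu > 97 & p$mu < 103))
  expect_true(all(p$sigma > 0.09 & p$sigma < 0.11))

  # normal with CV 0.1: lambda near 1, flat median
  y2 <- rnorm(n, 100, 10)
  m2 <- fit_lms(y2[y2 > 0], age[y2 > 0])
  expect_lt(abs(m2$lambda - 1), 0.35)
  mu2 <- lifespanvol:::lms_params(m2, grid)$mu
  expect_lt(diff(range(mu2)) / stats::median(mu2), 0.02)
})

test_that("a single df-grid entry skips the search", {
  set.seed(62)
  y <- rlnorm(500, log(50), 0.15)
  age <- runif(500, 3, 60)
  m <- fit_lms(y, age, df_grid = data.frame(df_mu = 2, df_sigma = 1))
  expect_equal(nrow(m$fit_meta$grid), 1)
  expect_equal(m$edf, 4)  # lambda + 2 + 1
  expect_error(fit_lms(y[1:30], age[1:30]), "at least 50")
  expect_error(fit_lms(y, runif(500, 40, 50)), "span")
})

test_that("centile curves follow the LMS quantile formula", {
  set.seed(63)
  y <- rlnorm(2000, log(100), 0.1)
  age <- runif(2000, 3, 90)
  m <- fit_lms(y, age, df_grid = data.frame(df_mu = 2, df_sigma = 1))
  grid <- seq(5, 85, 5)
  # level 50 is exactly the mu curve
  expect_equal(centile_curve(m, grid, 50),
               lifespanvol:::lms_params(m, grid)$mu)
  # hand arithmetic at lambda = 1
  m1 <- m
  m1$lambda <- 1
  m1$beta_mu <- c(log(100), rep(0, length(m1$beta_mu) - 1))
  m1$beta_sigma <- log(0.1)
  expect_equal(centile_curve(m1, 40, 97.5), 100 * (1 + 0.1 * qnorm(0.975)),
               tolerance = 1e-6)
  expect_equal(centile_curve(m1, 40, 97.5), 119.5996, tolerance = 1e-4)
  # lambda -> 0 agrees with the exact log branch
  mA <- m1; mA$lambda <- 1e-8
  mB <- m1; mB$lambda <- 0
  expect_equal(centile_curve(mA, 40, 97.5), centile_curve(mB, 40, 97.5),
               tolerance = 1e-5)
  # monotone in level at every age
  lv <- c(1, 5, 25, 50, 75, 95, 99)
  vals <- sapply(lv, function(l) centile_curve(m, grid, l))
  expect_true(all(apply(vals, 1, function(v) all(diff(v) > 0))))
  expect_error(centile_curve(m, 100, 50), "outside the fitted range")
})

test_that("centile lookup inverts the centile curve", {
  set.seed(64)
  y <- rlnorm(1000, log(80), 0.12)
  age <- runif(1000, 3, 70)
  m <- fit_lms(y, age, df_grid = data.frame(df_mu = 2, df_sigma = 1))
  v5 <- centile_curve(m, 35, 5)
  expect_equal(centile_of(m, 35, v5), 5, tolerance = 1e-6)
  v50 <- centile_curve(m, 35, 50)
  expect_equal(centile_of(m, 35, v50), 50, tolerance = 1e-6)
})

test_that("fitted centiles are calibrated on fresh BCCG data", {
  set.seed(65)
  n <- 10000
  age <- runif(n, 3, 90)
  mu <- 3500 - 8 * (age - 45)
  y <- rlnorm(n, log(mu), 0.09)
  m <- fit_lms(y, age)
  age2 <- runif(n, 3, 90)
  y2 <- rlnorm(n, log(3500 - 8 * (age2 - 45)), 0.09)
  cent <- centile_of(m, age2, y2, allow_extrapolation = TRUE)
  for (lv in c(5, 25, 50, 75, 95)) {
    cover <- mean(cent < lv) * 100
    expect_lt(abs(cover - lv), 1.5)
  }
})

test_that("GAIC selection does not systematically overfit a flat median", {
  set.seed(66)
  max_df <- c(df_mu = 6, df_sigma = 4)
  picks <- replicate(20, {
    age <- runif(1500, 3, 90)
    y <- rlnorm(1500, log(200), 0.1)
    m <- fit_lms(y, age)
    g <- m$fit_meta$grid
    sel <- g[which.min(g$gaic), ]
    sel$df_mu == max_df["df_mu"] && sel$df_sigma == max_df["df_sigma"]
  })
  expect_lte(mean(picks), 0.2)
})

test_that("centile tables are tidy and strictly ordered", {
  set.seed(67)
  y <- rlnorm(800, log(60), 0.1)
  age <- runif(800, 3, 80)
  m <- fit_lms(y, age, df_grid = data.frame(df_mu = 3, df_sigma = 2))
  tab <- centile_table(m, ages = seq(5, 75, 5),
                       stratum = list(region_hemisphere = "amygdala_L",
                                      sex = "F"))
  expect_equal(names(tab), c("region_hemisphere", "sex", "age", "level",
                             "value"))
  by_age <- split(tab, tab$age)
  expect_true(all(vapply(by_age, function(d)
    all(diff(d$value[order(d$level)]) > 0), logical(1))))
})
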