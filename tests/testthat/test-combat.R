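test_that("the covariate design has the documented structure and rank", {
  ages <- c(10, 25, 30, 45, 50, 60, 70, 80)
  sexes <- rep(c("M", "F"), 4)
  d <- build_design(ages, sexes)
  expect_equal(qr(d)$rank, 5)
  expect_equal(colnames(d), c("intercept", "sex", "age1", "age2", "age3"))
  expect_equal(unname(d[, "sex"]), rep(c(0.5, -0.5), 4))

  # all ages at the centre: age columns vanish
  expect_warning(d45 <- build_design(rep(45, 4), rep("M", 4)), "constant sex")
  expect_equal(ncol(d45), 1)
  d45b <- build_design(rep(45, 4), c("M", "F", "M", "F"))
  expect_equal(qr(d45b)$rank, 2)

  expect_error(build_design(numeric(0), character(0)), "empty")
})

test_that("a pure location shift between batches is removed exactly", {
  # identical within-feature variances make the standardized batch effects
  # equal across features, so the EB prior is degenerate and harmonized
  # batch means must match the hand mean-matching oracle exactly
  set.seed(30)
  n <- 120
  base <- rnorm(n, 0, 3)
  dat1 <- rbind(base + 100, base + 200, base + 300)
  dat2 <- dat1 + 10
  dat <- cbind(dat1, dat2)
  batches <- rep(c("b1", "b2"), each = n)
  design <- matrix(1, 2 * n, 1, dimnames = list(NULL, "intercept"))
  fit <- fit_combat(dat, batches, design)
  harm <- apply_combat(fit, dat, batches, design)
  m1 <- rowMeans(harm[, batches == "b1"])
  m2 <- rowMeans(harm[, batches == "b2"])
  expect_lt(max(abs(m1 - m2)), 1e-6)
  # oracle: remove each batch's mean, restore the size-weighted grand mean
  # (EB scale shrinkage may rescale deviations by a fraction of a percent)
  oracle <- dat
  for (b in c("b1", "b2")) {
    idx <- batches == b
    oracle[, idx] <- dat[, idx] - rowMeans(dat[, idx]) + rowMeans(dat)
  }
  expect_lt(max(abs(harm - oracle)), 0.02 * sd(dat))
})

test_that("null site effects are shrunk and batch gaps reduced", {
  set.seed(31)
  n <- 2000
  age <- runif(2 * n, 5, 85)
  sex <- sample(c("M", "F"), 2 * n, TRUE)
  mu <- 500 - 2 * age
  dat <- rbind(mu + rnorm(2 * n, 0, 30),
               2 * mu + rnorm(2 * n, 0, 40),
               800 + rnorm(2 * n, 0, 20))
  batches <- rep(c("b1", "b2"), each = n)
  design <- build_design(age, sex)
  fit <- fit_combat(dat, batches, design)
  expect_lt(max(abs(fit$gamma_star)), max(abs(fit$gamma_hat)) + 1e-12)
  harm <- apply_combat(fit, dat, batches, design)
  gap <- function(x) abs(rowMeans(x[, batches == "b1"]) -
                           rowMeans(x[, batches == "b2"]))
  expect_true(all(gap(harm) <= gap(dat)))
})

test_that("EB iteration respects the convergence contract", {
  set.seed(32)
  dat <- matrix(rnorm(16 * 200, 100, 10), 16)
  batches <- rep(c("a", "b"), each = 100)
  design <- matrix(1, 200, 1, dimnames = list(NULL, "intercept"))
  fit_loose <- fit_combat(dat, batches, design, tol = 1e9)
  expect_equal(fit_loose$n_iter, 1L)
  fit_tight <- fit_combat(dat, batches, design, tol = 1e-8)
  expect_gte(fit_tight$n_iter, fit_loose$n_iter)
  expect_true(all(fit_tight$delta_star > 0))
})

test_that("identity adjustment and fixed-point refitting hold", {
  set.seed(33)
  dat <- matrix(rnorm(4 * 300, 50, 5), 4)
  batches <- rep(c("a", "b", "c"), each = 100)
  design <- matrix(1, 300, 1, dimnames = list(NULL, "intercept"))
  fit <- fit_combat(dat, batches, design)
  ident <- fit
  ident$gamma_star[] <- 0
  ident$delta_star[] <- 1
  expect_equal(apply_combat(ident, dat, batches, design), dat,
               tolerance = 1e-8, ignore_attr = TRUE)

  harm <- apply_combat(fit, dat, batches, design)
  refit <- fit_combat(harm, batches, design)
  expect_lt(max(abs(refit$gamma_star)), 0.05)
  expect_lt(max(abs(refit$delta_star - 1)), 0.05)
})

test_that("fit and apply reject contract violations", {
  set.seed(34)
  dat <- matrix(rnorm(3 * 40, 10, 2), 3)
  batches <- rep(c("a", "b"), each = 20)
  design <- matrix(1, 40, 1, dimnames = list(NULL, "intercept"))
  expect_error(fit_combat(dat, rep("a", 40), design), "2 batches")
  expect_error(fit_combat(dat, c(rep("a", 39), "b"), design), "2 subjects")
  dat0 <- dat
  dat0[2, batches == "b"] <- 7
  expect_error(fit_combat(dat0, batches, design), "zero variance.*'b'")

  fit <- fit_combat(dat, batches, design)
  expect_error(apply_combat(fit, dat, c(rep("a", 20), rep("z", 20)), design),
               "not seen")
  expect_error(
    apply_combat(fit, dat[, 1:21], c(rep("a", 20), "b"), design[1:21, , drop = FALSE]),
    "single-subject")
})

test_that("our ComBat agrees with the sva reference implementation", {
  skip_if_not_installed("sva")
  set.seed(35)
  n <- 300
  batches <- rep(c("a", "b", "c"), c(120, 100, 80))
  age <- runif(n, 10, 80)
  sex <- sample(c("M", "F"), n, TRUE)
  mu <- 100 + 0.3 * age + 5 * (sex == "M")
  dat <- rbind(f1 = mu + rnorm(n, 0, 4),
               f2 = 2 * mu + rnorm(n, 0, 6),
               f3 = 50 + 0.1 * age + rnorm(n, 0, 2))
  dat[, batches == "b"] <- dat[, batches == "b"] + 8
  dat[, batches == "c"] <- dat[, batches == "c"] * 1.2
  des <- build_design(age, sex)
  ours <- apply_combat(fit_combat(dat, batches, des), dat, batches, des)
  u <- (age - 45) / 45
  mod <- stats::model.matrix(~ I(ifelse(sex == "M", .5, -.5)) + u + I(u^2) + I(u^3))
  theirs <- suppressMessages(sva::ComBat(dat, batch = batches, mod = mod,
                                         par.prior = TRUE))
  expect_lt(max(abs(ours - theirs)), 1e-5)
})

test_that("harmonizing a cohort removes site variance but keeps age structure", {
  set.seed(36)
  cfg <- sim_config(n_sites = 8, site_sizes = rep(700, 8),
                    site_age_ranges = rep(list(c(5, 85)), 8),
                    site_shift_sd = 200, site_scale_range = c(0.85, 1.15),
                    outlier_rate = 0, seed = 55)
  tab <- generate_cohort(cfg)
  adj <- adjust_icv(tab)$table
  harm <- harmonize_cohort(adj)$table
  site_var <- function(t, cl) {
    r <- resid(lm(t[[cl]] ~ poly(t$age, 3) + t$sex))
    var(tapply(r, t$site_id, mean))
  }
  for (cl in c("thalamus_L", "putamen_R")) {
    expect_lt(site_var(harm, cl), 0.1 * site_var(adj, cl))
  }
  # the generating ventricular age slope survives harmonization within 5%
  slope_true <- abs(default_trajectories()$lateral_ventricle$decline_rate)
  slope_fit <- coef(lm(lateral_ventricle_L ~ age + sex, harm))["age"]
  expect_lt(abs(slope_fit - slope_true) / slope_true, 0.05)
  # shape and ordering preserved
  expect_identical(dim(harm), dim(adj))
  expect_identical(harm$participant_id, adj$participant_id)

  one <- adj[adj$site_id == adj$site_id[1], ]
  expect_warning(pass <- harmonize_cohort(one), "single site")
  expect_identical(pass$table, one)
})
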