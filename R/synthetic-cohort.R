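#' Trajectory parameters for one subcortical structure
#'
#' Describes the ground-truth mean age trajectory of a structure used by the
#' synthetic cohort generator. Three archetypes cover the patterns seen in
#' large lifespan compilations: basal-ganglia-like volumes that peak in the
#' first decade and decline monotonically afterwards
#' (`"early_peak_decline"`), limbic/thalamic volumes that follow a flattened
#' inverted U with a long plateau and decline only after the sixth decade
#' (`"inverted_U"`), and ventricular volumes that grow throughout life
#' (`"monotonic_increase"`).
#'
#' All trajectories are piecewise linear, which keeps ground truth exactly
#' computable in recovery tests. The early-peak archetype rises from age 3 to
#' a peak at age 8 then declines by `decline_rate` per year; the inverted-U
#' archetype rises from age 3 to age 25, stays flat at `level` until
#' `plateau_end`, then declines by `late_rate` per year; the monotonic
#' archetype grows linearly from `level` at age 3 by `decline_rate` per year
#' (the rate field is reused with positive sign).
#'
#' @param archetype one of `"early_peak_decline"`, `"inverted_U"`,
#'   `"monotonic_increase"`.
#' @param level volume scale in mm^3: the peak (early-peak), plateau
#'   (inverted-U) or age-3 (monotonic increase) mean volume. Must be > 0.
#' @param decline_rate mm^3/year decline after the peak (early-peak), or
#'   growth per year (monotonic increase).
#' @param plateau_end age in years at which late decline starts
#'   (inverted-U only); must lie in (30, 70).
#' @param late_rate mm^3/year decline after `plateau_end` (inverted-U only).
#' @param sex_effect additive male minus female mean difference in mm^3.
#' @return an object of class `trajectory_params`.
#' @examples
#' tp <- trajectory_params("inverted_U", level = 5000, plateau_end = 60,
#'                         late_rate = 20)
#' true_mean(tp, age = 40)
#' @export
trajectory_params <- function(archetype = c("early_peak_decline", "inverted_U",
                                            "monotonic_increase"),
                              level, decline_rate = 0, plateau_end = 60,
                              late_rate = 0, sex_effect = 0) {
  archetype <- match.arg(archetype)
  stopifnot(is.numeric(level), length(level) == 1L, level > 0)
  if (archetype == "inverted_U" && (plateau_end <= 30 || plateau_end >= 70)) {
    stop("plateau_end must lie in (30, 70) for the inverted_U archetype")
  }
  structure(list(archetype = archetype, level = level,
                 decline_rate = decline_rate, plateau_end = plateau_end,
                 late_rate = late_rate, sex_effect = sex_effect),
            class = "trajectory_params")
}

#' Ground-truth mean volume at a given age and sex
#'
#' Evaluates the noiseless mean trajectory defined by a
#' [trajectory_params()] object. Sex enters additively with a sum-to-zero
#' (+1/2, -1/2) coding, so `sex = NULL` gives the cross-sex reference curve.
#'
#' @param params a [trajectory_params()] object.
#' @param age numeric vector of ages in years, within \[3, 90\].
#' @param sex `"M"`, `"F"` (recycled), or `NULL` for the cross-sex mean.
#' @return numeric vector of mean volumes in mm^3.
#' @export
true_mean <- function(params, age, sex = NULL) {
  stopifnot(inherits(params, "trajectory_params"))
  if (any(age < 3 | age > 90)) stop("age must lie within [3, 90]")
  base <- switch(params$archetype,
    early_peak_decline = {
      # linear rise from 0.96*level at age 3 to the peak at age 8
      rise <- params$level * (0.96 + 0.008 * (age - 3))
      fall <- params$level - params$decline_rate * (age - 8)
      ifelse(age < 8, rise, fall)
    },
    inverted_U = {
      rise <- params$level * (0.92 + (0.08 / 22) * (age - 3))
      fall <- params$level - params$late_rate * (age - params$plateau_end)
      ifelse(age < 25, rise, ifelse(age <= params$plateau_end, params$level, fall))
    },
    monotonic_increase = params$level + abs(params$decline_rate) * (age - 3),
    stop("unknown archetype: ", params$archetype)
  )
  s <- if (is.null(sex)) 0 else ifelse(sex == "M", 0.5, -0.5)
  base + params$sex_effect * s
}

#' Default ground-truth trajectories for the eight structures
#'
#' Volume scales and rates are set once, at values typical of FreeSurfer
#' per-hemisphere segmentations of healthy cohorts: basal ganglia structures
#' decline from an early-life peak, thalamus/hippocampus/amygdala follow a
#' flattened inverted U with decline after age 60, and the lateral ventricles
#' enlarge steadily across life.
#'
#' @return named list of [trajectory_params()], one per region of
#'   [subcortical_regions()].
#' @export
default_trajectories <- function() {
  list(
    lateral_ventricle = trajectory_params("monotonic_increase", level = 3000,
                                          decline_rate = 120, sex_effect = 800),
    thalamus    = trajectory_params("inverted_U", level = 7000, plateau_end = 55,
                                    late_rate = 28, sex_effect = 420),
    caudate     = trajectory_params("early_peak_decline", level = 3700,
                                    decline_rate = 6, sex_effect = 200),
    putamen     = trajectory_params("early_peak_decline", level = 5300,
                                    decline_rate = 13, sex_effect = 320),
    pallidum    = trajectory_params("early_peak_decline", level = 1750,
                                    decline_rate = 3.2, sex_effect = 110),
    accumbens   = trajectory_params("early_peak_decline", level = 580,
                                    decline_rate = 1.6, sex_effect = 35),
    hippocampus = trajectory_params("inverted_U", level = 3900, plateau_end = 60,
                                    late_rate = 24, sex_effect = 210),
    amygdala    = trajectory_params("inverted_U", level = 1650, plateau_end = 60,
                                    late_rate = 7, sex_effect = 120)
  )
}

#' Simulation configuration for a multi-site cohort
#'
#' Collects every knob of the synthetic multi-site generator: per-site sample
#' sizes, age ranges (optionally with truncated-normal age distributions),
#' sex composition, additive/multiplicative site effects, the ICV coupling
#' slope, residual noise (optionally heteroscedastic in age for selected
#' regions), and a low-rate outlier contamination channel.
#'
#' @param n_sites number of sites.
#' @param site_sizes integer vector (length `n_sites`) of per-site sample
#'   sizes.
#' @param site_age_ranges list of `c(lo, hi)` year intervals within
#'   \[3, 90\], one per site.
#' @param sex_ratio fraction male in \[0, 1\]; scalar or one value per site.
#' @param site_shift_sd SD (mm^3) of the additive per-site, per-feature
#'   offsets gamma.
#' @param site_scale_range `c(lo, hi)`, `lo > 0`: multiplicative per-site,
#'   per-feature factors delta drawn uniformly in this range.
#' @param icv_mean,icv_sd population mean and SD of intracranial volume
#'   (mm^3).
#' @param icv_slope_b mm^3 of regional volume per mm^3 of ICV (allometric
#'   coupling, common to all regions).
#' @param noise_sd_base residual SD in mm^3; a scalar applied to every
#'   region, or a named vector with one entry per region.
#' @param heteroscedastic_regions character vector of region names whose
#'   residual SD grows linearly with age.
#' @param hetero_slope mm^3/year growth of the residual SD for
#'   heteroscedastic regions (SD at age a is base + hetero_slope*(a - 3));
#'   a scalar, or a named vector with one entry per heteroscedastic region.
#' @param outlier_rate fraction of rows (in \[0, 1)) whose 16 volumes are
#'   displaced.
#' @param outlier_scale displacement in units of the row's noise SD; >= 3.
#' @param site_age_means,site_age_sds optional per-site age mean/SD
#'   (years). When supplied, ages are drawn from a normal truncated to the
#'   site's range; otherwise uniformly on the range.
#' @param seed integer seed; the generator is fully reproducible given the
#'   config.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_sites, site_sizes, site_age_ranges,
                       sex_ratio = 0.48,
                       site_shift_sd = 150, site_scale_range = c(0.9, 1.1),
                       icv_mean = 1.5e6, icv_sd = 1.5e5, icv_slope_b = 0.002,
                       noise_sd_base = c(lateral_ventricle = 1700, thalamus = 420,
                                         caudate = 210, putamen = 350,
                                         pallidum = 110, accumbens = 55,
                                         hippocampus = 190, amygdala = 85),
                       heteroscedastic_regions = c("lateral_ventricle",
                                                   "hippocampus", "amygdala"),
                       hetero_slope = c(lateral_ventricle = 40,
                                        hippocampus = 4, amygdala = 2),
                       outlier_rate = 0.005, outlier_scale = 6,
                       site_age_means = NULL, site_age_sds = NULL,
                       seed = 1L) {
  stopifnot(n_sites >= 1, length(site_sizes) == n_sites,
            all(site_sizes >= 0), length(site_age_ranges) == n_sites)
  if (sum(site_sizes) == 0) stop("sum(site_sizes) must be positive")
  for (r in site_age_ranges) {
    if (length(r) != 2L || r[1] < 3 || r[2] > 90 || r[1] > r[2]) {
      stop("each site age range must be an interval within [3, 90]")
    }
  }
  if (!length(sex_ratio) %in% c(1L, n_sites) ||
      any(sex_ratio < 0 | sex_ratio > 1)) {
    stop("sex_ratio must be in [0, 1], scalar or one per site")
  }
  stopifnot(site_shift_sd >= 0, icv_sd >= 0, all(hetero_slope >= 0),
            site_scale_range[1] > 0, site_scale_range[1] <= site_scale_range[2],
            outlier_rate >= 0, outlier_rate < 1,
            outlier_rate == 0 || outlier_scale >= 3)
  if (length(noise_sd_base) > 1L) {
    if (!all(subcortical_regions() %in% names(noise_sd_base))) {
      stop("vector noise_sd_base must be named with every region")
    }
  }
  stopifnot(all(noise_sd_base >= 0))
  unknown <- setdiff(heteroscedastic_regions, subcortical_regions())
  if (length(unknown)) stop("unknown heteroscedastic region(s): ",
                            paste(unknown, collapse = ", "))
  if (length(hetero_slope) > 1L &&
      !all(heteroscedastic_regions %in% names(hetero_slope))) {
    stop("vector hetero_slope must be named with every heteroscedastic region")
  }
  structure(list(n_sites = as.integer(n_sites),
                 site_sizes = as.integer(site_sizes),
                 site_age_ranges = site_age_ranges,
                 sex_ratio = sex_ratio,
                 site_shift_sd = site_shift_sd,
                 site_scale_range = site_scale_range,
                 icv_mean = icv_mean, icv_sd = icv_sd,
                 icv_slope_b = icv_slope_b,
                 noise_sd_base = noise_sd_base,
                 heteroscedastic_regions = heteroscedastic_regions,
                 hetero_slope = hetero_slope,
                 outlier_rate = outlier_rate, outlier_scale = outlier_scale,
                 site_age_means = site_age_means, site_age_sds = site_age_sds,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Bundled reference sample characteristics
#'
#' Summary descriptors (age mean/SD/range, size, sex counts) of the 88
#' healthy-control samples of a large multi-site lifespan MRI compilation
#' (total N = 18,605). These drive the default site structure of the
#' generator and the in-package cohort arithmetic.
#'
#' @return data.frame with columns `sample`, `age_mean`, `age_sd`,
#'   `age_min`, `age_max`, `n`, `n_male`, `n_female`.
#' @export
reference_samples <- function() {
  path <- system.file("extdata", "reference_samples.csv",
                      package = "lifespanvol", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Simulation config mirroring the reference multi-site compilation
#'
#' Builds a [sim_config()] whose site structure (number of sites, sizes, age
#' distributions, sex ratios) follows the bundled [reference_samples()]
#' table, optionally scaled down in size.
#'
#' @param scale multiply all site sizes by this factor (rounded up to at
#'   least 2 participants per retained site).
#' @param seed integer seed passed through to the config.
#' @param ... further arguments forwarded to [sim_config()] (effect sizes,
#'   noise levels and so on).
#' @return a `sim_config`.
#' @export
reference_sim_config <- function(scale = 1, seed = 1L, ...) {
  ref <- reference_samples()
  sizes <- pmax(2L, as.integer(round(ref$n * scale)))
  sim_config(n_sites = nrow(ref), site_sizes = sizes,
             site_age_ranges = Map(c, pmax(3, ref$age_min),
                                   pmin(90, ref$age_max)),
             sex_ratio = ifelse(ref$n > 0, ref$n_male / ref$n, 0.5),
             site_age_means = ref$age_mean, site_age_sds = pmax(ref$age_sd, 0.2),
             seed = seed, ...)
}

# truncated-normal sampler via inverse CDF (exact, vectorized)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  pmin(hi, pmax(lo, stats::qnorm(u, mean, sd)))
}

# per-region residual SD at given ages under a config
noise_sd_at <- function(config, region, age) {
  base <- if (length(config$noise_sd_base) > 1L) {
    unname(config$noise_sd_base[region])
  } else {
    config$noise_sd_base
  }
  if (region %in% config$heteroscedastic_regions) {
    slope <- if (length(config$hetero_slope) > 1L) {
      unname(config$hetero_slope[region])
    } else {
      config$hetero_slope
    }
    base + slope * (age - 3)
  } else {
    rep(base, length(age))
  }
}

#' Generate a synthetic multi-site cross-sectional cohort
#'
#' Draws one participant table under the generative model the downstream
#' analysis assumes. For participant j at site i with age a, sex s and
#' intracranial volume ICV_j, the observed volume of region r in one
#' hemisphere is
#' \deqn{v = \delta_{ir} (m_r(a, s) + b (ICV_j - \bar{ICV}) + e) + \gamma_{ir}}
#' where m_r is the ground-truth trajectory, b the ICV coupling slope,
#' gamma and delta additive and multiplicative site-by-feature effects, and
#' e Gaussian noise whose left/right pair is correlated at 0.8. The
#' multiplicative site effect acts after the ICV coupling so the
#' location-scale model assumed by ComBat matches the generator. A fraction
#' `outlier_rate` of rows has all 16 volumes displaced by
#' `outlier_scale` noise SDs.
#'
#' @param config a [sim_config()].
#' @param trajectories named list of [trajectory_params()] per region;
#'   defaults to [default_trajectories()].
#' @return a cohort data.frame with the [cohort_columns()] schema. The same
#'   (config, seed) always yields the identical table.
#' @export
generate_cohort <- function(config, trajectories = default_trajectories()) {
  stopifnot(inherits(config, "sim_config"))
  regions <- subcortical_regions()
  missing_tr <- setdiff(regions, names(trajectories))
  if (length(missing_tr)) stop("trajectories missing for: ",
                               paste(missing_tr, collapse = ", "))
  with_seed(config$seed, {
    hemi_cor <- 0.8
    site_ids <- sprintf("site%03d", seq_len(config$n_sites))
    # per-site x region location/scale effects
    gamma <- matrix(stats::rnorm(config$n_sites * length(regions), 0,
                                 config$site_shift_sd),
                    config$n_sites, dimnames = list(site_ids, regions))
    delta <- matrix(stats::runif(config$n_sites * length(regions),
                                 config$site_scale_range[1],
                                 config$site_scale_range[2]),
                    config$n_sites, dimnames = list(site_ids, regions))
    ratios <- rep(config$sex_ratio, length.out = config$n_sites)
    pieces <- vector("list", config$n_sites)
    for (i in seq_len(config$n_sites)) {
      n_i <- config$site_sizes[i]
      if (n_i == 0L) next
      rng <- config$site_age_ranges[[i]]
      age <- if (!is.null(config$site_age_means)) {
        rtruncnorm(n_i, config$site_age_means[i], config$site_age_sds[i],
                   rng[1], rng[2])
      } else {
        stats::runif(n_i, rng[1], rng[2])
      }
      sex <- ifelse(stats::runif(n_i) < ratios[i], "M", "F")
      icv <- stats::rnorm(n_i, config$icv_mean, config$icv_sd)
      df <- data.frame(participant_id = sprintf("%s_p%05d", site_ids[i],
                                                seq_len(n_i)),
                       site_id = site_ids[i], age = age, sex = sex, icv = icv,
                       stringsAsFactors = FALSE)
      for (r in regions) {
        m <- true_mean(trajectories[[r]], age, sex)
        sd_r <- noise_sd_at(config, r, age)
        z1 <- stats::rnorm(n_i); z2 <- stats::rnorm(n_i)
        eL <- sd_r * z1
        eR <- sd_r * (hemi_cor * z1 + sqrt(1 - hemi_cor^2) * z2)
        core <- m + config$icv_slope_b * (icv - config$icv_mean)
        df[[paste0(r, "_L")]] <- delta[i, r] * (core + eL) + gamma[i, r]
        df[[paste0(r, "_R")]] <- delta[i, r] * (core + eR) + gamma[i, r]
      }
      pieces[[i]] <- df
    }
    tab <- do.call(rbind, pieces)
    rownames(tab) <- NULL
    n_out <- floor(config$outlier_rate * nrow(tab))
    if (n_out > 0) {
      rows <- sample.int(nrow(tab), n_out)
      sign <- sample(c(-1, 1), n_out, replace = TRUE)
      for (r in regions) {
        sd_r <- noise_sd_at(config, r, tab$age[rows])
        shift <- sign * config$outlier_scale * sd_r
        tab[rows, paste0(r, "_L")] <- tab[rows, paste0(r, "_L")] + shift
        tab[rows, paste0(r, "_R")] <- tab[rows, paste0(r, "_R")] + shift
      }
    }
    tab[cohort_columns()]
  })
}
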