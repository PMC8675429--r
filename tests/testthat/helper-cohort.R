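# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

# a mid-sized reference-structured cohort taken through QC, ICV adjustment
# and harmonization (n ~ 10,000); reused by trajectory/variability tests
harmonized_cohort <- function() {
  if (is.null(.fixtures$harm)) {
    cfg <- reference_sim_config(scale = 0.55, seed = 7)
    tab <- generate_cohort(cfg)
    fc <- filter_complete(tab)
    mh <- mahalanobis_exclude(fc$table)
    ad <- adjust_icv(mh$table)
    .fixtures$harm <- harmonize_cohort(ad$table)$table
    .fixtures$adjusted <- ad$table
  }
  .fixtures$harm
}

adjusted_cohort <- function() {
  harmonized_cohort()
  .fixtures$adjusted
}

# small complete cohort for schema/QC tests
small_cohort <- function(seed = 3) {
  cfg <- sim_config(n_sites = 4, site_sizes = rep(60, 4),
                    site_age_ranges = rep(list(c(5, 85)), 4), seed = seed)
  generate_cohort(cfg)
}

# a noise-free generator config (all effect channels off)
silent_config <- function(n = 50, seed = 1) {
  sim_config(n_sites = 1, site_sizes = n,
             site_age_ranges = list(c(5, 85)),
             site_shift_sd = 0, site_scale_range = c(1, 1),
             icv_slope_b = 0, noise_sd_base = 0, hetero_slope = 0,
             outlier_rate = 0, seed = seed)
}
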