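#' Subcortical structures and cohort table schema
#'
#' The analysis covers eight subcortical structures, each measured in both
#' hemispheres: lateral ventricle, thalamus, caudate, putamen, pallidum,
#' nucleus accumbens, hippocampus and amygdala. Together with intracranial
#' volume (ICV) these form the fixed column schema of a cohort table.
#'
#' @return `subcortical_regions()` returns the character vector of the eight
#'   region names; `volume_columns()` the 16 `{region}_{L|R}` column labels in
#'   their fixed documented order; `cohort_columns()` the full cohort table
#'   header (id, site, age, sex, icv, then the 16 volumes).
#' @export
subcortical_regions <- function() {
  c("lateral_ventricle", "thalamus", "caudate", "putamen",
    "pallidum", "accumbens", "hippocampus", "amygdala")
}

#' @rdname subcortical_regions
#' @export
volume_columns <- function() {
  as.vector(t(outer(subcortical_regions(), c("L", "R"), paste, sep = "_")))
}

#' @rdname subcortical_regions
#' @export
cohort_columns <- function() {
  c("participant_id", "site_id", "age", "sex", "icv", volume_columns())
}

# internal: validate a cohort data.frame's schema, stop with informative
# message on violation; returns the table invisibly
check_cohort <- function(table, require_rows = TRUE) {
  if (!is.data.frame(table)) stop("cohort table must be a data.frame")
  missing_cols <- setdiff(cohort_columns(), names(table))
  if (length(missing_cols)) {
    stop("cohort table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (require_rows && nrow(table) == 0L) stop("cohort table has no rows")
  bad_sex <- !is.na(table$sex) & !table$sex %in% c("M", "F")
  if (any(bad_sex)) {
    stop("invalid sex value(s) in row(s): ",
         paste(utils::head(which(bad_sex), 10L), collapse = ", "),
         " (must be 'M' or 'F')")
  }
  ok_age <- is.na(table$age) | (table$age >= 3 & table$age <= 90)
  if (!all(ok_age)) {
    stop("age outside [3, 90] in row(s): ",
         paste(utils::head(which(!ok_age), 10L), collapse = ", "))
  }
  if (any(!is.na(table$icv) & table$icv <= 0)) stop("icv must be positive when present")
  invisible(table)
}

# internal: run code with a temporary RNG state seeded at `seed`,
# restoring the caller's .Random.seed afterwards
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

# internal: derive a deterministic 31-bit sub-seed for a named pipeline stage
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1013L + h * 7919) %% 2147483647)
}
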