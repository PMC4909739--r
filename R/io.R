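#' Read a tidy per-pot observation table
#'
#' Expects UTF-8 comma-separated values with header columns `pot_id`,
#' `treatment`, `cut`, `harvest_day`, `shoot_dm_g_kg`, `shoot_p_mg_kg`,
#' `activity_bq_kg`, `count_date` (ISO 8601). Schema violations are
#' reported with the offending rows.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_pot_observations <- function(path) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_observations(obs)
  obs
}

#' Read a seed-budget table
#' @param path CSV with `treatment`, `cut` and either `pseed_mg_kg` or the
#'   raw columns `sown_seed_p`, `residual_seed_p`, `shoot_p`, `root_p`,
#'   `collet_p` (mg P per kg soil).
#' @return Data frame.
#' @export
read_seed_budgets <- function(path) {
  sb <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"treatment" %in% names(sb)) {
    stop("seed-budget table lacks 'treatment'", call. = FALSE)
  }
  sb
}

#' Read a jar-level titration table
#' @param path CSV with `jar_id`, `treatment`, `start_day`, `end_day`,
#'   `hcl_normality`, `v_sample_ml`, `soil_dry_mass_kg` (and optionally
#'   `v_blank_ml`).
#' @return Data frame.
#' @export
read_titrations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a fertilizer spec from YAML
#'
#' Expected layout: `name`, `total_p_g_per_kg`, optional `dry_solid_pct`,
#' and `constituents:` mapping element names to `{value:, unit:}` pairs.
#'
#' @param path YAML file path.
#' @return A [fertilizer_spec()].
#' @export
read_fertilizer_spec <- function(path) {
  y <- yaml::read_yaml(path)
  fertilizer_spec(name = y$name, total_p_g_per_kg = y$total_p_g_per_kg,
                  constituents = if (is.null(y$constituents)) list()
                                 else y$constituents,
                  dry_solid_pct = if (is.null(y$dry_solid_pct)) NA_real_
                                  else y$dry_solid_pct)
}

#' Read a pipeline run configuration from YAML
#' @param path YAML with `observations`, optional `seed_budgets`,
#'   `labeling` (`activity_bq_per_kg`, `label_date`, `half_life_days`),
#'   `doses` (named), `control`, `reference`, `alpha`.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$labeling)) stop("config lacks a 'labeling' block", call. = FALSE)
  y
}

#' Write a data frame as a tidy CSV at full precision
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tidy_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
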