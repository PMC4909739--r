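#' Run the partitioning pipeline from a configuration
#'
#' Reads the observation and seed-budget tables named in the config, fits
#' [partition_p32()], and writes per-cut detail, per-pot cumulative, the
#' treatment-level partition table, a mean/SE/SNK-letter summary per
#' variable, and a flag log under `out_dir`.
#'
#' @param config Path to a YAML run configuration (see
#'   [read_run_config()]) or an equivalent named list.
#' @param out_dir Output directory, created if needed. `NULL` writes
#'   nothing.
#' @return The `"p32_partition"` fit, invisibly.
#' @export
run_partition <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  if (is.null(cfg$labeling)) {
    stop("config lacks a 'labeling' block", call. = FALSE)
  }
  obs <- if (is.character(cfg$observations))
    read_pot_observations(cfg$observations) else cfg$observations
  sb <- if (is.null(cfg$seed_budgets)) NULL
        else if (is.character(cfg$seed_budgets))
          read_seed_budgets(cfg$seed_budgets) else cfg$seed_budgets
  lab <- labeling_event(cfg$labeling$activity_bq_per_kg,
                        cfg$labeling$label_date,
                        cfg$labeling$half_life_days %||% P32_HALF_LIFE_DAYS)
  fit <- partition_p32(obs, lab, doses = unlist(cfg$doses),
                       seed_budgets = sb,
                       control = cfg$control %||% "control",
                       reference = cfg$reference)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tidy_csv(fit$per_cut, file.path(out_dir, "partition_per_cut.csv"))
    write_tidy_csv(fit$per_pot_cumulative,
                   file.path(out_dir, "partition_per_pot.csv"))
    write_tidy_csv(fit$cumulative, file.path(out_dir, "partition_table.csv"))
    if (!is.null(fit$effectiveness)) {
      write_tidy_csv(fit$effectiveness, file.path(out_dir, "effectiveness.csv"))
    }
    sm <- summary(fit, alpha = cfg$alpha %||% 0.05)
    letters_tab <- do.call(rbind, lapply(names(sm$comparisons), function(v) {
      s <- sm$comparisons[[v]]
      cbind(variable = v, s$groups, F = s$F, p = s$p)
    }))
    if (!is.null(letters_tab)) {
      write_tidy_csv(letters_tab, file.path(out_dir, "summary_snk.csv"))
    }
    fl <- fit$per_cut[nzchar(fit$per_cut$flags),
                      c("pot_id", "treatment", "cut", "flags")]
    write_tidy_csv(fl, file.path(out_dir, "flags.csv"))
  }
  invisible(fit)
}

#' Generate and write a synthetic dataset bundle
#'
#' @param config A [sim_config()], or a list/YAML path with optional fields
#'   `seed` (required), `cv`, `n_reps` overriding [default_sim_config()],
#'   and an optional `incubation: {seed:}` block.
#' @param out_dir Output directory; `NULL` writes nothing.
#' @return List with the pot-experiment bundle and the incubation bundle,
#'   invisibly.
#' @export
run_simulate <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (inherits(cfg, "sim_config")) {
    pot_cfg <- cfg
  } else {
    if (is.null(cfg$seed)) stop("simulation config lacks 'seed'", call. = FALSE)
    pot_cfg <- default_sim_config(seed = cfg$seed, cv = cfg$cv %||% 0.10)
    if (!is.null(cfg$n_reps)) pot_cfg$n_reps <- as.integer(cfg$n_reps)
  }
  if (pot_cfg$n_reps < 2) {
    warning("n_reps < 2: group statistics will be unavailable", call. = FALSE)
  }
  pot <- simulate_pot_experiment(pot_cfg)
  inc_seed <- if (!inherits(cfg, "sim_config") && !is.null(cfg$incubation))
    cfg$incubation$seed %||% (pot_cfg$seed + 1L) else pot_cfg$seed + 1L
  inc <- simulate_incubation(incubation_config(seed = inc_seed,
                                               titration_sd_ml = 0.05))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tidy_csv(pot$observations, file.path(out_dir, "observations.csv"))
    write_tidy_csv(pot$seed_budgets, file.path(out_dir, "seed_budgets.csv"))
    write_tidy_csv(pot$ground_truth, file.path(out_dir, "ground_truth.csv"))
    write_tidy_csv(inc$titrations, file.path(out_dir, "titrations.csv"))
  }
  invisible(list(pot = pot, incubation = inc))
}

#' Fertilizer budget and compliance report for a target P dose
#'
#' @param spec A [fertilizer_spec()] or path to its YAML.
#' @param dose_mg_p_per_kg Target P rate, mg P per kg soil.
#' @param soil_t_per_ha Soil mass for per-hectare conversion.
#' @param limits Heavy-metal limits, mg per kg DM.
#' @param out_dir Output directory; `NULL` writes nothing.
#' @return List with `dm_g_per_kg`, `budget` (per-kg and per-ha rates) and
#'   `compliance`, invisibly.
#' @export
run_budget <- function(spec, dose_mg_p_per_kg = 50, soil_t_per_ha = 3500,
                       limits = french_sludge_limits(), out_dir = NULL) {
  if (is.character(spec)) spec <- read_fertilizer_spec(spec)
  rates <- coapplication_rates(dose_mg_p_per_kg, spec)
  rates$kg_per_ha <- per_hectare(rates$g_per_kg_soil, soil_t_per_ha)
  comp <- heavy_metal_compliance(spec, limits)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tidy_csv(rates, file.path(out_dir, "budget.csv"))
    write_tidy_csv(comp$metals, file.path(out_dir, "compliance.csv"))
  }
  invisible(list(dm_g_per_kg = dm_for_dose(dose_mg_p_per_kg, spec),
                 budget = rates, compliance = comp))
}

#' Respiration series report from a titration table
#'
#' @param titrations Data frame or CSV path of jar-level titration records.
#' @param out_dir Output directory; `NULL` writes nothing.
#' @return Named list of [cumulative_respiration()] series, invisibly.
#' @export
run_respire <- function(titrations, out_dir = NULL) {
  tt <- if (is.character(titrations)) read_titrations(titrations) else titrations
  series <- respiration_series(tt)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(series)) {
      write_tidy_csv(series[[nm]],
                     file.path(out_dir, paste0("respiration_", nm, ".csv")))
    }
  }
  invisible(series)
}

#' Mean/SE/SNK summary of any grouped value column
#'
#' @param data Data frame or CSV path.
#' @param value,group Column names.
#' @param alpha Significance level.
#' @param out_dir Output directory; `NULL` writes nothing.
#' @return The [snk_letters()] result, invisibly.
#' @export
run_stats <- function(data, value, group = "treatment", alpha = 0.05,
                      out_dir = NULL) {
  d <- if (is.character(data)) utils::read.csv(data) else data
  res <- snk_letters(d[[value]], d[[group]], alpha = alpha)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- cbind(res$groups, F = res$F, p = res$p, alpha = alpha)
    write_tidy_csv(out, file.path(out_dir, paste0("stats_", value, ".csv")))
  }
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
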