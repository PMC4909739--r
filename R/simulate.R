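#' Configuration for the synthetic pot-experiment generator
#'
#' Defines the true pool sizes, availability fractions and noise model of a
#' labeled pot experiment. Per treatment: the P dose, the true fraction of
#' shoot uptake derived from the fertilizer per cut, the soil-derived uptake
#' per cut, the seed P allocated to shoots at the first cut, shoot dry
#' matter per cut, and an optional soil-pool specific-activity multiplier
#' (`sa_multiplier`, 1 = the equal-SA assumption holds; other values emulate
#' microbial immobilization perturbing the traced pool).
#'
#' @param treatments Named list; each element a list with `dose` (mg P per
#'   kg soil), `fert_fraction` (per-cut true Pdff fractions in `[0,1)`),
#'   `soil_uptake` (per-cut mg P per kg soil), `seed_alloc` (mg P per kg
#'   soil, first cut), `shoot_dm` (per-cut g per kg soil), optional
#'   `sa_multiplier`.
#' @param cut_days Harvest days after sowing.
#' @param n_reps Pots per treatment.
#' @param R_bq_per_kg Introduced labeling activity, Bq per kg soil.
#' @param label_date Labeling (= sowing) date.
#' @param half_life_days Tracer half-life, days.
#' @param ic_trajectory Per-cut isotopic composition of the soil pool,
#'   percent of R per mg P kg-1 (slightly decreasing trajectories emulate
#'   isotopic exchange over time).
#' @param count_delay_days Days between harvest and scintillation counting.
#' @param cv_dm,cv_p Multiplicative lognormal CVs for dry matter and for the
#'   P-uptake components.
#' @param cv_count Relative SD of the additive Gaussian counting error.
#' @param sown_seed_p Seed P sown, mg P per kg soil.
#' @param root_shoot_ratio,collet_frac Whole-plant P split (relative to
#'   shoot P) used to build the seed-budget side experiment.
#' @param seed RNG seed; mandatory.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(treatments, cut_days = c(27, 38, 59), n_reps = 5L,
                       R_bq_per_kg = 3.7e6, label_date = "2015-03-01",
                       half_life_days = P32_HALF_LIFE_DAYS,
                       ic_trajectory = c(3.3, 3.0, 2.75),
                       count_delay_days = 0,
                       cv_dm = 0.10, cv_p = 0.10, cv_count = 0.10,
                       sown_seed_p = 1.6, root_shoot_ratio = 0.6,
                       collet_frac = 0.1, seed = NULL) {
  if (is.null(seed)) {
    stop("refusing to simulate without an explicit RNG seed", call. = FALSE)
  }
  n_cut <- length(cut_days)
  if (length(ic_trajectory) != n_cut) {
    stop("ic_trajectory must have one value per cut", call. = FALSE)
  }
  for (nm in names(treatments)) {
    tr <- treatments[[nm]]
    stopifnot(length(tr$fert_fraction) == n_cut,
              length(tr$soil_uptake) == n_cut)
    if (any(tr$fert_fraction < 0 | tr$fert_fraction >= 1)) {
      stop("fert_fraction must lie in [0, 1)", call. = FALSE)
    }
    if (is.null(tr$sa_multiplier)) treatments[[nm]]$sa_multiplier <- 1
  }
  if (any(c(cv_dm, cv_p, cv_count) < 0)) stop("CVs must be >= 0", call. = FALSE)
  structure(list(treatments = treatments, cut_days = cut_days,
                 n_reps = as.integer(n_reps), R_bq_per_kg = R_bq_per_kg,
                 label_date = as.Date(label_date),
                 half_life_days = half_life_days,
                 ic_trajectory = ic_trajectory,
                 count_delay_days = count_delay_days,
                 cv_dm = cv_dm, cv_p = cv_p, cv_count = cv_count,
                 sown_seed_p = sown_seed_p,
                 root_shoot_ratio = root_shoot_ratio,
                 collet_frac = collet_frac, seed = seed),
            class = "sim_config")
}

#' Default configuration emulating the TCSS greenhouse experiment
#'
#' Three treatments (unfertilized control, TSP and TCSS at 50 mg P per kg
#' soil), five replicate pots, three cuts at 27/38/59 days, soil labeled
#' with 3.7 MBq 32P per kg. True magnitudes are calibrated to the published
#' cumulative means (shoot P uptake 4.6/19.7/12.5 mg P kg-1, seed
#' allocation 0.62/0.89/0.67, true Pdff 0.55/0.56, first-cut soil-derived
#' uptake 1.11/3.13/1.14 mg P kg-1) under the equal-SA assumption.
#'
#' @inheritParams sim_config
#' @param cv Common CV applied to dry matter, P uptake, and counting.
#' @return A [sim_config()].
#' @export
default_sim_config <- function(seed, cv = 0.10) {
  sim_config(
    treatments = list(
      control = list(dose = 0, fert_fraction = c(0, 0, 0),
                     soil_uptake = c(1.11, 1.30, 1.57),
                     seed_alloc = 0.62, shoot_dm = c(0.90, 0.95, 1.05)),
      TSP = list(dose = 50, fert_fraction = c(0.55, 0.55, 0.55),
                 soil_uptake = c(3.13, 2.90, 1.94),
                 seed_alloc = 0.89, shoot_dm = c(1.70, 1.80, 1.80)),
      TCSS = list(dose = 50, fert_fraction = c(0.56, 0.56, 0.56),
                  soil_uptake = c(1.14, 1.70, 1.99),
                  seed_alloc = 0.67, shoot_dm = c(1.20, 1.25, 1.35))),
    cv_dm = cv, cv_p = cv, cv_count = cv,
    seed = seed)
}

# mean-preserving multiplicative lognormal draw
rlnorm_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, length.out = n))
  sigma <- sqrt(log(1 + cv^2))
  mean * stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate a labeled pot experiment with known ground truth
#'
#' Draws per-pot, per-cut shoot P uptake as the sum of seed-derived,
#' soil-derived and fertilizer-derived components (multiplicative lognormal
#' noise on the latter two and on dry matter), attaches shoot radioactivity
#' as soil-pool isotopic composition times soil-derived uptake (seed and
#' fertilizer P carry no label), decays the activities to the count dates so
#' the analysis pipeline must decay-correct them, and returns the matching
#' seed-budget table and the generating ground truth.
#'
#' @param config A [sim_config()].
#' @return List of class `"p32_simulation"` with `observations` (the
#'   per-pot table read by [partition_p32()]), `seed_budgets`,
#'   `ground_truth` (per-treatment per-cut and cumulative true partitions),
#'   `labeling` and `config`.
#' @export
simulate_pot_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_cut <- length(config$cut_days)
    obs <- list(); truth <- list(); budgets <- list()
    for (nm in names(config$treatments)) {
      tr <- config$treatments[[nm]]
      seed_c <- c(tr$seed_alloc, rep(0, n_cut - 1))
      fert_c <- tr$fert_fraction / (1 - tr$fert_fraction) *
        (tr$soil_uptake + seed_c)
      for (rep_i in seq_len(config$n_reps)) {
        S <- rlnorm_cv(n_cut, tr$soil_uptake, config$cv_p)
        FF <- ifelse(fert_c > 0, rlnorm_cv(n_cut, fert_c, config$cv_p), 0)
        dm <- rlnorm_cv(n_cut, tr$shoot_dm, config$cv_dm)
        pt <- seed_c + S + FF
        r_pct <- config$ic_trajectory * tr$sa_multiplier * S
        act_ref <- r_pct / 100 * config$R_bq_per_kg
        elapsed <- config$cut_days + config$count_delay_days
        act_count <- decay_correct(act_ref, -elapsed, config$half_life_days)
        act_count <- pmax(0, act_count +
                            stats::rnorm(n_cut, 0, config$cv_count * act_count))
        obs[[length(obs) + 1]] <- data.frame(
          pot_id = sprintf("%s_%d", nm, rep_i), treatment = nm,
          cut = seq_len(n_cut), harvest_day = config$cut_days,
          shoot_dm_g_kg = dm, shoot_p_mg_kg = pt,
          activity_bq_kg = act_count,
          count_date = as.character(config$label_date + elapsed))
      }
      # seed-budget side experiment consistent with the allocation by construction
      shoot1 <- seed_c[1] + tr$soil_uptake[1] + fert_c[1]
      share <- 1 / (1 + config$root_shoot_ratio + config$collet_frac)
      depletion <- tr$seed_alloc / share
      if (depletion > config$sown_seed_p) {
        stop("sown seed P too small for requested seed allocation in '",
             nm, "'", call. = FALSE)
      }
      budgets[[nm]] <- data.frame(
        treatment = nm, cut = 1L,
        sown_seed_p = config$sown_seed_p,
        residual_seed_p = config$sown_seed_p - depletion,
        shoot_p = shoot1,
        root_p = shoot1 * config$root_shoot_ratio,
        collet_p = shoot1 * config$collet_frac)
      pt_c <- seed_c + tr$soil_uptake + fert_c
      r_true <- config$ic_trajectory * tr$sa_multiplier * tr$soil_uptake
      truth[[nm]] <- data.frame(
        treatment = nm, cut = c(seq_len(n_cut), NA),
        scope = c(rep("per_cut", n_cut), "cumulative"),
        Pt = c(pt_c, sum(pt_c)),
        Pseed = c(seed_c, sum(seed_c)),
        Psoil = c(tr$soil_uptake, sum(tr$soil_uptake)),
        Pfert = c(fert_c, sum(fert_c)),
        r_over_R = c(r_true, sum(r_true)),
        Pdff = 100 * c(fert_c, sum(fert_c)) / c(pt_c, sum(pt_c)),
        CPU = if (tr$dose > 0) 100 * c(fert_c, sum(fert_c)) / tr$dose
              else NA_real_)
    }
    observations <- do.call(rbind, obs)
    rownames(observations) <- NULL
    # label conservation: no pot may carry more activity than was introduced
    tot <- tapply(observations$activity_bq_kg, observations$pot_id, sum)
    if (any(tot > config$R_bq_per_kg)) {
      stop("simulated plant activity exceeds introduced R; check config",
           call. = FALSE)
    }
    gt <- do.call(rbind, truth); rownames(gt) <- NULL
    structure(list(observations = observations,
                   seed_budgets = do.call(rbind, budgets),
                   ground_truth = gt,
                   labeling = labeling_event(config$R_bq_per_kg,
                                             config$label_date,
                                             config$half_life_days),
                   config = config),
              class = "p32_simulation")
  })
}

#' @export
print.p32_simulation <- function(x, ...) {
  cat("Synthetic 32P pot experiment:",
      length(unique(x$observations$treatment)), "treatments x",
      x$config$n_reps, "pots x", length(x$config$cut_days), "cuts\n")
  invisible(x)
}

#' Configuration for the synthetic incubation (respiration) experiment
#'
#' Each treatment respires as a two-pool model: a basal rate plus an
#' exponentially decaying flush, `flux(t) = basal + A exp(-k t)` in mg C
#' per kg soil per day, integrated exactly over the sampling intervals and
#' inverted into NaOH-trap back-titration volumes.
#'
#' @param treatments Named list of `list(basal =, A =, k =)` per treatment.
#' @param schedule_days Sampling days.
#' @param n_jars Soil jars per treatment.
#' @param n_blanks Blank (no-soil) jars.
#' @param soil_dry_mass_kg Dry soil per jar.
#' @param naoh_ml,naoh_molarity Trap volume (mL) and molarity.
#' @param hcl_normality Back-titration normality, eq per L.
#' @param titration_sd_ml Gaussian reading error on titration volumes.
#' @param seed RNG seed; mandatory.
#' @return List of class `"incubation_config"`.
#' @export
incubation_config <- function(treatments = list(
                                control = list(basal = 1.85, A = 48, k = 0.5),
                                TSP = list(basal = 2.0, A = 52, k = 0.5),
                                TCSS = list(basal = 1.9, A = 65, k = 0.5)),
                              schedule_days = c(1, 2, 3, 5, 8, 10, 15, 23,
                                                32, 42, 63),
                              n_jars = 3L, n_blanks = 4L,
                              soil_dry_mass_kg = 0.1,
                              naoh_ml = 5, naoh_molarity = 0.5,
                              hcl_normality = 0.1,
                              titration_sd_ml = 0, seed = NULL) {
  if (is.null(seed)) {
    stop("refusing to simulate without an explicit RNG seed", call. = FALSE)
  }
  structure(list(treatments = treatments, schedule_days = schedule_days,
                 n_jars = as.integer(n_jars), n_blanks = as.integer(n_blanks),
                 soil_dry_mass_kg = soil_dry_mass_kg, naoh_ml = naoh_ml,
                 naoh_molarity = naoh_molarity, hcl_normality = hcl_normality,
                 titration_sd_ml = titration_sd_ml, seed = seed),
            class = "incubation_config")
}

# exact integral of basal + A exp(-k t) over [t0, t1]
flush_interval_mass <- function(basal, A, k, t0, t1) {
  basal * (t1 - t0) + if (k > 0) A / k * (exp(-k * t0) - exp(-k * t1))
                      else A * (t1 - t0)
}

#' Simulate NaOH-trap titration records for an incubation experiment
#'
#' @param config An [incubation_config()].
#' @return List of class `"incubation_simulation"`: `titrations` (jar-level
#'   records including blank jars, readable by [respiration_series()]) and
#'   `true_interval_masses` (per-treatment data frame of the generating
#'   interval masses, mg C per kg soil).
#' @export
simulate_incubation <- function(config) {
  stopifnot(inherits(config, "incubation_config"))
  with_seed(config$seed, {
    days <- config$schedule_days
    t0 <- c(0, utils::head(days, -1))
    blank_true <- config$naoh_ml * config$naoh_molarity / config$hcl_normality
    trap_meq <- config$naoh_ml * config$naoh_molarity
    rows <- list(); truth <- list()
    for (nm in names(config$treatments)) {
      tr <- config$treatments[[nm]]
      mass_kg <- flush_interval_mass(tr$basal, tr$A, tr$k, t0, days)
      truth[[nm]] <- data.frame(treatment = nm, day = days,
                                interval_mass = mass_kg)
      meq <- mass_kg * config$soil_dry_mass_kg / MG_C_PER_MEQ
      if (any(meq > trap_meq)) {
        stop("trap saturation: interval CO2 exceeds NaOH capacity in '",
             nm, "'", call. = FALSE)
      }
      for (j in seq_len(config$n_jars)) {
        v <- blank_true - meq / config$hcl_normality +
          stats::rnorm(length(days), 0, config$titration_sd_ml)
        rows[[length(rows) + 1]] <- data.frame(
          jar_id = sprintf("%s_%d", nm, j), treatment = nm,
          start_day = t0, end_day = days,
          hcl_normality = config$hcl_normality,
          v_sample_ml = v, soil_dry_mass_kg = config$soil_dry_mass_kg)
      }
    }
    for (b in seq_len(config$n_blanks)) {
      rows[[length(rows) + 1]] <- data.frame(
        jar_id = sprintf("blank_%d", b), treatment = "blank",
        start_day = t0, end_day = days,
        hcl_normality = config$hcl_normality,
        v_sample_ml = blank_true +
          stats::rnorm(length(days), 0, config$titration_sd_ml),
        soil_dry_mass_kg = NA_real_)
    }
    titr <- do.call(rbind, rows); rownames(titr) <- NULL
    tm <- do.call(rbind, truth); rownames(tm) <- NULL
    structure(list(titrations = titr, true_interval_masses = tm,
                   config = config),
              class = "incubation_simulation")
  })
}

#' Cumulated degree days
#'
#' Running physiological time: the sum over days of the daily mean
#' temperature above a base temperature.
#'
#' @param daily_mean_temps Daily mean temperatures, deg C.
#' @param base Base temperature, deg C (default 0).
#' @return Total cumulated degree days.
#' @examples
#' degree_days(rep(25.67, 27))  # ~693
#' @export
degree_days <- function(daily_mean_temps, base = 0) {
  sum(pmax(0, daily_mean_temps - base))
}
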