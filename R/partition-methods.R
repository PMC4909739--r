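#' @export
print.p32_partition <- function(x, digits = 3, ...) {
  cat("Isotope-dilution partition of shoot P uptake (",
      x$mode, " mode)\n", sep = "")
  cat("Control: ", x$control,
      if (!is.null(x$reference)) paste0("; AE reference: ", x$reference),
      "\n\n", sep = "")
  cols <- intersect(c("treatment", "n", "dose", "Pt", "Pseed", "Psoil",
                      "Pfert", "r_over_R", "SA", "L", "Pdff", "CPU"),
                    names(x$cumulative))
  print(format_num_df(x$cumulative[, cols], digits))
  if (!is.null(x$effectiveness)) {
    cat("\nAgronomic effectiveness (% of ", x$reference, "):\n", sep = "")
    print(format_num_df(x$effectiveness, digits))
  }
  fl <- x$per_cut$flags[nzchar(x$per_cut$flags)]
  if (length(fl)) cat("\nFlags raised: ", paste(unique(fl), collapse = ", "),
                      "\n", sep = "")
  invisible(x)
}

format_num_df <- function(d, digits) {
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], signif, digits = digits)
  d
}

#' Summarize a fitted P partition with treatment comparisons
#'
#' Adds one-way ANOVA and Student-Newman-Keuls letter groupings over the
#' per-pot cumulative values for each partition variable, in the reporting
#' style of isotope pot-experiment tables (mean : SE with superscript
#' letters).
#'
#' @param object A [partition_p32()] fit (per-pot mode).
#' @param variables Variables to compare across treatments.
#' @param alpha Significance level for the letter display.
#' @param ... Unused.
#' @return A list of class `"summary.p32_partition"` with elements `table`
#'   (cumulative treatment summary), `comparisons` (one [snk_letters()]
#'   result per variable) and `effectiveness`.
#' @export
summary.p32_partition <- function(object,
                                  variables = c("Pt", "Psoil", "Pfert",
                                                "r_over_R", "SA", "L",
                                                "Pdff", "CPU"),
                                  alpha = 0.05, ...) {
  pp <- object$per_pot_cumulative
  comparisons <- lapply(stats::setNames(variables, variables), function(v) {
    ok <- is.finite(pp[[v]])
    if (length(unique(pp$treatment[ok])) < 2) return(NULL)
    snk_letters(pp[[v]][ok], pp$treatment[ok], alpha = alpha)
  })
  structure(list(table = object$cumulative,
                 comparisons = Filter(Negate(is.null), comparisons),
                 effectiveness = object$effectiveness,
                 alpha = alpha, mode = object$mode),
            class = "summary.p32_partition")
}

#' @export
print.summary.p32_partition <- function(x, digits = 3, ...) {
  cat("Cumulative partition (treatment means):\n")
  print(format_num_df(x$table, digits))
  cat("\nTreatment comparisons (one-way ANOVA + SNK letters, alpha = ",
      x$alpha, "):\n", sep = "")
  for (v in names(x$comparisons)) {
    s <- x$comparisons[[v]]
    cat(sprintf("  %-8s F = %s, p = %s | %s\n", v,
                format(signif(s$F, 3)), format(signif(s$p, 3)),
                paste(sprintf("%s %s (%s)", s$groups$group,
                              signif(s$groups$mean, 3), s$groups$letters),
                      collapse = "; ")))
  }
  if (!is.null(x$effectiveness)) {
    cat("\nAgronomic effectiveness:\n")
    print(format_num_df(x$effectiveness, digits))
  }
  invisible(x)
}

#' Extract cumulative partition coefficients
#'
#' @param object A [partition_p32()] fit.
#' @param ... Unused.
#' @return Numeric matrix (treatments x quantities) of the cumulative
#'   partition: Pt, Pseed, Psoil, Pfert, r/R, SA, L, Pdff, CPU.
#' @export
coef.p32_partition <- function(object, ...) {
  cols <- intersect(c("Pt", "Pseed", "Psoil", "Pfert", "r_over_R",
                      "SA", "L", "Pdff", "CPU"), names(object$cumulative))
  m <- as.matrix(object$cumulative[, cols])
  rownames(m) <- object$cumulative$treatment
  m
}

#' Plot per-cut P uptake and its sources
#'
#' Draws cumulative shoot P uptake against harvest day per treatment, and a
#' stacked bar chart of the cumulated soil/seed/fertilizer partition.
#'
#' @param x A [partition_p32()] fit.
#' @param which `1` uptake trajectories, `2` partition bars, or both.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.p32_partition <- function(x, which = 1:2, ...) {
  obs <- x$per_cut
  if (1 %in% which) {
    trt <- split(obs, obs$treatment)
    days <- sort(unique(obs$harvest_day))
    mat <- sapply(trt, function(d) {
      m <- tapply(d$Pt, d$harvest_day, mean)
      cumsum(m[as.character(days)])
    })
    graphics::matplot(days, mat, type = "b", pch = 19, lty = 1,
                      xlab = "days after sowing",
                      ylab = "cumulative shoot P uptake (mg P kg-1 soil)", ...)
    graphics::legend("topleft", legend = colnames(mat), col = seq_len(ncol(mat)),
                     pch = 19, lty = 1, bty = "n")
  }
  if (2 %in% which) {
    cum <- x$cumulative
    h <- t(as.matrix(cum[, c("Psoil", "Pseed", "Pfert")]))
    colnames(h) <- cum$treatment
    graphics::barplot(pmax(h, 0), legend.text = c("soil", "seed", "fertilizer"),
                      ylab = "cumulative shoot P uptake (mg P kg-1 soil)")
  }
  invisible(x)
}

#' Simulate new pot experiments from a fitted partition
#'
#' Uses the fitted cumulative magnitudes (per-treatment soil-derived uptake,
#' fertilizer fraction, seed allocation, doses, labeling) to parameterize
#' the synthetic generator and draw new experiments, e.g. for parametric
#' bootstrap of Pdff/CPU.
#'
#' @param object A [partition_p32()] fit.
#' @param nsim Number of simulated experiments.
#' @param seed RNG seed (required for reproducibility; mandatory).
#' @param n_reps Pots per treatment in each simulated experiment.
#' @param cv Coefficient of variation applied to P uptake, dry matter and
#'   counting.
#' @param ... Unused.
#' @return A list of `nsim` simulation bundles (see
#'   [simulate_pot_experiment()]).
#' @export
simulate.p32_partition <- function(object, nsim = 1, seed = NULL,
                                   n_reps = 5L, cv = 0.10, ...) {
  if (is.null(seed)) stop("simulate() requires an explicit seed", call. = FALSE)
  cum <- object$cumulative
  cuts <- sort(unique(object$per_cut$cut))
  days <- sort(unique(object$per_cut$harvest_day))
  n_cut <- length(cuts)
  treatments <- lapply(seq_len(nrow(cum)), function(i) {
    soil_total <- max(cum$Psoil[i], 1e-6)
    pt <- max(cum$Pt[i], 1e-6)
    list(dose = if (is.finite(cum$dose[i])) cum$dose[i] else 0,
         fert_fraction = rep(max(min(cum$Pfert[i] / pt, 0.99), 0), n_cut),
         soil_uptake = rep(soil_total / n_cut, n_cut),
         seed_alloc = cum$Pseed[i],
         shoot_dm = rep(1, n_cut))
  })
  names(treatments) <- cum$treatment
  base_cfg <- sim_config(
    treatments = treatments,
    cut_days = days,
    n_reps = n_reps,
    R_bq_per_kg = object$labeling$activity_bq_per_kg,
    label_date = as.character(object$labeling$label_date),
    half_life_days = object$labeling$half_life_days,
    ic_trajectory = rep(ic0(cum$r_over_R[cum$treatment == object$control],
                            cum$Pt[cum$treatment == object$control],
                            cum$Pseed[cum$treatment == object$control]),
                        n_cut),
    cv_dm = cv, cv_p = cv, cv_count = cv,
    seed = seed)
  lapply(seq_len(nsim), function(i) {
    cfg <- base_cfg
    cfg$seed <- seed + i - 1L
    simulate_pot_experiment(cfg)
  })
}
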