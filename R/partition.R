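#' Describe a soil 32P labeling event
#'
#' @param activity_bq_per_kg Introduced activity R, Bq per kg soil.
#' @param label_date Date the soil was labeled (anything `as.Date` accepts).
#' @param half_life_days Isotope half-life, days.
#' @return A list of class `"labeling_event"`.
#' @examples
#' labeling_event(3.7e6, "2015-03-01")
#' @export
labeling_event <- function(activity_bq_per_kg, label_date,
                           half_life_days = P32_HALF_LIFE_DAYS) {
  if (!is.finite(activity_bq_per_kg) || activity_bq_per_kg <= 0) {
    stop("introduced activity must be > 0", call. = FALSE)
  }
  if (!is.finite(half_life_days) || half_life_days <= 0) {
    stop("half-life must be > 0", call. = FALSE)
  }
  structure(list(activity_bq_per_kg = activity_bq_per_kg,
                 label_date = as.Date(label_date),
                 half_life_days = half_life_days),
            class = "labeling_event")
}

obs_required_cols <- c("pot_id", "treatment", "cut", "harvest_day",
                       "shoot_p_mg_kg", "activity_bq_kg", "count_date")

validate_observations <- function(observations) {
  missing <- setdiff(obs_required_cols, names(observations))
  if (length(missing)) {
    stop("observation table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(observations)) stop("observation table is empty", call. = FALSE)
  bad <- which(observations$shoot_p_mg_kg < 0 | observations$activity_bq_kg < 0)
  if (length(bad)) {
    stop("negative shoot P or activity in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(observations)
}

# Seed-derived shoot P per treatment x cut. Budgets may carry either a
# precomputed pseed_mg_kg column or the raw whole-plant split; cuts beyond
# `seed_cuts` get 0 (seed reserves are depleted from the second cut on).
seed_allocation_table <- function(seed_budgets, treatments, cuts,
                                  seed_cuts = 1L) {
  grid <- expand.grid(treatment = treatments, cut = cuts,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$pseed <- 0
  if (is.null(seed_budgets)) return(grid)
  sb <- as.data.frame(seed_budgets)
  if (!"cut" %in% names(sb)) sb$cut <- 1L
  if (!"pseed_mg_kg" %in% names(sb)) {
    sb$pseed_mg_kg <- seed_p_allocated(
      sb$sown_seed_p, sb$residual_seed_p,
      shoot_p = sb$shoot_p,
      root_p = if ("root_p" %in% names(sb)) sb$root_p else 0,
      collet_p = if ("collet_p" %in% names(sb)) sb$collet_p else 0)
  }
  for (i in seq_len(nrow(grid))) {
    if (grid$cut[i] > seed_cuts) next
    hit <- sb$treatment == grid$treatment[i] & sb$cut == grid$cut[i]
    if (any(hit)) grid$pseed[i] <- mean(sb$pseed_mg_kg[hit])
  }
  grid
}

#' Partition shoot P uptake into soil, seed, and fertilizer sources
#'
#' Fits the isotope-dilution source partitioning to a labeled pot experiment.
#' Shoot counts are decay-corrected to the labeling date and expressed as a
#' percentage of the introduced activity R; the unfertilized control anchors
#' the isotopic composition of soil-derived P (assumed equal across
#' treatments), from which each fertilized pot's soil-derived uptake follows
#' as `(Pt0 - Pseed0) * r/r0` per cut, fertilizer-derived uptake as the
#' mass-balance residual, and the cut-level partitions are summed per pot
#' into cumulative Pdff, CPU, SA and L-values.
#'
#' @param observations Data frame of per-pot, per-cut records with columns
#'   `pot_id`, `treatment`, `cut`, `harvest_day`, `shoot_p_mg_kg` (mg P per
#'   kg soil), `activity_bq_kg` (measured, uncorrected), `count_date`
#'   (ISO 8601), optionally `shoot_dm_g_kg`.
#' @param labeling A [labeling_event()].
#' @param doses Named numeric vector of P application rates (mg P per kg
#'   soil) for fertilized treatments; the control is implicitly 0.
#' @param seed_budgets Optional data frame with `treatment`, `cut` and either
#'   `pseed_mg_kg` or the raw budget columns `sown_seed_p`,
#'   `residual_seed_p`, `shoot_p`, `root_p`, `collet_p` (all mg P per kg
#'   soil). Seed allocation is 0 for cuts beyond `seed_cuts`.
#' @param control Name of the unfertilized control treatment.
#' @param reference Name of the reference fertilizer for agronomic
#'   effectiveness (e.g. `"TSP"`); `NULL` skips AE.
#' @param mode `"per_pot"` (default: per-cut partitioning of every pot
#'   against per-cut control means, then cumulation per pot — the arithmetic
#'   used for replicate-level statistics) or `"aggregate"` (partitioning of
#'   cumulated treatment means; a diagnostic/teaching mode).
#' @param seed_cuts Highest cut index that still receives seed P (default 1).
#' @return An object of class `"p32_partition"`; see [summary.p32_partition()].
#' @seealso [partition_aggregate()] for the means-level chain on its own.
#' @export
partition_p32 <- function(observations, labeling, doses,
                          seed_budgets = NULL,
                          control = "control", reference = NULL,
                          mode = c("per_pot", "aggregate"),
                          seed_cuts = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(labeling, "labeling_event"))
  obs <- as.data.frame(validate_observations(observations))
  obs$treatment <- as.character(obs$treatment)
  if (!control %in% obs$treatment) {
    stop("cannot partition: control treatment '", control,
         "' absent from observations", call. = FALSE)
  }
  if (!is.null(reference) && !reference %in% obs$treatment) {
    stop("reference treatment '", reference, "' absent from observations",
         call. = FALSE)
  }
  treatments <- unique(obs$treatment)
  fertilized <- setdiff(treatments, control)
  dose_of <- stats::setNames(rep(NA_real_, length(treatments)), treatments)
  dose_of[control] <- 0
  if (length(fertilized)) dose_of[fertilized] <- doses[fertilized]

  # tracer recovery per pot x cut, decay-corrected to the labeling date
  elapsed <- as.numeric(as.Date(obs$count_date) - labeling$label_date)
  r_bq <- decay_correct(obs$activity_bq_kg, elapsed, labeling$half_life_days)
  obs$r_over_R <- fraction_recovered(r_bq, labeling$activity_bq_per_kg)

  cuts <- sort(unique(obs$cut))
  seed_tab <- seed_allocation_table(seed_budgets, treatments, cuts, seed_cuts)
  obs$Pseed <- seed_tab$pseed[match(paste(obs$treatment, obs$cut),
                                    paste(seed_tab$treatment, seed_tab$cut))]

  # per-cut control anchors
  ctl <- obs[obs$treatment == control, , drop = FALSE]
  anchors <- do.call(rbind, lapply(cuts, function(cc) {
    k <- ctl[ctl$cut == cc, , drop = FALSE]
    data.frame(cut = cc,
               Pt0 = mean(k$shoot_p_mg_kg),
               r0 = mean(k$r_over_R),
               Pseed0 = if (nrow(k)) k$Pseed[1] else 0)
  }))
  if (any(anchors$Pt0 <= anchors$Pseed0)) {
    stop("degenerate control: mean Pt0 <= Pseed0 in at least one cut",
         call. = FALSE)
  }
  if (any(anchors$r0 <= 0)) {
    stop("partition undefined: control tracer recovery is 0 in a cut",
         call. = FALSE)
  }

  a <- anchors[match(obs$cut, anchors$cut), ]
  is_ctl <- obs$treatment == control
  obs$Psoil <- ifelse(is_ctl,
                      obs$shoot_p_mg_kg - obs$Pseed,
                      psoil_from_tracer(a$Pt0, a$Pseed0, obs$r_over_R, a$r0))
  obs$Pfert <- ifelse(is_ctl, 0,
                      pfert_residual(obs$shoot_p_mg_kg, obs$Pseed, obs$Psoil))
  obs$flags <- flag_join(
    ifelse(obs$Pfert < 0, "negative-Pfert", ""),
    ifelse(obs$Psoil < 0, "negative-Psoil", ""),
    ifelse(obs$r_over_R == 0, "zero-activity", ""))
  names(obs)[names(obs) == "shoot_p_mg_kg"] <- "Pt"

  per_pot_cum <- cumulate_pots(obs, dose_of)

  if (mode == "aggregate") {
    means <- aggregate_means(obs, control)
    cumulative <- partition_aggregate(means, control = control)
  } else {
    cumulative <- summarize_partition(per_pot_cum, dose_of)
  }

  effectiveness <- NULL
  if (!is.null(reference)) {
    ref_row <- cumulative[cumulative$treatment == reference, ]
    effectiveness <- do.call(rbind, lapply(fertilized, function(tr) {
      ae <- agronomic_effectiveness(
        cumulative[cumulative$treatment == tr, ],
        list(Pfert = ref_row$Pfert, Pdff = ref_row$Pdff, treatment = reference))
      data.frame(treatment = tr, AE_CPU = ae$AE_CPU, AE_Pdff = ae$AE_Pdff,
                 reference = reference)
    }))
  }

  structure(list(per_cut = obs,
                 per_pot_cumulative = per_pot_cum,
                 cumulative = cumulative,
                 effectiveness = effectiveness,
                 labeling = labeling, doses = dose_of,
                 control = control, reference = reference, mode = mode,
                 call = match.call()),
            class = "p32_partition")
}

flag_join <- function(...) {
  parts <- cbind(...)
  apply(parts, 1, function(p) paste(p[nzchar(p)], collapse = ";"))
}

# per-pot cumulation over cuts with ratio quantities recomputed from sums
cumulate_pots <- function(obs, dose_of) {
  key <- interaction(obs$treatment, obs$pot_id, drop = TRUE)
  out <- do.call(rbind, lapply(split(obs, key), function(p) {
    p <- p[order(p$cut), ]
    cumulate_cuts(p, dose = dose_of[[p$treatment[1]]])
  }))
  rownames(out) <- NULL
  out
}

#' Cumulate per-cut partition rows into a cumulative partition
#'
#' Mass quantities (Pt, Pseed, Psoil, Pfert) and tracer recovery sum over
#' cuts; Pdff, CPU, SA and the L-value are recomputed from the cumulated
#' sums, not averaged.
#'
#' @param per_cut Data frame of per-cut rows for a single pot or treatment,
#'   with columns `treatment`, `cut`, `Pt`, `Pseed`, `Psoil`, `Pfert`,
#'   `r_over_R` and optionally `pot_id`, `flags`.
#' @param dose Applied P dose, mg P per kg soil (`NA` or 0 suppresses CPU).
#' @return One-row data frame of the cumulative partition.
#' @export
cumulate_cuts <- function(per_cut, dose = NA_real_) {
  p <- as.data.frame(per_cut)
  if (length(unique(p$treatment)) != 1) {
    stop("cumulate_cuts: rows mix treatments", call. = FALSE)
  }
  if (is.unsorted(p$cut, strictly = TRUE)) p <- p[order(p$cut), ]
  if (anyDuplicated(p$cut)) {
    stop("cumulate_cuts: duplicated cut index", call. = FALSE)
  }
  Pt <- sum(p$Pt); Pseed <- sum(p$Pseed)
  Psoil <- sum(p$Psoil); Pfert <- sum(p$Pfert)
  r <- sum(p$r_over_R)
  data.frame(
    treatment = p$treatment[1],
    pot_id = if ("pot_id" %in% names(p)) p$pot_id[1] else NA,
    n_cuts = nrow(p),
    Pt = Pt, Pseed = Pseed, Psoil = Psoil, Pfert = Pfert,
    r_over_R = r,
    SA = if (Pt > 0) specific_activity(r, Pt) else NA_real_,
    L = if (r > 0) l_value(Pt, r) else NA_real_,
    Pdff = if (Pt > 0) pdff(Pfert, Pt) else NA_real_,
    CPU = if (is.finite(dose) && dose > 0) cpu(Pfert, dose) else NA_real_,
    flags = if ("flags" %in% names(p))
      paste(unique(p$flags[nzchar(p$flags)]), collapse = ";") else "",
    stringsAsFactors = FALSE)
}

# treatment-level summary (mean +/- SE over pots) of per-pot cumulatives
summarize_partition <- function(per_pot_cum, dose_of) {
  out <- do.call(rbind, lapply(split(per_pot_cum, per_pot_cum$treatment),
                               function(d) {
    m <- function(v) mean(v, na.rm = TRUE)
    se <- function(v) {
      v <- v[is.finite(v)]
      if (length(v) < 2) return(NA_real_)
      stats::sd(v) / sqrt(length(v))
    }
    data.frame(
      treatment = d$treatment[1], n = nrow(d), dose = dose_of[[d$treatment[1]]],
      Pt = m(d$Pt), Pt_se = se(d$Pt),
      Pseed = m(d$Pseed),
      Psoil = m(d$Psoil), Psoil_se = se(d$Psoil),
      Pfert = m(d$Pfert), Pfert_se = se(d$Pfert),
      r_over_R = m(d$r_over_R), r_over_R_se = se(d$r_over_R),
      SA = m(d$SA), SA_se = se(d$SA),
      L = m(d$L), L_se = se(d$L),
      Pdff = m(d$Pdff), Pdff_se = se(d$Pdff),
      CPU = m(d$CPU), CPU_se = se(d$CPU),
      flags = paste(unique(d$flags[nzchar(d$flags)]), collapse = ";"),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

aggregate_means <- function(obs, control) {
  out <- do.call(rbind, lapply(split(obs, obs$treatment), function(d) {
    pots <- split(d, d$pot_id)
    data.frame(treatment = d$treatment[1],
               Pt = mean(vapply(pots, function(p) sum(p$Pt), 0)),
               Pseed = mean(vapply(pots, function(p) sum(p$Pseed), 0)),
               r_over_R = mean(vapply(pots, function(p) sum(p$r_over_R), 0)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Isotope-dilution partitioning of cumulated treatment means
#'
#' The desk-scale (aggregate) form of the partitioning chain: given one row
#' of cumulated means per treatment, compute SA and L per treatment, anchor
#' the soil isotopic composition in the control, and split the fertilized
#' treatments' uptake into soil-, seed- and fertilizer-derived fractions
#' with Pdff and CPU. Because it runs on aggregated means rather than on
#' per-replicate, per-cut values, its Psoil/Pfert differ from a replicate
#' cumulation whenever recoveries vary across cuts; ratio quantities
#' (SA, L) are unaffected.
#'
#' @param means Data frame with columns `treatment`, `Pt` (mg P per kg
#'   soil), `r_over_R` (percent of R), optionally `Pseed` (default 0) and
#'   `dose` (mg P per kg soil).
#' @param control Name of the control treatment (dose 0).
#' @return The input with columns `SA`, `L`, `Psoil`, `Pfert`, `Pdff`,
#'   `CPU`, `IC0` appended.
#' @export
partition_aggregate <- function(means, control = "control") {
  m <- as.data.frame(means)
  if (!control %in% m$treatment) {
    stop("cannot partition: no '", control, "' row", call. = FALSE)
  }
  if (!"Pseed" %in% names(m)) m$Pseed <- 0
  if (!"dose" %in% names(m)) m$dose <- NA_real_
  ctl <- m[m$treatment == control, ]
  ic <- ic0(ctl$r_over_R, ctl$Pt, ctl$Pseed)
  is_ctl <- m$treatment == control
  m$SA <- specific_activity(m$r_over_R, m$Pt)
  m$L <- l_value(m$Pt, m$r_over_R)
  m$Psoil <- ifelse(is_ctl, m$Pt - m$Pseed,
                    psoil_from_tracer(ctl$Pt, ctl$Pseed, m$r_over_R,
                                      ctl$r_over_R))
  m$Pfert <- ifelse(is_ctl, 0, pfert_residual(m$Pt, m$Pseed, m$Psoil))
  m$Pdff <- pdff(m$Pfert, m$Pt)
  m$CPU <- ifelse(!is_ctl & is.finite(m$dose) & m$dose > 0,
                  100 * m$Pfert / m$dose, NA_real_)
  m$IC0 <- ic
  m
}
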