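#' C-CO2 trapped in a NaOH jar from back-titration volumes
#'
#' CO2 absorbed by the NaOH trap consumes alkali (CO2 + 2 NaOH -> Na2CO3);
#' back-titrating the residual NaOH with HCl to the phenolphthalein endpoint
#' measures one milliequivalent per milliequivalent of trapped CO2, i.e.
#' 6 mg C per meq of HCl difference between blank and sample jars.
#'
#' @param v_blank_ml Titration volume of the blank (no-soil) jar, mL HCl.
#'   Replicate blanks should be averaged per sampling interval first.
#' @param v_sample_ml Titration volume of the soil jar, mL HCl.
#' @param hcl_normality Titrant normality, eq per L (0.1 N in the standard
#'   protocol).
#' @param soil_dry_mass_kg Optional dry soil mass in the jar; when given the
#'   result is per kg soil.
#' @return mg C-CO2 (absolute, or per kg soil when `soil_dry_mass_kg` is
#'   given). Negative values (sample titre above blank) are returned as-is
#'   for flagging, never clipped.
#' @examples
#' c_from_titration(10, 5, 0.1)            # 3 mg C
#' c_from_titration(10, 5, 0.1, 0.1)       # 30 mg C per kg soil
#' @export
c_from_titration <- function(v_blank_ml, v_sample_ml, hcl_normality = 0.1,
                             soil_dry_mass_kg = NULL) {
  if (any(is.na(v_blank_ml))) {
    stop("cannot compute C-CO2 without a blank titration", call. = FALSE)
  }
  if (any(hcl_normality <= 0)) stop("HCl normality must be > 0", call. = FALSE)
  meq <- (v_blank_ml - v_sample_ml) * hcl_normality  # mL * eq/L = meq
  mg_c <- meq * MG_C_PER_MEQ
  if (is.null(soil_dry_mass_kg)) return(mg_c)
  if (any(soil_dry_mass_kg <= 0)) {
    stop("soil dry mass must be > 0", call. = FALSE)
  }
  mg_c / soil_dry_mass_kg
}

# 12 g C per mol CO2 binding 2 eq NaOH -> 6 mg C per meq
MG_C_PER_MEQ <- 6

#' Daily C-CO2 flux from an interval mass
#'
#' Interval-averaged respiration rate, conventionally assigned to the
#' interval's end day.
#'
#' @param mass_mg_per_kg C-CO2 evolved over the interval, mg C per kg soil.
#' @param interval_days Interval length, days (> 0).
#' @return mg C per kg soil per day.
#' @export
daily_flux <- function(mass_mg_per_kg, interval_days) {
  if (any(interval_days <= 0)) {
    stop("interval length must be > 0 days", call. = FALSE)
  }
  mass_mg_per_kg / interval_days
}

#' Cumulative respiration series from interval masses
#'
#' @param end_days Interval end days (sampling schedule), strictly
#'   increasing; intervals run from the previous end day (0 at the start).
#' @param interval_masses mg C per kg soil evolved per interval.
#' @param exclude_negative Exclude flagged negative interval masses from the
#'   running sum (default, keeps cumulative curves physically nondecreasing
#'   under titration noise); they remain visible in the output.
#' @return Data frame of class `"respiration_series"` with `day`,
#'   `interval_days`, `interval_mass`, `daily_flux`, `cumulative`, `flags`.
#' @export
cumulative_respiration <- function(end_days, interval_masses,
                                   exclude_negative = TRUE) {
  if (length(end_days) != length(interval_masses)) {
    stop("schedule and masses differ in length", call. = FALSE)
  }
  if (is.unsorted(end_days, strictly = TRUE) || any(end_days <= 0)) {
    stop("sampling days must be positive and strictly increasing",
         call. = FALSE)
  }
  iv <- diff(c(0, end_days))
  contrib <- if (exclude_negative) pmax(interval_masses, 0) else interval_masses
  out <- data.frame(day = end_days,
                    interval_days = iv,
                    interval_mass = interval_masses,
                    daily_flux = daily_flux(interval_masses, iv),
                    cumulative = cumsum(contrib),
                    flags = ifelse(interval_masses < 0, "negative-mass", ""))
  class(out) <- c("respiration_series", class(out))
  out
}

#' Respiration series per treatment from a titration table
#'
#' Blank rows (treatment `"blank"`, no soil mass) are averaged per interval
#' and used to correct every soil jar of that interval; jar-level interval
#' masses are then averaged per treatment and accumulated.
#'
#' @param titrations Data frame with columns `jar_id`, `treatment`,
#'   `start_day`, `end_day`, `hcl_normality`, `v_blank_ml` (optional if
#'   blank rows are present), `v_sample_ml`, `soil_dry_mass_kg`.
#' @param blank_label Treatment label identifying blank jars.
#' @inheritParams cumulative_respiration
#' @return Named list of [cumulative_respiration()] series, one per
#'   treatment.
#' @export
respiration_series <- function(titrations, blank_label = "blank",
                               exclude_negative = TRUE) {
  tt <- as.data.frame(titrations)
  need <- c("jar_id", "treatment", "start_day", "end_day",
            "hcl_normality", "v_sample_ml")
  missing <- setdiff(need, names(tt))
  if (length(missing)) {
    stop("titration table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  blanks <- tt[tt$treatment == blank_label, , drop = FALSE]
  soil <- tt[tt$treatment != blank_label, , drop = FALSE]
  if (!"v_blank_ml" %in% names(soil) || anyNA(soil$v_blank_ml)) {
    if (!nrow(blanks)) {
      stop("cannot compute C-CO2: no blank volumes and no blank jars",
           call. = FALSE)
    }
    bm <- tapply(blanks$v_sample_ml, blanks$end_day, mean)
    soil$v_blank_ml <- bm[as.character(soil$end_day)]
    if (anyNA(soil$v_blank_ml)) {
      stop("missing blank jar for at least one sampling day", call. = FALSE)
    }
  }
  soil$mass <- c_from_titration(soil$v_blank_ml, soil$v_sample_ml,
                                soil$hcl_normality, soil$soil_dry_mass_kg)
  lapply(split(soil, soil$treatment), function(d) {
    days <- sort(unique(d$end_day))
    if (any(tapply(d$start_day, d$end_day, function(s) length(unique(s))) > 1)) {
      stop("overlapping intervals for one sampling day", call. = FALSE)
    }
    m <- tapply(d$mass, d$end_day, mean)[as.character(days)]
    cumulative_respiration(days, as.numeric(m),
                           exclude_negative = exclude_negative)
  })
}

#' Substrate-induced-respiration estimate of microbial biomass C
#'
#' A literature-derived heuristic: the respiration flush after substrate
#' addition, multiplied by a conversion factor of 40, approximates soil
#' microbial biomass carbon.
#'
#' @param flush_c_mg_per_kg Flush of C-CO2, mg C per kg soil.
#' @param factor Conversion factor (default 40).
#' @return mg biomass-C per kg soil.
#' @export
sir_biomass_estimate <- function(flush_c_mg_per_kg, factor = 40) {
  if (any(flush_c_mg_per_kg < 0)) {
    stop("flush must be >= 0", call. = FALSE)
  }
  factor * flush_c_mg_per_kg
}
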