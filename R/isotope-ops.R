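#' Fraction of introduced radioactivity recovered in shoots (r/R)
#'
#' @param shoot_activity Decay-corrected shoot activity, Bq per kg soil.
#' @param R Introduced soil labeling activity, Bq per kg soil.
#' @return Percent of the introduced activity recovered (100 * r/R).
#' @examples
#' fraction_recovered(4.366e5, 3.7e6)  # 11.8%
#' @export
fraction_recovered <- function(shoot_activity, R) {
  if (any(!is.finite(R)) || any(R <= 0)) {
    stop("introduced activity 'R' must be > 0", call. = FALSE)
  }
  100 * shoot_activity / R
}

#' Specific activity of P taken up by shoots
#'
#' SA is the ratio between the fractional tracer recovery r/R and shoot P
#' uptake: the tracer "concentration" of the P actually acquired. Units are
#' fraction-of-R per mg P per kg soil; its reciprocal is the L-value.
#'
#' @param r_over_R Tracer recovery in percent of introduced R.
#' @param shoot_p Shoot P uptake, mg P per kg soil (must be > 0).
#' @return SA, fraction of R per mg P kg-1.
#' @examples
#' specific_activity(11.8, 4.6)  # 0.0257
#' @export
specific_activity <- function(r_over_R, shoot_p) {
  if (any(!is.finite(shoot_p)) || any(shoot_p <= 0)) {
    stop("SA is undefined for shoot P uptake <= 0", call. = FALSE)
  }
  (r_over_R / 100) / shoot_p
}

#' L-value: plant estimate of isotopically exchangeable soil P
#'
#' The L-value is shoot P uptake divided by the fraction of introduced
#' radioactivity recovered, i.e. the size of the unlabeled-P pool the plant
#' sampled with the tracer. It equals 1/SA and is never smaller than the
#' uptake itself while recovery stays at or below 100%.
#'
#' @param shoot_p Shoot P uptake, mg P per kg soil.
#' @param r_over_R Tracer recovery in percent of R (must be > 0).
#' @return L, mg P per kg soil.
#' @examples
#' l_value(4.6, 11.8)   # ~39, unfertilized control
#' l_value(19.7, 20.1)  # ~98, TSP
#' @export
l_value <- function(shoot_p, r_over_R) {
  if (any(!is.finite(r_over_R)) || any(r_over_R <= 0)) {
    stop("L-value is undefined for tracer recovery <= 0", call. = FALSE)
  }
  shoot_p / (r_over_R / 100)
}

#' Seed P allocated to shoots
#'
#' The unlabeled P remobilized from sown seeds is the depletion of the seed
#' reserve (sown minus residual seed P), of which the shoots receive the
#' share of shoot P in whole-plant (shoot + root + collet) P at that harvest.
#'
#' @param sown_seed_p P content of the sown seeds, mg P per kg soil.
#' @param residual_seed_p P left in recovered residual seeds, mg P per kg soil.
#' @param shoot_p,root_p,collet_p Whole-plant P split at harvest, mg P per kg
#'   soil. Their sum must be positive.
#' @return Seed-derived P allocated to shoots, mg P per kg soil.
#' @examples
#' seed_p_allocated(1.2, 0.3, shoot_p = 3.0, root_p = 1.2, collet_p = 0.3)  # 0.6
#' @export
seed_p_allocated <- function(sown_seed_p, residual_seed_p,
                             shoot_p, root_p = 0, collet_p = 0) {
  if (any(residual_seed_p > sown_seed_p)) {
    stop("residual seed P exceeds sown seed P", call. = FALSE)
  }
  total <- shoot_p + root_p + collet_p
  if (any(!is.finite(total)) || any(total <= 0)) {
    stop("whole-plant P (shoot + root + collet) must be > 0", call. = FALSE)
  }
  (sown_seed_p - residual_seed_p) * shoot_p / total
}

#' Isotopic composition of soil-derived P in the control (IC0)
#'
#' Tracer recovery per unit of soil-derived uptake in the unfertilized
#' control. Under the equal-SA assumption this composition applies to the
#' soil-derived P of every treatment and anchors the partitioning.
#'
#' @param r0 Control tracer recovery, percent of R.
#' @param Pt0 Control shoot P uptake, mg P per kg soil.
#' @param Pseed0 Control seed-derived shoot P, mg P per kg soil.
#' @return IC0, percent of R per mg P kg-1.
#' @examples
#' ic0(11.8, 4.6, 0.62)  # 2.965
#' @export
ic0 <- function(r0, Pt0, Pseed0 = 0) {
  if (any(Pt0 <= Pseed0)) {
    stop("degenerate control: Pt0 must exceed Pseed0", call. = FALSE)
  }
  r0 / (Pt0 - Pseed0)
}

#' Soil-derived P uptake of a fertilized treatment from tracer ratios
#'
#' Under the equal-SA assumption the soil-derived uptake of a fertilized
#' treatment is the control's soil-derived uptake scaled by the ratio of
#' tracer recoveries: `(Pt0 - Pseed0) * r_f / r0`.
#'
#' @param Pt0,Pseed0 Control shoot P uptake and seed allocation, mg P kg-1.
#' @param r_f Fertilized-treatment tracer recovery, percent of R.
#' @param r0 Control tracer recovery, percent of R (must be > 0).
#' @return Psoil of the fertilized treatment, mg P per kg soil.
#' @examples
#' psoil_from_tracer(4.6, 0.62, r_f = 20.1, r0 = 11.8)  # 6.78
#' @export
psoil_from_tracer <- function(Pt0, Pseed0, r_f, r0) {
  if (any(!is.finite(r0)) || any(r0 <= 0)) {
    stop("partition undefined: control tracer recovery r0 must be > 0",
         call. = FALSE)
  }
  (Pt0 - Pseed0) * r_f / r0
}

#' Fertilizer-derived P as the mass-balance residual
#'
#' `Pfert = Pt - Pseed - Psoil`. Negative values can arise from measurement
#' noise; they are returned as-is (never clipped, so treatment means stay
#' unbiased) and should be flagged downstream.
#'
#' @param Pt,Pseed,Psoil Components in mg P per kg soil.
#' @return Pfert, mg P per kg soil (possibly negative under noise).
#' @export
pfert_residual <- function(Pt, Pseed, Psoil) {
  Pt - Pseed - Psoil
}

#' Percentage of shoot P derived from fertilizer (Pdff)
#'
#' @param Pfert Fertilizer-derived shoot P, mg P per kg soil.
#' @param Pt Total shoot P uptake, mg P per kg soil (must be > 0).
#' @return Pdff in percent.
#' @examples
#' pdff(10.9, 19.7)  # 55.3
#' @export
pdff <- function(Pfert, Pt) {
  if (any(!is.finite(Pt)) || any(Pt <= 0)) {
    stop("Pdff undefined for total uptake <= 0", call. = FALSE)
  }
  100 * Pfert / Pt
}

#' Coefficient of fertilizer P utilization (CPU, fertilizer P recovery)
#'
#' @param Pfert Fertilizer-derived shoot P, mg P per kg soil.
#' @param applied_dose P application rate, mg P per kg soil (must be > 0).
#' @return CPU in percent of the applied dose.
#' @examples
#' cpu(10.9, 50)  # 21.8
#' @export
cpu <- function(Pfert, applied_dose) {
  if (any(!is.finite(applied_dose)) || any(applied_dose <= 0)) {
    stop("CPU undefined for applied dose <= 0", call. = FALSE)
  }
  100 * Pfert / applied_dose
}

#' Agronomic effectiveness of a test fertilizer against a reference
#'
#' AE compares a test fertilizer with a water-soluble reference (typically
#' TSP) either through the fertilizer-derived uptake (AE_CPU, ratio of Pfert
#' and hence of CPU at equal dose) or through the contribution to plant
#' nutrition (AE_Pdff, ratio of Pdff).
#'
#' @param test,reference Lists (or one-row data frames) carrying `Pfert` and
#'   `Pdff`, e.g. rows of a partition table; `reference` may also name its
#'   treatment in a `treatment` field.
#' @return A list of class `"ae_result"` with `AE_CPU`, `AE_Pdff` (percent)
#'   and `reference_treatment`.
#' @examples
#' agronomic_effectiveness(list(Pfert = 7.0, Pdff = 56),
#'                         list(Pfert = 10.9, Pdff = 55.3, treatment = "TSP"))
#' @export
agronomic_effectiveness <- function(test, reference) {
  pf_ref <- reference$Pfert
  pd_ref <- reference$Pdff
  if (is.null(pf_ref) || is.null(pd_ref) ||
      !is.finite(pf_ref) || !is.finite(pd_ref) ||
      pf_ref <= 0 || pd_ref <= 0) {
    stop("AE undefined: reference must have positive Pfert and Pdff",
         call. = FALSE)
  }
  structure(
    list(AE_CPU = 100 * test$Pfert / pf_ref,
         AE_Pdff = 100 * test$Pdff / pd_ref,
         reference_treatment = if (!is.null(reference$treatment))
           as.character(reference$treatment) else NA_character_),
    class = "ae_result")
}

#' @export
print.ae_result <- function(x, ...) {
  cat(sprintf("Agronomic effectiveness vs %s: AE_CPU = %.1f%%, AE_Pdff = %.1f%%\n",
              x$reference_treatment, x$AE_CPU, x$AE_Pdff))
  invisible(x)
}
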