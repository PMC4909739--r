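#' Define a fertilizer composition sheet
#'
#' Constituent concentrations are unit-tagged per element (`"g_per_kg"` or
#' `"mg_per_kg"` of dry matter) and converted explicitly in the budget
#' arithmetic; no silent unit inference.
#'
#' @param name Fertilizer identifier.
#' @param total_p_g_per_kg Total P content, g P per kg dry matter.
#' @param constituents Named list; each element a list
#'   `list(value =, unit = "g_per_kg" | "mg_per_kg")`.
#' @param dry_solid_pct Optional dry-solid content, percent.
#' @return List of class `"fertilizer_spec"`.
#' @examples
#' fertilizer_spec("TSP", 196.65)
#' @export
fertilizer_spec <- function(name, total_p_g_per_kg, constituents = list(),
                            dry_solid_pct = NA_real_) {
  if (!is.finite(total_p_g_per_kg) || total_p_g_per_kg <= 0) {
    stop("invalid spec: total P must be > 0", call. = FALSE)
  }
  for (nm in names(constituents)) {
    cc <- constituents[[nm]]
    if (!is.list(cc) || is.null(cc$value) || is.null(cc$unit) ||
        !cc$unit %in% c("g_per_kg", "mg_per_kg")) {
      stop("constituent '", nm,
           "' must be list(value=, unit='g_per_kg'|'mg_per_kg')",
           call. = FALSE)
    }
    if (cc$value < 0) {
      stop("invalid spec: negative concentration for '", nm, "'",
           call. = FALSE)
    }
  }
  structure(list(name = name, total_p_g_per_kg = total_p_g_per_kg,
                 constituents = constituents, dry_solid_pct = dry_solid_pct),
            class = "fertilizer_spec")
}

#' @export
print.fertilizer_spec <- function(x, ...) {
  cat("Fertilizer spec '", x$name, "': total P ", x$total_p_g_per_kg,
      " g P kg-1 DM, ", length(x$constituents), " constituents\n", sep = "")
  invisible(x)
}

#' Dry-matter dose needed for a target P application rate
#'
#' @param dose_mg_p_per_kg Target P rate, mg P per kg soil.
#' @param spec A [fertilizer_spec()].
#' @return g fertilizer dry matter per kg soil.
#' @examples
#' dm_for_dose(50, fertilizer_spec("TCSS", 23.30))  # 2.146 g DM kg-1
#' @export
dm_for_dose <- function(dose_mg_p_per_kg, spec) {
  stopifnot(inherits(spec, "fertilizer_spec"))
  if (any(dose_mg_p_per_kg < 0)) stop("dose must be >= 0", call. = FALSE)
  # mg P / (g P per kg DM) = g DM
  dose_mg_p_per_kg / spec$total_p_g_per_kg
}

#' Co-applied constituent rates at a target P dose
#'
#' Everything carried with the fertilizer at the dry-matter dose implied by
#' the P rate: `dm_for_dose(dose) * concentration`, unit-converted to grams
#' per kg soil.
#'
#' @inheritParams dm_for_dose
#' @return Data frame with `constituent`, `g_per_kg_soil`.
#' @export
coapplication_rates <- function(dose_mg_p_per_kg, spec) {
  dm_g <- dm_for_dose(dose_mg_p_per_kg, spec)  # g DM per kg soil
  rows <- lapply(names(spec$constituents), function(nm) {
    cc <- spec$constituents[[nm]]
    conc_g_per_kg <- switch(cc$unit,
                            g_per_kg = cc$value,
                            mg_per_kg = cc$value / 1000)
    data.frame(constituent = nm,
               g_per_kg_soil = dm_g * conc_g_per_kg / 1000)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(constituent = character(), g_per_kg_soil = numeric())
  rownames(out) <- NULL
  out
}

#' Convert a per-kg-soil rate to a per-hectare rate
#'
#' @param rate_g_per_kg_soil Amount in g per kg soil.
#' @param soil_t_per_ha Plough-layer soil mass, t per ha (3500 t for 25 cm
#'   depth at bulk density 1.4).
#' @return kg per ha.
#' @examples
#' per_hectare(0.459, 3500)  # ~1607 kg ha-1
#' @export
per_hectare <- function(rate_g_per_kg_soil, soil_t_per_ha = 3500) {
  if (any(!is.finite(soil_t_per_ha)) || any(soil_t_per_ha <= 0)) {
    stop("soil mass per ha must be > 0", call. = FALSE)
  }
  # g/kg soil * (t/ha * 1000 kg/t) / 1000 g/kg = kg/ha
  rate_g_per_kg_soil * soil_t_per_ha
}

#' Check a fertilizer against heavy-metal concentration limits
#'
#' A static compliance check of total metal concentrations in the product
#' (mg per kg dry matter) against regulatory limit values; metals in the
#' spec without a limit are skipped with a warning.
#'
#' @param spec A [fertilizer_spec()] whose metal constituents are tagged
#'   `mg_per_kg`.
#' @param limits Named numeric vector of limit values, mg per kg DM.
#'   Defaults to [french_sludge_limits()].
#' @return List of class `"compliance_report"`: data frame `metals`
#'   (concentration, limit, pass) and logical `overall`.
#' @export
heavy_metal_compliance <- function(spec, limits = french_sludge_limits()) {
  stopifnot(inherits(spec, "fertilizer_spec"))
  present <- intersect(names(spec$constituents), names(limits))
  skipped <- setdiff(names(limits), names(spec$constituents))
  unchecked <- setdiff(
    names(spec$constituents)[vapply(spec$constituents,
                                    function(cc) cc$unit == "mg_per_kg", TRUE)],
    names(limits))
  unchecked <- intersect(unchecked, metal_names())
  if (length(unchecked)) {
    warning("no limit value for metal(s): ", paste(unchecked, collapse = ", "),
            "; skipped", call. = FALSE)
  }
  metals <- do.call(rbind, lapply(present, function(m) {
    cc <- spec$constituents[[m]]
    conc <- if (cc$unit == "g_per_kg") cc$value * 1000 else cc$value
    data.frame(metal = m, conc_mg_per_kg = conc, limit_mg_per_kg = limits[[m]],
               pass = conc <= limits[[m]])
  }))
  if (is.null(metals)) {
    metals <- data.frame(metal = character(), conc_mg_per_kg = numeric(),
                         limit_mg_per_kg = numeric(), pass = logical())
  }
  rownames(metals) <- NULL
  structure(list(metals = metals, overall = all(metals$pass),
                 skipped_limits = skipped),
            class = "compliance_report")
}

metal_names <- function() c("Cu", "Zn", "Cr", "Ni", "Pb", "Cd", "Hg")

#' @export
print.compliance_report <- function(x, ...) {
  print(x$metals)
  cat("Overall:", if (x$overall) "PASS" else "FAIL", "\n")
  invisible(x)
}

#' French regulatory limits for heavy metals in agricultural sewage sludge
#'
#' Limit concentrations (mg per kg dry matter) permitted for sludge applied
#' to agricultural land in France.
#'
#' @return Named numeric vector.
#' @export
french_sludge_limits <- function() {
  c(Cu = 1000, Zn = 3000, Cr = 1000, Ni = 200, Pb = 800, Cd = 20, Hg = 10)
}

#' Published composition of the studied thermally conditioned sewage sludge
#'
#' The composition sheet of the TCSS studied in the source pot experiment:
#' total P 23.30 g P per kg DM (the text value, which reproduces the
#' published equivalent-rate column exactly; the table rounds to 23.0),
#' with major constituents in g per kg DM and trace metals in mg per kg DM.
#'
#' @return A [fertilizer_spec()].
#' @export
tcss_fertilizer_spec <- function() {
  fertilizer_spec(
    name = "TCSS",
    total_p_g_per_kg = 23.30,
    dry_solid_pct = 57,
    constituents = list(
      organic_C = list(value = 214,  unit = "g_per_kg"),
      total_N   = list(value = 13,   unit = "g_per_kg"),
      N_NO3     = list(value = 0.03, unit = "mg_per_kg"),
      N_NH4     = list(value = 1.9,  unit = "g_per_kg"),
      Olsen_P   = list(value = 0.24, unit = "g_per_kg"),
      organic_P = list(value = 0.8,  unit = "g_per_kg"),
      total_K   = list(value = 1.4,  unit = "g_per_kg"),
      Al        = list(value = 29.6, unit = "g_per_kg"),
      Fe        = list(value = 11.5, unit = "g_per_kg"),
      CaCO3     = list(value = 217,  unit = "g_per_kg"),
      Mn        = list(value = 297,  unit = "mg_per_kg"),
      Cu        = list(value = 731,  unit = "mg_per_kg"),
      Zn        = list(value = 2408, unit = "mg_per_kg"),
      Cr        = list(value = 134,  unit = "mg_per_kg"),
      Ni        = list(value = 57,   unit = "mg_per_kg"),
      Pb        = list(value = 463,  unit = "mg_per_kg"),
      Cd        = list(value = 15,   unit = "mg_per_kg"),
      Hg        = list(value = 7,    unit = "mg_per_kg")))
}

#' Triple super phosphate composition used as the reference fertilizer
#' @return A [fertilizer_spec()] with total P 196.65 g P per kg.
#' @export
tsp_fertilizer_spec <- function() {
  fertilizer_spec(name = "TSP", total_p_g_per_kg = 196.65)
}
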