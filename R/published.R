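#' Published cumulative treatment means of the TCSS pot experiment
#'
#' Cumulative (three-cut) treatment means reported for the greenhouse
#' experiment that motivated this package: shoot/root dry matter, shoot P
#' uptake, seed P allocated to shoots, tracer recovery, and the published
#' Psoil/Pfert/Pdff/CPU values, for the unfertilized control, the TSP
#' reference and the TCSS treatment (both applied at 50 mg P per kg soil).
#' These means are the desk-scale inputs for the ratio chain (SA, L, Pdff,
#' CPU, AE); the published Psoil and Pfert columns come from per-replicate,
#' per-cut cumulation whose raw inputs are not published, so they are inputs
#' here, not recomputable outputs.
#'
#' @return Data frame with one row per treatment.
#' @export
tcss_published_summary <- function() {
  data.frame(
    treatment   = c("control", "TSP", "TCSS"),
    dose        = c(0, 50, 50),          # mg P per kg soil
    shoot_dm    = c(2.9, 5.3, 3.8),      # g per kg soil
    root_dm     = c(1.8, 2.8, 2.1),
    Pt          = c(4.6, 19.7, 12.5),    # mg P per kg soil
    Pseed       = c(0.62, 0.89, 0.67),
    r_over_R    = c(11.8, 20.1, 14.0),   # percent of introduced R
    Psoil_published = c(4.7, 8.8, 5.5),
    Pfert_published = c(NA, 10.9, 7.0),
    stringsAsFactors = FALSE)
}
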