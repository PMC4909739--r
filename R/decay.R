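#' Correct a radioactivity measurement for decay
#'
#' Converts an activity measured (or known) at one time to the equivalent
#' activity at a reference time `elapsed` days earlier. With `elapsed > 0`
#' a decayed count is corrected *back up* to the reference (e.g. the soil
#' labeling date); with `elapsed < 0` the correction runs forward, so the
#' operation is its own inverse under sign flip.
#'
#' 32P decays with a half-life of about 14.28 days (roughly 5% per day), so
#' counts taken at harvests spread over weeks are not comparable until they
#' are referred to a common date.
#'
#' @param activity Measured activity (Bq, or any proportional unit).
#' @param elapsed Days between the reference time and the measurement time
#'   (measurement minus reference). May be negative.
#' @param half_life Isotope half-life in days. Default [P32_HALF_LIFE_DAYS].
#' @return Activity at the reference time, same units as `activity`.
#' @examples
#' decay_correct(100, 14.276)            # one half-life back: 200 Bq
#' decay_correct(decay_correct(50, 7), -7)  # round trip: 50 Bq
#' @export
decay_correct <- function(activity, elapsed, half_life = P32_HALF_LIFE_DAYS) {
  if (any(!is.finite(half_life)) || any(half_life <= 0)) {
    stop("'half_life' must be a positive number of days", call. = FALSE)
  }
  activity * 2^(elapsed / half_life)
}

#' Half-life of 32P in days
#'
#' Package-wide default used when decay-correcting shoot counts to the
#' labeling date.
#' @export
P32_HALF_LIFE_DAYS <- 14.276
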