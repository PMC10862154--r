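# Closed-form kinetics of a basic multicellular unit (BMU): longitudinal
# cutting-cone advance by osteoclasts and radial infilling by osteoblasts at
# constant apposition rate. Because real canals show substantial resting
# periods during which neither resorption nor deposition occurs, these
# constant-rate durations are lower-bound estimates.

#' Default BMU kinetic parameters
#'
#' Osteoclasts advance longitudinally at about 40 um/day; osteoblastic radial
#' apposition proceeds at 1.0-1.5 um/day; infilling runs from the cement line
#' (about 100 um radius) to the finished Haversian canal (about 10 um
#' radius).
#'
#' @return List with `advance_rate_um_per_d`, `appo_rate_um_per_d` (range),
#'   `r_cement_um`, `r_final_um`.
#' @export
bmu_kinetics <- function() {
  list(
    advance_rate_um_per_d = 40,
    appo_rate_um_per_d = c(1.0, 1.5),
    r_cement_um = 100,
    r_final_um = 10
  )
}

#' Duration of radial infilling at constant apposition rate
#'
#' `(r_start - r_end) / rate` days. With the default radii (100 -> 10 um)
#' and apposition rates of 1.0-1.5 um/day this spans 60-90 days.
#'
#' @param r_start_um Starting (cement-line) radius, um.
#' @param r_end_um Final (canal) radius, um; must not exceed `r_start_um`.
#' @param appo_rate_um_per_d Radial apposition rate, um/day (> 0).
#' @return Days to infill.
#' @export
infill_duration <- function(r_start_um = 100, r_end_um = 10,
                            appo_rate_um_per_d = 1.0) {
  if (any(appo_rate_um_per_d <= 0)) stop("apposition rate must be > 0")
  if (any(r_start_um < r_end_um)) stop("r_start_um must be >= r_end_um")
  (r_start_um - r_end_um) / appo_rate_um_per_d
}

#' Longitudinal cutting-cone advance
#'
#' `days * rate` micrometres of osteoclastic tunnelling.
#'
#' @param days Elapsed time, days (>= 0).
#' @param advance_rate_um_per_d Longitudinal advance rate, um/day.
#' @return Advance, um.
#' @export
cutting_advance <- function(days, advance_rate_um_per_d = 40) {
  if (any(days < 0)) stop("days must be >= 0")
  if (any(advance_rate_um_per_d <= 0)) stop("advance rate must be > 0")
  days * advance_rate_um_per_d
}
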