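#' Transport directions
#'
#' Bidirectional Transwell assays dose either the apical (AP) or the
#' basolateral (BL) compartment. `"AP_to_BL"` models intestinal absorption
#' (apical donor), `"BL_to_AP"` models secretion/efflux (basolateral donor).
#'
#' @format Character vector of the two recognised direction codes.
#' @export
DIRECTIONS <- c("AP_to_BL", "BL_to_AP")

#' Normalise a transport direction code
#'
#' Accepts the canonical codes plus the common arrow and hyphen spellings
#' ("AP-BL", "AP>BL", "a-b", ...) and returns `"AP_to_BL"` or `"BL_to_AP"`.
#'
#' @param x character vector of direction labels.
#' @return character vector with elements from [DIRECTIONS].
#' @export
match_direction <- function(x) {
  key <- gsub("[^ab]", "", tolower(gsub("ap", "a", gsub("bl", "b", tolower(x)))))
  out <- ifelse(key == "ab", "AP_to_BL", ifelse(key == "ba", "BL_to_AP", NA))
  if (anyNA(out))
    validation_error(paste0("unrecognised direction label(s): ",
                            paste(unique(x[is.na(out)]), collapse = ", ")))
  out
}

#' Parameters of the two-compartment monolayer transport simulator
#'
#' The simulator models a Transwell insert as two well-stirred compartments
#' separated by a cell monolayer. Net solute flux from donor to receiver is
#'
#' \deqn{J = A\,[\,p\,(C_d - C_r) - s\,(1-i)\,V_{max} C_d/(K_m + C_d)\,]}
#'
#' where \eqn{p} is the passive permeability, the Michaelis-Menten term is a
#' saturable apically-directed efflux (P-gp/MRP2-like) driven by the donor
#' concentration, and \eqn{s = +1} for AP-to-BL transport (efflux opposes
#' absorption) or \eqn{s = -1} for BL-to-AP (efflux adds to secretion).
#' `inhibition` scales the efflux capacity by \eqn{(1-i)}, emulating
#' co-incubation with an efflux inhibitor such as verapamil or cyclosporin.
#'
#' @param p_passive passive permeability coefficient, cm/s (>= 0).
#' @param vmax maximal efflux flux density, ug/cm^2/s (>= 0; 0 disables
#'   carrier-mediated efflux).
#' @param km efflux half-saturation concentration, ug/mL (> 0).
#' @param inhibition fraction in \[0, 1\] by which efflux capacity is reduced.
#' @param area membrane area, cm^2. Default 1.12 (12-well Transwell insert).
#' @param vol_ap apical compartment volume, mL. Default 0.5.
#' @param vol_bl basolateral compartment volume, mL. Default 1.5.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   measurement noise applied to sampled concentrations (>= 0; 0 = noiseless).
#' @param seed integer seed for the measurement-noise stream.
#' @return An object of class `transport_sim_params` (a validated list).
#' @seealso [sampling_schedule()], [simulate_well()], [simulate_condition()]
#' @examples
#' transport_sim_params(p_passive = 5e-6, vmax = 3e-4, km = 25)
#' @export
transport_sim_params <- function(p_passive, vmax = 0, km = 25, inhibition = 0,
                                 area = 1.12, vol_ap = 0.5, vol_bl = 1.5,
                                 noise_cv = 0, seed = 1L) {
  check_scalar(p_passive, "p_passive", lower = 0)
  check_scalar(vmax, "vmax", lower = 0)
  check_scalar(km, "km", lower = 0, allow_equal_lower = FALSE)
  check_scalar(inhibition, "inhibition", lower = 0, upper = 1)
  check_scalar(area, "area", lower = 0, allow_equal_lower = FALSE)
  check_scalar(vol_ap, "vol_ap", lower = 0, allow_equal_lower = FALSE)
  check_scalar(vol_bl, "vol_bl", lower = 0, allow_equal_lower = FALSE)
  check_scalar(noise_cv, "noise_cv", lower = 0)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    validation_error("'seed' must be a single integer")
  structure(
    list(p_passive = p_passive, vmax = vmax, km = km, inhibition = inhibition,
         area = area, vol_ap = vol_ap, vol_bl = vol_bl, noise_cv = noise_cv,
         seed = as.integer(seed)),
    class = "transport_sim_params")
}

#' @export
print.transport_sim_params <- function(x, ...) {
  cat("Two-compartment monolayer simulator parameters\n")
  cat(sprintf("  passive permeability : %.3g cm/s\n", x$p_passive))
  cat(sprintf("  efflux Vmax          : %.3g ug/cm^2/s (inhibition %.0f%%)\n",
              x$vmax, 100 * x$inhibition))
  cat(sprintf("  efflux Km            : %.3g ug/mL\n", x$km))
  cat(sprintf("  area %.3g cm^2; volumes AP %.3g mL / BL %.3g mL\n",
              x$area, x$vol_ap, x$vol_bl))
  cat(sprintf("  measurement noise CV : %.3g (seed %d)\n", x$noise_cv, x$seed))
  invisible(x)
}

#' Receiver sampling schedule with blank-buffer replacement
#'
#' At each scheduled time a fixed aliquot `vs` is withdrawn from the receiver
#' compartment for quantitation and replaced with blank transport buffer, so
#' the receiver volume stays constant while its concentration is diluted.
#' This is the sampling protocol the dilution correction in
#' [cumulative_amounts()] undoes.
#'
#' @param times strictly increasing sampling times, minutes (> 0).
#'   Default `c(30, 60, 90, 120, 150, 180)`.
#' @param vs sample volume withdrawn and replaced at each time, mL.
#'   Default 0.2. Must be smaller than the receiver volume it is drawn from.
#' @return An object of class `sampling_schedule`.
#' @export
sampling_schedule <- function(times = c(30, 60, 90, 120, 150, 180), vs = 0.2) {
  if (!is.numeric(times) || length(times) < 1L || anyNA(times))
    validation_error("'times' must be a non-empty numeric vector")
  if (any(times <= 0) || any(diff(times) <= 0))
    validation_error("'times' must be strictly increasing and positive")
  check_scalar(vs, "vs", lower = 0, allow_equal_lower = FALSE)
  structure(list(times = as.numeric(times), vs = vs),
            class = "sampling_schedule")
}
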