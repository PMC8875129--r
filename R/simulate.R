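# Two-compartment Transwell transport simulator.
#
# State is (donor mass, receiver mass) in ug; the monolayer flux is
# integrated with an adaptive stiff-capable solver between sampling events,
# and each sampling is an instantaneous state jump: withdraw vs mL of
# receiver fluid, then restore the volume with blank buffer. Measurement
# noise perturbs only the recorded concentrations, never the trajectory.

.flux_sign <- function(direction) if (direction == "AP_to_BL") 1 else -1

.donor_receiver_volumes <- function(params, direction) {
  if (direction == "AP_to_BL")
    list(vd = params$vol_ap, vr = params$vol_bl)
  else
    list(vd = params$vol_bl, vr = params$vol_ap)
}

# Noiseless trajectory over the sampling schedule; the mechanistic core.
# Returns one row per sampling time with the pre-withdrawal receiver
# concentration, the exact cumulative transported mass, and the mass
# bookkeeping needed to audit conservation.
.simulate_trajectory <- function(params, schedule, direction, c0) {
  vols <- .donor_receiver_volumes(params, direction)
  if (schedule$vs >= vols$vr)
    validation_error(sprintf(
      "sample volume vs = %g mL must be smaller than the receiver volume %g mL",
      schedule$vs, vols$vr))
  s <- .flux_sign(direction)
  eff_scale <- (1 - params$inhibition) * params$vmax

  derivs <- function(t, y, p) {
    cd <- y[1] / vols$vd
    cr <- y[2] / vols$vr
    j <- params$area *
      (params$p_passive * (cd - cr) - s * eff_scale * cd / (params$km + cd))
    list(c(-j, j))
  }

  m0 <- c0 * vols$vd
  state <- c(donor = m0, receiver = 0)
  times_s <- schedule$times * 60
  n <- length(times_s)
  conc_true <- donor_mass <- receiver_mass <- numeric(n)
  withdrawn <- 0
  withdrawn_cum <- cum_mass <- numeric(n)
  t_prev <- 0
  for (k in seq_len(n)) {
    sol <- deSolve::lsoda(state, c(t_prev, times_s[k]), derivs, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
    state <- sol[nrow(sol), c("donor", "receiver")]
    if (any(!is.finite(state)))
      stop("flux integration produced a non-finite state; check parameters")
    cr <- state[["receiver"]] / vols$vr
    conc_true[k] <- cr
    # cumulative transported mass: what is in the receiver now plus all
    # mass already carried away in earlier samples
    cum_mass[k] <- state[["receiver"]] + withdrawn
    # sampling event: withdraw, then replace with blank buffer
    taken <- cr * schedule$vs
    state[["receiver"]] <- state[["receiver"]] - taken
    withdrawn <- withdrawn + taken
    donor_mass[k] <- state[["donor"]]
    receiver_mass[k] <- state[["receiver"]]
    withdrawn_cum[k] <- withdrawn
    t_prev <- times_s[k]
  }
  data.frame(
    time_min = schedule$times,
    conc_true = conc_true,
    cum_mass_true = cum_mass,
    donor_mass = donor_mass,
    receiver_mass = receiver_mass,
    withdrawn_cum = withdrawn_cum,
    initial_mass = m0
  )
}

# Multiplicative lognormal measurement noise with unit mean:
# sdlog^2 = log(1 + cv^2), meanlog = -sdlog^2/2.
.measurement_noise_factors <- function(n, noise_cv) {
  if (noise_cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + noise_cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

.well_from_trajectory <- function(truth, params, schedule, direction, c0,
                                  seed, well_id, compound) {
  vols <- .donor_receiver_volumes(params, direction)
  if (params$noise_cv > 0) {
    set.seed(seed)
    fac <- .measurement_noise_factors(nrow(truth), params$noise_cv)
  } else {
    fac <- rep(1, nrow(truth))
  }
  structure(
    list(well_id = well_id, compound = compound, direction = direction,
         c0 = c0, vr = vols$vr, vs = schedule$vs, area = params$area,
         times = truth$time_min, concs = truth$conc_true * fac,
         truth = truth, seed = as.integer(seed)),
    class = "well_series")
}

#' Simulate one Transwell well
#'
#' Integrates the two-compartment transport model (see
#' [transport_sim_params()] for the flux law) across the sampling schedule,
#' applying the sample-and-replace dilution at every scheduled time, and
#' perturbs the recorded receiver concentrations with multiplicative
#' lognormal noise of coefficient of variation `noise_cv`.
#'
#' @param params a [transport_sim_params()] object.
#' @param schedule a [sampling_schedule()] object.
#' @param direction `"AP_to_BL"` or `"BL_to_AP"` (see [match_direction()]).
#' @param c0 initial donor concentration, ug/mL (> 0).
#' @param seed seed for the measurement-noise stream; defaults to
#'   `params$seed`.
#' @param well_id,compound labels carried into the output.
#' @return A `well_series` object: the measured receiver concentration time
#'   series plus a `truth` data frame with the noiseless trajectory
#'   (pre-withdrawal concentration, exact cumulative transported mass, and
#'   donor/receiver/withdrawn mass bookkeeping).
#' @examples
#' p <- transport_sim_params(p_passive = 5e-6)
#' w <- simulate_well(p, sampling_schedule(), "AP_to_BL", c0 = 100)
#' w$concs
#' @export
simulate_well <- function(params, schedule, direction, c0,
                          seed = params$seed, well_id = "W1",
                          compound = "drug") {
  stopifnot(inherits(params, "transport_sim_params"),
            inherits(schedule, "sampling_schedule"))
  direction <- match_direction(direction)
  check_scalar(c0, "c0", lower = 0, allow_equal_lower = FALSE)
  truth <- .simulate_trajectory(params, schedule, direction, c0)
  .well_from_trajectory(truth, params, schedule, direction, c0,
                        seed, well_id, compound)
}

#' @export
print.well_series <- function(x, ...) {
  cat(sprintf("Well %s (%s, %s, C0 = %g ug/mL): %d samples, %g-%g min\n",
              x$well_id, x$compound, x$direction, x$c0,
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Convert simulated wells to the tidy long-format table
#'
#' One row per well per sampling time, in the column layout expected by
#' [read_wells()] / [analyze_wells()].
#'
#' @param wells a list of `well_series` objects.
#' @param condition condition label recycled across wells.
#' @return data.frame with columns `well_id, condition, compound, direction,
#'   c0_ug_per_ml, vr_ml, vs_ml, area_cm2, time_min, conc_ug_per_ml`.
#' @export
wells_to_table <- function(wells, condition = "cond") {
  do.call(rbind, lapply(wells, function(w) {
    data.frame(well_id = w$well_id, condition = condition,
               compound = w$compound, direction = w$direction,
               c0_ug_per_ml = w$c0, vr_ml = w$vr, vs_ml = w$vs,
               area_cm2 = w$area, time_min = w$times,
               conc_ug_per_ml = w$concs)
  }))
}

#' Simulate a full bidirectional condition
#'
#' Runs `n_wells` replicate wells per direction at each donor concentration
#' in `c0_list`, with independent measurement noise per well. Per-well noise
#' seeds are derived deterministically from the master seed so a dataset is
#' bit-reproducible. The noiseless trajectory for a given (direction, c0) is
#' computed once and shared across its replicates, which are identical up to
#' their noise streams.
#'
#' @param params a [transport_sim_params()] object.
#' @param schedule a [sampling_schedule()] object.
#' @param c0_list donor concentrations to simulate, ug/mL.
#' @param n_wells replicate wells per direction per concentration (>= 1).
#' @param seed master seed; defaults to `params$seed`.
#' @param directions which directions to run; default both.
#' @param condition condition label; default derived from the compound.
#' @param compound compound label.
#' @return An object of class `simulated_dataset`: list with `wells` (tidy
#'   measurement table as in [wells_to_table()]), `truth` (per well_id and
#'   time: noiseless concentration and exact cumulative transported mass),
#'   `params`, `schedule`, `seed`.
#' @examples
#' p <- transport_sim_params(p_passive = 5e-6, noise_cv = 0.05)
#' d <- simulate_condition(p, sampling_schedule(), c0_list = 100, n_wells = 3,
#'                         seed = 42)
#' head(d$wells)
#' @export
simulate_condition <- function(params, schedule, c0_list, n_wells,
                               seed = params$seed, directions = DIRECTIONS,
                               condition = NULL, compound = "drug") {
  stopifnot(inherits(params, "transport_sim_params"),
            inherits(schedule, "sampling_schedule"))
  if (!is.numeric(n_wells) || n_wells < 1)
    validation_error("'n_wells' must be >= 1")
  directions <- match_direction(directions)
  if (is.null(condition)) condition <- compound
  grid <- expand.grid(rep = seq_len(n_wells), direction = directions,
                      c0 = c0_list, stringsAsFactors = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  well_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))

  traj_cache <- list()
  wells <- vector("list", nrow(grid))
  truth_rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    dir_i <- grid$direction[i]; c0_i <- grid$c0[i]
    key <- paste(dir_i, c0_i, sep = "@")
    if (is.null(traj_cache[[key]]))
      traj_cache[[key]] <- .simulate_trajectory(params, schedule, dir_i, c0_i)
    wid <- sprintf("W%03d_%s_c%g_r%d", i,
                   if (dir_i == "AP_to_BL") "AB" else "BA", c0_i, grid$rep[i])
    w <- .well_from_trajectory(traj_cache[[key]], params, schedule, dir_i,
                               c0_i, well_seeds[i], wid, compound)
    wells[[i]] <- w
    truth_rows[[i]] <- data.frame(
      well_id = wid, direction = dir_i, c0_ug_per_ml = c0_i,
      time_min = w$truth$time_min, conc_true = w$truth$conc_true,
      cum_mass_true = w$truth$cum_mass_true,
      donor_mass = w$truth$donor_mass,
      receiver_mass = w$truth$receiver_mass,
      withdrawn_cum = w$truth$withdrawn_cum,
      initial_mass = w$truth$initial_mass)
  }
  structure(
    list(wells = wells_to_table(wells, condition = condition),
         truth = do.call(rbind, truth_rows),
         params = params, schedule = schedule, seed = as.integer(seed)),
    class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("Simulated bidirectional dataset: %d wells x %d times (seed %d)\n",
              length(unique(x$wells$well_id)),
              length(unique(x$wells$time_min)), x$seed))
  invisible(x)
}

#' Generate calibration standards from a known straight line
#'
#' Emits (nominal concentration, signal) pairs with
#' `signal = slope * conc + intercept`, optionally perturbed by
#' multiplicative lognormal noise — the synthetic counterpart of running a
#' standard series on the instrument. When `segments` is supplied (a data
#' frame with columns `lo, hi, slope, intercept`), each concentration uses
#' the line of the segment whose range contains it, emulating a segmented
#' standard curve.
#'
#' @param nominal_concs positive nominal concentrations, ug/mL. The default
#'   is the 14-level standard series 0.025-100 ug/mL used for the assay.
#' @param slope,intercept single straight-line truth (ignored when
#'   `segments` given).
#' @param segments optional data.frame `lo, hi, slope, intercept`.
#' @param noise_cv multiplicative noise CV on the signal (0 = exact).
#' @param seed RNG seed used when `noise_cv > 0`.
#' @param analyte label column value.
#' @return data.frame `analyte, nominal_conc, signal`.
#' @examples
#' generate_standards(slope = 1.8823, intercept = 0.07998,
#'                    nominal_concs = c(0.025, 0.1, 1))
#' @export
generate_standards <- function(nominal_concs = c(0.025, 0.05, 0.1, 0.25, 0.5,
                                                 1, 2.5, 5, 7.5, 10, 15, 30,
                                                 50, 100),
                               slope = 1, intercept = 0, segments = NULL,
                               noise_cv = 0, seed = 1L, analyte = "analyte") {
  if (any(nominal_concs < 0))
    validation_error("'nominal_concs' must be non-negative")
  if (is.null(segments)) {
    signal <- slope * nominal_concs + intercept
  } else {
    stopifnot(all(c("lo", "hi", "slope", "intercept") %in% names(segments)))
    seg_idx <- vapply(nominal_concs, function(cc) {
      hit <- which(cc >= segments$lo & cc <= segments$hi)
      if (!length(hit))
        validation_error(sprintf("concentration %g outside every segment", cc))
      hit[1]
    }, integer(1))
    signal <- segments$slope[seg_idx] * nominal_concs +
      segments$intercept[seg_idx]
  }
  if (noise_cv > 0) {
    set.seed(seed)
    signal <- signal * .measurement_noise_factors(length(signal), noise_cv)
  }
  data.frame(analyte = analyte, nominal_conc = nominal_concs, signal = signal)
}
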