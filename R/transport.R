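# Core assay math: TEER, dilution-corrected cumulative transport, transport
# rate, apparent permeability, efflux ratio and mechanism classification.

#' Transepithelial electrical resistance
#'
#' `TEER = (R1 - R0) * A`, in ohm.cm^2. R0 is the blank reference: an
#' insert without cells before the experiment, or the pre-dose cell reading
#' during one. Negative values are returned (a monolayer-failure signal for
#' the caller to flag), not censored.
#'
#' @param r1 measured resistance, ohm.
#' @param r0 blank/reference resistance, ohm.
#' @param area membrane area, cm^2 (default 1.12).
#' @return TEER in ohm.cm^2 (vectorised).
#' @examples
#' teer(500, 120, 1.12)
#' @export
teer <- function(r1, r0, area = 1.12) {
  if (any(!is.finite(r1)) || any(!is.finite(r0)) || any(!is.finite(area)))
    validation_error("TEER inputs must be finite")
  if (any(area <= 0)) validation_error("'area' must be positive")
  (r1 - r0) * area
}

#' Assess monolayer integrity from resistance records
#'
#' Computes TEER per record and flags wells under an advisory integrity
#' threshold. The threshold is a lab convention, not a hard rule; flagged
#' wells are reported, never dropped.
#'
#' @param resistance data.frame with columns `r1_ohm`, `r0_ohm`,
#'   `area_cm2`, and optionally `well_id`, `context`.
#' @param threshold advisory minimum TEER, ohm.cm^2 (default 300).
#' @return the input with columns `teer_ohm_cm2` and `integrity_ok` added.
#' @export
assess_teer <- function(resistance, threshold = 300) {
  req <- c("r1_ohm", "r0_ohm", "area_cm2")
  miss <- setdiff(req, names(resistance))
  if (length(miss))
    schema_error(paste0("resistance table missing column(s): ",
                        paste(miss, collapse = ", ")))
  resistance$teer_ohm_cm2 <- teer(resistance$r1_ohm, resistance$r0_ohm,
                                  resistance$area_cm2)
  resistance$integrity_ok <- resistance$teer_ohm_cm2 >= threshold
  resistance
}

#' Dilution-corrected cumulative transport amounts
#'
#' Each receiver sample removes `vs` mL of fluid that is replaced with
#' blank buffer, so later concentrations are diluted. The corrected
#' cumulative transported mass at sample n is
#' \deqn{\Delta Q_n = C_n V_R + V_S \sum_{i=0}^{n-1} C_i}
#' with \eqn{C_0 = 0}: the mass currently in the receiver plus the mass
#' carried away by all earlier samples.
#'
#' A missing concentration poisons its own and all later values (`NA`),
#' because the prefix sum cannot be corrected past a gap.
#'
#' @param concs measured receiver concentrations at the sampling times,
#'   ug/mL.
#' @param vr receiver volume, mL.
#' @param vs sample volume, mL (default 0.2); must satisfy `vs < vr`.
#' @return numeric vector of cumulative amounts, ug, one per sample.
#' @examples
#' cumulative_amounts(c(1, 2), vr = 1.5, vs = 0.2)  # 1.5, 3.2
#' @export
cumulative_amounts <- function(concs, vr, vs = 0.2) {
  check_scalar(vr, "vr", lower = 0, allow_equal_lower = FALSE)
  check_scalar(vs, "vs", lower = 0)
  if (vs >= vr) validation_error("'vs' must be smaller than 'vr'")
  if (length(concs) < 1L) validation_error("'concs' must be non-empty")
  if (any(concs[!is.na(concs)] < 0))
    validation_error("concentrations must be non-negative")
  prior <- cumsum(c(0, concs[-length(concs)]))  # sum of C_0 .. C_{n-1}
  dq <- concs * vr + vs * prior
  if (anyNA(concs)) {
    first_na <- which(is.na(concs))[1]
    dq[seq(first_na, length(dq))] <- NA_real_
  }
  dq
}

#' Transport rate by linear regression
#'
#' Ordinary least-squares slope of cumulative amount versus time, with free
#' intercept (absorbs any initial lag). Times are supplied in minutes and
#' the rate is returned per second, the unit in which Papp is conventionally
#' quoted. An optional fit window restricts the regression, e.g. to the
#' early sink phase when transport slows at late times.
#'
#' @param dq cumulative transported amounts, ug (from
#'   [cumulative_amounts()]).
#' @param times sampling times, minutes.
#' @param window optional `c(lo, hi)` in minutes; only samples with
#'   `lo <= t <= hi` enter the fit. Default: all samples.
#' @return list with `rate` (ug/s), `intercept` (ug), `r2`, `n`, and
#'   `fit_window` (minutes actually used).
#' @examples
#' transport_rate(c(1, 2, 3), times = c(60, 120, 180))$rate  # 1 ug / 60 s
#' @export
transport_rate <- function(dq, times, window = NULL) {
  if (length(dq) != length(times))
    validation_error("'dq' and 'times' must have equal length")
  keep <- !is.na(dq) & !is.na(times)
  if (!is.null(window)) {
    if (length(window) != 2L || window[1] >= window[2])
      validation_error("'window' must be c(lo, hi) with lo < hi")
    keep <- keep & times >= window[1] & times <= window[2]
  }
  t_s <- times[keep] * 60
  q <- dq[keep]
  if (length(q) < 2L)
    validation_error("at least 2 points are required to fit a transport rate")
  if (stats::var(t_s) == 0)
    validation_error("zero time variance in the fit window")
  fm <- stats::lm(q ~ t_s)
  ss_tot <- sum((q - mean(q))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::resid(fm)^2) / ss_tot
  list(rate = unname(stats::coef(fm)[2]),
       intercept = unname(stats::coef(fm)[1]),
       r2 = r2, n = length(q),
       fit_window = range(times[keep]))
}

#' Apparent permeability coefficient
#'
#' \deqn{P_{app} = \frac{\Delta Q / \Delta t}{A \, C_0}} in cm/s: the
#' transport rate normalised by membrane area and initial donor
#' concentration. Reported in summaries as multiples of 1e-6 cm/s.
#'
#' @param rate transport rate, ug/s.
#' @param area membrane area, cm^2.
#' @param c0 initial donor concentration, ug/mL.
#' @return Papp in cm/s (vectorised over `rate`).
#' @examples
#' papp(0.001, area = 1.12, c0 = 100)  # 8.93e-06 cm/s
#' @export
papp <- function(rate, area, c0) {
  check_scalar(area, "area", lower = 0, allow_equal_lower = FALSE)
  check_scalar(c0, "c0", lower = 0, allow_equal_lower = FALSE)
  rate / (area * c0)
}

#' Efflux ratio
#'
#' `ER = Papp(BL->AP) / Papp(AP->BL)`. The primary group statistic is the
#' ratio of direction means; when per-well pairing exists, the mean and SD
#' of per-well ratios are reported alongside by [summarize_groups()].
#'
#' @param papp_ba Papp in the BL-to-AP (secretory) direction, cm/s.
#' @param papp_ab Papp in the AP-to-BL (absorptive) direction, cm/s (> 0).
#' @return the ratio; `NA` if either argument is `NA` (e.g. a missing
#'   secretory arm).
#' @examples
#' efflux_ratio(1.766e-6, 1.225e-6)
#' @export
efflux_ratio <- function(papp_ba, papp_ab) {
  if (length(papp_ba) != length(papp_ab))
    validation_error("'papp_ba' and 'papp_ab' must have equal length")
  bad <- !is.na(papp_ab) & papp_ab <= 0
  if (any(bad))
    validation_error("Papp(AP->BL) must be positive to form an efflux ratio")
  papp_ba / papp_ab
}

#' Classify the transport mechanism from an efflux ratio
#'
#' Efflux ratios strictly greater than the threshold (default 1.5) indicate
#' likely carrier-mediated (active) efflux; ratios at or below it are
#' consistent with passive diffusion. A missing ER (e.g. no secretory arm
#' was run) is classified `"undetermined"`.
#'
#' @param er efflux ratio(s).
#' @param threshold decision threshold, strict inequality (default 1.5).
#' @return character vector with levels `"passive-consistent"`,
#'   `"active-transport-likely"`, `"undetermined"`.
#' @examples
#' classify_mechanism(c(1.442, 3.531, NA))
#' @export
classify_mechanism <- function(er, threshold = 1.5) {
  if (any(!is.na(er) & er <= 0))
    validation_error("efflux ratios must be positive")
  ifelse(is.na(er), "undetermined",
         ifelse(er > threshold, "active-transport-likely",
                "passive-consistent"))
}

#' Analyse a table of well time series
#'
#' Runs the per-well pipeline — dilution-corrected cumulative amounts,
#' transport-rate regression, Papp — on a tidy long-format measurement
#' table (one row per well per time; see [read_wells()] for the schema).
#'
#' @param wells tidy wells data.frame (columns `well_id, condition,
#'   compound, direction, c0_ug_per_ml, vr_ml, vs_ml, area_cm2, time_min,
#'   conc_ug_per_ml`).
#' @param window optional fit window in minutes, passed to
#'   [transport_rate()].
#' @return data.frame, one row per well: identifiers plus `rate_ug_per_s`,
#'   `rate_r2`, `papp_cm_per_s`, `n_points`, `window_lo`, `window_hi`.
#' @export
analyze_wells <- function(wells, window = NULL) {
  wells <- validate_wells(wells)
  out <- lapply(split(wells, wells$well_id), function(g) {
    g <- g[order(g$time_min), , drop = FALSE]
    dq <- cumulative_amounts(g$conc_ug_per_ml, vr = g$vr_ml[1],
                             vs = g$vs_ml[1])
    fit <- transport_rate(dq, g$time_min, window = window)
    data.frame(well_id = g$well_id[1], condition = g$condition[1],
               compound = g$compound[1], direction = g$direction[1],
               c0_ug_per_ml = g$c0_ug_per_ml[1],
               rate_ug_per_s = fit$rate, rate_r2 = fit$r2,
               papp_cm_per_s = papp(fit$rate, g$area_cm2[1],
                                    g$c0_ug_per_ml[1]),
               n_points = fit$n,
               window_lo = fit$fit_window[1], window_hi = fit$fit_window[2])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise per-well permeabilities by condition
#'
#' For each condition: n and mean +/- SD Papp per direction, the efflux
#' ratio of direction means, its classification, and — when both directions
#' have the same number of wells — the mean +/- SD of per-well ratios
#' (wells paired by replicate order within each direction).
#'
#' @param well_results output of [analyze_wells()].
#' @param er_threshold classification threshold passed to
#'   [classify_mechanism()].
#' @return data.frame, one row per condition, with Papp columns in cm/s
#'   (`*_mean`, `*_sd`), `er`, `er_well_mean`, `er_well_sd`,
#'   `classification`.
#' @export
summarize_groups <- function(well_results, er_threshold = 1.5) {
  req <- c("condition", "direction", "papp_cm_per_s")
  miss <- setdiff(req, names(well_results))
  if (length(miss))
    schema_error(paste0("well results missing column(s): ",
                        paste(miss, collapse = ", ")))
  out <- lapply(split(well_results, well_results$condition), function(g) {
    ab <- g$papp_cm_per_s[g$direction == "AP_to_BL"]
    ba <- g$papp_cm_per_s[g$direction == "BL_to_AP"]
    if (!length(ab))
      validation_error(sprintf(
        "condition '%s' has no AP_to_BL wells; summary undefined",
        g$condition[1]))
    er <- if (length(ba)) efflux_ratio(mean(ba), mean(ab)) else NA_real_
    if (length(ba) && length(ba) == length(ab)) {
      ratios <- efflux_ratio(ba, ab)
      er_wm <- mean(ratios)
      er_ws <- if (length(ratios) > 1L) stats::sd(ratios) else NA_real_
    } else {
      er_wm <- er_ws <- NA_real_
    }
    data.frame(condition = g$condition[1],
               compound = g$compound[1],
               n_ab = length(ab), n_ba = length(ba),
               papp_ab_mean = mean(ab),
               papp_ab_sd = if (length(ab) > 1L) stats::sd(ab) else NA_real_,
               papp_ba_mean = if (length(ba)) mean(ba) else NA_real_,
               papp_ba_sd = if (length(ba) > 1L) stats::sd(ba) else NA_real_,
               er = er, er_well_mean = er_wm, er_well_sd = er_ws,
               classification = classify_mechanism(er, er_threshold))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
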