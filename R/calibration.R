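# Segmented linear calibration: fitting, back-calculation and QC stats.
#
# Bioanalytical runs that span three-plus orders of magnitude are routinely
# split into a low and a high standard curve; the boundary standard is fit
# in both segments by default.

#' Fit a (possibly segmented) linear calibration curve
#'
#' Ordinary least-squares fit of signal on nominal concentration, either as
#' one line or as two segments split at `split_at` (the boundary standard is
#' included in both segments). Weighted fits (`1/x`, `1/x^2`) are available
#' for assays whose variance grows with concentration.
#'
#' @param standards data.frame with columns `nominal_conc` (ug/mL, > 0) and
#'   `signal`. A column `analyte` is carried through if present.
#' @param split_at optional boundary concentration separating the low and
#'   high segments (e.g. 2.5 for a 0.025-2.5 / 2.5-100 design). `NULL` fits
#'   a single segment.
#' @param weighting `"none"` (default), `"1/x"` or `"1/x2"`.
#' @param min_r warn when any segment's correlation coefficient falls below
#'   this (default 0.99).
#' @return Object of class `calibration_curve`: list with `analyte`,
#'   `segments` (data.frame `lo, hi, slope, intercept, r, n`), and `lloq`
#'   (the lowest standard of the lowest segment).
#' @examples
#' std <- generate_standards(slope = 0.2159, intercept = 0.0002,
#'                           nominal_concs = c(0.1, 0.25, 0.5, 1, 2.5, 5))
#' fit_calibration(std)
#' @export
fit_calibration <- function(standards, split_at = NULL, weighting = "none",
                            min_r = 0.99) {
  req <- c("nominal_conc", "signal")
  if (!all(req %in% names(standards)))
    schema_error(paste0("standards table must have columns ",
                        paste(req, collapse = ", ")))
  x <- standards$nominal_conc
  y <- standards$signal
  if (any(!is.finite(x)) || any(x <= 0))
    validation_error("nominal concentrations must be positive and finite")
  weighting <- match.arg(weighting, c("none", "1/x", "1/x2"))

  seg_ranges <- if (is.null(split_at)) {
    list(c(min(x), max(x)))
  } else {
    check_scalar(split_at, "split_at", lower = min(x), upper = max(x))
    list(c(min(x), split_at), c(split_at, max(x)))
  }

  fit_one <- function(rng) {
    sel <- x >= rng[1] & x <= rng[2]
    xs <- x[sel]; ys <- y[sel]
    if (sum(sel) < 3L)
      validation_error(sprintf(
        "segment [%g, %g] has %d standards; at least 3 are required",
        rng[1], rng[2], sum(sel)))
    if (stats::var(xs) == 0)
      validation_error("zero concentration variance within a segment")
    w <- switch(weighting, none = NULL, `1/x` = 1 / xs, `1/x2` = 1 / xs^2)
    fm <- if (is.null(w)) stats::lm(ys ~ xs) else stats::lm(ys ~ xs, weights = w)
    co <- stats::coef(fm)
    data.frame(lo = rng[1], hi = rng[2], slope = unname(co[2]),
               intercept = unname(co[1]),
               r = abs(stats::cor(xs, ys)), n = sum(sel))
  }
  segments <- do.call(rbind, lapply(seg_ranges, fit_one))
  if (any(segments$slope <= 0))
    validation_error("calibration slope must be positive")
  low_r <- segments$r < min_r
  if (any(low_r))
    warning(sprintf("calibration segment(s) with r < %g: %s", min_r,
                    paste(sprintf("[%g-%g] r=%.4f", segments$lo[low_r],
                                  segments$hi[low_r], segments$r[low_r]),
                          collapse = "; ")))
  structure(
    list(analyte = if ("analyte" %in% names(standards))
           as.character(standards$analyte[1]) else "analyte",
         segments = segments, lloq = min(x), weighting = weighting),
    class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve for %s (LLOQ %g ug/mL)\n", x$analyte, x$lloq))
  for (i in seq_len(nrow(x$segments)))
    with(x$segments[i, ], cat(sprintf(
      "  [%g-%g ug/mL]  y = %.6gx %s %.6g   (r = %.4f, n = %d)\n",
      lo, hi, slope, ifelse(intercept < 0, "-", "+"), abs(intercept), r, n)))
  invisible(x)
}

#' Back-calculate concentrations from signals
#'
#' Inverts the calibration line(s): `conc = (signal - intercept)/slope`,
#' using the segment whose back-calculated value falls inside its range.
#' A value landing between two segments' ranges is assigned to the nearer
#' segment with a warning. Values below the LLOQ are returned but flagged;
#' negative back-calculated values are flagged non-quantifiable and set to
#' `NA`.
#'
#' @param curve a [fit_calibration()] result.
#' @param signal numeric vector of measured signals.
#' @return data.frame `signal, conc, flag` with flag one of `"ok"`,
#'   `"below_lloq"`, `"non_quantifiable"`.
#' @export
back_calculate <- function(curve, signal) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(!is.finite(signal)))
    validation_error("signals must be finite")
  seg <- curve$segments
  cand <- vapply(seq_len(nrow(seg)),
                 function(i) (signal - seg$intercept[i]) / seg$slope[i],
                 numeric(length(signal)))
  cand <- matrix(cand, nrow = length(signal))
  conc <- numeric(length(signal))
  flag <- rep("ok", length(signal))
  gap_warned <- FALSE
  zero_tol <- 1e-8 * max(seg$hi)  # round-off guard near zero concentration
  for (j in seq_along(signal)) {
    inside <- which(cand[j, ] >= seg$lo & cand[j, ] <= seg$hi)
    if (length(inside)) {
      conc[j] <- cand[j, inside[1]]
    } else {
      # distance from each candidate to its own segment's range
      d <- pmax(seg$lo - cand[j, ], cand[j, ] - seg$hi, 0)
      k <- which.min(d)
      conc[j] <- cand[j, k]
      if (conc[j] >= curve$lloq && !gap_warned &&
          conc[j] <= max(seg$hi) && nrow(seg) > 1L) {
        warning("signal(s) back-calculate between segment ranges; assigned to nearer segment")
        gap_warned <- TRUE
      }
    }
    if (conc[j] < 0 && conc[j] >= -zero_tol) conc[j] <- 0
    if (conc[j] < 0) {
      conc[j] <- NA_real_
      flag[j] <- "non_quantifiable"
    } else if (conc[j] < curve$lloq) {
      flag[j] <- "below_lloq"
    }
  }
  data.frame(signal = signal, conc = conc, flag = flag)
}

#' Precision and recovery statistics for QC samples
#'
#' For each QC level: intra-day precision (RSD of replicates within a day,
#' averaged across days), inter-day precision (RSD of the daily means) and
#' relative recovery (grand mean measured / nominal x 100). Sample standard
#' deviations (n-1 denominator) are used throughout. With fewer than two
#' replicates in a day, or fewer than two days, the corresponding RSD is
#' reported as `NA` rather than invented.
#'
#' @param qc data.frame with columns `nominal` (the QC level, ug/mL),
#'   `measured` (back-calculated concentration, ug/mL) and optionally `day`
#'   (any label; a single day is assumed when absent).
#' @param rsd_limit advisory acceptance limit on RSD, percent (default 10).
#' @param recovery_limits advisory acceptance band on recovery, percent
#'   (default `c(85, 115)`). Results outside the bands are flagged in the
#'   `acceptable` column but never removed.
#' @return data.frame, one row per level: `nominal, n, n_days,
#'   intra_day_rsd, inter_day_rsd, recovery, acceptable`.
#' @examples
#' qc <- data.frame(nominal = 10, measured = c(9, 10, 11))
#' qc_stats(qc)
#' @export
qc_stats <- function(qc, rsd_limit = 10, recovery_limits = c(85, 115)) {
  req <- c("nominal", "measured")
  if (!all(req %in% names(qc)))
    schema_error("QC table must have columns nominal, measured")
  if (!"day" %in% names(qc)) qc$day <- 1L
  rsd <- function(v) if (length(v) < 2L) NA_real_ else
    100 * stats::sd(v) / mean(v)
  out <- lapply(split(qc, qc$nominal), function(g) {
    daily_mean <- tapply(g$measured, g$day, mean)
    daily_rsd <- tapply(g$measured, g$day, rsd)
    intra <- if (all(is.na(daily_rsd))) NA_real_ else
      mean(daily_rsd, na.rm = TRUE)
    inter <- if (length(daily_mean) < 2L) NA_real_ else
      100 * stats::sd(daily_mean) / mean(daily_mean)
    recovery <- 100 * mean(g$measured) / g$nominal[1]
    data.frame(nominal = g$nominal[1], n = nrow(g),
               n_days = length(daily_mean),
               intra_day_rsd = intra, inter_day_rsd = inter,
               recovery = recovery,
               acceptable = (is.na(intra) || intra <= rsd_limit) &&
                 (is.na(inter) || inter <= rsd_limit) &&
                 recovery >= recovery_limits[1] &&
                 recovery <= recovery_limits[2])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$nominal), , drop = FALSE]
}
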