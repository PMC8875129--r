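# Inhibitor / co-administration effect analysis: percent changes, group
# contrasts and report assembly.

#' Signed percent change between a baseline and a treated value
#'
#' `(treated - baseline) / baseline * 100`; negative values are decreases.
#' [format_change()] renders the conventional "decrease of x%" phrasing.
#'
#' @param baseline baseline value (non-zero).
#' @param treated treated/co-administered value.
#' @return signed percent change (vectorised).
#' @examples
#' percent_change(3.531, 2.126)  # -39.79: ER decrease under verapamil
#' @export
percent_change <- function(baseline, treated) {
  if (any(!is.na(baseline) & baseline == 0))
    validation_error("percent change is undefined for a zero baseline")
  (treated - baseline) / baseline * 100
}

#' Render a percent change as assay-report prose
#'
#' @param pct signed percent change from [percent_change()].
#' @param digits decimal places (default 2).
#' @return character: `"decrease of 39.79%"`, `"increase of 9.96%"` or
#'   `"no change"`.
#' @export
format_change <- function(pct, digits = 2) {
  ifelse(is.na(pct), "not estimable",
         ifelse(pct < 0, sprintf("decrease of %.*f%%", digits, -pct),
                ifelse(pct > 0, sprintf("increase of %.*f%%", digits, pct),
                       "no change")))
}

#' Contrast two groups of per-well permeabilities
#'
#' Welch two-sample t test on per-well Papp between a baseline and a
#' treated condition, per direction. With fewer than two wells in either
#' group the contrast is descriptive only (no p value). When both groups
#' are degenerate (zero variance) the convention is p = 1 for equal means
#' and p = 0 otherwise.
#'
#' @param baseline,treated numeric vectors of per-well Papp (cm/s) or any
#'   per-well metric.
#' @param alpha significance level for the `significant` flag (default
#'   0.05).
#' @return list: `mean_baseline`, `mean_treated`, `pct_change`, `statistic`,
#'   `p_value`, `significant`, `n`.
#' @export
contrast_groups <- function(baseline, treated, alpha = 0.05) {
  baseline <- baseline[!is.na(baseline)]
  treated <- treated[!is.na(treated)]
  if (!length(baseline) || !length(treated))
    validation_error("both groups must contain at least one value")
  mb <- mean(baseline); mt <- mean(treated)
  res <- list(mean_baseline = mb, mean_treated = mt,
              pct_change = percent_change(mb, mt),
              statistic = NA_real_, p_value = NA_real_,
              significant = NA, n = c(length(baseline), length(treated)))
  if (length(baseline) >= 2L && length(treated) >= 2L) {
    if (stats::var(baseline) == 0 && stats::var(treated) == 0) {
      res$p_value <- if (isTRUE(all.equal(mb, mt))) 1 else 0
      res$statistic <- if (res$p_value == 1) 0 else Inf
    } else {
      tt <- stats::t.test(treated, baseline, var.equal = FALSE)
      res$statistic <- unname(tt$statistic)
      res$p_value <- tt$p.value
    }
    res$significant <- res$p_value < alpha
  }
  res
}

#' Pairwise effect table between conditions
#'
#' For each requested (baseline, treated) pair, compares Papp per direction
#' (Welch test on per-well values) and the efflux ratio (ratio of direction
#' means; no test, since the group ER is a single derived number per
#' condition).
#'
#' @param well_results output of [analyze_wells()].
#' @param pairs list of `c(baseline, treated)` condition-label pairs.
#' @param alpha significance level (default 0.05).
#' @param p_adjust multiplicity adjustment across the Papp contrasts:
#'   `"none"` (default) or any method of [stats::p.adjust()], e.g.
#'   `"holm"`.
#' @return data.frame: `baseline, treated, metric, base_value,
#'   treated_value, pct_change, p_value, significant`.
#' @export
effect_table <- function(well_results, pairs, alpha = 0.05,
                         p_adjust = "none") {
  summaries <- summarize_groups(well_results)
  rows <- list()
  for (pr in pairs) {
    if (length(pr) != 2L)
      validation_error("each pair must be c(baseline, treated)")
    for (lbl in pr)
      if (!lbl %in% well_results$condition)
        validation_error(sprintf("unknown condition '%s'", lbl))
    for (dir in DIRECTIONS) {
      b <- well_results$papp_cm_per_s[well_results$condition == pr[1] &
                                        well_results$direction == dir]
      t_ <- well_results$papp_cm_per_s[well_results$condition == pr[2] &
                                         well_results$direction == dir]
      if (!length(b) || !length(t_)) next
      ct <- contrast_groups(b, t_, alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        baseline = pr[1], treated = pr[2],
        metric = paste0("papp_", if (dir == "AP_to_BL") "ab" else "ba"),
        base_value = ct$mean_baseline, treated_value = ct$mean_treated,
        pct_change = ct$pct_change, p_value = ct$p_value,
        significant = ct$significant)
    }
    eb <- summaries$er[summaries$condition == pr[1]]
    et <- summaries$er[summaries$condition == pr[2]]
    rows[[length(rows) + 1L]] <- data.frame(
      baseline = pr[1], treated = pr[2], metric = "er",
      base_value = eb, treated_value = et,
      pct_change = if (is.na(eb) || is.na(et)) NA_real_ else
        percent_change(eb, et),
      p_value = NA_real_, significant = NA)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (p_adjust != "none") {
    sel <- !is.na(res$p_value)
    res$p_value[sel] <- stats::p.adjust(res$p_value[sel], method = p_adjust)
    res$significant[sel] <- res$p_value[sel] < alpha
  }
  res
}

#' Assemble the human-readable report tables
#'
#' Formats group summaries (Papp scaled to 1e-6 cm/s, "mean +/- SD") and
#' the pairwise effect table, rendering missing arms as an em dash, the
#' convention for conditions whose secretory direction was not run.
#' Generation is pure: identical inputs give identical output.
#'
#' @param summaries output of [summarize_groups()].
#' @param effects optional output of [effect_table()].
#' @return list with `groups` (formatted data.frame), `effects` (or
#'   `NULL`), and `text` (character vector, a plain-text rendering).
#' @export
build_report <- function(summaries, effects = NULL) {
  if (anyDuplicated(summaries$condition))
    validation_error("duplicate condition labels in summaries")
  fmt_ms <- function(m, s) ifelse(
    is.na(m), "—",
    ifelse(is.na(s), sprintf("%.3f", m * 1e6),
           sprintf("%.3f ± %.3f", m * 1e6, s * 1e6)))
  groups <- data.frame(
    condition = summaries$condition,
    n = paste(summaries$n_ab, summaries$n_ba, sep = "/"),
    papp_ab_1e6_cm_s = fmt_ms(summaries$papp_ab_mean, summaries$papp_ab_sd),
    papp_ba_1e6_cm_s = fmt_ms(summaries$papp_ba_mean, summaries$papp_ba_sd),
    er = ifelse(is.na(summaries$er), "—", sprintf("%.3f", summaries$er)),
    classification = summaries$classification)
  text <- c(
    "Bidirectional transport summary (Papp in 1e-6 cm/s, mean +/- SD)",
    utils::capture.output(print(groups, row.names = FALSE)))
  eff_fmt <- NULL
  if (!is.null(effects)) {
    eff_fmt <- effects
    text <- c(text, "", "Pairwise effects:",
              utils::capture.output(print(effects, row.names = FALSE)))
    for (i in seq_len(nrow(effects)))
      if (effects$metric[i] == "er" && !is.na(effects$pct_change[i]))
        text <- c(text, sprintf(
          "  ER %s -> %s: %.3f to %.3f, %s",
          effects$baseline[i], effects$treated[i], effects$base_value[i],
          effects$treated_value[i], format_change(effects$pct_change[i])))
  }
  list(groups = groups, effects = eff_fmt, text = text)
}
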