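# CSV dialects of the pipeline. All files are UTF-8, comma-separated with
# a header row and "." as decimal separator; an em dash or empty field
# means missing (the convention used for absent assay arms).

.read_csv <- function(path, what) {
  if (!file.exists(path))
    schema_error(paste0(what, " file not found"), file = path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", "", "—"))
  if (!nrow(df)) schema_error(paste0(what, " file is empty"), file = path)
  df
}

.require_columns <- function(df, cols, file, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    schema_error(sprintf("%s table missing column(s): %s", what,
                         paste(miss, collapse = ", ")),
                 file = file, column = miss[1])
  invisible(df)
}

#' Validate (and normalise) a tidy wells table
#'
#' Checks the schema and per-row constraints of the long-format measurement
#' table, normalises direction labels, and orders rows by well and time.
#' Constants (c0, volumes, area) must be consistent within each well.
#'
#' @param wells data.frame; see [read_wells()] for the column layout.
#' @param file optional file name used in error messages.
#' @return the validated data.frame.
#' @export
validate_wells <- function(wells, file = NULL) {
  req <- c("well_id", "condition", "compound", "direction", "c0_ug_per_ml",
           "vr_ml", "vs_ml", "area_cm2", "time_min", "conc_ug_per_ml")
  .require_columns(wells, req, file, "wells")
  num_cols <- c("c0_ug_per_ml", "vr_ml", "vs_ml", "area_cm2", "time_min",
                "conc_ug_per_ml")
  for (cc in num_cols)
    if (!is.numeric(wells[[cc]]))
      schema_error("column must be numeric", file = file, column = cc)
  bad <- which(!is.finite(wells$c0_ug_per_ml) | wells$c0_ug_per_ml <= 0)
  if (length(bad))
    schema_error("c0 must be positive", file = file, row = bad[1],
                 column = "c0_ug_per_ml")
  bad <- which(wells$vs_ml >= wells$vr_ml | wells$vr_ml <= 0 |
                 wells$vs_ml <= 0)
  if (length(bad))
    schema_error("need 0 < vs_ml < vr_ml", file = file, row = bad[1],
                 column = "vs_ml")
  bad <- which(!is.na(wells$conc_ug_per_ml) & wells$conc_ug_per_ml < 0)
  if (length(bad))
    schema_error("concentrations must be non-negative", file = file,
                 row = bad[1], column = "conc_ug_per_ml")
  wells$direction <- match_direction(wells$direction)
  for (g in split(seq_len(nrow(wells)), wells$well_id)) {
    for (cc in c("c0_ug_per_ml", "vr_ml", "vs_ml", "area_cm2", "direction",
                 "condition"))
      if (length(unique(wells[[cc]][g])) != 1L)
        schema_error(sprintf("well '%s' has inconsistent %s",
                             wells$well_id[g[1]], cc),
                     file = file, column = cc)
    tt <- wells$time_min[g]
    if (anyDuplicated(tt))
      schema_error(sprintf("well '%s' has duplicate time points",
                           wells$well_id[g[1]]), file = file,
                   column = "time_min")
  }
  wells[order(wells$well_id, wells$time_min), , drop = FALSE]
}

#' Read a tidy wells CSV
#'
#' One row per well per sampling time. Columns: `well_id, condition,
#' compound, direction, c0_ug_per_ml, vr_ml, vs_ml, area_cm2, time_min,
#' conc_ug_per_ml`. Direction accepts `AP_to_BL` / `BL_to_AP` and common
#' variants ("AP-BL", "AP>BL", ...). An em dash or empty concentration is
#' read as missing.
#'
#' @param path CSV path.
#' @return validated data.frame (see [validate_wells()]).
#' @export
read_wells <- function(path) {
  validate_wells(.read_csv(path, "wells"), file = path)
}

#' Write a tidy wells CSV
#' @param wells wells data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wells <- function(wells, path) {
  utils::write.csv(wells, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a calibration standards CSV
#'
#' Columns: `analyte, nominal_conc_ug_per_ml, signal`, optional `day`.
#' "signal" may be a raw analyte response or an analyte/internal-standard
#' peak-area ratio; the pipeline treats the two identically.
#'
#' @param path CSV path.
#' @return data.frame with columns renamed to `analyte, nominal_conc,
#'   signal` (+ `day` if present).
#' @export
read_standards <- function(path) {
  df <- .read_csv(path, "standards")
  .require_columns(df, c("analyte", "nominal_conc_ug_per_ml", "signal"),
                   path, "standards")
  names(df)[names(df) == "nominal_conc_ug_per_ml"] <- "nominal_conc"
  if (any(!is.finite(df$nominal_conc) | df$nominal_conc <= 0))
    schema_error("nominal concentrations must be positive", file = path,
                 column = "nominal_conc_ug_per_ml")
  df
}

#' Read an electrical-resistance CSV
#'
#' Columns: `well_id, r1_ohm, r0_ohm, area_cm2`, optional `context`
#' (`pre-experiment` or `in-experiment`).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_resistance <- function(path) {
  df <- .read_csv(path, "resistance")
  .require_columns(df, c("well_id", "r1_ohm", "r0_ohm", "area_cm2"),
                   path, "resistance")
  df
}
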