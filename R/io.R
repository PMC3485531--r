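#' Read and write segmental curve studies
#'
#' Two plain-text study formats are supported.
#'
#' CSV (wide): header `time_pct_rr` followed by the 16 canonical segment
#' columns of [lv_segments()]; one row per time sample; decimal point,
#' comma separator, UTF-8. A trailing `global` column is accepted and
#' ignored on read (the global curve is always recomputed as the segment
#' sum).
#'
#' JSON: object with `study_id`, optional `rr_interval_ms`, `times` array,
#' and `segments` object mapping each canonical segment name to its volume
#' array.
#'
#' @param path File path.
#' @param format `"csv"`, `"json"`, or `"auto"` (by file extension).
#' @return [read_study()] returns a [curve_set()]; [write_study()] returns
#'   `path` invisibly.
#' @export
#' @examples
#' path <- system.file("extdata", "synthetic_example_study.csv",
#'                     package = "stvloss")
#' analyze_study(read_study(path))
read_study <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "json") read_study_json(path) else read_study_csv(path)
}

read_study_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (!"time_pct_rr" %in% names(df))
    stop("study CSV '", path, "' lacks required column 'time_pct_rr'")
  missing <- setdiff(lv_segments(), names(df))
  if (length(missing))
    stop("study CSV '", path, "' is missing segment column(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(df), c("time_pct_rr", "global", lv_segments()))
  if (length(extra))
    stop("study CSV '", path, "' has unexpected column(s): ",
         paste(extra, collapse = ", "))
  validate_read(df$time_pct_rr, df[lv_segments()], path)
  curve_set(df$time_pct_rr, as.matrix(df[lv_segments()]),
            study_id = sub("\\.[^.]*$", "", basename(path)))
}

read_study_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("times", "segments"))
    if (is.null(j[[f]])) stop("study JSON '", path, "' lacks field '", f, "'")
  missing <- setdiff(lv_segments(), names(j$segments))
  if (length(missing))
    stop("study JSON '", path, "' is missing segment(s): ",
         paste(missing, collapse = ", "))
  validate_read(j$times, j$segments[lv_segments()], path)
  curve_set(j$times, j$segments[lv_segments()],
            rr_interval_ms = j$rr_interval_ms,
            study_id = if (is.null(j$study_id)) basename(path) else j$study_id)
}

# line-numbered diagnostics ahead of the type-level validation
validate_read <- function(times, seg_cols, path) {
  bad <- which(diff(times) <= 0)
  if (length(bad))
    stop("study '", path, "': time not strictly increasing at sample(s) ",
         paste(utils::head(bad + 1L, 5L), collapse = ", "))
  for (s in names(seg_cols)) {
    v <- as.numeric(seg_cols[[s]])
    neg <- which(v < 0)
    if (length(neg))
      stop("study '", path, "': negative volume in segment '", s,
           "' at sample(s) ", paste(utils::head(neg, 5L), collapse = ", "))
  }
}

#' @rdname read_study
#' @param curve_set A [curve_set()] to write.
#' @param include_global Add a recomputable `global` column to the CSV.
#' @export
write_study <- function(curve_set, path, format = c("auto", "csv", "json"),
                        include_global = FALSE) {
  stopifnot(inherits(curve_set, "curve_set"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    df <- data.frame(time_pct_rr = curve_set$times,
                     curve_set$volumes, check.names = FALSE)
    if (include_global) df$global <- rowSums(curve_set$volumes)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    segs <- lapply(lv_segments(), function(s) curve_set$volumes[, s])
    names(segs) <- lv_segments()
    jsonlite::write_json(
      list(study_id = curve_set$study_id,
           rr_interval_ms = curve_set$rr_interval_ms,
           times = curve_set$times, segments = segs),
      path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Serialize a dyssynchrony report
#'
#' [report_to_list()] turns an `stv_report` into a plain list suitable for
#' JSON (`ml_pct_rr` keys for the STV areas, percentages on the 0-100
#' scale); [write_report()] writes it; [report_row()] flattens the scalar
#' metrics to a one-row data.frame for cohort assembly.
#'
#' @param report An `stv_report` from [analyze_study()].
#' @param path Output path for the JSON.
#' @return A list, the path (invisibly), or a one-row data.frame.
#' @export
report_to_list <- function(report) {
  stopifnot(inherits(report, "stv_report"))
  es <- report$es_table
  list(
    study_id = report$study_id,
    n_samples = report$n_samples,
    sdi_divisor = report$sdi_divisor,
    edv_ml = report$edv, esv_ml = report$esv, ef_pct = report$ef,
    sdi_pct_rr = report$sdi, le_pct_rr = report$le,
    pre_stv_ml_pct_rr = report$pre_stv,
    post_stv_ml_pct_rr = report$post_stv,
    total_stv_ml_pct_rr = report$total_stv,
    global_es_time_pct_rr = attr(es, "global_es_time"),
    global_es_volume_ml = attr(es, "global_es_volume"),
    segments = lapply(seq_len(nrow(report$entries)), function(i)
      as.list(report$entries[i, ])))
}

#' @rdname report_to_list
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname report_to_list
#' @export
report_row <- function(report) {
  stopifnot(inherits(report, "stv_report"))
  data.frame(study_id = report$study_id, t(coef(report)))
}

#' Read and write per-patient cohort tables
#'
#' The cohort CSV has one row per patient: `patient_id`, the eight
#' `<metric>_baseline` columns, optionally the `<metric>_followup` columns,
#' `delta_esv_pct` and `responder`, as produced by [cohort_metrics()].
#'
#' @param cohort_df Per-patient data.frame.
#' @param path File path.
#' @return [read_cohort_csv()] returns a data.frame; [write_cohort_csv()]
#'   the path invisibly.
#' @export
write_cohort_csv <- function(cohort_df, path) {
  utils::write.csv(cohort_df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("patient_id", "responder", "delta_esv_pct")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("cohort CSV '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  df$responder <- as.logical(df$responder)
  df
}
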