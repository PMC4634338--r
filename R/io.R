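# Readers and writers for the challenge-style tabular formats. Plain CSV
# with a header row; all internal change values are normalized to the
# 100*ln scale (loss negative, ventricular expansion positive).

.req_cols <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("file ", path, " is missing column(s): ", paste(miss, collapse = ", "))
}

#' Read volume records from CSV
#'
#' Expects columns `subject`, `group`, `visit`, `scan`, `weeks` (or
#' `time_years`), `structure`, `volume`. Validates positivity of volumes
#' and uniqueness of the (subject, visit, scan, structure) key, reporting
#' offending row numbers.
#'
#' @param path CSV file path.
#' @return A validated data.frame of scan records with `time_years`.
#' @export
read_volumes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .req_cols(df, c("subject", "group", "visit", "scan", "structure", "volume"),
            path)
  if (!"time_years" %in% names(df)) {
    .req_cols(df, "weeks", path)
    df$time_years <- df$weeks * 7 / 365.25
  }
  bad <- which(!is.finite(df$volume) | df$volume <= 0)
  if (length(bad))
    stop("non-positive volume(s) at row(s): ",
         paste(head(bad, 10L), collapse = ", "))
  key <- paste(df$subject, df$visit, df$scan, df$structure)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (subject, visit, scan, structure) key(s) at row(s): ",
         paste(head(dup, 10L), collapse = ", "))
  df
}

#' Write volume records to CSV
#' @param volumes Data.frame of scan records.
#' @param path Output path.
#' @export
write_volumes <- function(volumes, path) {
  write.csv(volumes, path, row.names = FALSE)
  invisible(path)
}

#' Read pair-change records from CSV and standardize to the 100*ln scale
#'
#' Expects columns `subject`, `group`, `start_visit`, `start_scan`,
#' `end_visit`, `end_scan`, `direction`, `structure`, `change`, plus a
#' `change_kind` column (or the `change_kind` argument): `"ln"` (already
#' standardized), `"percent"` (percent change, converted through
#' `100 * ln(1 + pct/100)`), or `"volume"` (a volume delta, converted
#' through `100 * ln((V_start + dV)/V_start)` using the start-scan volume
#' looked up in `volumes`). Signed `delta_t_years` is derived from the
#' design's visit times.
#'
#' @param path CSV file path.
#' @param design The [study_design()] giving visit times.
#' @param change_kind Override/declare the change kind for the whole file.
#' @param volumes Volume records, required when `change_kind = "volume"`.
#' @return A validated data.frame of pair-change records with `change` on
#'   the `100 * ln` scale and `change_kind = "ln"`.
#' @export
read_changes <- function(path, design = study_design(), change_kind = NULL,
                         volumes = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .req_cols(df, c("subject", "group", "start_visit", "start_scan",
                  "end_visit", "end_scan", "direction", "structure",
                  "change"), path)
  if (is.null(change_kind)) {
    if (!"change_kind" %in% names(df))
      stop("declare change_kind (column or argument) for ", path)
    change_kind <- unique(df$change_kind)
    if (length(change_kind) != 1L)
      stop("mixed change_kind values in ", path)
  }
  if (!change_kind %in% c("ln", "percent", "volume"))
    stop("unknown change_kind: ", change_kind)
  nv <- design$n_visits
  bad <- which(df$start_visit < 1L | df$start_visit > nv |
                 df$end_visit < 1L | df$end_visit > nv)
  if (length(bad))
    stop("visit index outside the design at row(s): ",
         paste(head(bad, 10L), collapse = ", "))
  tv <- visit_time_years(design, seq_len(nv))
  df$delta_t_years <- tv[df$end_visit] - tv[df$start_visit]

  if (change_kind == "percent") {
    df$change <- c_direct_percent(df$change)
  } else if (change_kind == "volume") {
    if (is.null(volumes))
      stop("change_kind 'volume' needs the volumes table to standardize")
    key <- paste(volumes$subject, volumes$visit, volumes$scan,
                 volumes$structure)
    m <- match(paste(df$subject, df$start_visit, df$start_scan,
                     df$structure), key)
    if (anyNA(m))
      stop("no start-scan volume for row(s): ",
           paste(head(which(is.na(m)), 10L), collapse = ", "))
    df$change <- c_direct(volumes$volume[m], df$change)
  }
  df$change_kind <- "ln"
  df
}

#' Write pair-change records to CSV
#' @param changes Data.frame of pair-change records.
#' @param path Output path.
#' @export
write_changes <- function(changes, path) {
  write.csv(changes, path, row.names = FALSE)
  invisible(path)
}

#' Structured fit report
#'
#' Serializes a fitted model (volume or direct) as structured JSON text:
#' estimates, standard error, variance components, restricted
#' log-likelihood and convergence diagnostics.
#'
#' @param fit A `"volume_lmm"` or `"direct_lmm"` object.
#' @param path Optional path; when given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
fit_report <- function(fit, path = NULL) {
  x <- unclass(fit)
  x$alpha_hat <- NULL # nuisance, omitted from the report
  x$model <- if (inherits(fit, "volume_lmm")) "repeated_volume"
             else "repeated_direct_change"
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
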