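#' Longitudinal study design
#'
#' Encodes the visit schedule of a serial-imaging study: an ordered set of
#' visit times (weeks from baseline), the subset of visits at which two
#' back-to-back scans are acquired, and the group sizes. The default is the
#' design of a two-year observational dementia cohort: nine visits at 0, 2,
#' 6, 12, 26, 38, 52, 78 and 104 weeks with duplicate same-day scans at the
#' 0-, 6- and 38-week visits, 46 cases with Alzheimer's disease and 23
#' healthy controls.
#'
#' @param visit_weeks Strictly increasing numeric vector of visit times in
#'   weeks; the first element must be 0 (baseline).
#' @param repeat_scan_visits Integer vector of visit indices (1-based into
#'   `visit_weeks`) at which two same-day scans are taken.
#' @param n_cases,n_controls Positive integer group sizes.
#'
#' @return An object of class `"study_design"`: a list with the four fields
#'   above plus `n_visits`.
#' @examples
#' d <- study_design()
#' visit_time_years(d, 7) # the 52-week visit, just under one year
#' @export
study_design <- function(visit_weeks = c(0, 2, 6, 12, 26, 38, 52, 78, 104),
                         repeat_scan_visits = c(1L, 3L, 6L),
                         n_cases = 46L, n_controls = 23L) {
  visit_weeks <- as.numeric(visit_weeks)
  if (length(visit_weeks) < 1L || visit_weeks[1L] != 0)
    stop("visit_weeks must start at 0 (baseline)")
  if (any(diff(visit_weeks) <= 0))
    stop("visit_weeks must be strictly increasing")
  repeat_scan_visits <- sort(unique(as.integer(repeat_scan_visits)))
  if (length(repeat_scan_visits) &&
      (min(repeat_scan_visits) < 1L || max(repeat_scan_visits) > length(visit_weeks)))
    stop("repeat_scan_visits must be valid visit indices")
  n_cases <- as.integer(n_cases); n_controls <- as.integer(n_controls)
  if (is.na(n_cases) || n_cases < 1L || is.na(n_controls) || n_controls < 1L)
    stop("group sizes must be positive integers")
  structure(list(visit_weeks = visit_weeks,
                 repeat_scan_visits = repeat_scan_visits,
                 n_cases = n_cases, n_controls = n_controls,
                 n_visits = length(visit_weeks)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Longitudinal study design\n")
  cat("  visits (weeks):", paste(x$visit_weeks, collapse = ", "), "\n")
  cat("  repeat-scan visits:",
      if (length(x$repeat_scan_visits))
        paste(x$visit_weeks[x$repeat_scan_visits], "wk", collapse = ", ")
      else "none", "\n")
  cat("  groups: ", x$n_cases, " cases / ", x$n_controls, " controls\n", sep = "")
  invisible(x)
}

#' Convert a visit index to time in years
#'
#' Visit times are recorded in weeks; models work in years. The conversion
#' is weeks * 7 / 365.25 (mean Julian year), fixed and documented.
#'
#' @param design A [study_design()].
#' @param j Visit index (1-based); may be a vector.
#' @return Time of the visit(s) in years from baseline.
#' @export
visit_time_years <- function(design, j) {
  stopifnot(inherits(design, "study_design"))
  j <- as.integer(j)
  if (any(is.na(j)) || any(j < 1L) || any(j > design$n_visits))
    stop("invalid visit index")
  design$visit_weeks[j] * 7 / 365.25
}

#' Scans implied by a design for one subject
#'
#' @param design A [study_design()].
#' @param visits Visit indices the subject attended (default all).
#' @return A data.frame with columns `visit`, `scan` (scan 2 only at
#'   repeat-scan visits), ordered by visit then scan.
#' @export
design_scans <- function(design, visits = seq_len(design$n_visits)) {
  stopifnot(inherits(design, "study_design"))
  visits <- sort(unique(as.integer(visits)))
  if (length(visits) && (min(visits) < 1L || max(visits) > design$n_visits))
    stop("invalid visit index")
  n_scans <- ifelse(visits %in% design$repeat_scan_visits, 2L, 1L)
  data.frame(visit = rep(visits, n_scans),
             scan = unlist(lapply(n_scans, seq_len), use.names = FALSE))
}

#' Enumerate forward scan pairs for one subject
#'
#' Returns every unordered pair of a subject's scans, oriented forward:
#' the chronologically earlier scan is the start, with same-day ties broken
#' by scan index (the lower scan index is the start). A subject with `s`
#' scans yields `s * (s - 1) / 2` pairs; under the default full schedule
#' (12 scans) that is 66 pairs, or 63 after dropping the three same-day
#' pairs.
#'
#' @param scans A data.frame with columns `visit` and `scan` describing one
#'   subject's scans (e.g. from [design_scans()]). A `subject` column, if
#'   present, must be constant.
#' @param include_same_day Keep pairs whose two scans share a visit?
#' @return A data.frame with columns `start_visit`, `start_scan`,
#'   `end_visit`, `end_scan`, `same_day`.
#' @export
enumerate_pairs <- function(scans, include_same_day = TRUE) {
  if (!is.data.frame(scans) || !all(c("visit", "scan") %in% names(scans)))
    stop("scans must be a data.frame with columns visit, scan")
  if ("subject" %in% names(scans) && length(unique(scans$subject)) > 1L)
    stop("enumerate_pairs operates on a single subject's scans")
  key <- paste(scans$visit, scans$scan, sep = ":")
  if (anyDuplicated(key)) stop("duplicate scan identifiers in input")
  ord <- order(scans$visit, scans$scan)
  v <- scans$visit[ord]; k <- scans$scan[ord]
  s <- length(v)
  if (s < 2L)
    return(data.frame(start_visit = integer(), start_scan = integer(),
                      end_visit = integer(), end_scan = integer(),
                      same_day = logical()))
  idx <- which(upper.tri(matrix(0, s, s)), arr.ind = TRUE) # col > row
  out <- data.frame(start_visit = v[idx[, "row"]], start_scan = k[idx[, "row"]],
                    end_visit = v[idx[, "col"]], end_scan = k[idx[, "col"]])
  out$same_day <- out$start_visit == out$end_visit
  out <- out[order(out$start_visit, out$start_scan, out$end_visit, out$end_scan), ]
  rownames(out) <- NULL
  if (!include_same_day) out <- out[!out$same_day, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclusion list of scans
#'
#' @param subject,visit,scan Parallel vectors identifying excluded scans.
#' @return An object of class `"exclusion_list"` (a data.frame).
#' @export
exclusion_list <- function(subject = character(), visit = integer(),
                           scan = integer()) {
  out <- data.frame(subject = as.character(subject),
                    visit = as.integer(visit), scan = as.integer(scan))
  out <- unique(out)
  class(out) <- c("exclusion_list", "data.frame")
  out
}

#' Letter code map for scan identifiers
#'
#' External exclusion lists may identify scans as `subject_letter` (e.g.
#' `"190_F"`), with letters assigned in acquisition order over the full
#' schedule. The letter-to-(visit, scan) assignment is a configuration
#' choice; the default maps A, B, C, ... to the scans of
#' [design_scans()] in order (so under the default design A/B are the two
#' baseline scans, C the 2-week scan, and so on).
#'
#' @param design A [study_design()].
#' @return data.frame with columns `letter`, `visit`, `scan`.
#' @export
scan_letter_map <- function(design) {
  sc <- design_scans(design)
  if (nrow(sc) > 26L) stop("more scans than letters; supply an explicit map")
  cbind(data.frame(letter = LETTERS[seq_len(nrow(sc))]), sc)
}

#' Read an exclusion list from file
#'
#' Two dialects are accepted: (i) a CSV with explicit `subject`, `visit`,
#' `scan` columns; (ii) a plain-text/CSV file whose first column holds
#' `subject_letter` identifiers (e.g. `190_F`), resolved through a letter
#' map ([scan_letter_map()] by default).
#'
#' @param path File path.
#' @param design A [study_design()]; required for the letter dialect.
#' @param letter_map Optional data.frame with columns `letter`, `visit`,
#'   `scan` overriding the default map.
#' @return An [exclusion_list()].
#' @export
read_exclusions <- function(path, design = study_design(), letter_map = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("subject", first) && grepl("visit", first)) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("subject", "visit", "scan")
    if (!all(need %in% names(df)))
      stop("exclusion file must have columns subject, visit, scan")
    return(exclusion_list(df$subject, df$visit, df$scan))
  }
  ids <- read.csv(path, header = grepl("scan|id", tolower(first)),
                  stringsAsFactors = FALSE)[[1L]]
  ids <- trimws(ids[nzchar(trimws(ids))])
  parts <- regmatches(ids, regexec("^(.*)_([A-Z])$", ids))
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad))
    stop("unparseable scan identifiers: ", paste(ids[bad], collapse = ", "))
  map <- if (is.null(letter_map)) scan_letter_map(design) else letter_map
  letter <- vapply(parts, `[`, "", 3L)
  m <- match(letter, map$letter)
  if (anyNA(m)) stop("scan letters outside the design's schedule")
  exclusion_list(vapply(parts, `[`, "", 2L), map$visit[m], map$scan[m])
}

#' Apply a scan exclusion list to volume or pair-change records
#'
#' Removes every volume record for an excluded scan and every pair-change
#' record whose start or end scan is excluded. Excluding a scan absent from
#' the records is a no-op reported with a warning.
#'
#' @param records A data.frame of volume records (columns `subject`,
#'   `visit`, `scan`, ...) or pair-change records (columns `subject`,
#'   `start_visit`, `start_scan`, `end_visit`, `end_scan`, ...).
#' @param exclusions An [exclusion_list()].
#' @return A list with `records` (the survivors), `n_removed` (rows
#'   dropped), and `removed` (the dropped rows).
#' @export
apply_exclusions <- function(records, exclusions) {
  stopifnot(is.data.frame(records))
  if (!inherits(exclusions, "exclusion_list"))
    exclusions <- exclusion_list(exclusions$subject, exclusions$visit,
                                 exclusions$scan)
  ex_key <- paste(exclusions$subject, exclusions$visit, exclusions$scan,
                  sep = ":")
  if (all(c("visit", "scan") %in% names(records))) {
    key <- paste(records$subject, records$visit, records$scan, sep = ":")
    hit <- key %in% ex_key
    unknown <- setdiff(ex_key, key)
  } else if (all(c("start_visit", "end_visit") %in% names(records))) {
    k1 <- paste(records$subject, records$start_visit, records$start_scan,
                sep = ":")
    k2 <- paste(records$subject, records$end_visit, records$end_scan,
                sep = ":")
    hit <- (k1 %in% ex_key) | (k2 %in% ex_key)
    unknown <- setdiff(ex_key, c(k1, k2))
  } else {
    stop("records are neither volume records nor pair-change records")
  }
  if (length(unknown))
    warning(length(unknown), " excluded scan(s) not present in records")
  out <- records[!hit, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, n_removed = sum(hit),
       removed = records[hit, , drop = FALSE])
}
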