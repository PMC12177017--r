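# Logger and annotation CSV ingestion, UTC alignment, bout trimming.

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl(",", header, fixed = TRUE) && grepl(";", header, fixed = TRUE)) ";" else ","
}

parse_utc <- function(x, what, path) {
  if (is.numeric(x)) return(as.numeric(x))
  t <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  fallback <- is.na(t)
  if (any(fallback)) {
    t[fallback] <- as.POSIXct(x[fallback], format = "%Y-%m-%d %H:%M:%OS", tz = "UTC")
  }
  if (anyNA(t)) {
    stop(sprintf("could not parse %s timestamps in %s (first bad value: '%s')",
                 what, path, x[which(is.na(t))[1]]))
  }
  as.numeric(t)
}

#' Read a logger-style acceleration CSV
#'
#' Expects the dialect written by [write_fixture()]: header
#' `timestamp,ax_g,ay_g,az_g` with ISO-8601 UTC timestamps. Either comma or
#' semicolon delimiters are accepted (logger exports vary); the delimiter is
#' detected from the header line. The sampling rate is inferred from the
#' median timestep. Individual id and position are parsed from a filename of
#' the form `<id>_<position>.csv` unless supplied.
#'
#' @param path CSV file path.
#' @param individual_id,species,position Optional metadata overrides.
#' @return An [accel_trace()].
#' @export
read_accel_csv <- function(path, individual_id = NULL, species = "unknown",
                           position = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("timestamp", "ax_g", "ay_g", "az_g")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing columns in ", path, ": ", paste(missing, collapse = ", "))
  }
  t <- parse_utc(df$timestamp, "acceleration", path)
  dup <- which(diff(t) == 0)
  if (length(dup)) {
    stop(sprintf("duplicated timestamp at row %d of %s", dup[1] + 1L, path))
  }
  base <- sub("\\.csv$", "", basename(path), ignore.case = TRUE)
  if (is.null(position)) {
    position <- if (grepl("_scute1$", base)) "scute1"
                else if (grepl("_scute3$", base)) "scute3" else "scute3"
  }
  if (is.null(individual_id)) individual_id <- sub("_scute[13]$", "", base)
  rate <- 1 / stats::median(diff(t))
  accel_trace(individual_id = individual_id, species = species,
              position = position, t = t,
              ax = df$ax_g, ay = df$ay_g, az = df$az_g,
              sample_rate_hz = rate)
}

#' Read a behaviour annotation CSV
#'
#' Expects a BORIS-export-like dialect: header `behaviour,start_utc,stop_utc`
#' with ISO-8601 UTC (or numeric-seconds) bout boundaries. Bouts are sorted
#' by start and validated: a bout with `stop <= start` or a pair of
#' overlapping bouts is an error.
#'
#' @param path CSV file path.
#' @param individual_id Optional override; default parsed from
#'   `<id>_annotations.csv` (or the bare file stem).
#' @return An [annotation_set()].
#' @export
read_annotation_csv <- function(path, individual_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("behaviour", "start_utc", "stop_utc")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing columns in ", path, ": ", paste(missing, collapse = ", "))
  }
  if (is.null(individual_id)) {
    individual_id <- sub("_annotations$", "",
                         sub("\\.csv$", "", basename(path), ignore.case = TRUE))
  }
  annotation_set(
    individual_id = individual_id,
    bouts = data.frame(behaviour = as.character(df$behaviour),
                       start_utc = parse_utc(df$start_utc, "bout start", path),
                       stop_utc = parse_utc(df$stop_utc, "bout stop", path),
                       stringsAsFactors = FALSE))
}

#' Label a trace sample-by-sample from annotated bouts, trimming bout margins
#'
#' Samples with time in the half-open interval
#' `[start + trim_s, stop - trim_s)` of a bout receive that bout's behaviour;
#' all other samples are `NA`. The default `trim_s = 1` discards the first
#' and last second of every bout to absorb video-to-logger synchronisation
#' error, so a bout lasting `<= 2 * trim_s` contributes no labels. Samples
#' outside bouts are retained (as `NA`) so coverage can be reported.
#'
#' @param trace An [accel_trace()].
#' @param ann An [annotation_set()] for the same individual.
#' @param trim_s Seconds trimmed from each end of every bout (>= 0).
#' @return A [labeled_series()].
#' @export
align_labels <- function(trace, ann, trim_s = 1) {
  stopifnot(inherits(trace, "accel_trace"), inherits(ann, "annotation_set"))
  if (!identical(trace$individual_id, ann$individual_id)) {
    stop("trace and annotations belong to different individuals")
  }
  if (trim_s < 0) stop("trim_s must be >= 0")
  n <- length(trace$t)
  label <- rep(NA_character_, n)
  bout_id <- rep(NA_integer_, n)
  eps <- 1e-6  # absorbs double jitter on UTC-scale timestamps
  for (i in seq_len(nrow(ann$bouts))) {
    lo <- ann$bouts$start_utc[i] + trim_s
    hi <- ann$bouts$stop_utc[i] - trim_s
    if (hi - lo <= eps) next
    idx <- which(trace$t >= lo - eps & trace$t < hi - eps)
    label[idx] <- ann$bouts$behaviour[i]
    bout_id[idx] <- i
  }
  labeled_series(trace, label, bout_id)
}
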