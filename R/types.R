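# Core data containers. Plain validated S3 lists: traces and windows are
# ragged/heterogeneous, so a data.frame is the wrong container until the
# feature-table stage.

#' Construct a validated tri-axial acceleration trace
#'
#' @param individual_id,species,position Metadata labels; `position` is one of
#'   `"scute1"`, `"scute3"`.
#' @param t Sample times (UTC seconds), strictly increasing with a uniform
#'   step of `1/sample_rate_hz`.
#' @param ax,ay,az Acceleration (g) on the surge, sway and heave axes.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param dynamic_range_g Clip bound in g (`NA` if unknown).
#' @param resolution_bits Quantisation depth (`NA` if unknown).
#' @return An `accel_trace` object.
#' @export
accel_trace <- function(individual_id, species, position, t, ax, ay, az,
                        sample_rate_hz, dynamic_range_g = NA_real_,
                        resolution_bits = NA_integer_) {
  n <- length(t)
  if (length(ax) != n || length(ay) != n || length(az) != n) {
    stop("t, ax, ay, az must have equal length")
  }
  if (n > 1) {
    dt <- diff(t)
    if (any(dt <= 0)) {
      stop(sprintf("timestamps must be strictly increasing (first violation at row %d)",
                   which(dt <= 0)[1] + 1L))
    }
    # 2e-6 s absorbs double representation error of UTC-epoch timestamps
    # (ulp of ~1.7e9 is ~2.4e-7 s) on top of exact-step generation.
    if (max(dt) - min(dt) > 2e-6) {
      stop("timestamps must have a uniform step")
    }
  }
  if (!is.na(dynamic_range_g) &&
      max(abs(c(ax, ay, az))) > dynamic_range_g + 1e-9) {
    stop("acceleration exceeds the declared dynamic range")
  }
  structure(
    list(individual_id = individual_id, species = species, position = position,
         t = as.numeric(t), ax = as.numeric(ax), ay = as.numeric(ay),
         az = as.numeric(az), sample_rate_hz = sample_rate_hz,
         dynamic_range_g = dynamic_range_g, resolution_bits = resolution_bits),
    class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> %s/%s @ %s: %d samples, %g Hz, +/-%s g, %s bit\n",
              x$species, x$individual_id, x$position, length(x$t),
              x$sample_rate_hz, format(x$dynamic_range_g),
              format(x$resolution_bits)))
  invisible(x)
}

#' Construct a validated set of behaviour annotations
#'
#' Bouts are sorted by start time and must not overlap within an individual.
#'
#' @param individual_id Individual label.
#' @param bouts Data frame with columns `behaviour`, `start_utc`, `stop_utc`
#'   (UTC seconds).
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(individual_id, bouts) {
  stopifnot(is.data.frame(bouts),
            all(c("behaviour", "start_utc", "stop_utc") %in% names(bouts)))
  bad <- which(bouts$stop_utc <= bouts$start_utc)
  if (length(bad)) {
    stop(sprintf("bout %d ('%s') has stop_utc <= start_utc",
                 bad[1], bouts$behaviour[bad[1]]))
  }
  bouts <- bouts[order(bouts$start_utc), , drop = FALSE]
  rownames(bouts) <- NULL
  if (nrow(bouts) > 1) {
    ov <- which(bouts$start_utc[-1] < bouts$stop_utc[-nrow(bouts)] - 1e-9)
    if (length(ov)) {
      stop(sprintf("bouts %d ('%s') and %d ('%s') overlap",
                   ov[1], bouts$behaviour[ov[1]],
                   ov[1] + 1L, bouts$behaviour[ov[1] + 1L]))
    }
  }
  structure(list(individual_id = individual_id, bouts = bouts),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %s: %d bouts, %.1f s labelled\n",
              x$individual_id, nrow(x$bouts),
              sum(x$bouts$stop_utc - x$bouts$start_utc)))
  invisible(x)
}

#' Construct a labelled series (trace plus per-sample labels)
#'
#' @param trace An [accel_trace()].
#' @param label Character vector, one behaviour per sample (`NA` outside
#'   trimmed bouts).
#' @param bout_id Integer vector, one bout index per sample (`NA` likewise).
#' @return A `labeled_series` object.
#' @export
labeled_series <- function(trace, label, bout_id) {
  stopifnot(inherits(trace, "accel_trace"),
            length(label) == length(trace$t),
            length(bout_id) == length(trace$t))
  structure(list(trace = trace, label = label, bout_id = as.integer(bout_id)),
            class = "labeled_series")
}

#' @export
print.labeled_series <- function(x, ...) {
  n <- length(x$label)
  cat(sprintf("<labeled_series> %s/%s: %d samples, %.1f%% labelled, %d behaviours\n",
              x$trace$individual_id, x$trace$position, n,
              100 * mean(!is.na(x$label)),
              length(unique(stats::na.omit(x$label)))))
  invisible(x)
}

#' Construct a fixed-length single-behaviour window
#'
#' @param individual_id,species,position,behaviour Metadata labels.
#' @param window_s Window duration in seconds (1 or 2).
#' @param freq_hz Sampling rate of the samples held (Hz).
#' @param ax,ay,az Sample arrays (g).
#' @param t0 Window start time (UTC seconds).
#' @return A `labeled_window` object.
#' @export
labeled_window <- function(individual_id, species, position, behaviour,
                           window_s, freq_hz, ax, ay, az, t0) {
  stopifnot(length(ax) == length(ay), length(ay) == length(az))
  structure(
    list(individual_id = individual_id, species = species, position = position,
         behaviour = behaviour, window_s = window_s, freq_hz = freq_hz,
         ax = ax, ay = ay, az = az, t0 = t0),
    class = "labeled_window")
}

#' @export
print.labeled_window <- function(x, ...) {
  cat(sprintf("<labeled_window> %s '%s': %g s @ %g Hz (%d samples)\n",
              x$individual_id, x$behaviour, x$window_s, x$freq_hz,
              length(x$ax)))
  invisible(x)
}
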