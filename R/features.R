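# Per-window summary metrics: per-axis moments and extrema, ODBA, VeDBA,
# and posture (pitch/roll) statistics.

#' Canonical metric names, in serialisation order
#' @export
feature_names <- c(
  "mean_x", "mean_y", "mean_z",
  "sd_x", "sd_y", "sd_z",
  "min_x", "min_y", "min_z",
  "max_x", "max_y", "max_z",
  "odba", "vedba",
  "pitch_mean", "roll_mean", "pitch_sd", "roll_sd")

#' Split a window into static and dynamic acceleration
#'
#' The static (gravity/posture) component on each axis is the window mean,
#' held constant across the window — windows here are at most 2 s, matching
#' the usual smoothing horizon for dynamic-body-acceleration metrics. The
#' dynamic (movement) component is the remainder, so `static + dynamic`
#' reconstructs the input exactly.
#'
#' @param window A [labeled_window()].
#' @return `list(static = list(x, y, z), dynamic = list(x, y, z))`.
#' @export
static_dynamic_split <- function(window) {
  stopifnot(inherits(window, "labeled_window"))
  n <- length(window$ax)
  if (n < 1) stop("window is empty")
  mx <- mean(window$ax); my <- mean(window$ay); mz <- mean(window$az)
  list(
    static = list(x = rep(mx, n), y = rep(my, n), z = rep(mz, n)),
    dynamic = list(x = window$ax - mx, y = window$ay - my, z = window$az - mz))
}

#' Compute the 18 summary metrics of one window
#'
#' Per-axis mean, standard deviation (n-1 denominator), minimum and maximum
#' on the raw samples; ODBA (mean over samples of the L1 norm of the dynamic
#' component) and VeDBA (mean L2 norm); and posture statistics from the
#' per-sample pitch `atan2(ax, sqrt(ay^2 + az^2))` and roll `atan2(ay, az)`
#' in degrees (mean and SD over the window).
#'
#' @param window A [labeled_window()] with at least 2 samples.
#' @return Named numeric vector of length 18 (see [feature_names]).
#' @export
compute_features <- function(window) {
  stopifnot(inherits(window, "labeled_window"))
  n <- length(window$ax)
  if (n < 2) stop("window must have at least 2 samples (sd undefined)")
  x <- window$ax; y <- window$ay; z <- window$az
  dx <- x - mean(x); dy <- y - mean(y); dz <- z - mean(z)
  pitch <- atan2(x, sqrt(y^2 + z^2)) * 180 / pi
  roll <- atan2(y, z) * 180 / pi
  out <- c(
    mean_x = mean(x), mean_y = mean(y), mean_z = mean(z),
    sd_x = stats::sd(x), sd_y = stats::sd(y), sd_z = stats::sd(z),
    min_x = min(x), min_y = min(y), min_z = min(z),
    max_x = max(x), max_y = max(y), max_z = max(z),
    odba = mean(abs(dx) + abs(dy) + abs(dz)),
    vedba = mean(sqrt(dx^2 + dy^2 + dz^2)),
    pitch_mean = mean(pitch), roll_mean = mean(roll),
    pitch_sd = stats::sd(pitch), roll_sd = stats::sd(roll))
  if (!all(is.finite(out))) stop("non-finite metric value computed")
  out[feature_names]
}

#' Assemble a feature table from a homogeneous set of windows
#'
#' All windows must share one window length and one frequency (the analysis
#' fits separate models per window/frequency cell). Rows are ordered by
#' (individual, start time) so the table is deterministic.
#'
#' @param windows List of [labeled_window()] objects.
#' @return Data frame with metadata columns (`individual_id`, `species`,
#'   `position`, `window_s`, `freq_hz`, `behaviour`, `t0`, `.row_id`) followed
#'   by the 18 metrics. `.row_id` is a provenance tag used by the
#'   leakage guard in the classification stage.
#' @export
build_feature_table <- function(windows) {
  meta_cols <- c("individual_id", "species", "position", "window_s",
                 "freq_hz", "behaviour", "t0", ".row_id")
  if (length(windows) == 0) {
    empty <- as.data.frame(
      c(stats::setNames(list(character(0), character(0), character(0),
                             numeric(0), numeric(0), character(0),
                             numeric(0), integer(0)), meta_cols),
        stats::setNames(rep(list(numeric(0)), length(feature_names)),
                        feature_names)))
    return(empty)
  }
  ws <- unique(vapply(windows, `[[`, numeric(1), "window_s"))
  fz <- unique(vapply(windows, `[[`, numeric(1), "freq_hz"))
  if (length(ws) > 1) stop("mixed window lengths in one feature table")
  if (length(fz) > 1) stop("mixed frequencies in one feature table")
  feats <- t(vapply(windows, compute_features, numeric(length(feature_names))))
  meta <- data.frame(
    individual_id = vapply(windows, `[[`, character(1), "individual_id"),
    species = vapply(windows, `[[`, character(1), "species"),
    position = vapply(windows, `[[`, character(1), "position"),
    window_s = ws, freq_hz = fz,
    behaviour = vapply(windows, `[[`, character(1), "behaviour"),
    t0 = vapply(windows, `[[`, numeric(1), "t0"),
    stringsAsFactors = FALSE)
  out <- cbind(meta, as.data.frame(feats))
  out <- out[order(out$individual_id, out$t0), , drop = FALSE]
  out$.row_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c(meta_cols, feature_names)]
}
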