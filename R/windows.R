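# Window segmentation and downsampling.

supported_window_s <- c(1, 2)
supported_freq_hz <- c(100, 50, 25, 12, 10, 8, 4, 2)

#' Segment a labelled series into fixed-length single-behaviour windows
#'
#' Each labelled run (maximal stretch of consecutive samples sharing one bout)
#' is tiled from its start into consecutive non-overlapping windows of
#' `window_s` seconds at the native sampling rate; the trailing remainder
#' shorter than a full window is discarded. A behaviour whose every bout is
#' shorter than 2 s simply yields no 2-s windows, so short behaviours can
#' still be analysed at 1 s.
#'
#' @param series A [labeled_series()].
#' @param window_s Window length in seconds: 1 or 2.
#' @return List of [labeled_window()] objects (possibly empty).
#' @export
segment <- function(series, window_s) {
  stopifnot(inherits(series, "labeled_series"))
  if (!window_s %in% supported_window_s) {
    stop("window_s must be one of ", paste(supported_window_s, collapse = ", "))
  }
  tr <- series$trace
  rate <- tr$sample_rate_hz
  n_win <- round(window_s * rate)
  key <- ifelse(is.na(series$bout_id), -1L, series$bout_id)
  runs <- rle(key)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (r in seq_along(runs$values)) {
    if (runs$values[r] < 0) next
    run_len <- runs$lengths[r]
    k <- run_len %/% n_win
    if (k == 0) next
    behaviour <- series$label[starts[r]]
    for (j in seq_len(k)) {
      i0 <- starts[r] + (j - 1L) * n_win
      idx <- i0:(i0 + n_win - 1L)
      out[[length(out) + 1L]] <- labeled_window(
        individual_id = tr$individual_id, species = tr$species,
        position = tr$position, behaviour = behaviour,
        window_s = window_s, freq_hz = rate,
        ax = tr$ax[idx], ay = tr$ay[idx], az = tr$az[idx],
        t0 = tr$t[i0])
    }
  }
  out
}

#' Downsample a window to a target frequency
#'
#' Output samples are taken at times `t0 + k/target_hz`,
#' `k = 0 ... round(window_s * target_hz) - 1`, each mapped to the nearest
#' native sample (no anti-alias filter, preserving the logger's quantised
#' values); non-integer rate ratios (e.g. 100 to 12 Hz) are handled by
#' nearest-neighbour snapping on the target time grid.
#'
#' @param window A [labeled_window()].
#' @param target_hz Target rate; must not exceed the window's rate and must
#'   be in the supported set (100, 50, 25, 12, 10, 8, 4, 2).
#' @return A [labeled_window()] at `target_hz`.
#' @export
resample <- function(window, target_hz) {
  stopifnot(inherits(window, "labeled_window"))
  if (!target_hz %in% supported_freq_hz) {
    stop("target_hz must be one of ", paste(supported_freq_hz, collapse = ", "))
  }
  if (target_hz > window$freq_hz) {
    stop("upsampling requested: target_hz exceeds the window's rate")
  }
  n_out <- round(window$window_s * target_hz)
  k <- seq_len(n_out) - 1L
  j <- pmin(round(k * window$freq_hz / target_hz) + 1L, length(window$ax))
  labeled_window(
    individual_id = window$individual_id, species = window$species,
    position = window$position, behaviour = window$behaviour,
    window_s = window$window_s, freq_hz = target_hz,
    ax = window$ax[j], ay = window$ay[j], az = window$az[j],
    t0 = window$t0)
}
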