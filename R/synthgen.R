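# Synthetic labelled tri-axial accelerometer cohorts.
#
# Axis convention used throughout the package:
#   x = surge (anterior), y = sway (left), z = heave (dorsal).
# A motionless animal on a level substrate therefore reads (0, 0, 1) g.

#' Define one behaviour of a synthetic ethogram
#'
#' A behaviour is characterised by a mean body posture (pitch and roll of the
#' carapace relative to gravity), a dominant limb-beat oscillation applied on
#' the surge axis, independent Gaussian sensor/movement noise, and a bout
#' duration model (exponential with a floor, so every bout survives the
#' one-second trimming applied at labelling time).
#'
#' @param name Behaviour label.
#' @param pitch_deg Mean posture pitch in degrees (positive = nose up).
#' @param roll_deg Mean posture roll in degrees (positive = left side up).
#' @param osc_freq_hz Dominant limb-beat frequency in Hz; 0 for motionless
#'   behaviours.
#' @param osc_amp_g Oscillation amplitude in g (>= 0).
#' @param noise_sd_g Per-axis Gaussian noise SD in g (>= 0).
#' @param bout_mean_s Mean bout duration in seconds.
#' @param bout_min_s Minimum bout duration in seconds (>= 3 so that at least
#'   one one-second window survives trimming of the first and last second).
#' @return A `behaviour_spec` object.
#' @export
behaviour_spec <- function(name, pitch_deg = 0, roll_deg = 0,
                           osc_freq_hz = 0, osc_amp_g = 0,
                           noise_sd_g = 0.02,
                           bout_mean_s = 20, bout_min_s = 6) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (osc_amp_g < 0) stop("osc_amp_g must be >= 0")
  if (noise_sd_g < 0) stop("noise_sd_g must be >= 0")
  if (osc_freq_hz < 0) stop("osc_freq_hz must be >= 0")
  if (bout_min_s < 3) stop("bout_min_s must be >= 3 so trimmed bouts retain samples")
  if (bout_mean_s <= 0) stop("bout_mean_s must be positive")
  structure(
    list(name = name, pitch_deg = pitch_deg, roll_deg = roll_deg,
         osc_freq_hz = osc_freq_hz, osc_amp_g = osc_amp_g,
         noise_sd_g = noise_sd_g, bout_mean_s = bout_mean_s,
         bout_min_s = bout_min_s),
    class = "behaviour_spec")
}

#' Default five-behaviour synthetic ethogram
#'
#' A compact captive-turtle-like repertoire. Each behaviour carries a distinct
#' posture/oscillation signature; `swim` and `slow_swim` share a similar
#' nose-down swimming posture and are separated mainly by limb-beat amplitude,
#' which is the cue most degraded by an unfavourable tag placement. All
#' oscillation frequencies are at or below 1 Hz (slow sea-turtle limb beats),
#' so a 2 Hz sampling rate still satisfies Nyquist.
#'
#' @return List of [behaviour_spec()] objects.
#' @export
default_ethogram <- function() {
  list(
    behaviour_spec("rest",      pitch_deg = 0,   roll_deg = 0,
                   osc_freq_hz = 0,   osc_amp_g = 0,    noise_sd_g = 0.03,
                   bout_mean_s = 40, bout_min_s = 10),
    behaviour_spec("swim",      pitch_deg = -30, roll_deg = 0,
                   osc_freq_hz = 0.8, osc_amp_g = 0.45, noise_sd_g = 0.05,
                   bout_mean_s = 30, bout_min_s = 8),
    behaviour_spec("slow_swim", pitch_deg = -20, roll_deg = 0,
                   osc_freq_hz = 0.7, osc_amp_g = 0.12, noise_sd_g = 0.05,
                   bout_mean_s = 25, bout_min_s = 8),
    behaviour_spec("breathe",   pitch_deg = 45,  roll_deg = 0,
                   osc_freq_hz = 0.4, osc_amp_g = 0.20, noise_sd_g = 0.05,
                   bout_mean_s = 12, bout_min_s = 6),
    behaviour_spec("scratch",   pitch_deg = 0,   roll_deg = 45,
                   osc_freq_hz = 0.9, osc_amp_g = 0.30, noise_sd_g = 0.06,
                   bout_mean_s = 15, bout_min_s = 6))
}

#' Configure a synthetic cohort
#'
#' Describes the recording campaign the simulator emulates: number of
#' individuals, ethogram, behaviour-to-behaviour transition weights, recording
#' duration, logger settings (sampling rate, dynamic range, bit depth), the
#' tag-position effect, and between-individual variation.
#'
#' @param species Cohort label.
#' @param n_individuals Number of individuals (>= 4 so the rare-behaviour
#'   filter is exercisable).
#' @param behaviours List of [behaviour_spec()] objects.
#' @param transition_weights Square non-negative matrix over behaviours with
#'   zero diagonal and positive row sums; `NULL` gives uniform off-diagonal
#'   weights.
#' @param duration_s Recording length per individual in seconds; must be at
#'   least twice the largest `bout_mean_s`.
#' @param sample_rate_hz Base sampling rate (Hz, even).
#' @param dynamic_range_g Clip bound of the analogue-to-digital conversion
#'   (g); loggers of this class use 2 or 4.
#' @param resolution_bits Quantisation depth (bits).
#' @param position_effect Named list with entries `scute1` and `scute3`, each
#'   `list(gain=, noise_sd_g=)`. The gain multiplies the dynamic (limb-beat)
#'   component only — gravity is unaffected by placement — and the noise SD is
#'   added on every axis. The default degrades the first-scute placement
#'   (gain 0.5, extra noise 0.1 g) relative to a clean third scute.
#' @param individual_sd Between-individual SD on log oscillation amplitude.
#' @param seed Integer base seed.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(species = "synthetic_turtle",
                          n_individuals = 8,
                          behaviours = default_ethogram(),
                          transition_weights = NULL,
                          duration_s = 360,
                          sample_rate_hz = 100,
                          dynamic_range_g = 2,
                          resolution_bits = 8,
                          position_effect = list(
                            scute1 = list(gain = 0.5, noise_sd_g = 0.1),
                            scute3 = list(gain = 1.0, noise_sd_g = 0.0)),
                          individual_sd = 0.1,
                          seed = 1L) {
  stopifnot(length(behaviours) >= 1L)
  for (b in behaviours) {
    if (!inherits(b, "behaviour_spec")) stop("behaviours must be behaviour_spec objects")
  }
  k <- length(behaviours)
  if (is.null(transition_weights)) {
    transition_weights <- matrix(1, k, k)
    diag(transition_weights) <- 0
    if (k == 1L) transition_weights <- matrix(1, 1, 1)  # self-loop degenerate case
  }
  if (!is.matrix(transition_weights) ||
      nrow(transition_weights) != ncol(transition_weights)) {
    stop("transition_weights must be a square matrix")
  }
  if (nrow(transition_weights) != k) {
    stop("transition_weights dimension must match the number of behaviours")
  }
  if (any(transition_weights < 0)) stop("transition_weights must be non-negative")
  if (any(rowSums(transition_weights) <= 0)) stop("transition_weights rows must have positive sum")
  if (n_individuals < 4) stop("n_individuals must be >= 4")
  if (sample_rate_hz %% 2 != 0) stop("sample_rate_hz must be divisible by 2")
  if (duration_s < 2 * max(vapply(behaviours, `[[`, 1, "bout_mean_s"))) {
    stop("duration_s too short: must be at least twice the largest bout_mean_s")
  }
  if (!all(c("scute1", "scute3") %in% names(position_effect))) {
    stop("position_effect must name scute1 and scute3")
  }
  structure(
    list(species = species, n_individuals = as.integer(n_individuals),
         behaviours = behaviours, transition_weights = transition_weights,
         duration_s = duration_s, sample_rate_hz = sample_rate_hz,
         dynamic_range_g = dynamic_range_g,
         resolution_bits = as.integer(resolution_bits),
         position_effect = position_effect,
         individual_sd = individual_sd, seed = as.integer(seed)),
    class = "cohort_config")
}

behaviour_names <- function(config) {
  vapply(config$behaviours, `[[`, character(1), "name")
}

# Recording start epoch for synthetic traces (UTC seconds).
.ethoacc_epoch <- as.numeric(as.POSIXct("2024-01-01 00:00:00", tz = "UTC"))

# Deterministic derived seed kept inside 32-bit range.
derive_seed <- function(seed, salt) {
  as.integer((as.double(seed) * 69069 + salt) %% 2147483647)
}

quantise_clip <- function(x, dynamic_range_g, resolution_bits) {
  step <- 2 * dynamic_range_g / (2^resolution_bits - 1)
  q <- round(x / step) * step
  pmin(pmax(q, -dynamic_range_g), dynamic_range_g)
}

# Draw a semi-Markov behaviour sequence tiling [0, duration_s).
draw_bout_sequence <- function(config) {
  k <- length(config$behaviours)
  w <- config$transition_weights
  means <- vapply(config$behaviours, `[[`, 1, "bout_mean_s")
  mins <- vapply(config$behaviours, `[[`, 1, "bout_min_s")
  state <- sample.int(k, 1L)
  states <- integer(0)
  lens <- numeric(0)
  total <- 0
  while (total < config$duration_s) {
    len <- max(mins[state], stats::rexp(1L, rate = 1 / means[state]))
    if (total + len > config$duration_s) len <- config$duration_s - total
    states <- c(states, state)
    lens <- c(lens, len)
    total <- total + len
    if (k > 1L) {
      state <- sample.int(k, 1L, prob = w[state, ])
    }
  }
  data.frame(state = states, duration = lens)
}

#' Simulate one individual at one tag position
#'
#' Draws a semi-Markov behaviour sequence (next behaviour proportional to the
#' transition-weight row; bout lengths exponential with a per-behaviour floor)
#' and synthesises the tri-axial signal sample by sample: the gravity unit
#' vector rotated to the behaviour's posture, plus a sinusoidal limb-beat
#' oscillation on the surge axis, plus independent Gaussian noise, then the
#' tag-position effect (dynamic gain and extra noise), and finally
#' quantisation to the logger's bit depth and clipping at the dynamic range.
#'
#' The behaviour sequence, the per-individual amplitude multiplier, and the
#' base noise stream depend only on `seed`, never on `position`, so the two
#' placements of one individual record the same underlying activity and
#' differ only through the position effect.
#'
#' @param config A [cohort_config()].
#' @param individual_id Individual label.
#' @param position `"scute1"` or `"scute3"`.
#' @param seed Integer seed for this individual.
#' @return `list(trace = accel_trace, annotations = annotation_set)`.
#' @export
simulate_individual <- function(config, individual_id, position, seed) {
  stopifnot(inherits(config, "cohort_config"))
  position <- match.arg(position, c("scute1", "scute3"))
  rate <- config$sample_rate_hz
  n <- round(config$duration_s * rate)
  if (n < 1) stop("duration too short to place a single sample")

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)

  # Position-independent draws: bout sequence, amplitude multiplier, base noise.
  set.seed(derive_seed(seed, 1L))
  bouts <- draw_bout_sequence(config)
  amp_mult <- exp(stats::rnorm(1L, 0, config$individual_sd))
  base_noise <- matrix(stats::rnorm(3L * n), n, 3L)

  # Position-specific extra noise stream.
  pos_idx <- match(position, c("scute1", "scute3"))
  set.seed(derive_seed(seed, 100L + pos_idx))
  extra_noise <- matrix(stats::rnorm(3L * n), n, 3L)

  eff <- config$position_effect[[position]]
  t_rel <- (seq_len(n) - 1L) / rate
  ax <- numeric(n); ay <- numeric(n); az <- numeric(n)

  start <- 0
  starts <- numeric(nrow(bouts)); stops <- numeric(nrow(bouts))
  for (i in seq_len(nrow(bouts))) {
    b <- config$behaviours[[bouts$state[i]]]
    stop_t <- start + bouts$duration[i]
    idx <- which(t_rel >= start - 1e-9 & t_rel < stop_t - 1e-9)
    p <- b$pitch_deg * pi / 180
    r <- b$roll_deg * pi / 180
    sx <- sin(p); sy <- cos(p) * sin(r); sz <- cos(p) * cos(r)
    amp <- b$osc_amp_g * amp_mult * eff$gain
    osc <- if (b$osc_freq_hz > 0 && amp > 0) {
      amp * sin(2 * pi * b$osc_freq_hz * t_rel[idx])
    } else 0
    ax[idx] <- sx + osc + b$noise_sd_g * base_noise[idx, 1L]
    ay[idx] <- sy + b$noise_sd_g * base_noise[idx, 2L]
    az[idx] <- sz + b$noise_sd_g * base_noise[idx, 3L]
    starts[i] <- start; stops[i] <- stop_t
    start <- stop_t
  }
  if (eff$noise_sd_g > 0) {
    ax <- ax + eff$noise_sd_g * extra_noise[, 1L]
    ay <- ay + eff$noise_sd_g * extra_noise[, 2L]
    az <- az + eff$noise_sd_g * extra_noise[, 3L]
  }

  ax <- quantise_clip(ax, config$dynamic_range_g, config$resolution_bits)
  ay <- quantise_clip(ay, config$dynamic_range_g, config$resolution_bits)
  az <- quantise_clip(az, config$dynamic_range_g, config$resolution_bits)

  t0 <- .ethoacc_epoch
  trace <- accel_trace(
    individual_id = individual_id, species = config$species,
    position = position, t = t0 + t_rel, ax = ax, ay = ay, az = az,
    sample_rate_hz = rate, dynamic_range_g = config$dynamic_range_g,
    resolution_bits = config$resolution_bits)
  ann <- annotation_set(
    individual_id = individual_id,
    bouts = data.frame(
      behaviour = behaviour_names(config)[bouts$state],
      start_utc = t0 + starts, stop_utc = t0 + stops,
      stringsAsFactors = FALSE))
  list(trace = trace, annotations = ann)
}

#' Simulate a full cohort (every individual at both tag positions)
#'
#' The two positions of one individual share the same behaviour sequence,
#' amplitude multiplier, and base noise stream, so with a null position effect
#' (`gain = 1`, `noise_sd_g = 0`) the two traces are identical. Per-individual
#' lognormal multipliers (SD `individual_sd` on the log scale) scale the
#' oscillation amplitudes.
#'
#' @param config A [cohort_config()].
#' @return `list(traces = <2 n traces>, annotations = <n annotation sets>)`;
#'   traces are named `<id>_<position>`, annotations `<id>`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  traces <- list(); annotations <- list()
  for (i in seq_len(config$n_individuals)) {
    id <- sprintf("ind%02d", i)
    ind_seed <- derive_seed(config$seed, 7919L * i)
    for (pos in c("scute1", "scute3")) {
      sim <- simulate_individual(config, id, pos, ind_seed)
      traces[[paste(id, pos, sep = "_")]] <- sim$trace
      if (pos == "scute1") annotations[[id]] <- sim$annotations
    }
  }
  list(traces = traces, annotations = annotations)
}

#' Write a cohort to logger-style fixture files
#'
#' One acceleration CSV per trace (`<id>_<position>.csv`, header
#' `timestamp,ax_g,ay_g,az_g`, ISO-8601 UTC timestamps at millisecond
#' precision) and one annotation CSV per individual (`<id>_annotations.csv`,
#' header `behaviour,start_utc,stop_utc`), in the dialects read by
#' [read_accel_csv()] and [read_annotation_csv()].
#'
#' @param traces List of `accel_trace` objects.
#' @param annotations List of `annotation_set` objects.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the character vector of files written.
#' @export
write_fixture <- function(traces, annotations, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  fmt_utc <- function(t) {
    # millisecond strings built by hand: format(.., "%OS3") truncates rather
    # than rounds, which corrupts exact 10 ms steps
    ms_total <- round(t * 1000)
    secs <- ms_total %/% 1000
    ms <- ms_total %% 1000
    paste0(format(as.POSIXct(secs, origin = "1970-01-01", tz = "UTC"),
                  "%Y-%m-%dT%H:%M:%S"),
           sprintf(".%03dZ", ms))
  }
  for (tr in traces) {
    path <- file.path(out_dir, sprintf("%s_%s.csv", tr$individual_id, tr$position))
    df <- data.frame(timestamp = fmt_utc(tr$t),
                     ax_g = sprintf("%.6f", tr$ax),
                     ay_g = sprintf("%.6f", tr$ay),
                     az_g = sprintf("%.6f", tr$az))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    paths <- c(paths, path)
  }
  for (ann in annotations) {
    path <- file.path(out_dir, sprintf("%s_annotations.csv", ann$individual_id))
    df <- data.frame(behaviour = ann$bouts$behaviour,
                     start_utc = fmt_utc(ann$bouts$start_utc),
                     stop_utc = fmt_utc(ann$bouts$stop_utc))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
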