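# Shared fixture builders; everything is generated in code at test time.

# A bare window holding the given signal arrays.
make_window <- function(ax, ay = rep(0, length(ax)), az = rep(1, length(ax)),
                        window_s = 2, freq_hz = length(ax) / window_s,
                        behaviour = "test", individual_id = "indA",
                        position = "scute3") {
  labeled_window(individual_id = individual_id, species = "sp",
                 position = position, behaviour = behaviour,
                 window_s = window_s, freq_hz = freq_hz,
                 ax = ax, ay = ay, az = az, t0 = 0)
}

# A constant-signal trace at `rate` Hz lasting `duration_s` seconds.
make_trace <- function(duration_s, rate, ax = 0, ay = 0, az = 1,
                       individual_id = "indA", position = "scute3", t0 = 0) {
  n <- round(duration_s * rate)
  t <- t0 + (seq_len(n) - 1) / rate
  accel_trace(individual_id = individual_id, species = "sp",
              position = position, t = t,
              ax = rep(ax, n), ay = rep(ay, n), az = rep(az, n),
              sample_rate_hz = rate)
}

make_annotations <- function(individual_id, behaviour, start, stop) {
  annotation_set(individual_id,
                 data.frame(behaviour = behaviour, start_utc = start,
                            stop_utc = stop, stringsAsFactors = FALSE))
}

# Mathematical (half-up) rounding, the convention of the labelled-sample
# counting rule; base::round() rounds half to even.
round_half_up <- function(x) floor(x + 0.5)

# A one-behaviour, noise-free cohort configuration for closed-form checks.
single_behaviour_config <- function(pitch_deg = 0, roll_deg = 0,
                                    osc_freq_hz = 0, osc_amp_g = 0,
                                    noise_sd_g = 0, duration_s = 10,
                                    sample_rate_hz = 100,
                                    dynamic_range_g = 2,
                                    resolution_bits = 8L, seed = 1L) {
  cohort_config(
    n_individuals = 4,
    behaviours = list(behaviour_spec(
      "only", pitch_deg = pitch_deg, roll_deg = roll_deg,
      osc_freq_hz = osc_freq_hz, osc_amp_g = osc_amp_g,
      noise_sd_g = noise_sd_g, bout_mean_s = duration_s / 2,
      bout_min_s = 3)),
    duration_s = duration_s, sample_rate_hz = sample_rate_hz,
    dynamic_range_g = dynamic_range_g, resolution_bits = resolution_bits,
    position_effect = list(scute1 = list(gain = 1, noise_sd_g = 0),
                           scute3 = list(gain = 1, noise_sd_g = 0)),
    individual_sd = 0, seed = seed)
}

# A small separable feature table: `k` classes offset in mean_x/mean_y,
# spread across `n_ind` individuals, `per` rows per class per individual.
make_separable_table <- function(k = 3, n_ind = 6, per = 8, noise = 0.02,
                                 seed = 1) {
  set.seed(seed)
  rows <- list()
  rid <- 0L
  for (ind in seq_len(n_ind)) {
    for (cls in seq_len(k)) {
      for (r in seq_len(per)) {
        rid <- rid + 1L
        feat <- stats::setNames(stats::rnorm(length(feature_names), 0, noise),
                                feature_names)
        feat["mean_x"] <- feat["mean_x"] + cls
        feat["mean_y"] <- feat["mean_y"] - cls
        rows[[rid]] <- data.frame(
          individual_id = sprintf("ind%02d", ind), species = "sp",
          position = "scute3", window_s = 2, freq_hz = 2,
          behaviour = paste0("beh", cls), t0 = rid, .row_id = rid,
          as.list(feat), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
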