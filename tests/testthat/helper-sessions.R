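# Shared fixtures, built in code.

# A small uniformly sampled session data frame with plausible values.
make_samples <- function(n = 100, fs = 100) {
  t <- (seq_len(n) - 1) / fs
  data.frame(
    t_ms = t * 1000,
    acc_x = 0.05 * sin(2 * pi * 0.2 * t), acc_y = 0.1 * cos(2 * pi * 0.2 * t),
    acc_z = 1 + 0.02 * sin(2 * pi * 0.3 * t),
    gyro_x = sin(t), gyro_y = cos(t), gyro_z = 0 * t,
    mag_x = 0.3 + 0 * t, mag_y = 0 * t, mag_z = 0.35 + 0 * t,
    pitch = 5 * sin(2 * pi * 0.5 * t), roll = 10 * sin(2 * pi * 0.4 * t),
    heading = (90 + 2 * t) %% 360)
}

make_session <- function(n = 100, fs = 100) {
  imu_session(make_samples(n, fs), fs = fs)
}

# Standard mixed-style acceptance session layouts: silent (bucket/cross-over)
# turns are kept a minority of boundaries, as in real swims where they occur
# only at backstroke walls.
mixed_session_spec <- function(seed, variant = c("six", "eight")) {
  variant <- match.arg(variant)
  if (variant == "six") {
    session_spec(
      lapply(c("front_crawl", "backstroke", "backstroke", "breaststroke",
               "butterfly", "front_crawl"), lap_spec),
      events = c("tumble", "bucket", "open", "stop", "tumble"),
      seed = seed)
  } else {
    session_spec(
      lapply(c("front_crawl", "backstroke", "backstroke", "backstroke",
               "breaststroke", "butterfly", "front_crawl", "backstroke"),
             lap_spec),
      events = c("tumble", "bucket", "crossover", "open", "stop", "tumble",
                 "tumble"),
      seed = seed)
  }
}

# Labeled energy-feature corpus from the generator (three prone styles).
make_feature_corpus <- function(n_per_class = 20, noise = default_noise()) {
  styles <- rep(c("butterfly", "breaststroke", "front_crawl"),
                each = n_per_class)
  feats <- t(vapply(styles, function(st) {
    l <- generate_lap(lap_spec(st), 100,
                      noise_sd_deg = noise$deg, noise_sd_g = noise$g)
    extract_features(l$signals[, c("acc_x", "acc_y", "acc_z")], 100)
  }, numeric(3)))
  rownames(feats) <- NULL
  list(features = feats, labels = styles)
}
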