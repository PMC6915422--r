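# Exhaustive DTW: enumerate every monotone warping path, take the cheapest.
dtw_enumerate <- function(a, b) {
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + (a[i] - b[j])^2
    if (acc >= best) return()
    if (i == length(a) && j == length(b)) { best <<- acc; return() }
    if (i < length(a)) walk(i + 1, j, acc)
    if (j < length(b)) walk(i, j + 1, acc)
    if (i < length(a) && j < length(b)) walk(i + 1, j + 1, acc)
  }
  walk(1, 1, 0)
  sqrt(best)
}

test_that("k-sigma band mask marks large deflections", {
  set.seed(3)
  x <- rnorm(20000)
  frac <- mean(band_mask(x, 2))
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
  expect_false(any(band_mask(rep(2, 100), 1)))
  x2 <- c(1, 1, 1, 3)
  expect_equal(band_mask(x2, 0), x2 != mean(x2))
  expect_error(band_mask(1, 2), "2 samples")
  # brute-force equivalence
  for (i in 1:1000) {
    x <- rnorm(sample(2:50, 1), sd = runif(1, 0.1, 10))
    k <- runif(1, 0, 3)
    expect_identical(band_mask(x, k), abs(x - mean(x)) > k * sd(x))
  }
})

test_that("roll-peak strokes respect both gates", {
  fs <- 100
  t <- (0:2999) / fs
  pars <- counting_params()
  # sinusoidal roll with a style k below sqrt(2): every extremum counts
  pars_k1 <- counting_params(k_by_style = c(front_crawl = 1,
                                            backstroke = 2.36,
                                            breaststroke = 0.74,
                                            butterfly = 1.34))
  out <- detect_roll_strokes(30 * sin(2 * pi * t / 3), fs, "front_crawl",
                             pars_k1)
  expect_equal(nrow(out$events), 20)  # 10 maxima + 10 minima
  expect_equal(sum(out$events$polarity == "max"), 10)

  # below the 20-degree minimum rotation: nothing counts
  out2 <- detect_roll_strokes(10 * sin(2 * pi * t / 3), fs, "front_crawl",
                              pars_k1)
  expect_equal(nrow(out2$events), 0)

  # flat roll with one 35-degree blip: exactly one stroke
  blip <- numeric(3000)
  blip[1450:1550] <- 35 * sin(pi * (0:100) / 100)
  out3 <- detect_roll_strokes(blip, fs, "front_crawl", pars)
  expect_equal(nrow(out3$events), 1)
  expect_equal(out3$events$t, 15, tolerance = 0.05)
  expect_error(detect_roll_strokes(rnorm(30), fs, "front_crawl", pars),
               "shorter")
})

test_that("pitch cycles span consecutive surviving minima", {
  fs <- 100
  l <- generate_lap(lap_spec("breaststroke", n_strokes = 8), fs)
  det <- detect_pitch_cycles(l$signals$pitch, fs, "breaststroke")
  expect_equal(nrow(det$cycles), 8)
  expect_equal(ncol(det$resampled), 200)
  expect_false(anyNA(det$resampled))
  expect_equal(det$cycles$end_t - det$cycles$start_t, rep(2, 8),
               tolerance = 0.05)
  # monotone pitch: no cycles
  mono <- detect_pitch_cycles(seq(-30, 30, length.out = 1000), fs,
                              "butterfly")
  expect_equal(nrow(mono$cycles), 0)
})

test_that("the mean wave is the central half of the cycle average", {
  one <- sin(pi * seq(0, 1, length.out = 200))
  tmpl <- build_mean_wave(rbind(one, one, one))
  expect_length(tmpl$wave, 100)
  expect_equal(tmpl$wave, one[51:150], ignore_attr = TRUE)
  tmpl2 <- build_mean_wave(rbind(one, -one))
  expect_equal(tmpl2$wave, rep(0, 100), ignore_attr = TRUE)
  expect_error(build_mean_wave(matrix(numeric(0), 0, 200)), "one cycle")
})

test_that("DTW distance matches exhaustive path enumeration", {
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dtw_distance(c(0, 0), c(1, 1)), sqrt(2))
  expect_error(dtw_distance(numeric(0), 1), "empty")
  set.seed(17)
  for (i in 1:1000) {
    a <- rnorm(sample(1:6, 1), sd = 2)
    b <- rnorm(sample(1:6, 1), sd = 2)
    d <- dtw_distance(a, b)
    expect_equal(d, dtw_enumerate(a, b))
    expect_equal(d, dtw_distance(b, a))
    expect_gte(d, 0)
  }
})

test_that("template rejection discards distorted cycles only", {
  set.seed(23)
  base <- 30 * sin(pi * seq(0, 1, length.out = 200))
  cycles <- t(vapply(1:8, function(i) base + rnorm(200, 0, 0.5),
                     numeric(200)))
  tmpl <- build_mean_wave(cycles)
  keep_all <- reject_outlier_cycles(cycles, tmpl)
  expect_true(all(keep_all$keep))

  # a half-amplitude, phase-shifted turn-approach artifact
  art <- 15 * sin(pi * seq(0, 1, length.out = 200) + 0.9) + rnorm(200, 0, 0.5)
  with_art <- rbind(cycles, art)
  tmpl2 <- build_mean_wave(with_art)
  rej <- reject_outlier_cycles(with_art, tmpl2)
  expect_equal(which(!rej$keep), 9)

  # infinite threshold keeps everything
  expect_true(all(reject_outlier_cycles(with_art, tmpl2, Inf)$keep))
})

test_that("noise-free laps count exactly for all four styles", {
  for (st in SWIM_STYLES) {
    l <- generate_lap(lap_spec(st), 100)
    cnt <- count_strokes(l$signals$pitch, l$signals$roll, 100, st)
    expect_equal(cnt$count, l$truth$n_strokes)
    expect_equal(cnt$stroke_times, l$truth$stroke_times, tolerance = 0.15)
  }
  empty <- count_strokes(numeric(0), numeric(0), 100, "front_crawl")
  expect_equal(empty$count, 0)
})

test_that("counts are monotone non-increasing in k and min rotation", {
  set.seed(37)
  nz <- default_noise()
  for (st in c("front_crawl", "backstroke", "breaststroke", "butterfly")) {
    l <- generate_lap(lap_spec(st), 100, noise_sd_deg = nz$deg)
    counts_k <- vapply(c(0.5, 1, 1.5, 2, 2.5, 3, 4), function(k) {
      pars <- counting_params(k_by_style = setNames(rep(k, 4), SWIM_STYLES))
      count_strokes(l$signals$pitch, l$signals$roll, 100, st, pars)$count
    }, numeric(1))
    expect_true(all(diff(counts_k) <= 0))
  }
  l <- generate_lap(lap_spec("front_crawl"), 100, noise_sd_deg = nz$deg)
  counts_r <- vapply(c(5, 15, 25, 35, 44, 60), function(r) {
    pars <- counting_params(min_rotation_deg = r)
    count_strokes(l$signals$pitch, l$signals$roll, 100, "front_crawl",
                  pars)$count
  }, numeric(1))
  expect_true(all(diff(counts_r) <= 0))
})
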