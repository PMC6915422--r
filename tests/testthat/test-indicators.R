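# Naive re-tabulation of the confusion matrix via a distance matrix.
accuracy_brute <- function(detected, truth, rejected = numeric(0),
                           tol = 0.3) {
  detected <- sort(detected); truth <- sort(truth)
  D <- outer(detected, truth, function(a, b) abs(a - b))
  tp <- 0
  if (length(detected) && length(truth)) {
    for (i in seq_along(detected)) {
      if (!any(is.finite(D[i, ]))) next
      j <- which.min(D[i, ])
      if (D[i, j] <= tol) {
        tp <- tp + 1
        D[, j] <- Inf
      }
    }
  }
  fp <- length(detected) - tp
  fn <- length(truth) - tp
  tn <- sum(vapply(rejected, function(r) {
    !length(truth) || min(abs(truth - r)) > tol
  }, logical(1)))
  if (tp + fp + fn + tn == 0) 1 else (tp + tn) / (tp + fp + fn + tn)
}

test_that("stroke rate is strokes per minute of lap time", {
  expect_equal(stroke_rate(20, 30), 40)
  expect_equal(stroke_rate(0, 30), 0)
  expect_equal(stroke_rate(8, 24), 20)
  expect_error(stroke_rate(5, 0), "positive")
})

test_that("trunk elevation is per-cycle pitch range, symmetric styles only", {
  cyc <- data.frame(pitch_min = c(-10, -12), pitch_max = c(25, 23))
  te <- trunk_elevation(cyc, "breaststroke")
  expect_equal(te$mean, 35)
  expect_equal(te$sd, 0)
  expect_null(trunk_elevation(cyc, "front_crawl"))
  expect_error(trunk_elevation(cyc[0, ], "butterfly"), "cycle")
})

test_that("body balance follows the dominant pitch component per style", {
  bb <- body_balance(rep(0, 100), "front_crawl")
  expect_equal(bb$mean, 0)
  expect_equal(bb$sd, 0)
  # undulation of +/-30 about -5: per-cycle max near 25, min near -35
  l <- generate_lap(lap_spec("breaststroke", pitch_amplitude = 30,
                             pitch_offset = -5), 100)
  det <- detect_pitch_cycles(l$signals$pitch, 100, "breaststroke")
  bb2 <- body_balance(l$signals$pitch, "breaststroke", det$cycles)
  expect_equal(bb2$mean[bb2$role == "max"], 25, tolerance = 0.5)
  expect_equal(bb2$mean[bb2$role == "min"], -35, tolerance = 0.5)
  # single cycle: zero sd in both roles
  bb3 <- body_balance(l$signals$pitch, "butterfly",
                      det$cycles[1, , drop = FALSE])
  expect_equal(bb3$sd, c(0, 0))
})

test_that("body rotation reports per-side stroke peaks or overall mean", {
  br <- body_rotation(rep(0, 50), "breaststroke")
  expect_equal(br$mean, 0)
  ev <- data.frame(peak_value = c(45.2, -44.8, 45.1, -45.3),
                   polarity = c("max", "min", "max", "min"))
  br2 <- body_rotation(rnorm(100), "front_crawl", ev)
  expect_equal(br2$mean[br2$role == "max"], 45.15)
  expect_equal(br2$mean[br2$role == "min"], -45.05)
  # asymmetric rotation shows up as unequal side means
  ev3 <- data.frame(peak_value = c(50, -30, 51, -29),
                    polarity = c("max", "min", "max", "min"))
  br3 <- body_rotation(rnorm(100), "backstroke", ev3)
  expect_gt(abs(br3$mean[br3$role == "max"]) -
              abs(br3$mean[br3$role == "min"]), 15)
})

test_that("detection accuracy tabulates the confusion matrix", {
  a <- detection_accuracy(1:10, 1:10)
  expect_equal(a$accuracy, 1)
  expect_equal(detection_accuracy(numeric(0), numeric(0))$accuracy, 1)
  # 9 matched of 10 true, none spurious
  a2 <- detection_accuracy((1:9) + 0.1, 1:10)
  expect_equal(a2$accuracy, 0.9)
  expect_equal(a2$fn, 1)
  # 10 detections, 2 beyond tolerance: TP 8, FP 2, FN 2
  a3 <- detection_accuracy(c(1:8, 9.5, 10.5), 1:10)
  expect_equal(c(a3$tp, a3$fp, a3$fn), c(8, 2, 2))
  expect_equal(a3$accuracy, 8 / 12)
  # rejected candidates away from truth count as true negatives
  a4 <- detection_accuracy(1:5, 1:5, rejected = c(7, 8))
  expect_equal(a4$tn, 2)
  expect_equal(a4$accuracy, 1)
})

test_that("detection accuracy matches a naive re-tabulation", {
  set.seed(71)
  for (i in 1:1000) {
    truth <- sort(runif(sample(0:20, 1), 0, 30))
    detected <- sort(c(truth[runif(length(truth)) < 0.8] +
                         rnorm(1, 0, 0.1),
                       runif(sample(0:3, 1), 0, 30)))
    rejected <- runif(sample(0:5, 1), 0, 30)
    a <- detection_accuracy(detected, truth, rejected)
    expect_equal(a$accuracy, accuracy_brute(detected, truth, rejected))
  }
})

test_that("session analysis produces the full indicator layout", {
  set.seed(81)
  corp <- make_feature_corpus(15)
  model <- train_style_model(corp$features, corp$labels, kind = "svm")
  spec <- session_spec(lapply(SWIM_STYLES, lap_spec),
                       events = c("tumble", "open", "tumble"), seed = 19)
  gs <- generate_session(spec)
  rpt <- analyze_session(gs$session, model)
  expect_s3_class(rpt, "session_report")
  expect_equal(nrow(rpt$laps), 4)
  expect_equal(rpt$laps$style, gs$truth$laps$style)
  expect_equal(rpt$laps$stroke_count, gs$truth$laps$n_strokes)

  # trunk elevation present iff symmetrical (n.a otherwise)
  sym <- rpt$laps$style %in% SYMMETRIC_STYLES
  expect_true(all(is.finite(rpt$laps$trunk_elev_mean[sym])))
  expect_true(all(is.na(rpt$laps$trunk_elev_mean[!sym])))
  # dominant-component min/max pattern
  expect_true(all(is.finite(rpt$laps$balance_max_mean[sym])))
  expect_true(all(is.na(rpt$laps$balance_max_mean[!sym])))
  expect_true(all(is.finite(rpt$laps$rotation_max_mean[!sym])))
  expect_true(all(is.na(rpt$laps$rotation_max_mean[sym])))

  # aggregates are recomputable from the lap table
  expect_equal(summarize_styles(rpt$laps), rpt$style_summary)
  bs_block <- rpt$style_summary[rpt$style_summary$style == "backstroke", ]
  expect_false("trunk_elevation" %in% bs_block$indicator)

  # serialization
  path <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_report(rpt, path, csv)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(parsed$laps), 4)
  expect_equal(nrow(read.csv(csv)), 4)
})

test_that("report assembly validates lap indices", {
  laps <- data.frame(index = c(1, 1), style = c("butterfly", "butterfly"),
                     lap_time = c(20, 21), stroke_count = c(10, 11),
                     stroke_rate = c(30, 31))
  expect_error(build_session_report(laps, data.frame()), "duplicate")
})
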