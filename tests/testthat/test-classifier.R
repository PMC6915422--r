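# Literal evaluation of the energy definition, as an independent oracle.
energy_brute <- function(x) {
  v <- sum(abs(x - mean(x))) / length(x)
  as.integer(sign(v) * floor(abs(v) + 0.5))
}

test_that("channel energy equals its literal definition", {
  expect_equal(channel_energy(rep(4.2, 50)), 0L)
  expect_equal(channel_energy(rep(c(5, -5), 100)), 5L)
  # sinusoid of amplitude A has mean absolute deviation 2A/pi
  t <- (0:9999) / 100
  for (A in c(3, 7.85, 12)) {
    expect_equal(channel_energy(A * sin(2 * pi * 0.5 * t)),
                 as.integer(round(2 * A / pi)))
  }
  set.seed(5)
  for (i in 1:1000) {
    x <- rnorm(sample(2:100, 1), mean = runif(1, -5, 5),
               sd = runif(1, 0, 10))
    expect_identical(channel_energy(x), energy_brute(x))
  }
  expect_error(channel_energy(numeric(0)), "empty")
})

test_that("backstroke z-axis rule separates supine from prone", {
  expect_true(is_backstroke(rep(-1, 100)))
  expect_false(is_backstroke(rep(1, 100)))
  expect_warning(flat <- is_backstroke(rep(0, 100)), "far from")
  expect_false(flat)
})

test_that("feature extraction reflects the lap's energy geometry", {
  expect_equal(unname(extract_features(matrix(0, 500, 3), 100)), c(0, 0, 0))
  set.seed(8)
  nz <- default_noise()
  l <- generate_lap(lap_spec("front_crawl"), 100, noise_sd_deg = nz$deg,
                    noise_sd_g = nz$g)
  f <- extract_features(l$signals[, c("acc_x", "acc_y", "acc_z")], 100)
  expect_true(f["Ey"] > f["Ex"] && f["Ey"] > f["Ez"])
})

test_that("both model kinds separate the synthetic corpus", {
  set.seed(31)
  corp <- make_feature_corpus(25)
  idx <- sample(75, 50)
  for (kind in c("svm", "ann")) {
    m <- train_style_model(corp$features[idx, ], corp$labels[idx],
                           kind = kind, seed = 2)
    train_acc <- mean(predict(m, corp$features[idx, ]) == corp$labels[idx])
    test_acc <- mean(predict(m, corp$features[-idx, ]) == corp$labels[-idx])
    expect_equal(train_acc, 1)
    expect_gte(test_acc, 0.95)
  }
})

test_that("ANN training is deterministic under a fixed seed", {
  set.seed(12)
  corp <- make_feature_corpus(10)
  m1 <- train_style_model(corp$features, corp$labels, kind = "ann", seed = 9)
  m2 <- train_style_model(corp$features, corp$labels, kind = "ann", seed = 9)
  expect_identical(m1$weights, m2$weights)
})

test_that("training rejects incomplete class coverage", {
  set.seed(1)
  corp <- make_feature_corpus(5)
  one <- corp$labels == "butterfly"
  expect_error(train_style_model(corp$features[one, ], corp$labels[one]),
               "every class")
  expect_error(train_style_model(corp$features, rep("backstroke", 15)),
               "z-axis rule")
})

test_that("SVM decision is invariant to training order", {
  # libsvm orders one-vs-one pairs by data appearance; canonicalize each
  # pairwise column (alphabetical pair name, sign flipped when reversed)
  canon <- function(d) {
    cn <- colnames(d)
    cols <- lapply(seq_along(cn), function(i) {
      p <- strsplit(cn[i], "/")[[1]]
      if (p[1] > p[2]) list(name = paste(p[2], p[1], sep = "/"),
                            v = -d[, i])
      else list(name = cn[i], v = d[, i])
    })
    out <- do.call(cbind, lapply(cols, `[[`, "v"))
    colnames(out) <- vapply(cols, `[[`, character(1), "name")
    out[, sort(colnames(out))]
  }
  set.seed(44)
  corp <- make_feature_corpus(15)
  m1 <- train_style_model(corp$features, corp$labels, kind = "svm",
                          tolerance = 1e-10)
  perm <- sample(nrow(corp$features))
  m2 <- train_style_model(corp$features[perm, ], corp$labels[perm],
                          kind = "svm", tolerance = 1e-10)
  grid <- as.matrix(expand.grid(Ex = 0:8, Ey = 0:8, Ez = 0:8))
  d1 <- attr(predict(m1$fit, grid, decision.values = TRUE),
             "decision.values")
  d2 <- attr(predict(m2$fit, grid, decision.values = TRUE),
             "decision.values")
  expect_equal(unname(canon(d1)), unname(canon(d2)), tolerance = 1e-6)
})

test_that("models serialize to JSON and reload with identical predictions", {
  set.seed(51)
  corp <- make_feature_corpus(10)
  grid <- as.matrix(expand.grid(Ex = 0:7, Ey = 0:7, Ez = 0:7))
  for (kind in c("svm", "ann")) {
    m <- train_style_model(corp$features, corp$labels, kind = kind, seed = 4)
    path <- withr::local_tempfile(fileext = ".json")
    save_style_model(m, path)
    m2 <- load_style_model(path)
    expect_identical(predict(m2, grid), predict(m, grid))
  }
})

test_that("lap classification short-circuits backstroke and uses the model", {
  set.seed(61)
  nz <- default_noise()
  corp <- make_feature_corpus(15)
  m <- train_style_model(corp$features, corp$labels, kind = "svm")
  for (st in SWIM_STYLES) {
    l <- generate_lap(lap_spec(st), 100, noise_sd_deg = nz$deg,
                      noise_sd_g = nz$g)
    expect_equal(classify_lap(l$signals[, c("acc_x", "acc_y", "acc_z")],
                              100, m), st)
  }
  # the rule fallback also labels generator laps correctly
  for (st in SWIM_STYLES) {
    l <- generate_lap(lap_spec(st), 100, noise_sd_deg = nz$deg,
                      noise_sd_g = nz$g)
    expect_equal(classify_lap(l$signals[, c("acc_x", "acc_y", "acc_z")],
                              100, NULL), st)
  }
  expect_error(classify_lap(matrix(0.1, 30, 3), 100, m), "shorter")
})
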