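# Per-lap stroke-style classification.
#
# Backstroke is recognized directly: it is the only style swum supine, so
# the low-passed z accelerometer sits near -1 g. The remaining three styles
# are separated by a classifier on per-lap accelerometer energy features
# (rounded mean absolute deviation of each 0.5 Hz low-passed channel,
# converted to m/s^2): front crawl has dominant y-axis energy from body
# roll; butterfly exceeds breaststroke in z (undulation) and x (speed).

#' Accelerometer channel energy
#'
#' `round(sum(|x(n) - mean(x)|) / N)`: the rounded mean absolute deviation
#' of a (filtered, m/s^2-scale) channel over a lap. Rounding is
#' half-away-from-zero.
#'
#' @param x Numeric series over the lap, in m/s^2.
#' @return Nonnegative integer.
#' @export
channel_energy <- function(x) {
  if (!length(x)) stop("empty span")
  v <- mean(abs(x - mean(x)))
  as.integer(sign(v) * floor(abs(v) + 0.5))
}

#' Extract per-lap energy features
#'
#' Applies the 48-order Hamming low-pass at 0.5 Hz to each accelerometer
#' channel, converts g to m/s^2, and returns the three channel energies.
#'
#' @param acc Matrix or data frame with accelerometer columns x, y, z in g.
#' @param fs Sampling rate in Hz.
#' @param cutoff_hz Filter cutoff (default 0.5).
#' @param order Filter order (default 48).
#' @return Named numeric vector `c(Ex, Ey, Ez)`.
#' @export
extract_features <- function(acc, fs, cutoff_hz = 0.5, order = 48L) {
  acc <- as.matrix(acc)
  stopifnot(ncol(acc) == 3L)
  e <- vapply(1:3, function(j) {
    xf <- hamming_lowpass(acc[, j], fs, cutoff_hz, order) * GRAVITY_MS2
    channel_energy(xf)
  }, numeric(1))
  setNames(e, c("Ex", "Ey", "Ez"))
}

#' Backstroke rule on the z accelerometer
#'
#' @param az z-axis accelerometer series in g over one lap (low-pass it
#'   first; [classify_lap()] does).
#' @param threshold Mean-az threshold in g (default -0.5, midway between
#'   the supine -1 g and prone +1 g regimes).
#' @return `TRUE` iff the lap is backstroke. A near-zero mean (sideways,
#'   degenerate) returns `FALSE` with a warning.
#' @export
is_backstroke <- function(az, threshold = -0.5) {
  if (!length(az)) stop("empty lap")
  m <- mean(az)
  if (abs(m) < 0.25) {
    warning(sprintf("mean z acceleration %.2f g is far from both +/-1 g", m))
  }
  m < threshold
}

THREE_CLASSES <- c("butterfly", "breaststroke", "front_crawl")

# --- small feed-forward network (3-10-3), gradient descent with momentum ---

ann_init <- function(n_in, n_hidden, n_out, seed) {
  set.seed(seed)
  list(W1 = matrix(rnorm(n_in * n_hidden, 0, 0.5), n_in, n_hidden),
       b1 = rep(0, n_hidden),
       W2 = matrix(rnorm(n_hidden * n_out, 0, 0.5), n_hidden, n_out),
       b2 = rep(0, n_out))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

ann_forward <- function(w, X) {
  H <- sigmoid(sweep(X %*% w$W1, 2, w$b1, "+"))
  Z <- sweep(H %*% w$W2, 2, w$b2, "+")
  Z <- Z - apply(Z, 1, max)
  P <- exp(Z) / rowSums(exp(Z))
  list(H = H, P = P)
}

ann_train <- function(X, Y, n_hidden = 10L, lr = 0.3, momentum = 0.5,
                      max_epochs = 3000L, tol = 1e-8, patience = 50L,
                      seed = 1L) {
  n <- nrow(X)
  w <- ann_init(ncol(X), n_hidden, ncol(Y), seed)
  v <- lapply(w, function(p) p * 0)
  loss_hist <- rep(NA_real_, max_epochs)
  best <- Inf; stall <- 0L
  for (ep in seq_len(max_epochs)) {
    fw <- ann_forward(w, X)
    loss <- -mean(rowSums(Y * log(pmax(fw$P, 1e-12))))
    loss_hist[ep] <- loss
    if (loss < best - tol) { best <- loss; stall <- 0L } else stall <- stall + 1L
    if (stall >= patience) break
    dZ <- (fw$P - Y) / n
    gW2 <- t(fw$H) %*% dZ
    gb2 <- colSums(dZ)
    dH <- dZ %*% t(w$W2) * fw$H * (1 - fw$H)
    gW1 <- t(X) %*% dH
    gb1 <- colSums(dH)
    g <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
    for (p in names(w)) {
      v[[p]] <- momentum * v[[p]] - lr * g[[p]]
      w[[p]] <- w[[p]] + v[[p]]
    }
  }
  w$epochs <- ep
  w$final_loss <- loss_hist[ep]
  w
}

#' Train a stroke-style model
#'
#' Trains either a support vector machine (polynomial kernel, box
#' constraint 1e5, degree 1 by default) or a 3-input / 10-hidden / 3-output
#' neural network trained by full-batch gradient descent with momentum
#' (momentum 0.5, learning rate 0.3), on per-lap energy features of the
#' three prone styles.
#'
#' @param features Matrix or data frame of energy features (columns Ex, Ey,
#'   Ez), one row per lap.
#' @param labels Character or factor labels in `c("butterfly",
#'   "breaststroke", "front_crawl")`; every class must be present.
#' @param kind `"svm"` or `"ann"`.
#' @param seed Integer seed (ANN weight initialization).
#' @param cost SVM box constraint (default 1e5).
#' @param degree SVM polynomial degree (default 1).
#' @param hidden ANN hidden-layer size (default 10).
#' @param lr,momentum ANN learning rate and momentum (defaults 0.3, 0.5).
#' @param ... Further arguments passed to [e1071::svm()] (e.g.
#'   `tolerance`).
#' @return A `style_model` object.
#' @export
train_style_model <- function(features, labels, kind = c("svm", "ann"),
                              seed = 1L, cost = 1e5, degree = 1L,
                              hidden = 10L, lr = 0.3, momentum = 0.5, ...) {
  kind <- match.arg(kind)
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  labels <- as.character(labels)
  if (!all(labels %in% THREE_CLASSES)) {
    stop("labels must be butterfly, breaststroke or front_crawl ",
         "(backstroke is handled by the z-axis rule)")
  }
  if (!all(THREE_CLASSES %in% labels)) {
    stop("need at least one example of every class")
  }
  y <- factor(labels, levels = THREE_CLASSES)
  if (kind == "svm") {
    fit <- e1071::svm(X, y, kernel = "polynomial", degree = degree,
                      gamma = 1, coef0 = 0, cost = cost, scale = TRUE, ...)
    model <- list(kind = "svm", fit = fit, levels = THREE_CLASSES,
                  hyper = list(cost = cost, degree = degree,
                               gamma = 1, coef0 = 0))
  } else {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[scl == 0] <- 1
    Xs <- scale(X, ctr, scl)
    Y <- diag(3)[as.integer(y), , drop = FALSE]
    w <- ann_train(Xs, Y, n_hidden = hidden, lr = lr, momentum = momentum,
                   seed = seed)
    model <- list(kind = "ann", weights = w[c("W1", "b1", "W2", "b2")],
                  center = ctr, scale = scl, levels = THREE_CLASSES,
                  hyper = list(hidden = hidden, lr = lr,
                               momentum = momentum, seed = seed,
                               epochs = w$epochs))
  }
  class(model) <- "style_model"
  model
}

#' @export
print.style_model <- function(x, ...) {
  cat(sprintf("<style_model> kind=%s classes={%s}\n", x$kind,
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Predict stroke styles from energy features
#'
#' @param object A `style_model`.
#' @param newdata Matrix or data frame of energy features.
#' @param ... Unused.
#' @return Character vector of style labels.
#' @export
predict.style_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (object$kind == "svm") {
    if (!is.null(object$fit)) {
      as.character(predict(object$fit, X))
    } else {
      svm_predict_manual(object$svm_pieces, X)
    }
  } else {
    Xs <- scale(X, object$center, object$scale)
    P <- ann_forward(object$weights, Xs)$P
    object$levels[max.col(P, ties.method = "first")]
  }
}

# Decompose an e1071 svm fit into plain numeric pieces (libsvm one-vs-one
# layout) so models serialize to JSON and predict without the fitted object.
svm_pieces <- function(fit, levels, hyper) {
  list(SV = unname(as.matrix(fit$SV)),
       coefs = unname(as.matrix(fit$coefs)),
       rho = as.numeric(fit$rho),
       nSV = as.integer(fit$nSV),
       labels = as.integer(fit$labels),
       levels = levels,
       center = as.numeric(fit$x.scale$`scaled:center`),
       scale = as.numeric(fit$x.scale$`scaled:scale`),
       gamma = fit$gamma, coef0 = fit$coef0, degree = fit$degree,
       hyper = hyper)
}

svm_predict_manual <- function(p, X) {
  Xs <- scale(X, p$center, p$scale)
  K <- (p$gamma * (Xs %*% t(p$SV)) + p$coef0)^p$degree  # n x nSV
  k <- length(p$nSV)
  start <- c(0L, cumsum(p$nSV))
  votes <- matrix(0L, nrow(X), k)
  pair <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      pair <- pair + 1L
      si <- (start[i] + 1L):start[i + 1L]
      sj <- (start[j] + 1L):start[j + 1L]
      dec <- K[, si, drop = FALSE] %*% p$coefs[si, j - 1L] +
        K[, sj, drop = FALSE] %*% p$coefs[sj, i] - p$rho[pair]
      win <- ifelse(dec > 0, i, j)
      for (r in seq_len(nrow(X))) {
        votes[r, win[r]] <- votes[r, win[r]] + 1L
      }
    }
  }
  cls <- p$labels[max.col(votes, ties.method = "first")]
  p$levels[cls]
}

#' Serialize a style model to JSON
#'
#' Stores hyperparameters plus weights (ANN) or support vectors and dual
#' coefficients (SVM); [load_style_model()] round-trips to identical
#' predictions.
#'
#' @param model A `style_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_style_model <- function(model, path) {
  stopifnot(inherits(model, "style_model"))
  obj <- if (model$kind == "svm") {
    list(kind = "svm",
         svm = svm_pieces(model$fit, model$levels, model$hyper))
  } else {
    list(kind = "ann", weights = model$weights, center = model$center,
         scale = model$scale, levels = model$levels, hyper = model$hyper)
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a style model from JSON
#' @param path Path written by [save_style_model()].
#' @return A `style_model`.
#' @export
load_style_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$kind == "svm") {
    p <- obj$svm
    p$SV <- as.matrix(p$SV)
    p$coefs <- as.matrix(p$coefs)
    model <- list(kind = "svm", fit = NULL, svm_pieces = p,
                  levels = p$levels, hyper = p$hyper)
  } else {
    w <- obj$weights
    w$W1 <- as.matrix(w$W1); w$W2 <- as.matrix(w$W2)
    model <- list(kind = "ann", weights = w, center = obj$center,
                  scale = obj$scale, levels = obj$levels, hyper = obj$hyper)
  }
  class(model) <- "style_model"
  model
}

#' Classify one lap's stroke style
#'
#' Backstroke short-circuit first (filtered z-axis rule); otherwise the
#' trained model (or a coarse energy-ordering rule when `model` is `NULL`:
#' front crawl if Ey dominates, else butterfly when Ez is at least
#' `rule_z_min`, else breaststroke).
#'
#' @param acc Lap accelerometer matrix/data frame (x, y, z in g).
#' @param fs Sampling rate in Hz.
#' @param model A `style_model`, or `NULL` for the rule fallback.
#' @param backstroke_threshold Mean-az threshold in g (default -0.5).
#' @param rule_z_min Butterfly z-energy threshold for the rule fallback
#'   (default 3 m/s^2).
#' @return Style label.
#' @export
classify_lap <- function(acc, fs, model = NULL, backstroke_threshold = -0.5,
                         rule_z_min = 3) {
  acc <- as.matrix(acc)
  az_f <- hamming_lowpass(acc[, 3], fs, 0.5, 48L)
  if (is_backstroke(az_f, backstroke_threshold)) return("backstroke")
  feats <- extract_features(acc, fs)
  if (is.null(model)) {
    if (feats["Ey"] > feats["Ex"] && feats["Ey"] > feats["Ez"]) {
      return("front_crawl")
    }
    return(if (feats["Ez"] >= rule_z_min) "butterfly" else "breaststroke")
  }
  predict(model, matrix(feats, nrow = 1,
                        dimnames = list(NULL, names(feats))))
}
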