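#' Train a classifier from the evaluated families
#'
#' Eight classifier families are supported under fixed, sensible
#' hyperparameters: linear and radial-kernel support vector machines
#' (`LSVM`, `RBFSVM`; cost 1, radial gamma `1/d`), logistic regression
#' (`LR`), k-nearest neighbours (`KNN`, k = 5, capped at the training-set
#' size), a decision tree (`DT`),
#' naive Bayes (`NB`), GentleBoost (`GB`; Newton-step boosted regression
#' stumps) and RUSBoost (`RB`; AdaBoost.M1 over stumps with per-round
#' majority-class undersampling). Features are expected to be z-scored.
#'
#' @param name One of `"LSVM"`, `"RBFSVM"`, `"LR"`, `"KNN"`, `"DT"`, `"NB"`,
#'   `"GB"`, `"RB"`.
#' @param X Numeric feature matrix (rows = samples).
#' @param y Binary class labels.
#' @param seed Seed for any training randomness.
#' @return Object of class `eegmci_classifier`.
#' @export
train_classifier <- function(name, X, y, seed = 1) {
  name <- match.arg(name, c("LSVM", "RBFSVM", "LR", "KNN", "DT", "NB",
                            "GB", "RB"))
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("training data contains a single class",
                           call. = FALSE)
  fit <- withr::with_seed(seed, switch(
    name,
    LSVM = e1071::svm(X, y, kernel = "linear", cost = 1, scale = FALSE),
    RBFSVM = e1071::svm(X, y, kernel = "radial", cost = 1,
                        gamma = 1 / ncol(X), scale = FALSE),
    LR = {
      df <- data.frame(X, check.names = FALSE)
      suppressWarnings(stats::glm(y ~ ., data = cbind(df, y = y),
                                  family = stats::binomial()))
    },
    KNN = list(X = X, y = y, k = min(5L, nrow(X))),
    DT = {
      df <- data.frame(X, check.names = FALSE)
      rpart::rpart(y ~ ., data = cbind(df, y = y), method = "class")
    },
    NB = e1071::naiveBayes(X, y),
    GB = gentleboost_fit(X, y, n_rounds = 50),
    RB = rusboost_fit(X, y, n_rounds = 50)
  ))
  structure(list(name = name, fit = fit, levels = levels(y),
                 features = colnames(X)),
            class = "eegmci_classifier")
}

#' Predict class labels
#'
#' @param model An `eegmci_classifier` from [train_classifier()].
#' @param X Feature matrix with the training columns.
#' @return Character vector of predicted labels.
#' @export
predict_classifier <- function(model, X) {
  stopifnot(inherits(model, "eegmci_classifier"))
  X <- as.matrix(X)
  if (!is.null(model$features)) X <- X[, model$features, drop = FALSE]
  out <- switch(
    model$name,
    LSVM = ,
    RBFSVM = as.character(predict(model$fit, X)),
    LR = {
      df <- data.frame(X, check.names = FALSE)
      p <- suppressWarnings(predict(model$fit, df, type = "response"))
      model$levels[(p > 0.5) + 1L]
    },
    KNN = as.character(class::knn(model$fit$X, X, model$fit$y,
                                  k = model$fit$k)),
    DT = {
      df <- data.frame(X, check.names = FALSE)
      as.character(predict(model$fit, df, type = "class"))
    },
    NB = as.character(predict(model$fit, X)),
    GB = ,
    RB = boost_predict(model$fit, X)
  )
  out
}

#' @export
predict.eegmci_classifier <- function(object, newdata, ...) {
  predict_classifier(object, newdata)
}

# ---- boosted stumps -------------------------------------------------------

# Weighted regression stump: threshold on one feature minimising weighted
# squared error against targets in [-1, 1]; returns left/right values.
fit_stump <- function(X, z, w) {
  best <- list(sse = Inf)
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    cuts <- unique(stats::quantile(xj, probs = seq(0.1, 0.9, by = 0.1),
                                   names = FALSE))
    for (cut in cuts) {
      left <- xj <= cut
      wl <- sum(w[left]); wr <- sum(w[!left])
      if (wl == 0 || wr == 0) next
      vl <- sum(w[left] * z[left]) / wl
      vr <- sum(w[!left] * z[!left]) / wr
      sse <- sum(w[left] * (z[left] - vl)^2) +
        sum(w[!left] * (z[!left] - vr)^2)
      if (sse < best$sse) {
        best <- list(sse = sse, j = j, cut = cut, vl = vl, vr = vr)
      }
    }
  }
  if (is.infinite(best$sse)) return(NULL)
  best
}

stump_value <- function(stump, X) {
  ifelse(X[, stump$j] <= stump$cut, stump$vl, stump$vr)
}

# GentleBoost: additive model of Newton-step regression stumps on y in
# {-1, +1}, weights w = exp(-y F) renormalised each round.
gentleboost_fit <- function(X, y, n_rounds = 50) {
  z <- ifelse(y == levels(y)[2], 1, -1)
  n <- length(z)
  w <- rep(1 / n, n)
  stumps <- list()
  F <- numeric(n)
  for (t in seq_len(n_rounds)) {
    st <- fit_stump(X, z, w)
    if (is.null(st)) break
    f <- stump_value(st, X)
    F <- F + f
    stumps[[t]] <- st
    w <- exp(-z * F)
    s <- sum(w)
    if (!is.finite(s) || s == 0) break
    w <- w / s
  }
  list(kind = "gentle", stumps = stumps, levels = levels(y))
}

# RUSBoost: AdaBoost.M1 over classification stumps, each round fit on a
# balanced random undersample of the majority class.
rusboost_fit <- function(X, y, n_rounds = 50) {
  z <- ifelse(y == levels(y)[2], 1, -1)
  n <- length(z)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  counts <- table(y)
  minority_n <- min(counts)
  for (t in seq_len(n_rounds)) {
    idx <- unlist(lapply(levels(y), function(cl) {
      i_cl <- which(y == cl)
      if (length(i_cl) > minority_n) {
        sample(i_cl, minority_n, prob = w[i_cl] / sum(w[i_cl]))
      } else i_cl
    }))
    st <- fit_stump(X[idx, , drop = FALSE], z[idx], w[idx] / sum(w[idx]))
    if (is.null(st)) break
    pred <- sign(stump_value(st, X))
    pred[pred == 0] <- 1
    err <- sum(w[pred != z]) / sum(w)
    if (err >= 0.5 || err <= 0) {
      if (err <= 0) { stumps[[t]] <- st; alphas[t] <- 5 }
      break
    }
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[t]] <- st
    alphas[t] <- alpha
    w <- w * exp(-alpha * z * pred)
    w <- w / sum(w)
  }
  list(kind = "rus", stumps = stumps, alphas = alphas, levels = levels(y))
}

boost_predict <- function(fit, X) {
  if (!length(fit$stumps)) {
    return(rep(fit$levels[1], nrow(X)))
  }
  F <- numeric(nrow(X))
  for (t in seq_along(fit$stumps)) {
    v <- stump_value(fit$stumps[[t]], X)
    if (fit$kind == "rus") v <- fit$alphas[t] * sign(v)
    F <- F + v
  }
  fit$levels[(F > 0) + 1L]
}
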