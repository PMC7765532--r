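# Shrinkage LDA with automatically chosen regularization intensity, and
# forward-backward stepwise feature selection scored by inner
# cross-validated balanced accuracy.

# Class level helpers: the positive class is "target" throughout.
.pos_class <- "target"
.neg_class <- "nontarget"

as_binary_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c(.pos_class, .neg_class))
  if (length(bad) > 0) stop("labels must be 'target'/'nontarget', got: ",
                            paste(bad, collapse = ", "))
  factor(labels, levels = c(.neg_class, .pos_class))
}

# Shrinkage intensity and inverse-covariance discriminant from per-class
# centred data; the analytic (Ledoit-Wolf style) intensity shrinks the
# pooled ML covariance toward a scaled identity nu*I, nu = trace(S)/d.
.lda_core <- function(mu_t, mu_n, Zt, Zn) {
  n <- nrow(Zt) + nrow(Zn)
  d <- length(mu_t)
  S <- (crossprod(Zt) + crossprod(Zn)) / n
  W2 <- (crossprod(Zt^2) + crossprod(Zn^2)) / n
  varS <- (n / (n - 1)^3) * n * (W2 - S^2)
  nu <- sum(diag(S)) / d
  Tgt <- diag(nu, d)
  denom <- sum((S - Tgt)^2)
  gamma <- if (denom <= 0) 1 else min(1, max(0, sum(varS) / denom))
  Sigma <- (1 - gamma) * S + gamma * Tgt
  w <- drop(solve(Sigma, mu_t - mu_n))
  b <- -sum(w * (mu_t + mu_n)) / 2
  list(w = w, b = b, gamma = gamma)
}

#' Fit a shrinkage LDA classifier
#'
#' Linear discriminant analysis for target vs non-target features. The
#' pooled within-class covariance is regularized toward a scaled identity
#' with an analytically chosen (Ledoit-Wolf style) shrinkage intensity
#' `gamma`, so the model stays well-posed even with fewer samples than
#' features and needs no hyper-parameter tuning. The decision threshold sits
#' at the midpoint of the projected class means (equal effective priors):
#' the evaluation metric is balanced accuracy, and empirical priors would
#' bias scores toward the majority non-target class.
#'
#' @param x numeric feature matrix (samples x features), no NAs.
#' @param labels `"target"`/`"nontarget"` per row, both present, at least 2
#'   samples per class.
#' @param selected optional ordered index vector into the columns of the
#'   full feature space this model consumes (recorded for [predict()]).
#' @return an `lda_model`: `w`, `b`, `gamma`, `means` (per class),
#'   `selected_features`, `n_features_source`.
#' @export
fit_lda <- function(x, labels, selected = NULL) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("NaN/NA features are not allowed")
  y <- as_binary_labels(labels)
  if (any(table(y) < 2)) stop("need both classes with at least 2 samples each")
  it <- y == .pos_class
  Xt <- x[it, , drop = FALSE]; Xn <- x[!it, , drop = FALSE]
  mu_t <- colMeans(Xt); mu_n <- colMeans(Xn)
  core <- .lda_core(mu_t, mu_n,
                    sweep(Xt, 2, mu_t), sweep(Xn, 2, mu_n))
  structure(list(w = core$w, b = core$b, gamma = core$gamma,
                 means = rbind(target = mu_t, nontarget = mu_n),
                 selected_features = selected %||% seq_len(ncol(x)),
                 n_features_source = if (is.null(selected)) ncol(x) else NA_integer_),
            class = "lda_model")
}

#' Predict labels and decision scores from an LDA model
#'
#' Scores are `w . x_selected + b`; the predicted label is `"target"` when
#' the score is strictly positive. When the model was fitted on a feature
#' subset, `x` may be either the full source feature matrix (columns are
#' indexed by `selected_features`) or already-subset columns.
#'
#' @param object an `lda_model`.
#' @param x feature matrix.
#' @param ... unused.
#' @return list with `scores` and `labels` (factor).
#' @export
predict.lda_model <- function(object, x, ...) {
  x <- as.matrix(x)
  d <- length(object$w)
  if (ncol(x) != d) {
    if (max(object$selected_features) <= ncol(x))
      x <- x[, object$selected_features, drop = FALSE]
    else stop("dimension mismatch: model expects ", d, " features, got ", ncol(x))
  }
  scores <- drop(x %*% object$w) + object$b
  list(scores = scores,
       labels = factor(ifelse(scores > 0, .pos_class, .neg_class),
                       levels = c(.neg_class, .pos_class)))
}

#' Balanced accuracy of predictions
#'
#' Mean of the true-positive (target) and true-negative (non-target) rates.
#'
#' @param truth,predicted label vectors.
#' @return list with `ca_target`, `ca_nontarget`, `ca_total`.
#' @export
balanced_accuracy <- function(truth, predicted) {
  truth <- as_binary_labels(truth); predicted <- as_binary_labels(predicted)
  cat_ <- mean(predicted[truth == .pos_class] == .pos_class)
  can <- mean(predicted[truth == .neg_class] == .neg_class)
  list(ca_target = cat_, ca_nontarget = can, ca_total = 0.5 * (cat_ + can))
}

# Fast inner-CV scorer used by stepwise_select: per fold, class moments over
# all candidate features are precomputed once, so scoring a feature subset
# costs one small-matrix solve plus the held-out projection.
.make_cv_scorer <- function(x, y, k, seed) {
  fold <- stratified_folds(as.integer(y), k, seed)
  folds <- lapply(seq_len(k), function(f) {
    tr <- fold != f
    it <- y == .pos_class
    Xt <- x[tr & it, , drop = FALSE]; Xn <- x[tr & !it, , drop = FALSE]
    mu_t <- colMeans(Xt); mu_n <- colMeans(Xn)
    Zt <- sweep(Xt, 2, mu_t); Zn <- sweep(Xn, 2, mu_n)
    n <- nrow(Zt) + nrow(Zn)
    list(S = (crossprod(Zt) + crossprod(Zn)) / n,
         W2 = (crossprod(Zt^2) + crossprod(Zn^2)) / n,
         n = n, mu_t = mu_t, mu_n = mu_n,
         xte = x[!tr, , drop = FALSE], yte = y[!tr])
  })
  function(sel) {
    if (length(sel) == 0) return(0.5)
    acc <- 0
    for (fd in folds) {
      S <- fd$S[sel, sel, drop = FALSE]
      W2 <- fd$W2[sel, sel, drop = FALSE]
      n <- fd$n; d <- length(sel)
      varS <- (n / (n - 1)^3) * n * (W2 - S^2)
      nu <- sum(diag(S)) / d
      denom <- sum((S - diag(nu, d))^2)
      gamma <- if (denom <= 0) 1 else min(1, max(0, sum(varS) / denom))
      Sigma <- (1 - gamma) * S + diag(gamma * nu, d)
      dm <- fd$mu_t[sel] - fd$mu_n[sel]
      w <- drop(solve(Sigma, dm))
      b <- -sum(w * (fd$mu_t[sel] + fd$mu_n[sel])) / 2
      sc <- drop(fd$xte[, sel, drop = FALSE] %*% w) + b
      pred <- sc > 0
      it <- fd$yte == .pos_class
      acc <- acc + 0.5 * (mean(pred[it]) + mean(!pred[!it]))
    }
    acc / length(folds)
  }
}

#' Forward-backward stepwise feature selection for shrinkage LDA
#'
#' Greedy wrapper selection. Starting from the empty model (score 0.5),
#' the forward step adds the candidate feature that most improves the score
#' when the improvement exceeds `tol`; the backward step removes the
#' included feature whose removal costs less than `tol`; the two alternate
#' until neither changes the set. The default scorer is `k_inner`-fold
#' cross-validated balanced accuracy of the shrinkage LDA computed within
#' the supplied (training) data only, so selection never sees evaluation
#' data. The default `tol` of 0.01 treats changes below one balanced-accuracy
#' point as insignificant, which keeps chance-level noise features out of
#' the model. Ties are broken toward the lowest feature index; the procedure
#' is deterministic given the data and `seed`. If no feature ever improves
#' on the empty model, the single best-scoring feature is kept.
#'
#' @param x feature matrix (samples x features).
#' @param labels `"target"`/`"nontarget"` per row.
#' @param scorer optional function(index vector) -> score; overrides the
#'   built-in cross-validated scorer.
#' @param tol minimal score improvement to accept a change.
#' @param max_features optional cap on the selected-set size (a compute
#'   budget for long feature vectors; `Inf` disables it).
#' @param k_inner folds of the built-in scorer.
#' @param seed fold seed of the built-in scorer.
#' @return list with `selected` (ordered index vector), `score`, and
#'   `model`, the final `lda_model` fitted on the selection.
#' @export
stepwise_select <- function(x, labels, scorer = NULL, tol = 0.01,
                            max_features = Inf, k_inner = 5L, seed = 1L) {
  x <- as.matrix(x)
  if (ncol(x) < 1) stop("need at least one candidate feature")
  y <- as_binary_labels(labels)
  scorer <- scorer %||% .make_cv_scorer(x, y, k_inner, seed)
  sel <- integer(0)
  score <- scorer(sel)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 2L * ncol(x) + 10L) break  # guard against add/remove cycling
    changed <- FALSE
    # forward
    if (length(sel) < max_features) {
      cand <- setdiff(seq_len(ncol(x)), sel)
      if (length(cand) > 0) {
        sc <- vapply(cand, function(j) scorer(c(sel, j)), numeric(1))
        best <- which.max(sc)  # first maximum = lowest index on ties
        if (sc[best] > score + tol) {
          sel <- c(sel, cand[best]); score <- sc[best]; changed <- TRUE
        }
      }
    }
    # backward
    if (length(sel) > 1) {
      sc <- vapply(seq_along(sel), function(i) scorer(sel[-i]), numeric(1))
      best <- which.max(sc)
      if (sc[best] > score - tol) {
        sel <- sel[-best]; score <- sc[best]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(sel) == 0) {
    sc <- vapply(seq_len(ncol(x)), function(j) scorer(j), numeric(1))
    sel <- which.max(sc); score <- sc[sel]
  }
  model <- fit_lda(x[, sel, drop = FALSE], y, selected = sel)
  list(selected = sel, score = score, model = model)
}
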