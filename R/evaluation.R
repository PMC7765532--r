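# Five-fold cross-validation with balanced accuracy, permutation chance
# levels, cross-condition transfer, nonparametric group tests, and the
# accuracy-table aggregation arithmetic.

accuracy_result <- function(ca_target, ca_nontarget, n_target, n_nontarget,
                            per_fold = NULL) {
  structure(list(ca_target = ca_target, ca_nontarget = ca_nontarget,
                 ca_total = 0.5 * (ca_target + ca_nontarget),
                 n_target = n_target, n_nontarget = n_nontarget,
                 per_fold = per_fold),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("balanced accuracy: CAtotal = %.3f (CAtarget = %.3f, CAnontarget = %.3f)\n",
              x$ca_total, x$ca_target, x$ca_nontarget))
  cat(sprintf("evaluated on %d target / %d non-target epochs\n",
              x$n_target, x$n_nontarget))
  invisible(x)
}

# Full-chain fit on trimmed epochs: spatial filter -> (stepwise) -> LDA.
# Returns a closure that predicts labels for new trimmed epochs.
.fit_chain <- function(train, n_filters, stepwise, max_features, k_inner, seed) {
  sf <- fit_spatial_filter(train, n_filters = n_filters)
  fx <- extract_features(train, sf)
  model <- if (stepwise)
    stepwise_select(fx$x, fx$labels, max_features = max_features,
                    k_inner = k_inner, seed = seed)$model
  else fit_lda(fx$x, fx$labels)
  list(filter = sf, model = model,
       predict = function(test) {
         ft <- extract_features(test, sf)
         predict(model, ft$x)$labels
       })
}

subset_trimmed <- function(trimmed, idx) {
  out <- trimmed
  out$data <- trimmed$data[idx, , , drop = FALSE]
  out$labels <- trimmed$labels[idx]
  out
}

#' Cross-validated balanced accuracy
#'
#' Stratified k-fold cross-validation (default five folds). For
#' `trimmed_epochs` input the full chain is refitted per fold on the
#' training folds only - CCA spatial filter, optional stepwise selection,
#' shrinkage LDA - and evaluated on the held-out fold, so no stage leaks
#' held-out information. For a plain feature matrix only the classifier
#' (optionally with stepwise selection) is refitted per fold. Reported
#' rates are fold means; the result is deterministic given the data and
#' `seed`.
#'
#' @param x a `trimmed_epochs` object or a feature matrix.
#' @param ... passed to methods.
#' @return an `accuracy_result` with fold means and a `per_fold` data frame.
#' @export
crossval <- function(x, ...) UseMethod("crossval")

.crossval_engine <- function(labels, k, seed, fit_fun, predict_fun) {
  y <- as_binary_labels(labels)
  fold <- stratified_folds(as.integer(y), k, seed)
  per_fold <- data.frame(fold = seq_len(k), ca_target = NA_real_,
                         ca_nontarget = NA_real_, ca_total = NA_real_)
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    fitted <- fit_fun(tr, f)
    acc <- balanced_accuracy(y[te], predict_fun(fitted, te))
    per_fold[f, -1] <- unlist(acc)
  }
  accuracy_result(mean(per_fold$ca_target), mean(per_fold$ca_nontarget),
                  n_target = sum(y == "target"),
                  n_nontarget = sum(y == "nontarget"),
                  per_fold = per_fold)
}

#' @rdname crossval
#' @param labels `"target"`/`"nontarget"` labels (matrix method).
#' @param k number of folds (at least 2).
#' @param seed fold-allocation seed.
#' @param stepwise run forward-backward feature selection inside each fold.
#' @param max_features stepwise selection cap (see [stepwise_select()]).
#' @param k_inner inner folds of the stepwise scorer.
#' @export
crossval.matrix <- function(x, labels, k = 5L, seed = 1L, stepwise = FALSE,
                            max_features = Inf, k_inner = 5L, ...) {
  .crossval_engine(labels, k, seed,
    fit_fun = function(tr, f) {
      xtr <- x[tr, , drop = FALSE]
      if (stepwise)
        stepwise_select(xtr, labels[tr], max_features = max_features,
                        k_inner = k_inner, seed = seed + f)$model
      else fit_lda(xtr, labels[tr])
    },
    predict_fun = function(model, te) predict(model, x[te, , drop = FALSE])$labels)
}

#' @rdname crossval
#' @param n_filters number of CCA spatial filters.
#' @export
crossval.trimmed_epochs <- function(x, k = 5L, seed = 1L, n_filters = 3L,
                                    stepwise = TRUE, max_features = 15L,
                                    k_inner = 5L, ...) {
  .crossval_engine(x$labels, k, seed,
    fit_fun = function(tr, f)
      .fit_chain(subset_trimmed(x, tr), n_filters, stepwise, max_features,
                 k_inner, seed + f),
    predict_fun = function(chain, te) chain$predict(subset_trimmed(x, te)))
}

#' Permutation-test chance level for the cross-validated accuracy
#'
#' Re-runs the identical cross-validation (including, for epoch input, the
#' per-fold spatial-filter and stepwise refits) on `m` label permutations to
#' build the null distribution of CAtotal under exchangeable classes. The
#' p-value uses the add-one estimator `p = (1 + #(null >= observed)) / (m + 1)`,
#' which is never zero; the observed accuracy is "above chance" when
#' `p < alpha`.
#'
#' @param x a `trimmed_epochs` object or feature matrix.
#' @param labels labels (required for matrix input; taken from the epochs
#'   otherwise).
#' @param m number of permutations, at least 19 (p-value resolution 0.05).
#' @param seed seed for permutations and fold allocation.
#' @param alpha significance level.
#' @param ... passed to [crossval()].
#' @return a `permutation_result`: `observed`, `null` (length m), `p_value`,
#'   `m`, `alpha`, `above_chance`.
#' @export
permutation_test <- function(x, labels = NULL, m = 200L, seed = 1L,
                             alpha = 0.05, ...) {
  if (m < 19) stop("m must be at least 19 for a p-value resolution of 0.05")
  is_epochs <- inherits(x, "trimmed_epochs")
  labels <- labels %||% (if (is_epochs) x$labels else stop("labels required"))
  observed <- if (is_epochs) crossval(x, seed = seed, ...)$ca_total
              else crossval(x, labels, seed = seed, ...)$ca_total
  set.seed(seed)
  perms <- replicate(m, sample(seq_along(labels)), simplify = FALSE)
  null <- vapply(seq_len(m), function(i) {
    yp <- labels[perms[[i]]]
    if (is_epochs) {
      xp <- x; xp$labels <- yp
      crossval(xp, seed = seed + i, ...)$ca_total
    } else crossval(x, yp, seed = seed + i, ...)$ca_total
  }, numeric(1))
  p <- (1 + sum(null >= observed)) / (m + 1)
  structure(list(observed = observed, null = null, p_value = p, m = m,
                 alpha = alpha, above_chance = p < alpha),
            class = "permutation_result")
}

#' Train on one dataset, evaluate on another
#'
#' Fits the full chain (spatial filter, optional stepwise selection,
#' shrinkage LDA) on the entire training dataset and evaluates it once on
#' the entire test dataset. Supports the condition-transfer design (train
#' SF, test CF, or vice versa) and the symbol-count grid (train with one
#' symbol count, test with each other count). Both datasets must share the
#' channel montage and decimated sample grid.
#'
#' @param train,test `trimmed_epochs` objects.
#' @param n_filters,stepwise,max_features,k_inner,seed as in [crossval()].
#' @return an `accuracy_result`.
#' @export
transfer_eval <- function(train, test, n_filters = 3L, stepwise = TRUE,
                          max_features = 15L, k_inner = 5L, seed = 1L) {
  stopifnot(inherits(train, "trimmed_epochs"), inherits(test, "trimmed_epochs"))
  if (!identical(train$channel_names, test$channel_names))
    stop("montage mismatch between train and test datasets")
  if (train$nd != test$nd)
    stop("decimated sample-count mismatch between train and test datasets")
  chain <- .fit_chain(train, n_filters, stepwise, max_features, k_inner, seed)
  acc <- balanced_accuracy(test$labels, chain$predict(test))
  accuracy_result(acc$ca_target, acc$ca_nontarget,
                  n_target = sum(test$labels == "target"),
                  n_nontarget = sum(test$labels == "nontarget"))
}

#' Nonparametric rank tests between accuracy distributions
#'
#' Dispatches the standard two-sided tests: Wilcoxon rank-sum for two
#' unpaired groups, Wilcoxon signed-rank for two paired groups, and
#' Kruskal-Wallis for three or more groups.
#'
#' @param groups list of numeric vectors (non-empty).
#' @param paired logical; only meaningful for two groups.
#' @return data frame with `method`, `statistic`, `p_value`.
#' @export
rank_tests <- function(groups, paired = FALSE) {
  if (!is.list(groups) || length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0)) stop("empty group")
  if (length(groups) == 2) {
    if (paired && length(groups[[1]]) != length(groups[[2]]))
      stop("paired groups must have equal lengths")
    ht <- suppressWarnings(
      stats::wilcox.test(groups[[1]], groups[[2]], paired = paired,
                         alternative = "two.sided", exact = FALSE))
  } else {
    if (paired) warning("paired ignored for more than two groups")
    ht <- stats::kruskal.test(groups)
  }
  data.frame(method = ht$method, statistic = unname(ht$statistic),
             p_value = ht$p.value)
}

#' Aggregate per-participant accuracy cells into table summaries
#'
#' Reproduces the aggregation arithmetic used for per-participant accuracy
#' tables: cells (one value per participant x column, or several per
#' session which are first averaged within participant), per-participant
#' means and SDs, column means, SDs, and medians, pairwise counts and
#' percentages of participants for which one column exceeds another, and
#' the extreme column means with their difference. A single-cell table
#' reports an SD of 0 with `sd_undefined = TRUE`.
#'
#' @param data data frame with columns `participant`, `column` (condition
#'   or symbol count), `value`, and optionally `session`.
#' @return an `accuracy_table`: `cells` (participant x column matrix of
#'   per-participant means), `column_stats` (mean, sd, median per column),
#'   `pairwise` (count and percentage of participants with column a >
#'   column b), `extremes` (max/min column mean and difference).
#' @export
aggregate_table <- function(data) {
  stopifnot(all(c("participant", "column", "value") %in% names(data)))
  cells <- tapply(data$value, list(data$participant, data$column), mean)
  column_stats <- data.frame(
    column = colnames(cells),
    mean = apply(cells, 2, mean, na.rm = TRUE),
    sd = apply(cells, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) 0 else stats::sd(v)
    }),
    median = apply(cells, 2, stats::median, na.rm = TRUE),
    n = apply(cells, 2, function(v) sum(!is.na(v))),
    row.names = NULL)
  cols <- colnames(cells)
  pairwise <- NULL
  if (length(cols) > 1) {
    combos <- utils::combn(cols, 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
      a <- combos[1, i]; b <- combos[2, i]
      ok <- !is.na(cells[, a]) & !is.na(cells[, b])
      na_gt <- sum(cells[ok, a] > cells[ok, b])
      data.frame(column_a = a, column_b = b, n = sum(ok),
                 count_a_gt_b = na_gt,
                 pct_a_gt_b = 100 * na_gt / sum(ok))
    }))
  }
  extremes <- list(max_column = cols[which.max(column_stats$mean)],
                   max_mean = max(column_stats$mean),
                   min_column = cols[which.min(column_stats$mean)],
                   min_mean = min(column_stats$mean),
                   difference = max(column_stats$mean) - min(column_stats$mean))
  structure(list(cells = cells, column_stats = column_stats,
                 pairwise = pairwise, extremes = extremes,
                 sd_undefined = nrow(cells) < 2),
            class = "accuracy_table")
}

#' Bundled reference accuracy tables
#'
#' Published per-participant balanced-accuracy summaries from a
#' 19-participant, 3-session visual oddball study, shipped as plain TSV and
#' used as worked-example input for [aggregate_table()]:
#'
#' * `conditions`: per-participant mean and SD for the CF and SF
#'   stimulation conditions (5 symbols);
#' * `transfer_conditions`: train/test accuracy rates (non-target, target,
#'   average with SDs) for same-condition cross-validation and
#'   cross-condition transfer;
#' * `symbols`: per-participant mean and SD for 4-9 displayed symbols;
#' * `transfer_symbols`: train/test accuracy grid over symbol counts.
#'
#' @return named list of data frames.
#' @export
reference_tables <- function() {
  rd <- function(f) utils::read.delim(
    system.file("extdata", f, package = "p300cca"), check.names = FALSE)
  list(conditions = rd("reference_accuracy_conditions.tsv"),
       transfer_conditions = rd("reference_transfer_conditions.tsv"),
       symbols = rd("reference_accuracy_symbols.tsv"),
       transfer_symbols = rd("reference_transfer_symbols.tsv"))
}
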