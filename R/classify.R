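# Classifier-evaluation harness: stratified 60/40 split, RBF-SVM grid
# search with cross-validation, ROC/AUC/f1 on the held-out test split, and
# exhaustive feature-subset comparison.

#' Grid-search configuration
#'
#' Defaults follow the published protocol: kernel width gamma stepped at
#' decade points over (1e-9, 1e3) and soft-margin cost over (1e-1, 1e13),
#' 5-fold stratified cross-validation on a 60% training split.
#'
#' @param gamma_values strictly increasing positive sequence
#' @param cost_values strictly increasing positive sequence
#' @param n_folds cross-validation folds (default 5)
#' @param train_fraction fraction of samples in the training split,
#'   in (0, 1) (default 0.6)
#' @param seed integer seed driving the split and fold assignment
#' @return a `grid_search_config`
#' @export
grid_search_config <- function(gamma_values = 10^seq(-9, 3),
                               cost_values = 10^seq(-1, 13),
                               n_folds = 5L, train_fraction = 0.6,
                               seed = 1L) {
  stopifnot(length(gamma_values) >= 1, all(diff(gamma_values) > 0),
            all(gamma_values > 0),
            length(cost_values) >= 1, all(diff(cost_values) > 0),
            all(cost_values > 0),
            n_folds >= 2, train_fraction > 0, train_fraction < 1)
  structure(list(gamma_values = gamma_values, cost_values = cost_values,
                 n_folds = as.integer(n_folds),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "grid_search_config")
}

#' ROC curve, AUC and f1 from decision values
#'
#' Sweeps the decision-value threshold over its unique values (ties
#' grouped), yielding a monotone (fpr, tpr) staircase from (0,0) to (1,1);
#' AUC is its trapezoidal area. f1 is computed at the fixed decision
#' boundary 0 with the diseased class positive.
#'
#' @param scores numeric decision values (larger = more diseased)
#' @param labels logical, `TRUE` = diseased
#' @return list: `fpr`, `tpr`, `thresholds`, `auc`, `f1`
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), is.logical(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes required for a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- !duplicated(grp, fromLast = TRUE) # last index of each tie group
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  pred <- scores > 0
  tp0 <- sum(pred & labels)
  f1 <- if (2 * tp0 + sum(pred & !labels) + sum(!pred & labels) == 0) 0 else
    2 * tp0 / (2 * tp0 + sum(pred & !labels) + sum(!pred & labels))
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, s[last]), auc = auc,
       f1 = f1)
}

# Stratified index split: returns logical vector (TRUE = training row).
stratified_split <- function(labels, train_fraction) {
  train <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_tr <- round(train_fraction * length(idx))
    if (n_tr < 1 || n_tr >= length(idx))
      stop("a class would be absent from one split; use a different seed ",
           "or a larger cohort")
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

# Stratified fold assignment 1..k for a logical label vector.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train and evaluate one RBF-SVM classifier
#'
#' Protocol: stratified seeded split into training (`train_fraction`) and
#' test sets; features z-scored on training statistics; grid search over
#' (gamma, cost) by stratified k-fold cross-validated accuracy on the
#' training split (folds shared across the grid); the best pair (ties:
#' lower cost, then lower gamma) refit on the full training split; ROC,
#' AUC and f1 measured on the untouched test split.
#'
#' @param table feature table (data.frame)
#' @param feature_subset character vector of feature columns to use
#' @param config a [grid_search_config()]
#' @param labels logical gold-standard labels (TRUE = diseased); default
#'   derives them from D2 via [gold_standard_labels()]
#' @return a `roc_result`: list with `auc`, `f1`, `fpr`, `tpr`,
#'   `thresholds`, `best_gamma`, `best_cost`, `cv_accuracy`,
#'   `feature_subset`, `n_train`, `n_test`
#' @export
train_and_evaluate <- function(table, feature_subset,
                               config = grid_search_config(),
                               labels = NULL) {
  stopifnot(inherits(config, "grid_search_config"),
            length(feature_subset) >= 1,
            all(feature_subset %in% names(table)))
  if (is.null(labels)) labels <- as.logical(gold_standard_labels(table))
  labels <- as.logical(labels)
  X <- as.matrix(table[, feature_subset, drop = FALSE])
  keep <- stats::complete.cases(X) & !is.na(labels)
  X <- X[keep, , drop = FALSE]; labels <- labels[keep]
  if (length(unique(labels)) < 2L || min(table(labels)) < 4)
    stop("need at least 4 samples per class")
  with_seed(config$seed, {
    train <- stratified_split(labels, config$train_fraction)
    mu <- colMeans(X[train, , drop = FALSE])
    sd <- apply(X[train, , drop = FALSE], 2, stats::sd)
    sd[sd == 0 | is.na(sd)] <- 1
    Z <- sweep(sweep(X, 2, mu), 2, sd, `/`)
    Xtr <- Z[train, , drop = FALSE]; ytr <- labels[train]
    Xte <- Z[!train, , drop = FALSE]; yte <- labels[!train]
    if (length(unique(yte)) < 2L)
      stop("a class is absent from the test split; use a different seed")
    folds <- stratified_folds(ytr, config$n_folds)
    grid <- expand.grid(gamma = config$gamma_values,
                        cost = config$cost_values)
    acc <- vapply(seq_len(nrow(grid)), function(i) {
      accs <- vapply(seq_len(config$n_folds), function(k) {
        in_fold <- folds == k
        if (length(unique(ytr[!in_fold])) < 2L) return(NA_real_)
        fit <- svm_fit_safe(Xtr[!in_fold, , drop = FALSE], ytr[!in_fold],
                            grid$gamma[i], grid$cost[i])
        if (is.null(fit)) return(NA_real_)
        mean((predict(fit, Xtr[in_fold, , drop = FALSE]) > 0) ==
               ytr[in_fold])
      }, numeric(1))
      mean(accs) # NA if any fold failed: that grid point is skipped
    }, numeric(1))
    if (all(is.na(acc))) stop("every grid point failed to fit")
    # ties: prefer the smaller cost, then the smaller gamma
    ord <- order(-acc, grid$cost, grid$gamma, na.last = TRUE)
    best <- ord[1]
    fit <- svm_fit(Xtr, ytr, grid$gamma[best], grid$cost[best])
    scores <- predict(fit, Xte)
    roc <- roc_curve(scores, yte)
    structure(list(auc = roc$auc, f1 = roc$f1, fpr = roc$fpr,
                   tpr = roc$tpr, thresholds = roc$thresholds,
                   best_gamma = grid$gamma[best],
                   best_cost = grid$cost[best],
                   cv_accuracy = acc[best],
                   feature_subset = feature_subset,
                   n_train = sum(train), n_test = sum(!train)),
              class = "roc_result")
  })
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "roc_result [%s]: AUC = %.3f, f1 = %.3f (gamma = %g, cost = %g)\n",
    paste(x$feature_subset, collapse = "+"), x$auc, x$f1,
    x$best_gamma, x$best_cost))
  invisible(x)
}

#' Evaluate every nonempty feature subset
#'
#' Exhaustively runs [train_and_evaluate()] on all `2^k - 1` subsets of the
#' pool under a shared seed (hence a shared train/test split), and ranks
#' them by AUC, ties broken by f1.
#'
#' @param table feature table
#' @param feature_pool character vector, at most 10 features
#' @param config a [grid_search_config()]
#' @param labels optional gold-standard labels (see [train_and_evaluate()])
#' @return data.frame sorted by decreasing AUC then f1, with columns
#'   `subset`, `n_features`, `auc`, `f1`, `best_gamma`, `best_cost`
#' @export
best_feature_combination <- function(table, feature_pool,
                                     config = grid_search_config(),
                                     labels = NULL) {
  k <- length(feature_pool)
  if (k > 10)
    stop("feature pool too large for exhaustive search (", k,
         " > 10); pass an explicit subset list instead")
  subsets <- unlist(lapply(seq_len(k), function(m)
    utils::combn(feature_pool, m, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(subsets, function(fs) {
    r <- train_and_evaluate(table, fs, config, labels)
    data.frame(subset = paste(fs, collapse = "+"), n_features = length(fs),
               auc = r$auc, f1 = r$f1, best_gamma = r$best_gamma,
               best_cost = r$best_cost, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$auc, -res$f1, res$n_features), ]
  rownames(res) <- NULL
  res
}
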