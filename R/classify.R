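#' Flatten connectivity matrices into a feature table
#'
#' Row-major off-diagonal flattening: for each subject-session matrix, the
#' 756 directed edges (for the 28-region atlas) become one feature row. The
#' column map records which `(source, target)` pair each feature indexes, so
#' matrices can be reconstructed.
#'
#' @param matrices list of `connectivity_matrix` (or plain matrices with
#'   identical dimnames)
#' @param labels binary class label per matrix
#' @param subject_ids subject id per matrix (used for grouped
#'   cross-validation); defaults to one subject per row
#' @return a `feature_table`: list with `x` (samples x features matrix),
#'   `y` (factor), `subject_ids`, `map` (data.frame feature/source/target)
#' @export
vectorize <- function(matrices, labels, subject_ids = NULL) {
  ws <- lapply(matrices, function(m)
    if (inherits(m, "connectivity_matrix")) m$weights else m)
  dn <- dimnames(ws[[1]])
  if (!all(vapply(ws, function(w) identical(dimnames(w), dn), logical(1))))
    stop("matrices carry inconsistent region labels")
  R <- nrow(ws[[1]])
  keep <- which(t(row(ws[[1]]) != col(ws[[1]])))  # row-major off-diagonal
  rc <- cbind(as.vector(t(row(ws[[1]])))[keep], as.vector(t(col(ws[[1]])))[keep])
  x <- t(vapply(ws, function(w) as.vector(t(w))[keep], numeric(length(keep))))
  map <- data.frame(feature = seq_along(keep),
                    source = dn[[2]][rc[, 2]], target = dn[[1]][rc[, 1]])
  colnames(x) <- paste0(map$source, "->", map$target)
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(nrow(x)))
  ft <- list(x = x, y = factor(labels), subject_ids = subject_ids, map = map)
  class(ft) <- "feature_table"
  ft
}

#' Rebuild a connectivity matrix from a feature row
#'
#' Inverse of [vectorize()] for one sample; the diagonal is zero.
#'
#' @param features numeric feature vector
#' @param map the column map from a `feature_table`
#' @param labels region labels defining the matrix dimnames
#' @return weight matrix
#' @export
unvectorize <- function(features, map, labels) {
  R <- length(labels)
  M <- matrix(0, R, R, dimnames = list(labels, labels))
  M[cbind(match(map$target, labels), match(map$source, labels))] <- features
  M
}

#' Z-score normalization fit on training data only
#'
#' Normalizes columns with training means and standard deviations; the test
#' set is transformed with the same statistics (no leakage). Zero-variance
#' training columns are centred but not divided.
#'
#' @param train,test numeric matrices with identical columns
#' @return list with `train`, `test`, `center`, `scale`
#' @export
zscore_train_apply <- function(train, test = NULL) {
  ctr <- colMeans(train)
  scl <- apply(train, 2, stats::sd)
  scl[scl == 0] <- 1
  tr <- sweep(sweep(train, 2, ctr), 2, scl, "/")
  te <- if (is.null(test)) NULL else sweep(sweep(test, 2, ctr), 2, scl, "/")
  list(train = tr, test = te, center = ctr, scale = scl)
}

#' Relief feature weights for binary classification
#'
#' ReliefF-style weighting: for every sample, its `k` nearest same-class
#' neighbours (hits) and `k` nearest other-class neighbours (misses) are
#' found by Euclidean distance, and each feature is credited with the mean
#' range-normalized difference to misses minus the mean difference to hits.
#' Separating features score high, irrelevant ones near zero. All samples
#' are used in turn, so the result is deterministic; ranking ties break by
#' feature index.
#'
#' @param x samples x features matrix
#' @param y binary labels
#' @param k_neighbors neighbours per class (default 3)
#' @return list with `weights` (per feature) and `ranking` (feature indices,
#'   best first)
#' @export
relief_rank <- function(x, y, k_neighbors = 3) {
  y <- factor(y)
  if (nlevels(y) != 2) stop("relief_rank requires exactly two classes")
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  n <- nrow(x); d <- ncol(x)
  rng <- apply(x, 2, function(col) diff(range(col)))
  rng[rng == 0] <- 1
  xn <- sweep(x, 2, rng, "/")
  D <- as.matrix(stats::dist(xn))
  diag(D) <- Inf
  w <- numeric(d)
  for (m in seq_len(n)) {
    same <- which(y == y[m]); same <- same[same != m]
    diff_cls <- which(y != y[m])
    hits <- same[order(D[m, same])][seq_len(min(k_neighbors, length(same)))]
    misses <- diff_cls[order(D[m, diff_cls])][seq_len(min(k_neighbors, length(diff_cls)))]
    dh <- abs(sweep(xn[hits, , drop = FALSE], 2, xn[m, ]))
    dm <- abs(sweep(xn[misses, , drop = FALSE], 2, xn[m, ]))
    w <- w + colMeans(dm) - colMeans(dh)
  }
  w <- w / n
  list(weights = w, ranking = order(-w, seq_len(d)))
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney AUC of decision values for the positive class, invariant to
#' monotone transforms of the scores.
#'
#' @param scores decision values (larger = more positive-class)
#' @param labels factor or logical; `positive` names the positive level
#' @param positive positive class level
#' @return AUC in `[0, 1]`
#' @export
rank_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Default classifier configuration
#'
#' The hyperparameter grids searched in the inner cross-validation: SVM cost
#' `C` in \{0.1, 1, 10\}, RBF kernel scale in \{auto, 1, 0.1, 0.01\} (the
#' Gaussian kernel is `exp(-||u - v||^2 / scale^2)`; `"auto"` sets
#' `1/scale^2` to `1/(n_features * mean feature variance)`), and the number
#' of Relief-selected features in \{20, 50, 100\}.
#'
#' Selection follows a one-standard-error rule anchored at the canonical
#' combination (C = 1, kernel scale auto, smallest feature count): the
#' anchor is kept unless another combination beats it by more than one
#' standard error of the best inner accuracy; when the anchor is absent
#' from the grids, the earliest eligible combination (grids are listed
#' smoothest-first) wins. Without that rule, inner accuracies tie under
#' weak signal and a degenerate combination can win by noise; its SVM
#' collapses to majority voting, which under leave-one-out is
#' systematically wrong for the held-out subject.
#'
#' @param cost_grid,scale_grid,k_features_grid grid values, in preference
#'   order
#' @param inner_folds folds of the inner grid-search CV (default 5)
#' @param k_neighbors Relief neighbours
#' @param seed seed controlling inner fold assignment
#' @return a `classifier_config` list
#' @export
classifier_config <- function(cost_grid = c(0.1, 1, 10),
                              scale_grid = c("auto", 1, 0.1, 0.01),
                              k_features_grid = c(20, 50, 100),
                              inner_folds = 5, k_neighbors = 3, seed = 1) {
  if (!length(cost_grid) || !length(scale_grid) || !length(k_features_grid))
    stop("grids must be non-empty")
  if (inner_folds < 2) stop("inner_folds must be >= 2")
  cfg <- list(cost_grid = cost_grid, scale_grid = scale_grid,
              k_features_grid = k_features_grid, inner_folds = inner_folds,
              k_neighbors = k_neighbors, seed = seed)
  class(cfg) <- "classifier_config"
  cfg
}

svm_gamma <- function(scale, x) {
  if (identical(scale, "auto")) {
    v <- mean(apply(x, 2, stats::var))
    if (v == 0) v <- 1
    1 / (ncol(x) * v)
  } else 1 / as.numeric(scale)^2
}

stratified_folds <- function(y, k, seed) {
  local_seed(seed)
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

fit_predict_svm <- function(xtr, ytr, xte, cost, gamma, positive = levels(ytr)[2]) {
  fit <- e1071::svm(xtr, ytr, type = "C-classification", kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
  pr <- stats::predict(fit, xte, decision.values = TRUE)
  dvm <- attr(pr, "decision.values")
  dv <- drop(dvm)
  # e1071 labels the decision column "A/B" with positive values favouring A;
  # orient so larger values favour the requested positive class
  first <- strsplit(colnames(dvm)[1], "/")[[1]][1]
  if (!identical(first, positive)) dv <- -dv
  list(pred = pr, dv = dv)
}

#' Leave-one-subject-out evaluation of the connectivity classifier
#'
#' Outer loop: one subject (all of its sessions) held out per fold, which
#' avoids identity leakage when the two classes are sessions of the same
#' subjects. Inside every outer fold, entirely on the training subjects:
#' z-score normalization is fitted, a stratified `inner_folds`-fold grid
#' search scores every (cost, kernel scale, feature count) combination —
#' with Relief re-ranked on each inner training split — the best combination
#' (ties to the earliest grid entry) is refitted on the whole training fold,
#' and the held-out samples are predicted. Metrics are pooled over all outer
#' folds; AUC comes from the rank statistic of the decision values.
#'
#' @param features a `feature_table` (from [vectorize()]), or a matrix with
#'   `labels` and `subject_ids` supplied separately
#' @param labels,subject_ids used when `features` is a plain matrix
#' @param config a `classifier_config`
#' @param positive positive class level for sensitivity (default: second
#'   class level)
#' @param sample_wise hold out single samples instead of whole subjects
#'   (identity-leaking variant, off by default)
#' @return a `classification_metrics` list: `accuracy`, `sensitivity`,
#'   `specificity`, `auc` (all percentages), `confusion`, `predictions`
#'   (per-sample data.frame with fold, truth, prediction, decision value)
#' @export
loocv_evaluate <- function(features, labels = NULL, subject_ids = NULL,
                           config = classifier_config(), positive = NULL,
                           sample_wise = FALSE) {
  if (inherits(features, "feature_table")) {
    x <- features$x; y <- features$y; sid <- features$subject_ids
  } else {
    x <- features; y <- factor(labels); sid <- subject_ids
    if (is.null(sid)) sid <- paste0("s", seq_len(nrow(x)))
  }
  if (nlevels(y) != 2) stop("binary classification requires two classes")
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  if (sample_wise) sid <- paste0("s", seq_len(nrow(x)))
  if (is.null(positive)) positive <- levels(y)[2]
  units <- unique(sid)
  grid <- expand.grid(k = config$k_features_grid,
                      cost = config$cost_grid,
                      scale = config$scale_grid,
                      stringsAsFactors = FALSE)
  preds <- vector("list", length(units))
  for (u in seq_along(units)) {
    te <- which(sid == units[u]); tr <- which(sid != units[u])
    if (nlevels(droplevels(y[tr])) < 2)
      stop("a class is absent from the training fold for subject ", units[u])
    xtr <- x[tr, , drop = FALSE]; ytr <- droplevels(y[tr])
    fold <- stratified_folds(ytr, min(config$inner_folds, min(table(ytr))),
                             seed = config$seed + u)
    acc_grid <- matrix(0, nrow(grid), max(fold))
    for (f in seq_len(max(fold))) {
      itr <- which(fold != f); ite <- which(fold == f)
      zs <- zscore_train_apply(xtr[itr, , drop = FALSE], xtr[ite, , drop = FALSE])
      rk <- relief_rank(zs$train, ytr[itr], config$k_neighbors)$ranking
      for (gidx in seq_len(nrow(grid))) {
        ksel <- rk[seq_len(min(grid$k[gidx], ncol(x)))]
        fp <- fit_predict_svm(zs$train[, ksel, drop = FALSE], ytr[itr],
                              zs$test[, ksel, drop = FALSE],
                              grid$cost[gidx],
                              svm_gamma(grid$scale[gidx], zs$train[, ksel, drop = FALSE]))
        acc_grid[gidx, f] <- mean(fp$pred == ytr[ite])
      }
    }
    # one-standard-error rule anchored at the canonical configuration
    # (C = 1, kernel scale auto, smallest feature count): keep the anchor
    # unless some combination beats it by more than one standard error.
    # A plain argmax is unstable when accuracies tie near chance, and the
    # combination that wins by noise can degenerate to majority voting,
    # which anti-predicts under leave-one-out
    mean_acc <- rowMeans(acc_grid)
    top <- which.max(mean_acc)
    se_top <- stats::sd(acc_grid[top, ]) / sqrt(ncol(acc_grid))
    if (!is.finite(se_top)) se_top <- 0
    eligible <- which(mean_acc >= mean_acc[top] - se_top)
    anchor <- which(grid$cost == 1 & grid$scale == "auto")
    anchor <- if (length(anchor)) anchor[which.min(grid$k[anchor])] else 1L
    best <- if (anchor %in% eligible) anchor else eligible[1]
    zs <- zscore_train_apply(xtr, x[te, , drop = FALSE])
    rk <- relief_rank(zs$train, ytr, config$k_neighbors)$ranking
    ksel <- rk[seq_len(min(grid$k[best], ncol(x)))]
    fp <- fit_predict_svm(zs$train[, ksel, drop = FALSE], ytr,
                          zs$test[, ksel, drop = FALSE],
                          grid$cost[best],
                          svm_gamma(grid$scale[best], zs$train[, ksel, drop = FALSE]),
                          positive = positive)
    preds[[u]] <- data.frame(fold = u, index = te, truth = y[te],
                             prediction = fp$pred, decision = fp$dv,
                             row.names = NULL)
  }
  preds <- do.call(rbind, preds)
  neg_level <- setdiff(levels(y), positive)
  tp <- sum(preds$truth == positive & preds$prediction == positive)
  tn <- sum(preds$truth == neg_level & preds$prediction == neg_level)
  fp_ <- sum(preds$truth == neg_level & preds$prediction == positive)
  fn <- sum(preds$truth == positive & preds$prediction == neg_level)
  metrics <- list(
    accuracy = 100 * (tp + tn) / nrow(preds),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp_),
    auc = 100 * rank_auc(preds$decision, preds$truth, positive),
    confusion = matrix(c(tn, fp_, fn, tp), 2, 2,
                       dimnames = list(predicted = c(neg_level, positive),
                                       truth = c(neg_level, positive))),
    positive = positive,
    predictions = preds)
  class(metrics) <- "classification_metrics"
  metrics
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  AUC %.2f%%\n",
              x$accuracy, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}
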