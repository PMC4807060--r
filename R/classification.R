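# Leave-one-out RBF-SVM evaluation of a symmetry feature, confusion-count
# metrics, and the rank-based ROC area.  The SVM solver is e1071 (libsvm);
# fold-wise standardisation, the median-heuristic kernel width, score
# orientation and the tie rule are handled here.

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' @param tp,fn,tn,fp Nonnegative integer confusion counts; `tp + fn` and
#'   `tn + fp` must each be at least 1 (both classes present).
#' @return List with `sensitivity`, `specificity` and `accuracy`, in
#'   percent.
#' @examples
#' metrics_from_counts(14, 1, 16, 0)
#' @export
metrics_from_counts <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be nonnegative integers", call. = FALSE)
  if (tp + fn < 1) stop("no positive subjects (tp + fn = 0)", call. = FALSE)
  if (tn + fp < 1) stop("no negative subjects (tn + fp = 0)", call. = FALSE)
  list(sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       accuracy = 100 * (tp + tn) / (tp + tn + fp + fn))
}

#' Rank-based ROC area
#'
#' Nonparametric AUC estimate: the probability that a randomly chosen
#' positive subject scores above a randomly chosen negative one, ties
#' counted half (the Mann-Whitney estimator).
#'
#' @param scores Numeric decision scores, higher = more positive.
#' @param labels Class labels parallel to `scores`.
#' @param positive The positive class label (default `"PD"`).
#' @return AUC in \[0, 1\].
#' @examples
#' roc_area(c(0.1, 0.4, 0.35, 0.8), c("CO", "CO", "PD", "PD"))
#' @export
roc_area <- function(scores, labels, positive = "PD") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  if (length(pos) == 0 || length(neg) == 0)
    stop("both classes must be present to compute a ROC area", call. = FALSE)
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# Standardise columns by training-fold statistics; zero-variance columns
# center to 0 with unit divisor.
.fold_scaler <- function(X_train) {
  mu <- colMeans(X_train)
  sds <- apply(X_train, 2, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  function(X) sweep(sweep(X, 2, mu), 2, sds, "/")
}

# Median-heuristic RBF width on standardised training data:
# gamma = 1 / (2 * median(pairwise distance)^2), falling back to 1/ncol.
.median_gamma <- function(X) {
  d <- as.numeric(stats::dist(X))
  d <- d[d > 0]
  if (length(d) == 0) return(1 / ncol(X))
  1 / (2 * stats::median(d)^2)
}

.fit_predict_svm <- function(X_train, y_train, X_test, positive,
                             cost, gamma) {
  if (is.null(gamma)) gamma <- .median_gamma(X_train)
  fit <- e1071::svm(X_train, y_train, kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
  dv_tr <- attr(stats::predict(fit, X_train, decision.values = TRUE),
                "decision.values")[, 1]
  # orient decision values so that larger = positive class
  orient <- if (mean(dv_tr[y_train == positive]) >=
                mean(dv_tr[y_train != positive])) 1 else -1
  dv <- attr(stats::predict(fit, X_test, decision.values = TRUE),
             "decision.values")[, 1]
  orient * dv
}

#' Leave-one-out RBF-SVM classification of a scalar or vector feature
#'
#' Each subject is predicted by an RBF-kernel SVM trained on all remaining
#' subjects.  Within every training fold the feature columns are
#' standardised using that fold's statistics only (no leakage), the kernel
#' width defaults to the median heuristic on the standardised fold, and an
#' optional inner leave-one-out grid search over `(cost, gamma)` can be
#' nested inside each fold.  The held-out subject's oriented decision value
#' is its ROC score; a subject is called positive only when its score is
#' strictly positive, so on-margin ties resolve to the negative (control)
#' class.
#'
#' @param x Numeric vector (one feature) or matrix (subjects in rows).
#' @param labels Class labels, one per subject; exactly two classes.
#' @param positive Positive class label (default `"PD"`).
#' @param cost SVM cost parameter (default 1).
#' @param gamma RBF width; `NULL` (default) = per-fold median heuristic.
#' @param tune If `TRUE`, select `(cost, gamma)` by an inner LOO grid
#'   search within each training fold (cost 0.1/1/10/100, gamma at 1/4x,
#'   1x, 4x the median heuristic).
#' @return Object of class `"classification_report"`: confusion counts,
#'   `sensitivity`/`specificity`/`accuracy` (percent), `roc_area`,
#'   per-subject `predictions` tibble, and a `non_informative` flag set
#'   when the feature has zero variance overall.
#' @export
loo_svm <- function(x, labels, positive = "PD", cost = 1, gamma = NULL,
                    tune = FALSE) {
  X <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1)
  labels <- as.character(labels)
  n <- nrow(X)
  stopifnot(length(labels) == n)
  classes <- unique(labels)
  if (length(classes) != 2)
    stop("exactly two classes are required (got: ",
         paste(classes, collapse = ", "), ")", call. = FALSE)
  if (!positive %in% classes)
    stop("positive class \"", positive, "\" not found in labels", call. = FALSE)
  if (min(table(labels)) < 2)
    stop("need at least 2 subjects per class for leave-one-out", call. = FALSE)
  negative <- setdiff(classes, positive)
  non_informative <- all(apply(X, 2, function(col) length(unique(col)) == 1))

  scores <- numeric(n)
  for (i in seq_len(n)) {
    X_tr <- X[-i, , drop = FALSE]
    y_tr <- factor(labels[-i], levels = c(negative, positive))
    scaler <- .fold_scaler(X_tr)
    Xs_tr <- scaler(X_tr)
    Xs_te <- scaler(X[i, , drop = FALSE])
    if (all(apply(Xs_tr, 2, function(col) length(unique(col)) == 1))) {
      scores[i] <- 0  # fold carries no information; resolves to negative
      next
    }
    cfg <- list(cost = cost, gamma = gamma)
    if (tune) cfg <- .tune_fold(Xs_tr, y_tr, positive)
    scores[i] <- .fit_predict_svm(Xs_tr, y_tr, Xs_te, positive,
                                  cfg$cost, cfg$gamma)
  }
  predicted <- ifelse(scores > 0, positive, negative)
  tp <- sum(predicted == positive & labels == positive)
  fn <- sum(predicted == negative & labels == positive)
  tn <- sum(predicted == negative & labels == negative)
  fp <- sum(predicted == positive & labels == negative)
  metrics <- metrics_from_counts(tp, fn, tn, fp)
  structure(
    list(tp = tp, fn = fn, tn = tn, fp = fp,
         sensitivity = metrics$sensitivity,
         specificity = metrics$specificity,
         accuracy = metrics$accuracy,
         roc_area = roc_area(scores, labels, positive),
         positive = positive,
         non_informative = non_informative,
         predictions = tibble::tibble(index = seq_len(n), label = labels,
                                      score = scores, predicted = predicted)),
    class = "classification_report")
}

# Inner LOO grid search within one training fold (leakage-free: uses the
# fold's data only).  Ties prefer smaller cost, then smaller gamma.
.tune_fold <- function(Xs, y, positive) {
  base_gamma <- .median_gamma(Xs)
  grid <- expand.grid(cost = c(0.1, 1, 10, 100),
                      gamma = base_gamma * c(0.25, 1, 4))
  grid <- grid[order(grid$cost, grid$gamma), ]
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    hits <- vapply(seq_len(nrow(Xs)), function(j) {
      yj <- y[-j]
      if (length(unique(yj)) < 2) return(NA)
      s <- .fit_predict_svm(Xs[-j, , drop = FALSE], yj,
                            Xs[j, , drop = FALSE], positive,
                            grid$cost[g], grid$gamma[g])
      pred <- if (s > 0) positive else setdiff(levels(y), positive)
      pred == as.character(y[j])
    }, logical(1))
    mean(hits, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(acc)
  list(cost = grid$cost[best], gamma = grid$gamma[best])
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> positive = %s\n", x$positive))
  cat(sprintf("  TP %d  FN %d  TN %d  FP %d\n", x$tp, x$fn, x$tn, x$fp))
  cat(sprintf("  sensitivity %.2f%%  specificity %.2f%%  accuracy %.2f%%\n",
              x$sensitivity, x$specificity, x$accuracy))
  cat(sprintf("  ROC area %.3f\n", x$roc_area))
  if (x$non_informative)
    cat("  NOTE: feature is constant across subjects (non-informative)\n")
  invisible(x)
}
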