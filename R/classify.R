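#' Train a bagged-tree (random forest) classifier on feature vectors
#'
#' Thin, seed-controlled wrapper around a random forest in which each tree
#' casts a unit vote for the predicted class. The out-of-bag (OOB) error --
#' computed from the samples left out of each tree's bootstrap resample --
#' serves as the generalization estimate, so no held-out split is needed.
#'
#' @param X Numeric feature matrix, one sample per row.
#' @param y Class labels (coerced to factor), one per row.
#' @param n_trees Number of trees.
#' @param seed Integer seed; fixed seed gives bit-reproducible predictions.
#' @param ... Further arguments passed to [randomForest::randomForest()].
#' @return Object of class `nv_forest`: list with the fitted `rf`,
#'   `n_trees`, `seed`, `levels`, `oob_error` (at `n_trees` trees).
#' @export
train_forest <- function(X, y, n_trees = 20L, seed = 1L, ...) {
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least two classes")
  stopifnot(nrow(X) == length(y))
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = y, ntree = n_trees, ...)
  structure(list(rf = rf, n_trees = n_trees, seed = seed,
                 levels = levels(y),
                 oob_error = unname(rf$err.rate[n_trees, "OOB"])),
            class = "nv_forest")
}

#' @export
print.nv_forest <- function(x, ...) {
  cat("Random forest:", x$n_trees, "trees,", length(x$levels),
      "classes, OOB error", format(x$oob_error, digits = 4), "\n")
  invisible(x)
}

#' @export
predict.nv_forest <- function(object, newdata, ...) {
  stats::predict(object$rf, newdata, ...)
}

#' Out-of-bag error as a function of ensemble size
#'
#' Trains a single forest of `max(tree_counts)` trees and reads the OOB
#' error of each requested prefix, so the k-tree ensemble is exactly the
#' first k trees of the largest one (nested ensembles).
#'
#' @inheritParams train_forest
#' @param tree_counts Increasing integer vector of ensemble sizes.
#' @return Object of class `oob_curve`: data frame with columns `trees`
#'   and `oob_error`.
#' @export
oob_curve <- function(X, y, tree_counts = c(1, 2, 3, 5, 10, 15, 20, 30, 50),
                      seed = 1L, ...) {
  tree_counts <- as.integer(tree_counts)
  stopifnot(length(tree_counts) >= 1L, all(diff(tree_counts) > 0L),
            all(tree_counts >= 1L))
  fit <- train_forest(X, y, n_trees = max(tree_counts), seed = seed, ...)
  out <- data.frame(trees = tree_counts,
                    oob_error = unname(fit$rf$err.rate[tree_counts, "OOB"]))
  class(out) <- c("oob_curve", "data.frame")
  out
}

#' @export
plot.oob_curve <- function(x, ...) {
  graphics::plot(x$trees, x$oob_error, type = "b", pch = 19,
                 xlab = "number of trees", ylab = "OOB error", ...)
  invisible(x)
}

#' Per-rank classification accuracy
#'
#' Trains one forest per requested taxonomic rank on the same feature
#' matrix and reports accuracy = 1 - OOB error for each. Ranks with fewer
#' than two distinct labels are skipped with a warning.
#'
#' @param records Data frame carrying the rank columns
#'   (`class`, `order`, `family`, `genus`, `species`).
#' @param features Feature matrix aligned row-by-row with `records`.
#' @param ranks Character vector of rank names to evaluate.
#' @inheritParams train_forest
#' @return Data frame with columns `rank`, `n_groups`, `oob_error`,
#'   `accuracy`.
#' @export
evaluate_ranks <- function(records, features,
                           ranks = c("class", "order", "family",
                                     "genus", "species"),
                           n_trees = 20L, seed = 1L) {
  stopifnot(nrow(records) == nrow(features))
  rows <- list()
  for (rk in ranks) {
    labs <- records[[rk]]
    if (is.null(labs)) stop("records lack rank column '", rk, "'")
    if (length(unique(labs)) < 2L) {
      warning("rank '", rk, "' has a single label; skipped")
      next
    }
    fit <- train_forest(features, labs, n_trees = n_trees, seed = seed)
    rows[[rk]] <- data.frame(rank = rk, n_groups = length(unique(labs)),
                             oob_error = fit$oob_error,
                             accuracy = 1 - fit$oob_error,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Macro-averaged one-vs-rest ROC over an ensemble-size grid
#'
#' For each ensemble size k in `tree_grid` a forest is trained and its
#' out-of-bag class predictions are scored one-vs-rest: each of the M
#' classes in turn is treated as positive, TP/FN/FP/TN are counted, and
#' TPR = TP/(TP+FN) and FPR = FP/(FP+TN) are averaged over the M classes.
#' The ROC curve is the set of these (FPR, TPR) points as k varies, sorted
#' by FPR with (0,0) and (1,1) anchors, and the AUC is the trapezoidal
#' area under it. Samples with no OOB prediction (possible at very small
#' k) are excluded from the confusion counts.
#'
#' @inheritParams train_forest
#' @param tree_grid Integer vector of ensemble sizes.
#' @return Object of class `roc_result`: list with `points` (data frame
#'   `trees`, `fpr`, `tpr`), `auc`, `seed`.
#' @export
roc_paper <- function(X, y, tree_grid = c(1, 2, 3, 5, 10, 15, 20, 30, 50),
                      seed = 1L) {
  if (length(tree_grid) == 0L) stop("empty tree grid")
  y <- factor(y)
  pts <- lapply(tree_grid, function(k) {
    fit <- train_forest(X, y, n_trees = k, seed = seed + k)
    pred <- fit$rf$predicted            # OOB predictions
    ok <- !is.na(pred)
    rates <- macro_ovr_rates(y[ok], factor(pred[ok], levels = levels(y)))
    data.frame(trees = k, fpr = rates["fpr"], tpr = rates["tpr"])
  })
  pts <- do.call(rbind, pts)
  rownames(pts) <- NULL
  structure(list(points = pts, auc = roc_auc(pts$fpr, pts$tpr),
                 seed = seed),
            class = "roc_result")
}

# macro-averaged one-vs-rest TPR/FPR from true and predicted factors
macro_ovr_rates <- function(truth, pred) {
  classes <- levels(truth)
  tpr <- fpr <- numeric(length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    pos <- truth == cl
    tp <- sum(pos & pred == cl)
    fn <- sum(pos & pred != cl)
    fp <- sum(!pos & pred == cl)
    tn <- sum(!pos & pred != cl)
    tpr[i] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    fpr[i] <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
  }
  c(tpr = mean(tpr, na.rm = TRUE), fpr = mean(fpr, na.rm = TRUE))
}

# trapezoidal AUC over (fpr, tpr) points with (0,0) and (1,1) anchors
roc_auc <- function(fpr, tpr) {
  x <- c(0, fpr, 1)
  y <- c(0, tpr, 1)
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.roc_result <- function(x, ...) {
  cat("Macro one-vs-rest ROC over", nrow(x$points),
      "ensemble size(s); AUC =", format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  pts <- x$points[order(x$points$fpr, x$points$tpr), ]
  graphics::plot(c(0, pts$fpr, 1), c(0, pts$tpr, 1), type = "b", pch = 19,
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "false positive rate", ylab = "true positive rate",
                 ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}
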