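# Ranking and classification metrics, and the leak-free k-fold
# cross-validation protocol: correlated pairs (a protein pair and the
# domain/residue pairs beneath it) are kept in the same fold, and held-out
# pairs enter training only as unlabeled transductive groundings.

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation: the probability that a random positive is
#' scored above a random negative, with ties counting one half.
#'
#' @param scores numeric vector.
#' @param labels vector in `{-1, +1}`.
#' @return scalar in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  if (!all(labels %in% c(-1, 1))) stop("labels must be -1 or +1")
  npos <- sum(labels == 1); nneg <- sum(labels == -1)
  if (npos == 0 || nneg == 0)
    stop("undefined metric: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' F1 score at a fixed decision threshold
#'
#' Harmonic mean of precision and recall; 0 when their sum is 0.
#'
#' @param preds predicted labels in `{-1, +1}`.
#' @param labels true labels in `{-1, +1}`.
#' @return scalar in `[0, 1]`.
#' @export
f1_score <- function(preds, labels) {
  if (!all(preds %in% c(-1, 1)) || !all(labels %in% c(-1, 1)))
    stop("labels must be -1 or +1")
  if (!any(labels == 1) && !any(preds == 1))
    stop("undefined metric: no positive labels or predictions")
  tp <- sum(preds == 1 & labels == 1)
  fp <- sum(preds == 1 & labels == -1)
  fn <- sum(preds == -1 & labels == 1)
  if (tp == 0) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

#' ROC curve points
#'
#' One `(FPR, TPR)` point per distinct score threshold, from `(0, 0)` to
#' `(1, 1)`; both coordinates are monotonically non-decreasing, and the
#' trapezoidal area under the points equals [auc()].
#'
#' @inheritParams auc
#' @return data.frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  if (!all(labels %in% c(-1, 1))) stop("labels must be -1 or +1")
  npos <- sum(labels == 1); nneg <- sum(labels == -1)
  if (npos == 0 || nneg == 0)
    stop("undefined metric: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie block
  tpr <- cumsum(y == 1)[keep] / npos
  fpr <- cumsum(y == -1)[keep] / nneg
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Leak-free fold assignment
#'
#' Labeled protein pairs are randomly partitioned into `k` folds. Every
#' labeled domain or residue pair whose ancestor protein pair (via the
#' parent maps of both members) is itself labeled inherits that ancestor's
#' fold, so no information about a held-out protein pair leaks through the
#' consistency rules; lower-level pairs without a labeled ancestor pair are
#' assigned uniformly at random.
#'
#' @param d dataset (needs `hierarchy` and `gold`).
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return list of class `mlpip_folds`: `k` plus one named integer vector
#'   per level (canonical pair key -> fold).
#' @export
make_folds <- function(d, k, seed = 0L) {
  h <- d$hierarchy
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  gp <- d$gold$protein
  if (is.null(gp) || nrow(gp) < k)
    stop("k exceeds the number of labeled protein pairs")
  with_seed(seed, {
    pkeys <- pair_key(gp$id_a, gp$id_b)
    pf <- stats::setNames(
      sample(rep(seq_len(k), length.out = length(pkeys))), pkeys)
    assign_child <- function(lab, parent_map) {
      if (is.null(lab) || nrow(lab) == 0L)
        return(stats::setNames(integer(), character()))
      keys <- pair_key(lab$id_a, lab$id_b)
      anc <- pair_key(unname(parent_map[lab$id_a]),
                      unname(parent_map[lab$id_b]))
      f <- unname(pf[anc])
      miss <- is.na(f) | unname(parent_map[lab$id_a]) ==
        unname(parent_map[lab$id_b])
      f[miss] <- sample(k, sum(miss), replace = TRUE)
      stats::setNames(as.integer(f), keys)
    }
    structure(list(k = k,
                   protein = pf,
                   domain = assign_child(d$gold$domain, h$parent_pd),
                   residue = assign_child(d$gold$residue, h$parent_pr)),
              class = "mlpip_folds")
  })
}

#' Cross-validated evaluation of an experimental setting
#'
#' For each fold, the model is trained on the remaining labeled pairs;
#' held-out pairs participate only as unlabeled transductive groundings
#' (their labels are never read during training) and are then scored.
#' Reports per-fold AUC and F1 per level (F1 at margin threshold 0),
#' fold averages, and the ROC over the collated test scores of all folds.
#'
#' @param dataset a [generate()] result (or compatible list).
#' @param grams named list of object Gram matrices; default: linear
#'   kernels on the dataset's features.
#' @param setting experiment setting (see [build_experiment()]).
#' @param cfg [train_config()].
#' @param k number of folds.
#' @param seed fold-assignment seed.
#' @param use_exists_n use the n-existential for residue-directed rules.
#' @return list of class `mlpip_cv_report`: per level, a data.frame
#'   `folds` (fold, n, auc, f1), `auc_mean`, `f1_mean`, `collated_auc`,
#'   `roc`.
#' @export
cross_validate <- function(dataset, grams = NULL, setting = "independent",
                           cfg = train_config(), k = 10L, seed = 0L,
                           use_exists_n = FALSE) {
  grams <- grams %||% lapply(dataset$features, linear_gram)
  folds <- make_folds(dataset, k, seed)
  lv_all <- intersect(levels3, names(grams))
  collated <- lapply(stats::setNames(nm = lv_all), function(lv)
    list(scores = numeric(), labels = integer()))
  rows <- list()
  for (j in seq_len(k)) {
    train_labels <- list(); test_pairs <- list(); test_y <- list()
    for (lv in lv_all) {
      lab <- dataset$gold[[lv]]
      if (is.null(lab) || nrow(lab) == 0L) next
      fold_of <- unname(folds[[lv]][pair_key(lab$id_a, lab$id_b)])
      tr <- lab[fold_of != j, , drop = FALSE]
      te <- lab[fold_of == j, , drop = FALSE]
      train_labels[[lv]] <- labeled_pairs(tr, lv)
      test_pairs[[lv]] <- te[, c("id_a", "id_b")]
      test_y[[lv]] <- te$label
    }
    t <- fit(dataset$hierarchy, grams, labels = train_labels,
             rules = setting, cfg = cfg, extra_pairs = test_pairs,
             use_exists_n = use_exists_n)
    for (lv in lv_all) {
      te <- test_pairs[[lv]]
      if (is.null(te) || nrow(te) == 0L) next
      sc <- unname(t$margins[[lv]][pair_key(te$id_a, te$id_b)])
      y <- test_y[[lv]]
      collated[[lv]]$scores <- c(collated[[lv]]$scores, sc)
      collated[[lv]]$labels <- c(collated[[lv]]$labels, y)
      both <- any(y == 1) && any(y == -1)
      rows[[length(rows) + 1L]] <- data.frame(
        level = lv, fold = j, n = length(y),
        auc = if (both) auc(sc, y) else NA_real_,
        f1 = if (any(y == 1) || any(classify(sc) == 1))
          f1_score(classify(sc), y) else NA_real_)
    }
  }
  rows <- do.call(rbind, rows)
  report <- lapply(stats::setNames(nm = lv_all), function(lv) {
    fr <- rows[rows$level == lv, c("fold", "n", "auc", "f1"), drop = FALSE]
    rownames(fr) <- NULL
    cl <- collated[[lv]]
    list(folds = fr,
         auc_mean = mean(fr$auc, na.rm = TRUE),
         f1_mean = mean(fr$f1, na.rm = TRUE),
         collated_auc = if (length(cl$labels) && any(cl$labels == 1) &&
                            any(cl$labels == -1))
           auc(cl$scores, cl$labels) else NA_real_,
         roc = if (length(cl$labels) && any(cl$labels == 1) &&
                   any(cl$labels == -1))
           roc_points(cl$scores, cl$labels) else NULL)
  })
  structure(c(report, list(setting = setting, k = k)),
            class = "mlpip_cv_report")
}

#' @export
print.mlpip_cv_report <- function(x, ...) {
  cat("<mlpip_cv_report> setting:", x$setting, " k =", x$k, "\n")
  for (lv in intersect(levels3, names(x))) {
    r <- x[[lv]]
    cat(sprintf("  %-8s AUC %.3f (collated %.3f)  F1 %.3f\n",
                lv, r$auc_mean, r$collated_auc, r$f1_mean))
  }
  invisible(x)
}
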