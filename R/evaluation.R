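# Performance assessment: ROC/AUC, repeated 10-fold cross-validation over
# the negative replicate sets, independent tests, and the one-sided
# feature-comparison statistics with Benjamini-Hochberg correction.

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney rank statistic: the probability that a random
#' positive outscores a random negative, with ties credited 0.5. The curve
#' is traced over the distinct score thresholds.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1 = positive) aligned with `scores`.
#' @return Object of class `roc_result`: list with `auc` and a `curve` data
#'   frame of (FPR, TPR) points.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop_tl("scores and labels must have equal length", "shape_error")
  }
  pos <- labels == 1L
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop_tl("need at least one positive and one negative label",
            "degenerate_labels_error")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(-scores)
  tpr <- c(0, cumsum(pos[ord]) / n_pos)
  fpr <- c(0, cumsum(!pos[ord]) / n_neg)
  # collapse runs of tied scores to single curve points
  keep <- c(TRUE, !duplicated(scores[ord], fromLast = TRUE))
  structure(list(auc = auc,
                 curve = data.frame(fpr = fpr[keep], tpr = tpr[keep])),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d curve points)\n", x$auc, nrow(x$curve)))
  invisible(x)
}

new_replicate_summary <- function(aucs, what) {
  structure(list(aucs = aucs, mean = mean(aucs), sd = stats::sd(aucs),
                 what = what),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("%s: AUC = %.4f +/- %.4f (%d replicates)\n",
              x$what, x$mean, x$sd, length(x$aucs)))
  invisible(x)
}

# seeded stratified fold assignment preserving the positive:negative ratio
stratified_folds <- function(labels, folds, seed) {
  assign_class <- function(idx) {
    with_local_seed(seed + length(idx),
                    sample(rep_len(seq_len(folds), length(idx))))
  }
  fold <- integer(length(labels))
  fold[labels == 1L] <- assign_class(which(labels == 1L))
  fold[labels == 0L] <- assign_class(which(labels == 0L))
  fold
}

#' Repeated k-fold cross-validation of an incremental model
#'
#' For each negative replicate of the gold standard: stratified `folds`-fold
#' split of the labeled proteins, LR tables refitted on each training fold
#' (no leakage), held-out scores pooled into one ROC AUC per replicate. The
#' summary reports the mean and SD over replicates.
#'
#' @param m Feature matrix.
#' @param gold A [gold_standard()] object.
#' @param features Feature names of the model, or NULL to use the top
#'   `k_features` of `ranking`.
#' @param ranking Optional `feature_ranking`.
#' @param k_features Model size when selecting from `ranking`.
#' @param folds Number of CV folds.
#' @param seed Seed for the fold assignments.
#' @param alpha,bins Passed to [target_lr()].
#' @param max_replicates Cap on the number of negative replicates evaluated.
#' @return A `replicate_summary` with one pooled AUC per replicate.
#' @export
cross_validate <- function(m, gold, features = NULL, ranking = NULL,
                           k_features = 6L, folds = 10L, seed = 1L,
                           alpha = 0.5, bins = 5L,
                           max_replicates = length(gold$negatives)) {
  if (is.null(features)) {
    if (is.null(ranking)) {
      stop_tl("supply either `features` or a `ranking`", "invalid_input_error")
    }
    features <- ranking$feature[seq_len(k_features)]
  }
  n_labeled <- length(gold$positives) + length(gold$negatives[[1]])
  loo <- folds == n_labeled
  if (!loo && (length(gold$positives) < folds ||
               length(gold$negatives[[1]]) < folds)) {
    stop_tl("need at least `folds` positives and negatives per replicate",
            "insufficient_data_error")
  }
  reps <- gold$negatives[seq_len(min(max_replicates,
                                     length(gold$negatives)))]
  aucs <- vapply(seq_along(reps), function(r) {
    neg <- reps[[r]]
    ids <- c(gold$positives, neg)
    labels <- c(rep(1L, length(gold$positives)), rep(0L, length(neg)))
    fold <- if (loo) seq_along(ids)
            else stratified_folds(labels, folds, derive_seed(seed, r))
    scores <- numeric(length(ids))
    for (k in seq_len(folds)) {
      test <- fold == k
      fit <- target_lr(m, ids[!test & labels == 1L],
                       ids[!test & labels == 0L],
                       features = features, alpha = alpha, bins = bins)
      scores[test] <- score_rows(fit, m[ids[test], , drop = FALSE])
    }
    roc_auc(scores, labels)$auc
  }, numeric(1))
  new_replicate_summary(aucs, sprintf("%d-fold CV, %d-feature model",
                                      folds, length(features)))
}

#' Cross-validated AUC of each incremental model
#'
#' Runs [cross_validate()] for model sizes 1..`k_max` along an mRMR ranking.
#'
#' @inheritParams cross_validate
#' @param k_max Largest model size.
#' @return Data frame with `k`, `feature` (the feature added at step k),
#'   `mean_auc`, `sd_auc`.
#' @export
incremental_auc <- function(m, gold, ranking, k_max, folds = 10L, seed = 1L,
                            alpha = 0.5, bins = 5L,
                            max_replicates = length(gold$negatives)) {
  if (k_max > nrow(ranking)) {
    stop_tl("k_max exceeds the number of ranked features", "range_error")
  }
  rows <- lapply(seq_len(k_max), function(k) {
    cv <- cross_validate(m, gold, ranking = ranking, k_features = k,
                         folds = folds, seed = seed, alpha = alpha,
                         bins = bins, max_replicates = max_replicates)
    data.frame(k = k, feature = ranking$feature[k], mean_auc = cv$mean,
               sd_auc = cv$sd)
  })
  do.call(rbind, rows)
}

#' Independent-test evaluation on a replicate grid
#'
#' Fits one model per gold-standard negative replicate and evaluates each on
#' every independent test negative replicate against the fixed test
#' positives, giving (gold replicates x test replicates) AUCs. Overlap
#' between training and test positives raises a `leakage_error`.
#'
#' @param m Feature matrix.
#' @param gold Training [gold_standard()].
#' @param test_positives Independent positive test ids.
#' @param test_negatives List of independent negative test id vectors.
#' @param features Model feature names.
#' @param alpha,bins Passed to [target_lr()].
#' @param max_replicates Cap on gold replicates used.
#' @return A `replicate_summary` over all grid cells.
#' @export
independent_test <- function(m, gold, test_positives, test_negatives,
                             features, alpha = 0.5, bins = 5L,
                             max_replicates = length(gold$negatives)) {
  overlap <- intersect(gold$positives, test_positives)
  if (length(overlap)) {
    stop_tl(sprintf("test positives overlap training positives (%s)",
                    paste(utils::head(overlap, 3L), collapse = ", ")),
            "leakage_error")
  }
  reps <- gold$negatives[seq_len(min(max_replicates,
                                     length(gold$negatives)))]
  aucs <- unlist(lapply(reps, function(neg) {
    fit <- target_lr(m, gold$positives, neg, features = features,
                     alpha = alpha, bins = bins)
    vapply(test_negatives, function(tneg) {
      ids <- c(test_positives, tneg)
      labels <- c(rep(1L, length(test_positives)), rep(0L, length(tneg)))
      roc_auc(score_rows(fit, m[ids, , drop = FALSE]), labels)$auc
    }, numeric(1))
  }))
  new_replicate_summary(aucs, sprintf(
    "independent test (%d x %d replicate grid)",
    length(reps), length(test_negatives)))
}

#' Feature comparison between targets and other proteins
#'
#' Continuous features are compared by a one-sided Wilcoxon rank-sum test,
#' binary features by a one-sided Fisher's exact test; in both cases the
#' tested direction is the enrichment/depletion observed in the data.
#' P values are Benjamini-Hochberg adjusted across all tested features.
#' Constant features are skipped with a warning.
#'
#' @param m Feature matrix with a `"kinds"` attribute.
#' @param positives Positive (target) ids.
#' @param negatives_pool Negative/background ids.
#' @return Data frame with per-feature test type, group summaries (means and
#'   mean ranks, or class fractions in percent), direction, one-sided `p`
#'   and BH-adjusted `p_adj`.
#' @export
compare_features <- function(m, positives, negatives_pool) {
  kinds <- attr(m, "kinds")
  if (is.null(kinds)) {
    stop_tl("feature matrix lacks a 'kinds' attribute", "schema_error")
  }
  rows <- lapply(names(m), function(f) {
    x <- m[positives, f]
    y <- m[negatives_pool, f]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y) || length(unique(c(x, y))) < 2L) {
      warning(sprintf("skipping constant or empty feature '%s'", f))
      return(NULL)
    }
    if (kinds[[f]] == "binary") {
      tab <- matrix(c(sum(x == 1), sum(x != 1), sum(y == 1), sum(y != 1)),
                    nrow = 2L)
      direction <- if (mean(x == 1) >= mean(y == 1)) "greater" else "less"
      p <- stats::fisher.test(tab, alternative = direction)$p.value
      data.frame(feature = f, test = "fisher",
                 positives = 100 * mean(x == 1), others = 100 * mean(y == 1),
                 direction = direction, p = p)
    } else {
      direction <- {
        r <- rank(c(x, y))
        if (mean(r[seq_along(x)]) >= mean(r[-seq_along(x)])) "greater"
        else "less"
      }
      p <- stats::wilcox.test(x, y, alternative = direction,
                              exact = FALSE)$p.value
      data.frame(feature = f, test = "rank_sum",
                 positives = mean(x), others = mean(y),
                 direction = direction, p = p)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
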