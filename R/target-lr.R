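# Likelihood-ratio naive Bayes. Each feature f gets a per-bin likelihood
# ratio LR(f) = P(f | target) / P(f | non-target) estimated from the gold
# standard; a protein's prediction score is the product of its features'
# LRs, which is proportional to its posterior odds of being a target since
# the prior odds are constant across proteins.

# ---- per-feature LR tables ----

#' Fit a per-bin likelihood-ratio table for one feature
#'
#' Binary features use their two categories; continuous features are cut
#' into `bins` equal-frequency bins on the pooled labeled values (infinite
#' outer edges). Per bin, `LR = ((TP + a)/(T + k a)) / ((FP + a)/(F + k a))`
#' with `T`/`F` the labeled positive/negative counts, `TP`/`FP` the counts
#' falling in the bin, `k` the number of bins and `a` the smoothing
#' pseudocount; `alpha = 0` reproduces the unsmoothed ratio literally.
#'
#' @param values Numeric feature values of the labeled proteins.
#' @param labels Binary labels (1 = positive) aligned with `values`.
#' @param kind `"binary"` or `"continuous"`.
#' @param alpha Smoothing pseudocount (>= 0).
#' @param bins Number of equal-frequency bins for continuous features.
#' @return List with the bin definition, per-bin `lr`, and the counts used.
#' @export
fit_lr_table <- function(values, labels, kind = "continuous", alpha = 0.5,
                         bins = 5L) {
  keep <- !is.na(values)
  values <- values[keep]
  labels <- labels[keep]
  t_n <- sum(labels == 1L)
  f_n <- sum(labels == 0L)
  if (t_n < 1L || f_n < 1L) {
    stop_tl("need at least one labeled positive and negative with values",
            "missing_labels_error")
  }
  if (kind == "binary" || length(unique(values)) <= 2L) {
    levels <- sort(unique(values))
    bin <- match(values, levels)
    k <- length(levels)
    def <- list(kind = "binary", levels = levels)
  } else {
    probs <- seq(0, 1, length.out = bins + 1L)
    inner <- unique(stats::quantile(values, probs[-c(1L, bins + 1L)],
                                    names = FALSE, type = 7))
    bin <- findInterval(values, inner, left.open = TRUE) + 1L
    k <- length(inner) + 1L
    def <- list(kind = "continuous", edges = inner,
                range = range(values))
  }
  tp <- tabulate(bin[labels == 1L], nbins = k)
  fp <- tabulate(bin[labels == 0L], nbins = k)
  lr <- ((tp + alpha) / (t_n + k * alpha)) / ((fp + alpha) / (f_n + k * alpha))
  c(def, list(lr = lr, tp = tp, fp = fp, t = t_n, f = f_n, alpha = alpha))
}

# map raw values onto bin indices of a fitted table (NA for unmatched)
lr_bin_index <- function(table, values) {
  if (table$kind == "binary") {
    match(values, table$levels)
  } else {
    ifelse(is.na(values), NA_integer_,
           findInterval(values, table$edges, left.open = TRUE) + 1L)
  }
}

#' Combine per-feature likelihood ratios into a prediction score
#'
#' Product over the model's features of the LR of the bin the protein's
#' value falls in; evaluated as a sum of logs and returned in linear space.
#' A missing feature value contributes LR = 1 (neutral evidence).
#'
#' @param values Named numeric vector (or single-row data frame) of a
#'   protein's feature values.
#' @param model A fitted [target_lr()] model.
#' @return Combined LR (positive scalar).
#' @export
combined_lr <- function(values, model) {
  if (!inherits(model, "target_lr")) {
    stop_tl("`model` must be a fitted target_lr model", "model_state_error")
  }
  if (is.data.frame(values)) values <- unlist(values[1L, , drop = TRUE])
  log_sum <- 0
  for (f in model$features) {
    tab <- model$tables[[f]]
    idx <- lr_bin_index(tab, values[[f]])
    if (!is.na(idx)) log_sum <- log_sum + log(tab$lr[idx])
  }
  exp(log_sum)
}

# vectorized scoring of a whole feature matrix (log-space accumulation)
score_rows <- function(model, m) {
  log_sum <- numeric(nrow(m))
  for (f in model$features) {
    tab <- model$tables[[f]]
    idx <- lr_bin_index(tab, m[[f]])
    contrib <- ifelse(is.na(idx), 0, log(tab$lr[idx]))
    log_sum <- log_sum + contrib
  }
  stats::setNames(exp(log_sum), rownames(m))
}

# ---- the model object ----

#' Fit a likelihood-ratio naive Bayes target prediction model
#'
#' Fits one likelihood-ratio table per feature on the labeled proteins
#' (positives vs one negative set) and combines them multiplicatively at
#' prediction time. Features may be given explicitly or taken as the top
#' `n_features` of an mRMR [mrmr_rank()] ranking.
#'
#' @param m Feature matrix (data frame with `"kinds"` attribute, rownames =
#'   protein ids).
#' @param positives Character vector of positive (known target) ids.
#' @param negatives Character vector of negative ids (one replicate).
#' @param features Character vector of feature names to use, or NULL to take
#'   them from `ranking`.
#' @param ranking Optional `feature_ranking`; its top `n_features` features
#'   are used when `features` is NULL.
#' @param n_features Number of top-ranked features to keep.
#' @param alpha Smoothing pseudocount for the LR tables.
#' @param bins Equal-frequency bin count for continuous features.
#' @param grade_cutoffs Named vector `c(high = , median = )`: combined-LR
#'   cutoffs for the confidence grades.
#' @return Object of class `target_lr`.
#' @seealso [predict.target_lr()], [cross_validate()], [incremental_models()]
#' @export
target_lr <- function(m, positives, negatives, features = NULL,
                      ranking = NULL, n_features = 6L, alpha = 0.5,
                      bins = 5L, grade_cutoffs = c(high = 100, median = 1)) {
  kinds <- attr(m, "kinds")
  if (is.null(kinds)) {
    stop_tl("feature matrix lacks a 'kinds' attribute", "schema_error")
  }
  if (is.null(features)) {
    if (is.null(ranking)) {
      stop_tl("supply either `features` or a `ranking`", "invalid_input_error")
    }
    if (n_features > nrow(ranking)) {
      stop_tl("n_features exceeds the ranked feature count", "range_error")
    }
    features <- ranking$feature[seq_len(n_features)]
  }
  missing_feats <- setdiff(features, names(m))
  if (length(missing_feats)) {
    stop_tl(sprintf("feature(s) absent from matrix: %s",
                    paste(missing_feats, collapse = ", ")), "schema_error")
  }
  missing_ids <- setdiff(c(positives, negatives), rownames(m))
  if (length(missing_ids)) {
    stop_tl("labeled ids absent from the feature matrix", "schema_error")
  }
  ids <- c(positives, negatives)
  labels <- c(rep(1L, length(positives)), rep(0L, length(negatives)))
  tables <- lapply(features, function(f) {
    fit_lr_table(m[ids, f], labels, kinds[[f]], alpha = alpha, bins = bins)
  })
  names(tables) <- features
  structure(list(features = features, tables = tables, alpha = alpha,
                 bins = bins, n_pos = length(positives),
                 n_neg = length(negatives), positives = positives,
                 grade_cutoffs = grade_cutoffs, call = match.call()),
            class = "target_lr")
}

#' @export
print.target_lr <- function(x, ...) {
  cat("Likelihood-ratio naive Bayes target prediction model\n")
  cat(sprintf("  features (%d): %s\n", length(x$features),
              paste(x$features, collapse = ", ")))
  cat(sprintf("  fitted on %d positives vs %d negatives (alpha = %g)\n",
              x$n_pos, x$n_neg, x$alpha))
  invisible(x)
}

#' @export
summary.target_lr <- function(object, ...) {
  tab <- coef(object)
  rng <- vapply(split(tab$lr, tab$feature), function(v) range(v), numeric(2))
  out <- data.frame(feature = colnames(rng), min_lr = rng[1L, ],
                    max_lr = rng[2L, ], row.names = NULL)
  out <- out[match(object$features, out$feature), ]
  structure(list(model = object, lr_range = out),
            class = "summary.target_lr")
}

#' @export
print.summary.target_lr <- function(x, ...) {
  print(x$model)
  cat("  per-feature LR range:\n")
  print.data.frame(x$lr_range, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Per-bin likelihood ratios of a fitted model
#'
#' @param object A `target_lr` model.
#' @param ... Unused.
#' @return Data frame with one row per feature bin: `feature`, `bin` (level
#'   or interval label), `lr` and `log2_lr`.
#' @export
coef.target_lr <- function(object, ...) {
  rows <- lapply(object$features, function(f) {
    tab <- object$tables[[f]]
    if (tab$kind == "binary") {
      lab <- as.character(tab$levels)
    } else {
      edges <- c(-Inf, tab$edges, Inf)
      lab <- sprintf("(%.4g, %.4g]", edges[-length(edges)], edges[-1L])
    }
    data.frame(feature = f, bin = lab, lr = tab$lr, log2_lr = log2(tab$lr),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Score proteins with a fitted model
#'
#' Scores every row of `newdata` by its combined LR, ranks by decreasing
#' score (ties broken by protein id) and assigns the high/median/low
#' confidence grade from the model's cutoffs.
#'
#' @param object A `target_lr` model.
#' @param newdata Feature matrix covering the model's features.
#' @param ... Unused.
#' @return Data frame with `protein_id`, `combined_lr`, `rank`, `grade` and
#'   `known` (TRUE for the model's training positives), ordered by rank.
#' @export
predict.target_lr <- function(object, newdata, ...) {
  missing_feats <- setdiff(object$features, names(newdata))
  if (length(missing_feats)) {
    stop_tl(sprintf("feature(s) absent from newdata: %s",
                    paste(missing_feats, collapse = ", ")), "schema_error")
  }
  scores <- score_rows(object, newdata)
  ord <- order(-scores, names(scores))
  cut <- object$grade_cutoffs
  grade <- ifelse(scores >= cut[["high"]], "high",
                  ifelse(scores >= cut[["median"]], "median", "low"))
  out <- data.frame(protein_id = names(scores), combined_lr = unname(scores),
                    grade = unname(grade),
                    known = names(scores) %in% object$positives,
                    stringsAsFactors = FALSE)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("protein_id", "combined_lr", "rank", "grade", "known")]
}

#' Per-feature LR contributions for selected proteins
#'
#' @param object A `target_lr` model.
#' @param newdata Feature matrix.
#' @param ids Protein ids (default all rows).
#' @return Matrix of per-feature LR contributions (rows = proteins), whose
#'   row products equal the combined LR.
#' @export
lr_contributions <- function(object, newdata, ids = rownames(newdata)) {
  out <- vapply(object$features, function(f) {
    tab <- object$tables[[f]]
    idx <- lr_bin_index(tab, newdata[ids, f])
    ifelse(is.na(idx), 1, tab$lr[idx])
  }, numeric(length(ids)))
  if (length(ids) == 1L) out <- matrix(out, nrow = 1L,
                                       dimnames = list(ids, object$features))
  rownames(out) <- ids
  out
}

#' Plot the per-bin likelihood ratios of a fitted model
#'
#' One panel per feature, bars at log2 LR per bin; bars above zero mark bins
#' enriched in targets.
#'
#' @param x A `target_lr` model.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.target_lr <- function(x, ...) {
  nf <- length(x$features)
  mf <- grDevices::n2mfrow(nf)
  old <- graphics::par(mfrow = mf, mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  tab <- coef(x)
  for (f in x$features) {
    sub <- tab[tab$feature == f, ]
    graphics::barplot(sub$log2_lr, names.arg = sub$bin, las = 2,
                      main = f, ylab = "log2 LR", ...)
    graphics::abline(h = 0)
  }
  invisible(x)
}

#' Simulate feature values from a fitted model
#'
#' Draws proteins from the fitted class-conditional bin distributions
#' (smoothed as in the LR tables): each feature's bin is sampled from
#' `P(bin | class)` and continuous features are drawn uniformly within the
#' bin (outer bins use the observed training range).
#'
#' @param object A `target_lr` model.
#' @param nsim Number of proteins to simulate.
#' @param seed Optional RNG seed.
#' @param class Simulate from the `"positive"` or `"negative"` class.
#' @param ... Unused.
#' @return Data frame of simulated feature values (`nsim` rows).
#' @export
simulate.target_lr <- function(object, nsim = 1L, seed = NULL,
                               class = c("positive", "negative"), ...) {
  class <- match.arg(class)
  if (!is.null(seed)) set.seed(seed)
  cols <- lapply(object$features, function(f) {
    tab <- object$tables[[f]]
    k <- length(tab$lr)
    counts <- if (class == "positive") tab$tp else tab$fp
    total <- if (class == "positive") tab$t else tab$f
    p <- (counts + tab$alpha) / (total + k * tab$alpha)
    bin <- sample.int(k, nsim, replace = TRUE, prob = p)
    if (tab$kind == "binary") {
      tab$levels[bin]
    } else {
      edges <- c(tab$range[1], tab$edges, tab$range[2])
      lo <- edges[pmin(bin, length(edges) - 1L)]
      hi <- edges[pmin(bin + 1L, length(edges))]
      stats::runif(nsim, lo, pmax(hi, lo))
    }
  })
  names(cols) <- object$features
  as.data.frame(cols)
}

#' Fit the incremental model series of an mRMR ranking
#'
#' Model_j uses the first j features of the ranking, each refitted from
#' scratch on the same labeled proteins.
#'
#' @param ranking A `feature_ranking`.
#' @param k_max Largest model size.
#' @inheritParams target_lr
#' @return List of `target_lr` models of sizes 1..k_max.
#' @export
incremental_models <- function(ranking, k_max, m, positives, negatives,
                               alpha = 0.5, bins = 5L) {
  if (k_max > nrow(ranking)) {
    stop_tl("k_max exceeds the number of ranked features", "range_error")
  }
  lapply(seq_len(k_max), function(j) {
    target_lr(m, positives, negatives,
              features = ranking$feature[seq_len(j)],
              alpha = alpha, bins = bins)
  })
}

# ---- serialization ----

#' Save / load a fitted model as JSON
#'
#' Stores the feature list, per-feature bin definitions and LR tables, the
#' smoothing constant and the grade cutoffs.
#'
#' @param model A `target_lr` model.
#' @param path JSON path.
#' @export
write_model_json <- function(model, path) {
  payload <- list(
    class = "target_lr",
    features = model$features,
    alpha = model$alpha,
    bins = model$bins,
    n_pos = model$n_pos,
    n_neg = model$n_neg,
    positives = model$positives,
    grade_cutoffs = as.list(model$grade_cutoffs),
    tables = model$tables
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @param path JSON path written by [write_model_json()].
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  tables <- lapply(p$tables, function(tab) {
    tab$lr <- as.numeric(tab$lr)
    tab
  })
  structure(list(features = p$features, tables = tables, alpha = p$alpha,
                 bins = p$bins, n_pos = p$n_pos, n_neg = p$n_neg,
                 positives = p$positives,
                 grade_cutoffs = unlist(p$grade_cutoffs),
                 call = NULL),
            class = "target_lr")
}
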