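# mRMR feature ranking on discrete mutual information. Continuous features
# are discretized into three states at mean +/- sd of the labeled training
# values (the convention of the classic mRMR implementation); binary
# features pass through unchanged. All MI terms are averaged over the
# negative replicate sets of the gold standard before ranking.

#' Discretize a feature vector
#'
#' Continuous values are cut into three states at `mean - sd`, `mean + sd`
#' (below/within/above), with the statistics taken from `stats` when supplied
#' (e.g., training values only). Binary vectors (at most two distinct finite
#' values) pass through unchanged. Missing values stay missing.
#'
#' @param values Numeric vector.
#' @param kind `"continuous"` or `"binary"`.
#' @param stats Optional `c(mean, sd)` to use instead of the sample values.
#' @return Integer vector of category codes (NA preserved).
#' @export
discretize <- function(values, kind = "continuous", stats = NULL) {
  obs <- values[is.finite(values)]
  if (length(unique(obs)) < 2L) {
    stop_tl("cannot discretize a constant feature", "constant_feature_error")
  }
  if (kind == "binary" || length(unique(obs)) == 2L) {
    lv <- sort(unique(obs))
    return(as.integer(factor(values, levels = lv)) - 1L)
  }
  if (is.null(stats)) stats <- c(mean(obs), stats::sd(obs))
  lo <- stats[1] - stats[2]
  hi <- stats[1] + stats[2]
  out <- ifelse(values < lo, 0L, ifelse(values > hi, 2L, 1L))
  as.integer(out)
}

#' Mutual information of two categorical vectors
#'
#' Plug-in estimate from the empirical joint distribution, in bits
#' (log base 2); `0 * log 0` terms contribute 0. Pairs with a missing value
#' in either vector are dropped.
#'
#' @param x,y Vectors of equal length (categories; NAs dropped pairwise).
#' @return Mutual information in bits, non-negative.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) {
    stop_tl("x and y must have equal length", "shape_error")
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (!length(x)) stop_tl("no complete observations", "shape_error")
  joint <- table(x, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  expected <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / expected[nz]))
}

# entropy in bits of one categorical vector
shannon_entropy <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Discretized label/feature columns for one negative replicate: rows are
# positives then negatives, features discretized on those labeled rows.
replicate_design <- function(m, positives, negatives, kinds) {
  ids <- c(positives, negatives)
  label <- c(rep(1L, length(positives)), rep(0L, length(negatives)))
  cols <- lapply(names(m), function(f) {
    v <- m[ids, f]
    if (length(unique(v[is.finite(v)])) < 2L) return(rep(NA_integer_,
                                                         length(v)))
    discretize(v, kinds[[f]])
  })
  names(cols) <- names(m)
  list(label = label, features = cols)
}

#' mRMR feature ranking averaged over negative replicates
#'
#' For each negative replicate, the class label and all (discretized)
#' features are tabulated on the labeled proteins and the relevance
#' `I(f, c)` and redundancy `I(f_j, f_i)` mutual-information terms are
#' computed; the terms are then averaged over replicates. Ranking is greedy:
#' the first feature maximizes mean relevance; each later step selects the
#' candidate maximizing relevance divided by its mean redundancy with the
#' already-selected set (quotient form). A zero mean redundancy makes the
#' quotient infinite, in which case candidates are compared by relevance.
#' Ties break lexicographically by feature name. Features that are constant
#' on the labeled proteins of every replicate are dropped with a warning.
#'
#' @param m Feature matrix (data frame with `"kinds"` attribute).
#' @param gold A [gold_standard()] object.
#' @param max_replicates Cap on the number of negative replicates used.
#' @return Object of class `feature_ranking`: data frame with `rank`,
#'   `feature`, `relevance`, `redundancy` plus attribute `mi_matrix`.
#' @export
mrmr_rank <- function(m, gold, max_replicates = length(gold$negatives)) {
  if (!length(gold$negatives)) {
    stop_tl("gold standard has no negative replicates", "missing_labels_error")
  }
  kinds <- attr(m, "kinds")
  if (is.null(kinds)) {
    stop_tl("feature matrix lacks a 'kinds' attribute", "schema_error")
  }
  reps <- gold$negatives[seq_len(min(max_replicates,
                                     length(gold$negatives)))]
  feats <- names(m)
  nf <- length(feats)
  rel_sum <- stats::setNames(numeric(nf), feats)
  red_sum <- matrix(0, nf, nf, dimnames = list(feats, feats))
  n_used <- stats::setNames(numeric(nf), feats)
  n_used_pair <- matrix(0, nf, nf, dimnames = list(feats, feats))
  for (neg in reps) {
    d <- replicate_design(m, gold$positives, neg, kinds)
    ok <- !vapply(d$features, function(v) all(is.na(v)), logical(1))
    for (f in feats[ok]) {
      rel_sum[f] <- rel_sum[f] + mutual_information(d$features[[f]], d$label)
      n_used[f] <- n_used[f] + 1
    }
    okf <- feats[ok]
    for (i in seq_along(okf)) {
      for (j in seq_len(i - 1L)) {
        mi <- mutual_information(d$features[[okf[i]]], d$features[[okf[j]]])
        red_sum[okf[i], okf[j]] <- red_sum[okf[i], okf[j]] + mi
        red_sum[okf[j], okf[i]] <- red_sum[okf[j], okf[i]] + mi
        n_used_pair[okf[i], okf[j]] <- n_used_pair[okf[i], okf[j]] + 1
        n_used_pair[okf[j], okf[i]] <- n_used_pair[okf[j], okf[i]] + 1
      }
    }
  }
  usable <- feats[n_used > 0]
  dropped <- setdiff(feats, usable)
  if (length(dropped)) {
    warning(sprintf("dropping constant feature(s): %s",
                    paste(dropped, collapse = ", ")))
  }
  relevance <- rel_sum[usable] / n_used[usable]
  redundancy <- red_sum[usable, usable, drop = FALSE] /
    pmax(n_used_pair[usable, usable, drop = FALSE], 1)
  ranking <- mrmr_greedy(relevance, redundancy)
  out <- data.frame(rank = seq_along(ranking$order),
                    feature = ranking$order,
                    relevance = unname(relevance[ranking$order]),
                    redundancy = ranking$mean_redundancy,
                    row.names = NULL)
  structure(out, class = c("feature_ranking", "data.frame"),
            mi_matrix = redundancy)
}

# greedy quotient-form selection given mean relevance vector and mean
# pairwise-MI matrix; ties by feature name (the vectors are name-sorted)
mrmr_greedy <- function(relevance, redundancy) {
  feats <- sort(names(relevance))
  relevance <- relevance[feats]
  selected <- character()
  mean_red <- numeric()
  while (length(selected) < length(feats)) {
    cand <- setdiff(feats, selected)
    if (!length(selected)) {
      pick <- cand[which.max(relevance[cand])]
      mean_red <- c(mean_red, NA_real_)
    } else {
      red <- vapply(cand, function(f) {
        mean(redundancy[f, selected])
      }, numeric(1))
      quotient <- ifelse(red > 0, relevance[cand] / red, Inf)
      best <- quotient == max(quotient)
      if (is.infinite(max(quotient)) && sum(best) > 1L) {
        # all-zero redundancy: fall back to relevance, then name
        sub <- cand[best]
        pick <- sub[which.max(relevance[sub])]
      } else {
        pick <- cand[best][1L]
      }
      mean_red <- c(mean_red, unname(red[pick]))
    }
    selected <- c(selected, pick)
  }
  list(order = selected, mean_redundancy = mean_red)
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat("mRMR feature ranking (quotient form, mean MI over replicates)\n")
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat(sprintf("... %d more features\n", nrow(x) - 10L))
  invisible(x)
}

#' Write an mRMR ranking report
#'
#' @param ranking A `feature_ranking` object.
#' @param path Output TSV path.
#' @export
write_ranking_tsv <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
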