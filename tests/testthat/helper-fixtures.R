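# hand-built model with prescribed per-feature LR tables (binary features);
# bin 0 has LR 1, bin 1 the given LR
fake_model <- function(lrs) {
  tables <- lapply(lrs, function(lr) {
    list(kind = "binary", levels = c(0, 1), lr = c(1, lr),
         tp = c(1, 1), fp = c(1, 1), t = 2, f = 2, alpha = 0)
  })
  structure(list(features = names(lrs), tables = tables, alpha = 0,
                 bins = 5L, n_pos = 2, n_neg = 2, positives = character(),
                 grade_cutoffs = c(high = 100, median = 1), call = NULL),
            class = "target_lr")
}

# random labeled fixture: mixed binary/continuous features, small universe
random_mrmr_fixture <- function(n_features, n_proteins, seed) {
  set.seed(seed)
  n_pos <- max(5L, n_proteins %/% 4L)
  ids <- sprintf("F%03d", seq_len(n_proteins))
  label <- c(rep(1L, n_pos), rep(0L, n_proteins - n_pos))
  vals <- lapply(seq_len(n_features), function(j) {
    if (stats::runif(1) < 0.5) {
      stats::rbinom(n_proteins, 1L, 0.2 + 0.4 * label * stats::runif(1))
    } else {
      stats::rnorm(n_proteins, mean = label * stats::runif(1, 0, 2))
    }
  })
  names(vals) <- sprintf("f%02d", seq_len(n_features))
  m <- as.data.frame(vals, row.names = ids)
  attr(m, "kinds") <- stats::setNames(
    ifelse(vapply(vals, function(v) length(unique(v)) <= 2, logical(1)),
           "binary", "continuous"), names(vals))
  gold <- gold_standard(ids[label == 1L], ids, size = n_proteins - n_pos,
                        n_replicates = 3L, seed = seed)
  list(m = m, gold = gold)
}
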