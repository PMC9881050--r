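test_that("ROC AUC worked examples and degenerate input", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))$auc, 0.75)
  expect_equal(roc_auc(c(5, 4, 1, 0), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(2, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), class = "degenerate_labels_error")
  r <- roc_auc(c(3, 2, 2, 1), c(1, 1, 0, 0))
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(utils::tail(r$curve$tpr, 1), 1)
})

test_that("AUC equals the pair-ordering fraction on random score sets", {
  set.seed(73)
  for (i in 1:200) {
    n <- sample(6:30, 1)
    labels <- c(1, 0, stats::rbinom(n - 2, 1, 0.5))
    scores <- sample(stats::rnorm(n %/% 2), n, replace = TRUE)  # force ties
    expect_equal(roc_auc(scores, labels)$auc, brute_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC equals the trapezoidal integral of the stored curve", {
  set.seed(74)
  scores <- c(stats::rnorm(30, 1), stats::rnorm(40))
  labels <- c(rep(1, 30), rep(0, 40))
  r <- roc_auc(scores, labels)
  trap <- sum(diff(r$curve$fpr) *
                (utils::head(r$curve$tpr, -1) + utils::tail(r$curve$tpr, -1)) / 2)
  expect_equal(r$auc, trap, tolerance = 1e-12)
})

test_that("cross-validation is seeded, stratified and near 0.5 under the null", {
  tg <- test_genome()
  cv1 <- cross_validate(tg$matrix, tg$gold,
                        features = c("signal_peptide", "degree_signal",
                                     "tsps"), seed = 5)
  cv2 <- cross_validate(tg$matrix, tg$gold,
                        features = c("signal_peptide", "degree_signal",
                                     "tsps"), seed = 5)
  expect_identical(cv1$aucs, cv2$aucs)
  expect_gt(cv1$mean, 0.8)

  # label-randomized gold standard: signal destroyed
  set.seed(75)
  shuffled <- tg$gold
  fake_pos <- sample(setdiff(rownames(tg$matrix),
                             unlist(tg$gold$negatives[1:5])), 40)
  shuffled$positives <- fake_pos
  cv_null <- cross_validate(tg$matrix, shuffled,
                            features = c("signal_peptide", "degree_signal",
                                         "tsps"),
                            seed = 6, max_replicates = 5)
  expect_lt(abs(cv_null$mean - 0.5), 3 * max(cv_null$sd, 0.02))

  expect_error(cross_validate(tg$matrix, tg$gold,
                              features = "tsps", folds = 200),
               class = "insufficient_data_error")
})

test_that("leave-one-out CV equals a directly coded LOO loop", {
  set.seed(77)
  n <- 24
  lab <- rep(c(1L, 0L), each = n / 2)
  ids <- sprintf("L%02d", seq_len(n))
  m <- data.frame(f = stats::rbinom(n, 1, ifelse(lab == 1, 0.8, 0.2)),
                  row.names = ids)
  attr(m, "kinds") <- c(f = "binary")
  gold <- structure(list(positives = ids[lab == 1],
                         negatives = list(ids[lab == 0]),
                         universe = ids, seeds = 1L),
                    class = "gold_standard")
  cv <- cross_validate(m, gold, features = "f", folds = n, seed = 3)
  # direct LOO: refit on all-but-one, score the held-out protein
  scores <- vapply(seq_len(n), function(i) {
    fit <- target_lr(m[-i, , drop = FALSE], ids[lab == 1L][ids[lab == 1L] != ids[i]],
                     ids[lab == 0L][ids[lab == 0L] != ids[i]],
                     features = "f")
    combined_lr(c(f = m$f[i]), fit)
  }, numeric(1))
  expect_equal(cv$aucs, roc_auc(scores, lab)$auc, tolerance = 1e-12)
})

test_that("independent tests build a full replicate grid and catch leakage", {
  tg <- test_genome()
  test_pos <- setdiff(rownames(tg$matrix),
                      c(tg$gold$positives,
                        unlist(tg$gold$negatives)))[1:15]
  test_negs <- lapply(1:4, function(i) {
    setdiff(rownames(tg$matrix),
            c(tg$gold$positives, test_pos))[(i * 15):(i * 15 + 14)]
  })
  res <- independent_test(tg$matrix, tg$gold, test_pos, test_negs,
                          features = c("signal_peptide", "tsps"),
                          max_replicates = 5)
  expect_length(res$aucs, 5 * 4)
  expect_equal(res$mean, mean(res$aucs))
  expect_equal(res$sd, stats::sd(res$aucs))
  expect_error(independent_test(tg$matrix, tg$gold,
                                c(test_pos, tg$gold$positives[1]),
                                test_negs, features = "tsps"),
               class = "leakage_error")
})

test_that("feature comparison picks the observed direction and adjusts by BH", {
  tg <- test_genome()
  rep_pool <- unique(unlist(tg$gold$negatives))
  # constant features (here: the all-zero nhr flag) are skipped with warning
  expect_warning(rept <- compare_features(tg$matrix, tg$gold$positives,
                                          rep_pool),
                 "constant or empty")
  expect_false("nhr" %in% rept$feature)
  expect_true(all(rept$p_adj >= rept$p - 1e-15))
  expect_true(all(rept$test[attr(tg$matrix, "kinds")[rept$feature] ==
                              "binary"] == "fisher"))
  # BH step-up: adjusted values are monotone in raw order
  ord <- order(rept$p)
  expect_true(all(diff(rept$p_adj[ord]) >= -1e-12))
  # signal peptide is enriched in positives by construction
  sp <- rept[rept$feature == "signal_peptide", ]
  expect_equal(sp$direction, "greater")
  expect_lt(sp$p_adj, 0.01)
})

test_that("one-sided Fisher matches the hypergeometric corner case", {
  ids <- sprintf("Q%02d", 1:20)
  m <- data.frame(f = c(rep(1, 10), rep(0, 10)), row.names = ids)
  attr(m, "kinds") <- c(f = "binary")
  rept <- compare_features(m, ids[1:10], ids[11:20])
  expect_equal(rept$p, 1 / choose(20, 10), tolerance = 1e-10)

  # identical groups (5 flag carriers in each): one-sided P >= 0.5
  m2 <- data.frame(f = rep(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0), 2),
                   row.names = ids)
  attr(m2, "kinds") <- c(f = "binary")
  rept2 <- compare_features(m2, ids[1:10], ids[11:20])
  expect_gte(rept2$p, 0.5)
})

test_that("one-sided P values match a permutation oracle", {
  set.seed(79)
  ids <- sprintf("R%02d", 1:40)
  x <- c(stats::rnorm(15, 0.8), stats::rnorm(25))
  m <- data.frame(f = x, row.names = ids)
  attr(m, "kinds") <- c(f = "continuous")
  rept <- compare_features(m, ids[1:15], ids[16:40])
  # permutation of group labels, rank-sum statistic, same tested direction
  obs <- sum(rank(x)[1:15])
  perm <- replicate(1e4, {
    idx <- sample(40, 15)
    sum(rank(x)[idx])
  })
  p_perm <- if (rept$direction == "greater") mean(perm >= obs)
            else mean(perm <= obs)
  expect_lt(abs(rept$p - p_perm), 0.02)
})
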