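test_that("LR tables reproduce the unsmoothed ratio and smoothing formula", {
  values <- c(rep(1, 80), rep(0, 20), rep(1, 20), rep(0, 80))
  labels <- c(rep(1L, 100), rep(0L, 100))
  tab <- fit_lr_table(values, labels, kind = "binary", alpha = 0)
  expect_equal(tab$lr[tab$levels == 1], 4.0)
  expect_equal(tab$lr[tab$levels == 0], 0.25)

  # equally distributed feature: LR = 1 in every bin
  same <- c(rep(1, 30), rep(0, 70), rep(1, 30), rep(0, 70))
  tab2 <- fit_lr_table(same, labels, kind = "binary", alpha = 0)
  expect_equal(tab2$lr, c(1, 1))

  # empty-in-negatives bin stays finite under the smoothed closed form
  v <- c(rep(1, 10), rep(0, 90), rep(0, 100))
  tab3 <- fit_lr_table(v, labels, kind = "binary", alpha = 0.5)
  expect_equal(tab3$lr[tab3$levels == 1],
               ((10 + 0.5) / (100 + 2 * 0.5)) / ((0 + 0.5) / (100 + 2 * 0.5)))
  expect_true(all(is.finite(tab3$lr) & tab3$lr > 0))

  expect_error(fit_lr_table(c(1, 0), c(1L, 1L)),
               class = "missing_labels_error")
})

test_that("combined LR is the product of per-feature contributions", {
  m <- fake_model(c(f1 = 2, f2 = 3, f3 = 0.5))
  expect_equal(combined_lr(c(f1 = 1, f2 = 1, f3 = 1), m), 3.0)
  expect_equal(combined_lr(c(f1 = 0, f2 = 0, f3 = 0), m), 1.0)
  # missing feature value is neutral evidence
  expect_equal(combined_lr(c(f1 = 1, f2 = NA, f3 = 0), m), 2.0)
  expect_error(combined_lr(c(f1 = 1), list()), class = "model_state_error")
})

test_that("log-space and linear-space products agree on random models", {
  set.seed(61)
  for (i in 1:1000) {
    k <- sample(2:8, 1)
    lrs <- stats::setNames(stats::rlnorm(k, 0, 2), paste0("f", seq_len(k)))
    m <- fake_model(lrs)
    on_bits <- stats::setNames(stats::rbinom(k, 1, 0.5), names(lrs))
    linear <- prod(ifelse(on_bits == 1, lrs, 1))
    expect_equal(combined_lr(on_bits, m), linear,
                 tolerance = 1e-9)
  }
})

test_that("scores are invariant under feature reordering", {
  m <- fake_model(c(a = 2, b = 5, c = 0.2))
  m_rev <- fake_model(c(c = 0.2, b = 5, a = 2))
  v <- c(a = 1, b = 1, c = 1)
  expect_equal(combined_lr(v, m), combined_lr(v, m_rev))
})

test_that("with alpha = 0 the combined LR equals the naive Bayes posterior odds ratio", {
  # small all-binary fixture: compute class posteriors directly
  set.seed(63)
  n <- 60
  lab <- c(rep(1L, 20), rep(0L, 40))
  f1 <- stats::rbinom(n, 1, ifelse(lab == 1, 0.8, 0.3))
  f2 <- stats::rbinom(n, 1, ifelse(lab == 1, 0.4, 0.6))
  ids <- sprintf("P%02d", seq_len(n))
  m <- data.frame(f1 = f1, f2 = f2, row.names = ids)
  attr(m, "kinds") <- c(f1 = "binary", f2 = "binary")
  fit <- target_lr(m, ids[lab == 1], ids[lab == 0],
                   features = c("f1", "f2"), alpha = 0)
  for (x1 in 0:1) for (x2 in 0:1) {
    p_f_pos <- mean(f1[lab == 1] == x1) * mean(f2[lab == 1] == x2)
    p_f_neg <- mean(f1[lab == 0] == x1) * mean(f2[lab == 0] == x2)
    if (p_f_neg == 0) next
    expect_equal(combined_lr(c(f1 = x1, f2 = x2), fit),
                 p_f_pos / p_f_neg, tolerance = 1e-12)
  }
})

test_that("genome prediction ranks by decreasing score with id tie-break", {
  tg <- test_genome()
  fit <- target_lr(tg$matrix, tg$gold$positives, tg$gold$negatives[[1]],
                   features = c("signal_peptide", "signaling_molecule",
                                "degree_signal", "tsps"))
  pr <- predict(fit, tg$matrix)
  expect_equal(nrow(pr), nrow(tg$matrix))
  expect_equal(pr$rank, seq_len(nrow(pr)))
  # recompute-and-sort oracle
  scores <- vapply(rownames(tg$matrix), function(id) {
    combined_lr(unlist(tg$matrix[id, ]), fit)
  }, numeric(1))
  ord <- order(-scores, names(scores))
  expect_equal(pr$protein_id, names(scores)[ord])
  expect_equal(pr$combined_lr, unname(scores[ord]), tolerance = 1e-12)
  # identical feature rows score identically and rank adjacently
  dup <- tg$matrix[c(1, 1), ]
  rownames(dup) <- c("z_aa", "z_ab")
  pr2 <- predict(fit, rbind(tg$matrix, dup))
  r <- pr2$rank[pr2$protein_id %in% c("z_aa", "z_ab")]
  expect_equal(abs(diff(r)), 1L)
  # grades partition by the cutoffs
  expect_true(all(pr$grade[pr$combined_lr >= 100] == "high"))
  expect_true(all(pr$grade[pr$combined_lr < 1] == "low"))
})

test_that("raising a positive-evidence flag strictly increases the score", {
  m <- fake_model(c(f1 = 3, f2 = 2))
  lo <- combined_lr(c(f1 = 0, f2 = 1), m)
  hi <- combined_lr(c(f1 = 1, f2 = 1), m)
  expect_gt(hi, lo)
})

test_that("per-feature contributions multiply to the combined LR", {
  tg <- test_genome()
  fit <- target_lr(tg$matrix, tg$gold$positives, tg$gold$negatives[[1]],
                   features = c("signal_peptide", "tsps", "degree_signal"))
  ids <- rownames(tg$matrix)[1:20]
  contrib <- lr_contributions(fit, tg$matrix, ids)
  pr <- predict(fit, tg$matrix[ids, ])
  expect_equal(apply(contrib, 1, prod)[pr$protein_id],
               stats::setNames(pr$combined_lr, pr$protein_id),
               tolerance = 1e-9)
})

test_that("incremental models nest along the ranking", {
  tg <- test_genome()
  rk <- suppressWarnings(mrmr_rank(tg$matrix, tg$gold, max_replicates = 3))
  models <- incremental_models(rk, 4, tg$matrix, tg$gold$positives,
                               tg$gold$negatives[[1]])
  expect_length(models, 4L)
  expect_equal(models[[1]]$features, rk$feature[1])
  for (j in 2:4) {
    expect_true(all(models[[j - 1]]$features %in% models[[j]]$features))
  }
  expect_error(incremental_models(rk, nrow(rk) + 1, tg$matrix,
                                  tg$gold$positives, tg$gold$negatives[[1]]),
               class = "range_error")
})

test_that("models survive a JSON round trip", {
  tg <- test_genome()
  fit <- target_lr(tg$matrix, tg$gold$positives, tg$gold$negatives[[1]],
                   features = c("signal_peptide", "tsps", "indegree_tf"))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  pr1 <- predict(fit, tg$matrix)
  pr2 <- predict(back, tg$matrix)
  expect_equal(pr2$combined_lr, pr1$combined_lr, tolerance = 1e-12)
  expect_identical(pr2$protein_id, pr1$protein_id)
})

test_that("simulated proteins reproduce the fitted class-conditional bins", {
  tg <- test_genome()
  fit <- target_lr(tg$matrix, tg$gold$positives, tg$gold$negatives[[1]],
                   features = c("signal_peptide", "tsps"))
  sim <- simulate(fit, nsim = 4000, seed = 71, class = "positive")
  tab <- fit$tables$signal_peptide
  p_target <- (tab$tp[2] + tab$alpha) / (tab$t + 2 * tab$alpha)
  expect_equal(mean(sim$signal_peptide == 1), p_target, tolerance = 0.05)
  rng <- fit$tables$tsps$range
  expect_true(all(sim$tsps >= rng[1] - 1e-9 & sim$tsps <= rng[2] + 1e-9))
})

test_that("model printing and summaries expose the fitted structure", {
  tg <- test_genome()
  fit <- target_lr(tg$matrix, tg$gold$positives, tg$gold$negatives[[1]],
                   features = c("signal_peptide", "tsps"))
  expect_output(print(fit), "2")
  s <- summary(fit)
  expect_s3_class(s, "summary.target_lr")
  cf <- coef(fit)
  expect_true(all(c("feature", "bin", "lr", "log2_lr") %in% names(cf)))
  expect_true(all(cf$lr > 0))
})
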