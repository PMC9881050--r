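seg <- function(s, k = 10) paste(rep(s, k), collapse = "")

test_that("pairwise identity is matches over alignment length", {
  expect_equal(pairwise_identity("ACDEFGHIKL", "ACDEFGHIKL"), 100)
  expect_equal(pairwise_identity("ACDE", "ACDF"), 75)
  expect_lt(pairwise_identity(seg("W"), seg("M")), 10)
  expect_error(pairwise_identity("", "ACD"), class = "empty_sequence_error")
})

test_that("greedy redundancy removal keeps a maximal sub-threshold set", {
  s1 <- "ACDEFGHIKL"
  a <- paste0(s1, "WWYYWWYYWW")
  b <- paste0(s1, "MMNNMMNNMM")
  cc <- paste0("PPQQPPQQPP", "MMNNMMNNMM")
  seqs <- c(A = a, B = b, C = cc)
  expect_gt(pairwise_identity(a, b), 40)
  expect_gt(pairwise_identity(b, cc), 40)
  expect_lt(pairwise_identity(a, cc), 40)
  kept <- remove_redundancy(seqs)
  expect_identical(kept, c("A", "C"))
  # idempotent
  expect_identical(remove_redundancy(seqs[kept]), kept)
  # duplicate pair: one kept
  expect_length(remove_redundancy(c(x = a, y = a)), 1L)
  # all dissimilar: all kept
  set.seed(31)
  far <- c(u = seg("A"), v = seg("W"), w = seg("Q"))
  expect_length(remove_redundancy(far), 3L)
})

test_that("retained sets never contain a pair above the identity threshold", {
  set.seed(33)
  base <- replicate(6, random_sequence(60))
  # inject near-duplicates of the first two
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), k)
    ch[idx] <- sample(c("A", "G", "S", "T"), k, replace = TRUE)
    paste(ch, collapse = "")
  }
  seqs <- c(base, mutate(base[1], 5), mutate(base[2], 8), base[1])
  names(seqs) <- sprintf("s%02d", seq_along(seqs))
  kept <- remove_redundancy(seqs, threshold = 40)
  pairs <- utils::combn(kept, 2)
  for (j in seq_len(ncol(pairs))) {
    expect_lte(pairwise_identity(seqs[[pairs[1, j]]], seqs[[pairs[2, j]]]),
               40)
  }
})

test_that("negative replicates are seeded, disjoint from exclusions", {
  universe <- sprintf("U%03d", 1:80)
  pos <- universe[1:10]
  excl <- universe[11:20]
  gs1 <- gold_standard(pos, universe, excl, size = 20, n_replicates = 25,
                       seed = 5)
  gs2 <- gold_standard(pos, universe, excl, size = 20, n_replicates = 25,
                       seed = 5)
  expect_identical(gs1$negatives, gs2$negatives)
  for (neg in gs1$negatives) {
    expect_length(neg, 20L)
    expect_length(intersect(neg, c(pos, excl)), 0L)
    expect_false(anyDuplicated(neg) > 0)
  }
  expect_error(gold_standard(pos, universe, universe[11:75], size = 20),
               class = "insufficient_universe_error")
})

test_that("redundancy filtering applies to the negative universe", {
  set.seed(35)
  seqs <- stats::setNames(replicate(12, random_sequence(50)),
                          sprintf("N%02d", 1:12))
  seqs["N11"] <- seqs["N01"]  # inject a duplicate
  gs <- gold_standard(positives = "N12", universe = names(seqs),
                      size = 5, n_replicates = 5, seed = 2,
                      sequences = seqs)
  drawn <- unique(unlist(gs$negatives))
  expect_false(all(c("N01", "N11") %in% drawn))
})

test_that("time split sends pre-cutoff and unknown-date targets to training", {
  years <- list(t2009 = 2009, t_unknown = NA, t_mixed = c(2012, 2009),
                t2012 = 2012, t2015 = c(2015, 2017))
  sp <- time_split(years, cutoff = 2010)
  expect_setequal(sp$train, c("t2009", "t_unknown", "t_mixed"))
  expect_setequal(sp$test, c("t2012", "t2015"))
  expect_length(intersect(sp$train, sp$test), 0L)
})

test_that("innovation statistics trace the jumping/crawling definitions", {
  drugs <- data.frame(drug_id = c("D1", "D2", "D3"),
                      drug_type = "protein",
                      approval_year = c(2000L, 2005L, 2010L),
                      stringsAsFactors = FALSE)
  drugs$targets <- list("T1", c("T1", "T2"), "T3")
  st <- innovation_stats(drugs, bin_years = 5)
  expect_equal(st$drugs$n_new, c(1, 1, 1))
  expect_equal(st$drugs$jumping, c(TRUE, FALSE, TRUE))
  b <- st$bins$protein
  expect_equal(b$new_target_fraction, c(1, 0.5, 1))
  # bin bookkeeping: new + validated = distinct targets used in the bin
  expect_equal(b$n_targets - b$n_new, c(0, 1, 0))
})

test_that("the chronologically first drug is always jumping", {
  set.seed(37)
  drugs <- simulate_drug_table(sprintf("P%03d", 1:60), n_drugs = 30,
                               jumping_fraction = 0.4, seed = 4)
  st <- innovation_stats(drugs)
  first <- which.min(st$drugs$approval_year)
  expect_true(st$drugs$jumping[first])
})

test_that("drug-disease overlap counts only eligible pairs", {
  pairs <- data.frame(
    drug_id = c("d1", "d2", "d3", "d4", "d5", "d6", "d7", "d8"),
    disease_id = c("m1", "m2", "m3", "m4", "m5", "m6", "m7", "m8"))
  drug_targets <- list(d1 = "g1", d2 = "g2", d3 = "g3", d4 = "g4",
                       d5 = "g5", d6 = character(), d7 = "g7",
                       d8 = character())
  disease_genes <- list(m1 = c("g1", "gx"), m2 = "g2", m3 = "gz",
                        m4 = "gy", m5 = "gw", m6 = "g6", m8 = "g8")
  # eligible: d1..d5 (d6/d8 no targets, m7 missing genes); overlaps: d1, d2
  expect_equal(drug_disease_overlap(pairs, drug_targets, disease_genes), 0.4)
  expect_equal(drug_disease_overlap(pairs[1:2, ], drug_targets,
                                    disease_genes), 1.0)
  expect_equal(drug_disease_overlap(pairs[3:5, ], drug_targets,
                                    disease_genes), 0.0)
})
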