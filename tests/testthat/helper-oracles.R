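# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive re-derivation (enumeration / brute force) kept free of
# the package's own code paths.

# all-pairs BFS betweenness by explicit shortest-path counting on an
# adjacency matrix; normalized as 2 * sum / ((N-1)(N-2))
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  stopifnot(n >= 3)
  # BFS from every source: distances and path counts
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  preds <- vector("list", n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    sg <- rep(0, n); sg[s] <- 1
    pred <- replicate(n, integer(), simplify = FALSE)
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) {
        for (w in which(adj[v, ] == 1)) {
          if (w == v) next
          if (is.infinite(d[w])) {
            d[w] <- d[v] + 1
            nxt <- c(nxt, w)
          }
          if (d[w] == d[v] + 1) {
            sg[w] <- sg[w] + sg[v]
            pred[[w]] <- c(pred[[w]], v)
          }
        }
      }
      frontier <- unique(nxt)
    }
    dist[s, ] <- d
    sigma[s, ] <- sg
    preds[[s]] <- pred
  }
  # count, for every unordered pair (s,t) and interior node v, the fraction
  # of shortest s-t paths through v, by enumerating all shortest paths
  enum_paths <- function(s, t, pred) {
    if (t == s) return(list(s))
    out <- list()
    for (p in pred[[t]]) {
      for (path in enum_paths(s, p, pred)) out <- c(out, list(c(path, t)))
    }
    out
  }
  b <- rep(0, n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      if (is.infinite(dist[s, t])) next
      paths <- enum_paths(s, t, preds[[s]])
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(paths, function(p) v %in% p, logical(1)))
        b[v] <- b[v] + through / length(paths)
      }
    }
  }
  2 * b / ((n - 1) * (n - 2))
}

# random undirected graph (adjacency matrix) with named nodes
random_small_graph <- function(n, p = 0.4) {
  adj <- matrix(0L, n, n)
  upper <- which(upper.tri(adj))
  adj[upper] <- stats::rbinom(length(upper), 1L, p)
  adj <- adj + t(adj)
  dimnames(adj) <- list(letters[seq_len(n)], letters[seq_len(n)])
  adj
}

adj_to_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# AUC as the fraction of correctly ordered positive-negative pairs,
# ties credited 0.5
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# entropy-based MI, written against the H(X)+H(Y)-H(X,Y) identity rather
# than the joint/marginal ratio used by the implementation
oracle_mi <- function(x, y) {
  ent <- function(v) {
    p <- as.numeric(table(v)) / length(v)
    -sum(p * log2(p))
  }
  ent(x) + ent(y) - ent(paste(x, y, sep = "\r"))
}

# exhaustive quotient-form greedy ranking from mean relevance/redundancy
oracle_mrmr <- function(relevance, redundancy) {
  feats <- sort(names(relevance))
  chosen <- character()
  while (length(chosen) < length(feats)) {
    cand <- setdiff(feats, chosen)
    if (!length(chosen)) {
      score <- relevance[cand]
    } else {
      score <- vapply(cand, function(f) {
        red <- mean(redundancy[f, chosen])
        if (red > 0) relevance[[f]] / red else Inf
      }, numeric(1))
      if (all(is.infinite(score[score == max(score)])) &&
          sum(score == max(score)) > 1) {
        tied <- cand[score == max(score)]
        score <- stats::setNames(rep(-Inf, length(cand)), cand)
        score[tied] <- relevance[tied]
      }
    }
    chosen <- c(chosen, cand[which.max(score)])
  }
  chosen
}

# small labeled feature-matrix fixture with a kinds attribute
make_feature_df <- function(values, kinds) {
  df <- as.data.frame(values)
  attr(df, "kinds") <- kinds
  df
}

# moderate synthetic genome shared across tests (memoized per session)
.test_genome_cache <- new.env(parent = emptyenv())
test_genome <- function() {
  if (is.null(.test_genome_cache$g)) {
    cfg <- genome_config(n_proteins = 600L, n_positives = 40L, seed = 42L)
    g <- simulate_genome(cfg)
    m <- assemble_feature_matrix(g$sequences, g$expression, g$annotations,
                                 g$networks)
    gs <- gold_standard(g$positives, names(g$sequences), size = 40L,
                        n_replicates = 10L, seed = 7L)
    .test_genome_cache$g <- list(genome = g, matrix = m, gold = gs)
  }
  .test_genome_cache$g
}

# random protein sequence over the 20 standard residues
random_sequence <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), len, replace = TRUE),
        collapse = "")
}
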