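# Synthetic genome generator. Emulates a genome-scale input bundle
# (sequences, annotations, tissue expression, PPI / signal-transduction /
# TF networks, class labels) in which known-target positives carry the
# class-conditional structure reported for real protein drug targets:
# binary-flag prevalences set to the published target vs non-target
# fractions, higher tissue specificity, preferential attachment to
# signaling-network hubs, higher TF indegree, and weak composition biases
# in the amino-acid sequences.

# baseline amino-acid frequencies (approximate human proteome composition)
BASE_AA_FREQ <- c(
  A = 0.070, R = 0.056, N = 0.036, D = 0.047, C = 0.023, Q = 0.048,
  E = 0.071, G = 0.066, H = 0.026, I = 0.043, L = 0.100, K = 0.057,
  M = 0.021, F = 0.036, P = 0.063, S = 0.083, T = 0.054, W = 0.012,
  Y = 0.027, V = 0.060
)

#' Configuration for the synthetic genome generator
#'
#' Defaults encode the reported class-conditional structure of protein drug
#' targets: binary prevalences are the published target/non-target
#' fractions (in percent of each group); expression concentration, network
#' attachment and count distributions reproduce the reported effect
#' directions. `null = TRUE` sets every positive-class parameter equal to
#' its negative-class value (no signal), for null-behavior checks.
#'
#' @param n_proteins Genome size.
#' @param n_positives Number of known-target positives.
#' @param n_tissues Number of tissues in the expression matrix.
#' @param seed Master seed; every draw derives from it.
#' @param null Generate a no-signal genome (all class-conditional
#'   distributions equal).
#' @param binary_prevalence Named list of `c(pos, neg)` Bernoulli rates for
#'   the twelve binary annotation flags.
#' @param tsps_concentration `c(pos, neg)` symmetric Dirichlet concentration
#'   of the tissue expression fractions (smaller = more tissue-specific).
#' @param indegree_lambda `c(pos, neg)` Poisson mean TF indegree.
#' @param attach_gamma `c(signal_pos, ppi_pos)` exponents biasing positive
#'   proteins toward high-degree network nodes.
#' @param aa_shift Named log-weights added to the baseline amino-acid
#'   frequencies for positive proteins.
#' @return A `genome_config` list, validated.
#' @export
genome_config <- function(n_proteins = 5000L, n_positives = 100L,
                          n_tissues = 32L, seed = 1L, null = FALSE,
                          binary_prevalence = NULL,
                          tsps_concentration = c(pos = 0.35, neg = 0.50),
                          indegree_lambda = c(pos = 7.48, neg = 2.96),
                          attach_gamma = c(signal = 2.0, ppi = 0.5),
                          aa_shift = NULL) {
  if (is.null(binary_prevalence)) {
    binary_prevalence <- list(
      signal_peptide       = c(0.8485, 0.1524),
      transmembrane        = c(0.6667, 0.2460),
      signaling_molecule   = c(0.9091, 0.2570),
      transcription_factor = c(0.0000, 0.0297),
      housekeeping         = c(0.2424, 0.5052),
      self_interacting     = c(0.2222, 0.0859),
      enzyme               = c(0.1515, 0.2092),
      gpcr                 = c(0.0505, 0.0187),
      ion_channel          = c(0.0000, 0.0104),
      nhr                  = c(0.0000, 0.0013),
      kinase               = c(0.0303, 0.0144),
      transporter          = c(0.0000, 0.0548)
    )
  }
  if (is.null(aa_shift)) {
    aa_shift <- c(K = -0.25, R = -0.25, H = -0.10, A = 0.08, C = 0.05,
                  G = 0.08, S = 0.08, T = 0.08, F = 0.08, W = 0.08,
                  Y = 0.08)
  }
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    n_positives = as.integer(n_positives),
    n_tissues = as.integer(n_tissues),
    seed = as.integer(seed),
    null = isTRUE(null),
    binary_prevalence = binary_prevalence,
    tsps_concentration = tsps_concentration,
    indegree_lambda = indegree_lambda,
    attach_gamma = attach_gamma,
    aa_shift = aa_shift,
    # c(pos, neg) parameters of the remaining continuous annotations
    domain_mu = c(pos = 3.33, neg = 1.44),
    age_mean = c(pos = 8.55, neg = 10.96),
    evorate_meanlog = c(pos = log(5.0), neg = log(4.2)),
    nns_lambda = c(pos = 2.2, neg = 2.0),
    ns_lambda = c(pos = 1.0, neg = 1.0),
    reaction_lambda = c(pos = 0.04, neg = 0.46),
    pathway_mu = c(pos = 6.13, neg = 0.97),
    seq_meanlog = log(400), seq_sdlog = 0.35, seq_min = 60L,
    ppi_m = 3L, signal_m = 2L
  )
  if (cfg$null) {
    cfg$binary_prevalence <- lapply(cfg$binary_prevalence,
                                    function(p) c(p[2], p[2]))
    for (nm in c("tsps_concentration", "indegree_lambda", "domain_mu",
                 "age_mean", "evorate_meanlog", "nns_lambda", "ns_lambda",
                 "reaction_lambda", "pathway_mu")) {
      cfg[[nm]][1] <- cfg[[nm]][2]
    }
    cfg$attach_gamma[] <- 0
    cfg$aa_shift[] <- 0
  }
  bad <- vapply(cfg$binary_prevalence,
                function(p) any(p < 0) || any(p > 1), logical(1))
  if (any(bad)) {
    stop_tl("binary prevalences must lie in [0, 1]", "config_error")
  }
  if (cfg$n_positives >= cfg$n_proteins) {
    stop_tl("n_positives must be smaller than n_proteins", "config_error")
  }
  if (cfg$n_tissues < 2L) {
    stop_tl("need at least two tissues", "config_error")
  }
  structure(cfg, class = "genome_config")
}

# Bernoulli flag with class-conditional prevalence
draw_flag <- function(prev, is_pos) {
  p <- ifelse(is_pos, prev[1], prev[2])
  as.integer(stats::runif(length(is_pos)) < p)
}

# assign the n_assign positive proteins to graph node slots with probability
# proportional to (degree + 1)^gamma; returns permutation of node ids
assign_hubs <- function(deg, ids, pos_ids, gamma) {
  n <- length(deg)
  stopifnot(length(ids) == n)
  w <- (deg + 1)^gamma
  pos_slots <- sample.int(n, length(pos_ids), prob = w)
  perm <- character(n)
  perm[pos_slots] <- pos_ids
  perm[-pos_slots] <- sample(setdiff(ids, pos_ids))
  perm
}

#' Generate a synthetic genome bundle
#'
#' All randomness derives from `cfg$seed`; identical configurations produce
#' identical bundles.
#'
#' @param cfg A [genome_config()].
#' @return Object of class `synthetic_genome`: list with `sequences` (named
#'   character), `expression` (genes x tissues matrix), `annotations` (data
#'   frame incl. SNP counts), `networks` (list `ppi`, `signal`, `tf`),
#'   `positives` (id vector) and `config`.
#' @export
simulate_genome <- function(cfg = genome_config()) {
  if (!inherits(cfg, "genome_config")) {
    stop_tl("`cfg` must be a genome_config", "config_error")
  }
  with_local_seed(cfg$seed, {
    n <- cfg$n_proteins
    ids <- sprintf("P%05d", seq_len(n))
    positives <- ids[seq_len(cfg$n_positives)]
    is_pos <- ids %in% positives

    # --- annotations ---
    ann <- data.frame(protein_id = ids, stringsAsFactors = FALSE)
    for (f in names(cfg$binary_prevalence)) {
      ann[[f]] <- draw_flag(cfg$binary_prevalence[[f]], is_pos)
    }
    pick <- function(par) ifelse(is_pos, par[1], par[2])
    ann$domain_count <- stats::rnbinom(n, size = 2, mu = pick(cfg$domain_mu))
    ann$age <- pmin(pmax(round(stats::rnorm(n, pick(cfg$age_mean), 3.5)),
                         1L), 16L)
    ann$evolutionary_rate <- stats::rlnorm(n, pick(cfg$evorate_meanlog), 0.6)
    ann$n_ns <- stats::rpois(n, pick(cfg$nns_lambda))
    ann$n_s <- stats::rpois(n, pick(cfg$ns_lambda))
    ann$reaction_count <- stats::rpois(n, pick(cfg$reaction_lambda))
    ann$pathway_count <- stats::rnbinom(n, size = 1, mu = pick(cfg$pathway_mu))

    # --- expression: symmetric Dirichlet fractions, scaled to 100 ---
    conc <- pick(cfg$tsps_concentration)
    g <- matrix(stats::rgamma(n * cfg$n_tissues, shape = rep(conc,
                                                             cfg$n_tissues)),
                nrow = n)
    # non-housekeeping proteins are undetected in >= 1 tissue
    n_zero <- ifelse(ann$housekeeping == 1L, 0L,
                     1L + stats::rbinom(n, cfg$n_tissues %/% 3L, 0.3))
    for (i in which(n_zero > 0L)) {
      g[i, sample.int(cfg$n_tissues, n_zero[i])] <- 0
    }
    expression <- 100 * g / rowSums(g)
    rownames(expression) <- ids
    colnames(expression) <- sprintf("tissue_%02d", seq_len(cfg$n_tissues))

    # --- sequences: class-conditional composition ---
    len <- pmax(round(stats::rlnorm(n, cfg$seq_meanlog, cfg$seq_sdlog)),
                cfg$seq_min)
    freq_neg <- BASE_AA_FREQ / sum(BASE_AA_FREQ)
    w <- freq_neg
    shift <- cfg$aa_shift[intersect(names(cfg$aa_shift), names(w))]
    w[names(shift)] <- w[names(shift)] * exp(shift)
    freq_pos <- w / sum(w)
    sequences <- vapply(seq_len(n), function(i) {
      fr <- if (is_pos[i]) freq_pos else freq_neg
      paste(sample(names(fr), len[i], replace = TRUE, prob = fr),
            collapse = "")
    }, character(1))
    names(sequences) <- ids

    # --- PPI network: preferential-attachment graph over all proteins ---
    ppi_raw <- igraph::sample_pa(n, power = 1, m = cfg$ppi_m,
                                 directed = FALSE)
    deg <- igraph::degree(ppi_raw)
    igraph::V(ppi_raw)$name <- assign_hubs(deg, ids, positives,
                                           cfg$attach_gamma[["ppi"]])
    selfers <- ids[ann$self_interacting == 1L]
    if (length(selfers)) {
      ppi_raw <- igraph::add_edges(ppi_raw,
                                   as.vector(rbind(selfers, selfers)))
    }
    ppi <- ppi_raw

    # --- signal-transduction network: signaling molecules only ---
    members <- ids[ann$signaling_molecule == 1L]
    pos_members <- intersect(members, positives)
    if (length(members) >= 3L) {
      sg <- igraph::sample_pa(length(members), power = 1, m = cfg$signal_m,
                              directed = FALSE)
      igraph::V(sg)$name <- assign_hubs(igraph::degree(sg), members,
                                        pos_members,
                                        cfg$attach_gamma[["signal"]])
    } else {
      sg <- igraph::make_empty_graph(directed = FALSE)
    }

    # --- TF-target network: Poisson indegree, flagged TFs as regulators ---
    tfs <- ids[ann$transcription_factor == 1L]
    if (length(tfs) < 10L) {
      tfs <- union(tfs, sample(setdiff(ids, tfs), 10L - length(tfs)))
    }
    indeg <- stats::rpois(n, pick(cfg$indegree_lambda))
    indeg <- pmin(indeg, length(tfs))
    from <- unlist(lapply(seq_len(n), function(i) {
      if (indeg[i] == 0L) character() else sample(tfs, indeg[i])
    }))
    to <- rep(ids, indeg)
    if (length(to)) {
      tf <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
    } else {
      tf <- igraph::make_empty_graph(directed = TRUE)
    }
    isolated <- setdiff(ids, igraph::V(tf)$name)
    if (length(isolated)) {
      tf <- igraph::add_vertices(tf, length(isolated), name = isolated)
    }

    structure(list(sequences = sequences, expression = expression,
                   annotations = ann,
                   networks = list(ppi = ppi, signal = sg, tf = tf),
                   positives = positives, config = cfg),
              class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("Synthetic genome: %d proteins (%d positives), %d tissues\n",
              x$config$n_proteins, x$config$n_positives,
              x$config$n_tissues))
  cat(sprintf("  networks: PPI %d edges, signal %d edges, TF %d edges\n",
              igraph::ecount(x$networks$ppi),
              igraph::ecount(x$networks$signal),
              igraph::ecount(x$networks$tf)))
  invisible(x)
}

#' Write a synthetic genome bundle to disk
#'
#' Writes `proteins.fasta`, `annotations.tsv`, `expression.tsv`,
#' `ppi.tsv` / `signal.tsv` / `tf.tsv` edge lists and `labels.tsv` into
#' `dir`, in the same formats the analysis functions read.
#'
#' @param genome A `synthetic_genome`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(genome$sequences, file.path(dir, "proteins.fasta"))
  utils::write.table(genome$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expr <- data.frame(gene_id = rownames(genome$expression),
                     genome$expression, check.names = FALSE)
  utils::write.table(expr, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_network(genome$networks$ppi, file.path(dir, "ppi.tsv"))
  write_network(genome$networks$signal, file.path(dir, "signal.tsv"))
  write_network(genome$networks$tf, file.path(dir, "tf.tsv"))
  utils::write.table(
    data.frame(protein_id = names(genome$sequences),
               label = as.integer(names(genome$sequences) %in%
                                    genome$positives)),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' Read an expression matrix TSV (genes x tissues)
#'
#' @param path TSV with a `gene_id` column and one column per tissue.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(m) <- df$gene_id
  m
}

#' Generate a synthetic drug-target table
#'
#' Drugs receive approval years uniform over `year_range` and target sets
#' drawn from `universe`; with probability `jumping_fraction` a drug's
#' targets are all first-use ("jumping"), otherwise at least one target is
#' reused from an earlier drug ("crawling", when an earlier target exists).
#'
#' @param universe Candidate target ids.
#' @param n_drugs Number of drugs.
#' @param year_range Approval-year range `c(first, last)`.
#' @param jumping_fraction Probability a drug gets an all-new target set.
#' @param type_probs Probabilities of drug types protein / peptide /
#'   small_molecule.
#' @param max_targets Maximal targets per drug.
#' @param seed RNG seed.
#' @return Data frame with `drug_id`, `drug_type`, `approval_year` and a
#'   list-column `targets`.
#' @export
simulate_drug_table <- function(universe, n_drugs = 100L,
                                year_range = c(1950L, 2017L),
                                jumping_fraction = 0.5,
                                type_probs = c(protein = 0.3,
                                               peptide = 0.2,
                                               small_molecule = 0.5),
                                max_targets = 3L, seed = 1L) {
  if (jumping_fraction < 0 || jumping_fraction > 1) {
    stop_tl("jumping_fraction must lie in [0, 1]", "config_error")
  }
  with_local_seed(seed, {
    years <- sort(sample(seq(year_range[1], year_range[2]), n_drugs,
                         replace = TRUE))
    types <- sample(names(type_probs), n_drugs, replace = TRUE,
                    prob = type_probs)
    used <- character()
    unused <- sample(universe)
    targets <- vector("list", n_drugs)
    for (i in seq_len(n_drugs)) {
      k <- sample.int(max_targets, 1L)
      jump <- stats::runif(1) < jumping_fraction || !length(used)
      if (jump) {
        k <- min(k, length(unused))
        tset <- unused[seq_len(k)]
        unused <- unused[-seq_len(k)]
      } else {
        reuse <- sample(used, 1L)
        k_new <- min(k - 1L, length(unused))
        tset <- c(reuse, if (k_new > 0L) unused[seq_len(k_new)])
        if (k_new > 0L) unused <- unused[-seq_len(k_new)]
      }
      targets[[i]] <- tset
      used <- union(used, tset)
    }
    data.frame(drug_id = sprintf("D%04d", seq_len(n_drugs)),
               drug_type = types, approval_year = years,
               stringsAsFactors = FALSE) -> df
    df$targets <- targets
    df
  })
}
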