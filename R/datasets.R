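# Gold-standard construction: homology redundancy removal, repeated negative
# sampling, approval-year time split, and the drug-innovation statistics.

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap opening 10, extension
#' 0.5); identity = matched positions / alignment length * 100, where the
#' alignment length counts every alignment column including gaps.
#'
#' @param a,b Amino-acid sequences (single strings).
#' @return Identity percentage in \[0, 100\].
#' @export
pairwise_identity <- function(a, b) {
  a <- validate_sequences(a)[[1]]
  b <- validate_sequences(b)[[1]]
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * sum(pat == sub & pat != "-") / length(pat)
}

#' Remove homologous redundancy from a protein set
#'
#' Greedy single pass in lexicographic id order: a protein is kept iff its
#' global identity to every already-kept protein is at most `threshold`
#' percent. Deterministic and idempotent; no retained pair exceeds the
#' threshold.
#'
#' @param seqs Named character vector of sequences.
#' @param threshold Identity threshold (percent) above which a pair is
#'   redundant.
#' @return Character vector of retained ids (in lexicographic order).
#' @export
remove_redundancy <- function(seqs, threshold = 40) {
  seqs <- validate_sequences(seqs)
  ids <- sort(names(seqs))
  kept <- character()
  for (id in ids) {
    redundant <- FALSE
    for (k in kept) {
      if (pairwise_identity(seqs[[id]], seqs[[k]]) > threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept <- c(kept, id)
  }
  kept
}

#' Build a gold standard with repeated negative sampling
#'
#' The positive set is taken as given (already non-redundant). Negatives are
#' drawn uniformly without replacement from `universe` minus `exclusions`
#' (every known or possible target), repeated `n_replicates` times with
#' per-replicate seeds derived from `seed`; when `sequences` is supplied the
#' eligible universe is first reduced to a non-redundant set with
#' [remove_redundancy()].
#'
#' @param positives Character vector of positive (target) ids.
#' @param universe Character vector of all candidate ids.
#' @param exclusions Ids to exclude from negatives in addition to
#'   `positives` (known and possible targets).
#' @param size Negatives per replicate.
#' @param n_replicates Number of negative replicate sets.
#' @param seed Master seed (integer); replicate r uses `seed + r`.
#' @param sequences Optional named sequences covering the universe, enabling
#'   the redundancy filter on the eligible pool.
#' @param identity_threshold Redundancy threshold passed on to
#'   [remove_redundancy()].
#' @return An object of class `gold_standard`: list with `positives`,
#'   `negatives` (list of id vectors), `universe`, `seeds`.
#' @export
gold_standard <- function(positives, universe, exclusions = character(),
                          size = 100L, n_replicates = 100L, seed = 1L,
                          sequences = NULL, identity_threshold = 40) {
  eligible <- setdiff(universe, union(positives, exclusions))
  if (!is.null(sequences)) {
    eligible <- remove_redundancy(sequences[intersect(eligible,
                                                      names(sequences))],
                                  identity_threshold)
  }
  if (length(eligible) < size) {
    stop_tl(sprintf("only %d eligible proteins for negative sets of size %d",
                    length(eligible), size),
            "insufficient_universe_error")
  }
  eligible <- sort(eligible)
  seeds <- seed + seq_len(n_replicates)
  negatives <- lapply(seeds, function(s) {
    with_local_seed(s, sample(eligible, size))
  })
  structure(list(positives = sort(unique(positives)), negatives = negatives,
                 universe = universe, seeds = seeds),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("Gold standard: %d positives, %d negative replicates of %d (universe %d)\n",
              length(x$positives), length(x$negatives),
              length(x$negatives[[1]]), length(x$universe)))
  invisible(x)
}

#' Time split of targets by first drug approval year
#'
#' Targets first used by a drug approved before `cutoff` - and targets with
#' no approval-date information - form the training side; targets first
#' introduced by drugs approved in or after `cutoff` form the independent
#' test side. A target with any pre-cutoff use stays in training.
#'
#' @param target_years Named list or vector: for each target id, its drugs'
#'   approval years (NA = unknown).
#' @param cutoff Split year.
#' @return List with `train` and `test` id vectors (disjoint).
#' @export
time_split <- function(target_years, cutoff = 2010L) {
  first_year <- vapply(target_years, function(y) {
    y <- y[!is.na(y)]
    if (!length(y)) NA_integer_ else as.integer(min(y))
  }, integer(1))
  ids <- names(target_years)
  train <- ids[is.na(first_year) | first_year < cutoff]
  test <- ids[!is.na(first_year) & first_year >= cutoff]
  list(train = sort(train), test = sort(test))
}

#' Read a drug-target table
#'
#' TSV with columns `drug_id`, `drug_type` (protein/peptide/small_molecule),
#' `approval_year` (empty = unknown) and `targets` (comma-separated ids).
#'
#' @param path TSV path.
#' @return Data frame with a list-column `targets`.
#' @export
read_drug_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = c("NA", ""))
  df$approval_year <- as.integer(df$approval_year)
  df$targets <- strsplit(ifelse(is.na(df$targets), "", df$targets), ",",
                         fixed = TRUE)
  df
}

#' Read a disease-gene table
#'
#' Long-format TSV with columns `disease_id`, `gene_id`.
#'
#' @param path TSV path.
#' @return Named list: disease id -> character vector of known related genes.
#' @export
read_disease_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  lapply(split(df$gene_id, df$disease_id), unique)
}

#' Target-innovation statistics of a drug timeline
#'
#' A target is "new" for a drug iff no drug with a strictly earlier approval
#' year used it ("validated" otherwise). A drug is "jumping" when all its
#' targets are new, "crawling" when at least one is validated. Fractions are
#' aggregated per approval-year bin; drugs without approval year or without
#' targets are excluded.
#'
#' @param drugs Data frame with `drug_id`, `drug_type`, `approval_year` and a
#'   list-column `targets` (see [read_drug_table()]).
#' @param bin_years Bin width in years.
#' @return List with per-drug classification (`drugs`), per-bin new-target
#'   and jumping-drug fractions by drug type (`bins`), and overall fractions
#'   per type (`overall`).
#' @export
innovation_stats <- function(drugs, bin_years = 5L) {
  drugs <- drugs[!is.na(drugs$approval_year) &
                   lengths(drugs$targets) > 0L, , drop = FALSE]
  if (!nrow(drugs)) {
    stop_tl("no drugs with approval year and targets", "invalid_input_error")
  }
  drugs <- drugs[order(drugs$approval_year, drugs$drug_id), , drop = FALSE]
  first_use <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(drugs))) {
    for (t in drugs$targets[[i]]) {
      if (is.null(first_use[[t]])) {
        first_use[[t]] <- drugs$approval_year[i]
      } else {
        first_use[[t]] <- min(first_use[[t]], drugs$approval_year[i])
      }
    }
  }
  new_flags <- lapply(seq_len(nrow(drugs)), function(i) {
    vapply(drugs$targets[[i]],
           function(t) first_use[[t]] >= drugs$approval_year[i], logical(1))
  })
  drugs$n_new <- vapply(new_flags, sum, numeric(1))
  drugs$n_targets <- lengths(drugs$targets)
  drugs$jumping <- drugs$n_new == drugs$n_targets
  y0 <- min(drugs$approval_year)
  drugs$bin <- y0 + bin_years * ((drugs$approval_year - y0) %/% bin_years)

  agg <- function(d) {
    # a bin's new targets are the distinct targets used in the bin whose
    # first use (by any drug, any type) falls inside the bin
    per_bin <- lapply(split(seq_len(nrow(d)), d$bin), function(ix) {
      targets <- unique(unlist(d$targets[ix]))
      yrs <- vapply(targets, function(t) first_use[[t]], numeric(1))
      bin <- d$bin[ix[1]]
      n_new <- sum(yrs >= bin & yrs < bin + bin_years)
      data.frame(bin = bin, n_targets = length(targets), n_new = n_new,
                 new_target_fraction = n_new / length(targets),
                 n_drugs = length(ix), n_jumping = sum(d$jumping[ix]),
                 jumping_fraction = mean(d$jumping[ix]),
                 row.names = NULL)
    })
    do.call(rbind, per_bin)
  }
  bins <- lapply(split(drugs, drugs$drug_type), agg)
  overall <- vapply(bins, function(b) {
    c(new_target_fraction = mean(b$new_target_fraction),
      jumping_fraction = mean(b$jumping_fraction))
  }, numeric(2))
  list(drugs = drugs[, c("drug_id", "drug_type", "approval_year", "bin",
                         "n_targets", "n_new", "jumping")],
       bins = bins, overall = t(overall))
}

#' Fraction of drug-disease pairs explained by a shared target gene
#'
#' Among drug-disease associations where the drug has at least one target and
#' the disease at least one known related gene, the fraction of pairs in
#' which some target of the drug is also a known related gene of the disease.
#'
#' @param pairs Data frame with columns `drug_id`, `disease_id`.
#' @param drug_targets Named list: drug id -> target id vector.
#' @param disease_genes Named list: disease id -> gene id vector.
#' @return Overlap fraction in \[0, 1\] (NA if no eligible pair).
#' @export
drug_disease_overlap <- function(pairs, drug_targets, disease_genes) {
  targets <- drug_targets[pairs$drug_id]
  genes <- disease_genes[pairs$disease_id]
  eligible <- lengths(targets) > 0L & lengths(genes) > 0L
  if (!any(eligible)) return(NA_real_)
  hits <- mapply(function(t, g) length(intersect(t, g)) > 0L,
                 targets[eligible], genes[eligible])
  mean(hits)
}
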