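# Residue-level lookup tables. All sequence features are defined over the 20
# standard amino acids plus the ambiguity codes B (Asp/Asn), Z (Glu/Gln), X
# (any) and U (selenocysteine). Ambiguity handling: B and Z keep the class
# memberships listed for them in the nine-class scheme; for hydropathy-based
# quantities B maps to D, Z to E, X to 0; U is treated like C for hydropathy
# and as non-ionizable everywhere.

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALLOWED <- c(AA_STANDARD, "B", "Z", "X", "U")

# Nine (overlapping) amino-acid classes; B and Z appear exactly where the
# classification scheme places them (small/charged/acidic for B; polar/
# charged/acidic for Z).
AA_CLASSES <- list(
  tiny      = c("A", "C", "G", "S", "T"),
  small     = c("A", "B", "C", "D", "G", "N", "P", "S", "T", "V"),
  aliphatic = c("A", "I", "L", "V"),
  aromatic  = c("F", "H", "W", "Y"),
  nonpolar  = c("A", "C", "F", "G", "I", "L", "M", "P", "V", "W", "Y"),
  polar     = c("D", "E", "H", "K", "N", "Q", "R", "S", "T", "Z"),
  charged   = c("B", "D", "E", "H", "K", "R", "Z"),
  basic     = c("H", "K", "R"),
  acidic    = c("B", "D", "E", "Z")
)

# Kyte-Doolittle hydropathy.
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I =  4.5, L =  3.8, K = -3.9, M =  1.9, F =  2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2,
  B = -3.5, Z = -3.5, X =  0.0, U =  2.5
)

# pepstats-style per-residue charge: K,R +1; H +0.5; D,E -1; B,Z -0.5
# (half-weight for the ambiguous acids); termini ignored.
RESIDUE_CHARGE <- c(
  K = 1, R = 1, H = 0.5, D = -1, E = -1, B = -0.5, Z = -0.5
)

# Bjellqvist pKa values (ProtParam convention). N-terminal pKa depends on the
# first residue; side chains: C, D, E, Y acidic; H, K, R basic.
PKA_SIDE_ACID <- c(C = 9.00, D = 4.05, E = 4.45, Y = 10.00)
PKA_SIDE_BASE <- c(H = 5.98, K = 10.00, R = 12.00)
PKA_CTERM <- 3.55
PKA_NTERM <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
               E = 7.70)
PKA_NTERM_DEFAULT <- 7.50

# Average residue masses (Da, minus water), used by the PEST score.
AA_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326,
  B = 114.5962, Z = 128.6231, X = 110.0000, U = 150.0388
)

# PEST score constants, isolated here so the scoring rule can be recalibrated
# in one place: score = w_depst * (mass % of D/E/P/S/T) - w_hydro * HI, where
# HI is the mass-weighted mean of the Kyte-Doolittle scale mapped onto
# 10*KD + 45 (range 0 for Arg to 90 for Ile).
PEST_CONSTANTS <- list(
  w_depst = 0.55,
  w_hydro = 0.50,
  hydro_index = 10 * KD_HYDROPATHY + 45,
  depst = c("D", "E", "P", "S", "T")
)

#' Validate and normalize protein sequences
#'
#' Upper-cases sequences and checks that every residue is one of the 20
#' standard amino acids or the ambiguity codes B, Z, X, U. Unknown letters
#' are rejected with an `invalid_residue_error`; empty sequences with an
#' `empty_sequence_error`.
#'
#' @param seqs Character vector of amino-acid sequences, optionally named by
#'   protein id.
#' @param allow_empty Keep zero-length sequences instead of erroring.
#' @return The validated, upper-cased character vector.
#' @export
validate_sequences <- function(seqs, allow_empty = FALSE) {
  if (!is.character(seqs)) {
    stop_tl("`seqs` must be a character vector", "invalid_input_error")
  }
  seqs <- toupper(seqs)
  if (!allow_empty && any(!nzchar(seqs))) {
    stop_tl("empty protein sequence", "empty_sequence_error")
  }
  bad <- grepl(sprintf("[^%s]", paste(AA_ALLOWED, collapse = "")), seqs)
  if (any(bad)) {
    offender <- sub(sprintf("^[%s]*", paste(AA_ALLOWED, collapse = "")), "",
                    seqs[bad][1L])
    stop_tl(sprintf("unknown residue letter '%s' in sequence %s",
                    substr(offender, 1L, 1L),
                    if (is.null(names(seqs))) which(bad)[1L]
                    else names(seqs)[bad][1L]),
            "invalid_residue_error")
  }
  seqs
}

#' Read protein sequences from a FASTA file
#'
#' Multi-record, line-wrapped FASTA; the id of each record is the first
#' whitespace-delimited token of its header line. Sequences are validated
#' against the amino-acid alphabet (20 standard residues plus B, Z, X, U).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of validated sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(names(seqs))) {
    stop_tl("duplicate sequence ids in FASTA", "duplicate_id_error")
  }
  validate_sequences(seqs)
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# residue count matrix: one row per sequence, one column per allowed letter
residue_counts <- function(seqs) {
  chars <- strsplit(seqs, "", fixed = TRUE)
  t(vapply(chars, function(ch) {
    tabulate(factor(ch, levels = AA_ALLOWED), nbins = length(AA_ALLOWED))
  }, integer(length(AA_ALLOWED))))
}

#' Amino-acid class composition
#'
#' Percentage of residues falling in each of the nine (overlapping) classes:
#' tiny, small, aliphatic, aromatic, nonpolar, polar, charged, basic, acidic.
#' Because the classes overlap, rows do not sum to 100.
#'
#' @param seqs Character vector of sequences (validated internally).
#' @return Numeric matrix, one row per sequence, nine columns.
#' @export
aa_class_percentages <- function(seqs) {
  seqs <- validate_sequences(seqs)
  counts <- residue_counts(seqs)
  colnames(counts) <- AA_ALLOWED
  len <- rowSums(counts)
  out <- vapply(AA_CLASSES, function(cls) {
    100 * rowSums(counts[, cls, drop = FALSE]) / len
  }, numeric(length(seqs)))
  if (length(seqs) == 1L) out <- matrix(out, nrow = 1L,
                                        dimnames = list(names(seqs),
                                                        names(AA_CLASSES)))
  rownames(out) <- names(seqs)
  out
}

#' Grand average of hydropathy (GRAVY)
#'
#' Sum of Kyte-Doolittle hydropathy values divided by sequence length.
#'
#' @param seqs Character vector of sequences.
#' @return Numeric vector of GRAVY values.
#' @export
gravy <- function(seqs) {
  seqs <- validate_sequences(seqs)
  counts <- residue_counts(seqs)
  drop(counts %*% KD_HYDROPATHY[AA_ALLOWED]) / rowSums(counts)
}

#' Sequence charge
#'
#' Sum of per-residue charges under the pepstats convention (K, R = +1;
#' H = +0.5; D, E = -1; B, Z = -0.5; termini ignored). Additive under
#' concatenation.
#'
#' @param seqs Character vector of sequences.
#' @return Numeric vector of net charges.
#' @export
sequence_charge <- function(seqs) {
  seqs <- validate_sequences(seqs)
  counts <- residue_counts(seqs)
  colnames(counts) <- AA_ALLOWED
  drop(counts[, names(RESIDUE_CHARGE), drop = FALSE] %*% RESIDUE_CHARGE)
}

# Henderson-Hasselbalch net charge of a residue-count vector at a given pH.
hh_net_charge <- function(counts, first_residue, pH) {
  # B counts as D, Z as E for ionization
  n_acid <- c(C = unname(counts["C"]),
              D = unname(counts["D"]) + unname(counts["B"]),
              E = unname(counts["E"]) + unname(counts["Z"]),
              Y = unname(counts["Y"]))
  n_base <- c(H = unname(counts["H"]), K = unname(counts["K"]),
              R = unname(counts["R"]))
  pk_n <- if (first_residue %in% names(PKA_NTERM)) PKA_NTERM[[first_residue]]
          else PKA_NTERM_DEFAULT
  pos <- sum(n_base / (1 + 10^(pH - PKA_SIDE_BASE[names(n_base)]))) +
    1 / (1 + 10^(pH - pk_n))
  neg <- sum(n_acid[c("C", "D", "E", "Y")] /
               (1 + 10^(PKA_SIDE_ACID[c("C", "D", "E", "Y")] - pH))) +
    1 / (1 + 10^(PKA_CTERM - pH))
  pos - neg
}

#' Theoretical isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge of the protein (side
#' chains C, D, E, Y, H, K, R plus both termini, Bjellqvist pKa set) is zero,
#' located by bisection on \[0, 14\] to |charge| < `tol`.
#'
#' @param seqs Character vector of sequences.
#' @param tol Charge tolerance at the returned pH.
#' @return Numeric vector of pI values in (0, 14).
#' @export
theoretical_pi <- function(seqs, tol = 1e-3) {
  seqs <- validate_sequences(seqs)
  counts <- residue_counts(seqs)
  colnames(counts) <- AA_ALLOWED
  first <- substr(seqs, 1L, 1L)
  vapply(seq_along(seqs), function(i) {
    lo <- 0; hi <- 14
    repeat {
      mid <- (lo + hi) / 2
      q <- hh_net_charge(counts[i, ], first[i], mid)
      if (abs(q) < tol || hi - lo < 1e-8) return(mid)
      if (q > 0) lo <- mid else hi <- mid
    }
  }, numeric(1))
}

# FoldIndex charge convention: full +/-1 charges only (K, R positive; D, E
# negative, with B -> D and Z -> E).
foldindex_charge <- c(K = 1, R = 1, D = -1, E = -1, B = -1, Z = -1)

# per-position fold index over a centered window truncated at the termini
fold_index_profile <- function(seq, window = 51L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  hyd <- (unname(KD_HYDROPATHY[ch]) + 4.5) / 9
  chg <- unname(foldindex_charge[ch])
  chg[is.na(chg)] <- 0
  half <- (window - 1L) %/% 2L
  lo <- pmax(seq_len(L) - half, 1L)
  hi <- pmin(seq_len(L) + half, L)
  cs_h <- cumsum(c(0, hyd))
  cs_c <- cumsum(c(0, chg))
  n <- hi - lo + 1L
  mean_h <- (cs_h[hi + 1L] - cs_h[lo]) / n
  mean_c <- (cs_c[hi + 1L] - cs_c[lo]) / n
  2.785 * mean_h - abs(mean_c) - 1.151
}

#' Intrinsic disorder score
#'
#' Per-position fold index (`2.785 * <H> - |<R>| - 1.151`, with `<H>` the mean
#' Kyte-Doolittle hydropathy rescaled to \[0, 1\] and `<R>` the mean residue
#' charge, over a centered window truncated at the termini). Maximal runs of
#' negative index with length at least `min_region` are summed and divided by
#' the sequence length.
#'
#' @param seqs Character vector of sequences.
#' @param window Sliding-window width (residues).
#' @param min_region Minimum length for a disordered region to be counted.
#' @return Numeric vector of disorder fractions in \[0, 1\].
#' @export
disorder_score <- function(seqs, window = 51L, min_region = 30L) {
  seqs <- validate_sequences(seqs)
  vapply(seqs, function(s) {
    idx <- fold_index_profile(s, window)
    neg <- idx < 0
    r <- rle(neg)
    disordered <- sum(r$lengths[r$values & r$lengths >= min_region])
    disordered / nchar(s)
  }, numeric(1), USE.NAMES = FALSE)
}

# score one candidate PEST region (character vector of residues)
pest_region_score <- function(ch) {
  m <- unname(AA_MASS[ch])
  total <- sum(m)
  depst <- 100 * sum(m[ch %in% PEST_CONSTANTS$depst]) / total
  hi <- sum(m * unname(PEST_CONSTANTS$hydro_index[ch])) / total
  PEST_CONSTANTS$w_depst * depst - PEST_CONSTANTS$w_hydro * hi
}

#' Find PEST motifs
#'
#' Candidate regions are the maximal stretches strictly between positively
#' charged residues (K, R, H) or the sequence termini. A candidate is valid
#' if it is at least `min_window` residues long and contains at least one P,
#' one of D/E and one of S/T; valid candidates scoring at least `threshold`
#' under the mass-fraction PEST score are classed "potential", the rest
#' "poor".
#'
#' @param seq A single sequence.
#' @param min_window Minimum region length.
#' @param threshold Score threshold for a "potential" motif.
#' @return Data frame with 0-based half-open `start`/`end`, `score` and
#'   `category` per valid candidate region.
#' @export
find_pest_motifs <- function(seq, min_window = 10L, threshold = 5.0) {
  seq <- validate_sequences(seq)[[1]]
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  flank <- which(ch %in% c("K", "R", "H"))
  bounds <- c(0L, flank, length(ch) + 1L)
  out <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    s <- bounds[i] + 1L   # first residue inside the region (1-based)
    e <- bounds[i + 1L] - 1L
    if (e - s + 1L < min_window) next
    reg <- ch[s:e]
    if (!any(reg == "P")) next
    if (!any(reg %in% c("D", "E"))) next
    if (!any(reg %in% c("S", "T"))) next
    sc <- pest_region_score(reg)
    out[[length(out) + 1L]] <- data.frame(
      start = s - 1L, end = e, score = sc,
      category = if (sc >= threshold) "potential" else "poor",
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), score = numeric(),
                      category = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Count potential PEST motifs
#'
#' @inheritParams find_pest_motifs
#' @param seqs Character vector of sequences.
#' @return Integer vector: number of "potential" PEST motifs per sequence.
#' @export
pest_count <- function(seqs, min_window = 10L, threshold = 5.0) {
  seqs <- validate_sequences(seqs)
  vapply(seqs, function(s) {
    m <- find_pest_motifs(s, min_window, threshold)
    sum(m$category == "potential")
  }, integer(1), USE.NAMES = FALSE)
}
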