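#' Tissue specificity score (TSPS)
#'
#' KL-divergence-like score of a gene's tissue expression profile against the
#' uniform distribution: `sum_i f_i * log2(f_i / p)` with `f_i` the fraction
#' of the gene's total expression in tissue i and `p = 1/n`. Zero-expression
#' tissues contribute 0; the score is 0 for a perfectly uniform profile and
#' reaches `log2(n)` for single-tissue expression.
#'
#' @param values Non-negative expression values across tissues (one gene), or
#'   a matrix with genes in rows.
#' @return TSPS value(s), non-negative.
#' @export
tsps <- function(values) {
  if (is.matrix(values)) return(apply(values, 1L, tsps))
  if (any(values < 0) || anyNA(values)) {
    stop_tl("expression values must be non-negative and non-missing",
            "invalid_input_error")
  }
  total <- sum(values)
  if (total == 0) {
    stop_tl("TSPS undefined for an all-zero expression profile",
            "undefined_score_error")
  }
  n <- length(values)
  f <- values / total
  f <- f[f > 0]
  sum(f * log2(f * n))
}

#' Housekeeping flag from an expression profile
#'
#' A gene is flagged housekeeping when it is detected (value strictly greater
#' than `detect_threshold`) in every tissue.
#'
#' @param values Expression values across tissues, or a genes-by-tissues
#'   matrix.
#' @param detect_threshold Detection cutoff (strict inequality).
#' @return Logical flag(s).
#' @export
housekeeping_flag <- function(values, detect_threshold = 0) {
  if (is.matrix(values)) {
    return(apply(values, 1L, housekeeping_flag,
                 detect_threshold = detect_threshold))
  }
  all(values > detect_threshold)
}

#' Nonsynonymous/synonymous polymorphism ratio
#'
#' Smoothed ratio `(N_ns + eps) / (N_s + eps)` of nonsynonymous to synonymous
#' SNP counts (GMAF >= 1% upstream); `eps` guards against zero denominators
#' from small samples.
#'
#' @param n_ns,n_s Non-negative SNP counts (vectorized).
#' @param eps Smoothing constant, must be positive.
#' @return Positive ratio(s).
#' @export
c_ratio <- function(n_ns, n_s, eps = 0.01) {
  if (eps <= 0) stop_tl("eps must be positive", "invalid_count_error")
  if (any(n_ns < 0, na.rm = TRUE) || any(n_s < 0, na.rm = TRUE)) {
    stop_tl("SNP counts must be non-negative", "invalid_count_error")
  }
  (n_ns + eps) / (n_s + eps)
}

# canonical feature list: name -> kind ("binary" or "continuous")
feature_kinds_catalog <- function() {
  binary <- c("signal_peptide", "transmembrane", "signaling_molecule",
              "transcription_factor", "housekeeping", "self_interacting",
              "enzyme", "gpcr", "ion_channel", "nhr", "kinase", "transporter")
  continuous <- c("tiny", "small", "aliphatic", "aromatic", "nonpolar",
                  "polar", "charged", "basic", "acidic", "gravy", "pi",
                  "charge", "domain_count", "disorder_score", "pest_count",
                  "tsps", "age", "evolutionary_rate", "c_ratio",
                  "reaction_count", "pathway_count", "degree_ppi",
                  "betweenness_ppi", "degree_signal", "betweenness_signal",
                  "indegree_tf", "outdegree_tf")
  c(stats::setNames(rep("binary", length(binary)), binary),
    stats::setNames(rep("continuous", length(continuous)), continuous))
}

#' Assemble the protein feature matrix
#'
#' Joins sequence-derived features, expression-derived features (TSPS),
#' annotation columns and network centralities into one data frame, one row
#' per protein in `sequences`. Proteins absent from a source get `NA` in the
#' corresponding columns (explicit missingness, never silent zeros). The
#' per-column kind (binary/continuous) is attached as attribute `"kinds"`.
#'
#' @param sequences Named character vector of validated protein sequences.
#' @param expression Numeric genes-by-tissues matrix (rownames = gene ids), or
#'   NULL.
#' @param annotations Data frame with a `protein_id` column plus binary flags
#'   and count/ordinal columns (see [feature_kinds_catalog()]), or NULL.
#'   Columns `n_ns`/`n_s` are converted to `c_ratio`.
#' @param networks Named list with optional elements `ppi`, `signal`
#'   (undirected igraph) and `tf` (directed igraph), or NULL.
#' @return Data frame of features with rownames = protein ids and attribute
#'   `"kinds"`.
#' @export
assemble_feature_matrix <- function(sequences, expression = NULL,
                                    annotations = NULL, networks = NULL) {
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop_tl("sequences must be uniquely named by protein id",
            "duplicate_id_error")
  }
  comp <- aa_class_percentages(sequences)
  out <- data.frame(comp,
                    gravy = gravy(sequences),
                    pi = theoretical_pi(sequences),
                    charge = sequence_charge(sequences),
                    disorder_score = disorder_score(sequences),
                    pest_count = as.numeric(pest_count(sequences)),
                    row.names = ids, check.names = FALSE)

  out$tsps <- NA_real_
  if (!is.null(expression)) {
    shared <- intersect(ids, rownames(expression))
    if (length(shared)) {
      out[shared, "tsps"] <- tsps(expression[shared, , drop = FALSE])
    }
  }

  catalog <- feature_kinds_catalog()
  ann_cols <- c(names(catalog)[catalog == "binary"], "domain_count", "age",
                "evolutionary_rate", "reaction_count", "pathway_count")
  for (col in ann_cols) out[[col]] <- NA_real_
  out$c_ratio <- NA_real_
  if (!is.null(annotations)) {
    if (anyDuplicated(annotations$protein_id)) {
      stop_tl("duplicate protein ids in annotation table",
              "duplicate_id_error")
    }
    idx <- match(ids, annotations$protein_id)
    for (col in intersect(ann_cols, names(annotations))) {
      out[[col]] <- as.numeric(annotations[[col]][idx])
    }
    if (all(c("n_ns", "n_s") %in% names(annotations))) {
      out$c_ratio <- c_ratio(annotations$n_ns[idx], annotations$n_s[idx])
    }
  }

  for (col in c("degree_ppi", "betweenness_ppi", "degree_signal",
                "betweenness_signal", "indegree_tf", "outdegree_tf")) {
    out[[col]] <- NA_real_
  }
  if (!is.null(networks)) {
    if (!is.null(networks$ppi)) {
      g <- networks$ppi
      shared <- intersect(ids, igraph::V(g)$name)
      out[shared, "degree_ppi"] <- degree_centrality(g, shared)
      out[shared, "betweenness_ppi"] <- betweenness_centrality(g, shared)
    }
    if (!is.null(networks$signal)) {
      g <- networks$signal
      shared <- intersect(ids, igraph::V(g)$name)
      out[shared, "degree_signal"] <- degree_centrality(g, shared)
      out[shared, "betweenness_signal"] <- betweenness_centrality(g, shared)
    }
    if (!is.null(networks$tf)) {
      g <- networks$tf
      shared <- intersect(ids, igraph::V(g)$name)
      deg <- tf_degrees(g, shared)
      out[shared, "indegree_tf"] <- deg[, "indegree"]
      out[shared, "outdegree_tf"] <- deg[, "outdegree"]
    }
  }

  out <- out[, names(catalog)]
  attr(out, "kinds") <- catalog
  out
}

#' Write / read a feature matrix as TSV
#'
#' The first line is a `#kind:` comment recording each column's binary or
#' continuous type, followed by a header row (`protein_id` + feature names)
#' and one row per protein. `read_feature_tsv` restores the `"kinds"`
#' attribute, so write/read round-trips the matrix exactly.
#'
#' @param m Feature matrix from [assemble_feature_matrix()].
#' @param path Output path.
#' @export
write_feature_tsv <- function(m, path) {
  kinds <- attr(m, "kinds")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#kind:\t", paste(kinds[names(m)], collapse = "\t")), con)
  df <- cbind(protein_id = rownames(m), m)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @param path Path to a TSV written by [write_feature_tsv()].
#' @export
read_feature_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  kinds_line <- NULL
  if (startsWith(first, "#kind:")) {
    kinds_line <- strsplit(first, "\t", fixed = TRUE)[[1]][-1L]
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  rownames(df) <- df$protein_id
  df$protein_id <- NULL
  for (j in seq_along(df)) df[[j]] <- as.numeric(df[[j]])
  if (!is.null(kinds_line)) {
    attr(df, "kinds") <- stats::setNames(kinds_line, names(df))
  }
  df
}
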