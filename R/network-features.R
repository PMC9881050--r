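# Network features. Graphs are igraph objects with a `name` vertex attribute;
# PPI and signal-transduction networks are undirected (self-loops allowed in
# the PPI network, where they encode self-interaction), the TF-target network
# is directed.

#' Read a network from an edge-list TSV
#'
#' Two id columns per line, tab-separated; lines starting with `#` are
#' comments. A header line `#directed` marks the network as directed.
#' Duplicate undirected edges are collapsed; self-loops are kept.
#'
#' @param path Edge-list path.
#' @param directed Directedness; default taken from a `#directed` comment
#'   line, else undirected.
#' @return An igraph graph.
#' @export
read_network <- function(path, directed = NULL) {
  lines <- readLines(path)
  if (is.null(directed)) directed <- any(grepl("^#directed", lines))
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(igraph::make_empty_graph(directed = directed))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  el <- cbind(vapply(parts, `[[`, character(1), 1L),
              vapply(parts, `[[`, character(1), 2L))
  g <- igraph::graph_from_edgelist(el, directed = directed)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = FALSE)
}

#' Write a network as an edge-list TSV
#'
#' @param g An igraph graph with named vertices.
#' @param path Output path.
#' @export
write_network <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (igraph::is_directed(g)) writeLines("#directed", con)
  el <- igraph::as_edgelist(g)
  utils::write.table(el, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

check_nodes <- function(g, nodes) {
  missing <- setdiff(nodes, igraph::V(g)$name)
  if (length(missing)) {
    stop_tl(sprintf("node(s) not in network: %s",
                    paste(utils::head(missing, 3L), collapse = ", ")),
            "unknown_node_error")
  }
}

#' Degree: number of distinct interaction partners
#'
#' Counts distinct neighbors; a self-loop is not an interaction partner (it
#' marks self-interaction instead, see [self_interacting()]).
#'
#' @param g An igraph graph.
#' @param nodes Node names (default all).
#' @return Named integer vector of degrees.
#' @export
degree_centrality <- function(g, nodes = igraph::V(g)$name) {
  check_nodes(g, nodes)
  simple <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  deg <- igraph::degree(simple, mode = "all")
  names(deg) <- igraph::V(simple)$name
  deg[nodes]
}

#' Self-interaction flag
#'
#' TRUE for nodes carrying a self-loop in the (PPI) network.
#'
#' @inheritParams degree_centrality
#' @return Named logical vector.
#' @export
self_interacting <- function(g, nodes = igraph::V(g)$name) {
  check_nodes(g, nodes)
  loops <- igraph::which_loop(g)
  loop_nodes <- unique(igraph::as_edgelist(g)[loops, 1L])
  stats::setNames(nodes %in% loop_nodes, nodes)
}

#' Normalized betweenness centrality
#'
#' `B(n) = 2 * sum_{s != n != t} sigma_st(n)/sigma_st / ((N-1)(N-2))` over
#' unordered node pairs, with shortest paths by breadth-first search on the
#' unweighted, undirected graph. Disconnected pairs (sigma_st = 0) contribute
#' nothing.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector of betweenness values in \[0, 1\].
#' @export
betweenness_centrality <- function(g, nodes = igraph::V(g)$name) {
  if (igraph::is_directed(g)) {
    stop_tl("betweenness is defined here for undirected networks only",
            "invalid_input_error")
  }
  check_nodes(g, nodes)
  if (igraph::vcount(g) < 3L) {
    stop_tl("betweenness undefined for networks with fewer than 3 nodes",
            "undefined_score_error")
  }
  simple <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  b <- igraph::betweenness(simple, directed = FALSE, normalized = TRUE)
  names(b) <- igraph::V(simple)$name
  b[nodes]
}

#' In/out-degree in the directed TF-target network
#'
#' Indegree of a gene = number of TFs regulating it; outdegree of a TF =
#' number of genes it regulates.
#'
#' @param g A directed igraph graph (edges TF -> target).
#' @param nodes Node names (default all).
#' @return Matrix with columns `indegree`, `outdegree`.
#' @export
tf_degrees <- function(g, nodes = igraph::V(g)$name) {
  if (!igraph::is_directed(g)) {
    stop_tl("TF network must be directed", "invalid_input_error")
  }
  check_nodes(g, nodes)
  ind <- igraph::degree(g, mode = "in")
  outd <- igraph::degree(g, mode = "out")
  names(ind) <- names(outd) <- igraph::V(g)$name
  cbind(indegree = ind[nodes], outdegree = outd[nodes])
}

#' Distance from a protein to a disease's known genes
#'
#' Minimum unweighted shortest-path length in the PPI network between the
#' protein and any known related gene of the disease; 0 if the protein is
#' itself a known disease gene, `Inf` if no disease gene is reachable.
#'
#' @param g Undirected igraph PPI network.
#' @param protein Protein id.
#' @param disease_genes Non-empty character vector of known disease gene ids.
#' @return Non-negative integer distance, or `Inf` when unreachable.
#' @export
disease_distance <- function(g, protein, disease_genes) {
  if (!length(disease_genes)) {
    stop_tl("empty disease gene set", "invalid_input_error")
  }
  if (protein %in% disease_genes) return(0)
  check_nodes(g, protein)
  present <- intersect(disease_genes, igraph::V(g)$name)
  if (!length(present)) return(Inf)
  d <- igraph::distances(g, v = protein, to = present, mode = "all")
  min(d)
}
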