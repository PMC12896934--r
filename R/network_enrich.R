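#' Degree-ranked hub genes on an interaction network
#'
#' Builds the subgraph induced by the query genes (the full network when no
#' query is given) and ranks its nodes by degree, descending; ties are
#' broken lexicographically by gene id. Only nodes that appear in at least
#' one edge of the induced subgraph are considered.
#'
#' @param edges Edge list data.frame (`from`, `to`) as from [read_edge_list()].
#' @param query Optional character vector restricting the network to these
#'   genes before ranking.
#' @param k Number of hubs to return (default 10).
#' @return data.frame `gene_id`, `degree`, `rank` with at most `k` rows
#'   (fewer, with a warning, when the induced subgraph is smaller).
#' @export
hub_genes <- function(edges, query = NULL, k = 10) {
  if (k < 1) stop_usage("k must be >= 1")
  if (!all(c("from", "to") %in% names(edges))) {
    stop_usage("edges must have columns 'from' and 'to'")
  }
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE)
  if (!is.null(query)) {
    keep <- intersect(igraph::V(g)$name, query)
    g <- igraph::induced_subgraph(g, keep)
    g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  }
  if (igraph::vcount(g) == 0) {
    warning("induced subgraph is empty; no hubs to report")
    return(data.frame(gene_id = character(), degree = integer(),
                      rank = integer(), stringsAsFactors = FALSE))
  }
  deg <- igraph::degree(g)
  ord <- order(-deg, names(deg))
  top <- utils::head(ord, k)
  if (length(top) < k) {
    warning(sprintf("only %d node(s) in the induced subgraph (k = %d)",
                    length(top), k))
  }
  data.frame(gene_id = names(deg)[top],
             degree = as.integer(deg[top]),
             rank = seq_along(top),
             stringsAsFactors = FALSE)
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, tests whether the query list overlaps the set more
#' than expected by chance in the given universe, using the upper-tail
#' hypergeometric probability `P(X >= k)` with `K` set members in a universe
#' of `N` genes and a query of size `n`. Set memberships are intersected
#' with the universe first; query genes outside the universe are dropped
#' with a message. Benjamini-Hochberg adjustment is applied across sets and
#' rows are sorted by p-value.
#'
#' @param query Character vector of genes of interest.
#' @param sets Gene-set collection as from [read_gmt()] (named list).
#' @param universe Character vector: the background gene universe (for a
#'   transcriptome analysis, all genes passing the expression filter).
#' @return data.frame with `set_name`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p_value`, `p_adjusted`, `genes` (overlap ids,
#'   `;`-separated).
#' @export
enrich <- function(query, sets, universe) {
  if (!length(universe)) stop_usage("universe must be non-empty")
  universe <- unique(universe)
  query <- unique(query)
  dropped <- setdiff(query, universe)
  if (length(dropped)) {
    message(sprintf("enrich: dropped %d query gene(s) outside the universe",
                    length(dropped)))
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), universe)
    K <- length(members)
    hit <- intersect(query, members)
    k <- length(hit)
    # upper tail including k itself: P(X >= k)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = K, query_size = n,
               universe_size = N, p_value = p,
               genes = paste(sort(hit), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set_name), ]
  rownames(out) <- NULL
  out[, c("set_name", "overlap", "set_size", "query_size", "universe_size",
          "p_value", "p_adjusted", "genes")]
}
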