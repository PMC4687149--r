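#' Collapse a SNP-level network to a gene-gene network
#'
#' Two genes are connected if at least one pair of their SNPs is connected
#' in the SNP-level network. A SNP edge whose endpoints map to the same
#' gene becomes a self-loop on that gene. Parallel gene edges arising from
#' multiple SNP pairs are merged into one, with the number of underlying
#' SNP edges kept as the edge attribute \code{n_snp_edges}.
#'
#' @param snp_network An undirected \pkg{igraph} SNP-level graph.
#' @param map A data.frame with columns \code{snp_id}, \code{gene_id}
#'   covering every SNP vertex in the network.
#' @return An undirected \pkg{igraph} gene-level graph (possible
#'   self-loops) with graph attribute \code{level = "gene"}.
#' @export
collapse_to_genes <- function(snp_network, map) {
  stopifnot(igraph::is_igraph(snp_network))
  stopifnot(all(c("snp_id", "gene_id") %in% names(map)))
  snps <- igraph::V(snp_network)$name
  gene_of <- stats::setNames(as.character(map$gene_id), map$snp_id)
  missing <- setdiff(snps, names(gene_of))
  if (length(missing) > 0L)
    stop("SNP(s) without a gene mapping: ", paste(missing, collapse = ", "))

  el <- igraph::as_edgelist(snp_network)
  if (nrow(el) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- g + igraph::vertices(unique(unname(gene_of[snps])))
  } else {
    ge <- cbind(gene_of[el[, 1]], gene_of[el[, 2]])
    # canonical endpoint order, then merge duplicates
    swap <- ge[, 1] > ge[, 2]
    ge[swap, ] <- ge[swap, 2:1]
    key <- paste(ge[, 1], ge[, 2], sep = "\r")
    mult <- table(key)
    uniq <- ge[!duplicated(key), , drop = FALSE]
    g <- igraph::graph_from_edgelist(uniq, directed = FALSE)
    igraph::E(g)$n_snp_edges <- as.integer(mult[paste(uniq[, 1], uniq[, 2],
                                                      sep = "\r")])
    iso <- setdiff(unique(unname(gene_of[snps])), igraph::V(g)$name)
    if (length(iso) > 0L) g <- g + igraph::vertices(iso)
  }
  igraph::set_graph_attr(g, "level", "gene")
}

#' Component statistics of a gene-level network
#'
#' Identical to [summarize_network()]: connected components by undirected
#' reachability (self-loops never join components), giant component size,
#' and distinct-neighbor degrees with self-loops excluded.
#'
#' @param gene_network An undirected \pkg{igraph} graph.
#' @return A \code{network_summary}.
#' @export
component_stats <- function(gene_network) summarize_network(gene_network)
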