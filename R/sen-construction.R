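#' Build a SNP-level statistical epistasis network
#'
#' Connects two SNPs whenever their pairwise information gain is strictly
#' greater than the threshold. Only SNPs incident to at least one edge
#' appear as vertices; isolated SNPs are dropped, so the vertex count is
#' the number of edge-incident SNPs.
#'
#' @param scores An \code{interaction_scores} object from [all_pairs_ig()].
#' @param threshold Edge-inclusion threshold in bits; \code{-Inf} yields the
#'   complete graph.
#' @return An undirected \pkg{igraph} graph with edge attribute \code{ig}
#'   and graph attribute \code{level = "snp"}.
#' @export
build_network <- function(scores, threshold) {
  stopifnot(inherits(scores, "interaction_scores"))
  if (is.na(threshold) || threshold == Inf)
    stop("'threshold' must be finite or -Inf")
  ig <- scores$ig
  sel <- which(upper.tri(ig) & ig > threshold, arr.ind = TRUE)
  if (nrow(sel) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    g <- igraph::graph_from_edgelist(
      cbind(scores$snp_ids[sel[, 1]], scores$snp_ids[sel[, 2]]),
      directed = FALSE)
    igraph::E(g)$ig <- ig[sel]
  }
  g <- igraph::set_graph_attr(g, "level", "snp")
  g
}

#' Summarize global network topology
#'
#' Reports the global properties used to judge a network against its
#' permutation nulls: vertex and edge counts, connected components, giant
#' component size and the degree sequence. Degree here counts distinct
#' neighbors, so self-loops contribute to the edge inventory but not to any
#' vertex's neighbor count, and the mean neighbor count equals
#' \eqn{2 M / N} with \eqn{M} the number of non-self-loop edges.
#'
#' @param network An undirected \pkg{igraph} graph.
#' @return A list of class \code{network_summary} with fields
#'   \code{n_vertices}, \code{n_edges}, \code{n_self_loops},
#'   \code{n_components}, \code{giant_component_size},
#'   \code{degree_sequence} (named, distinct-neighbor counts) and
#'   \code{mean_neighbors}.
#' @export
summarize_network <- function(network) {
  stopifnot(igraph::is_igraph(network))
  nv <- igraph::vcount(network)
  loops <- igraph::which_loop(network)
  simple <- igraph::delete_edges(network, igraph::E(network)[loops])
  simple <- igraph::simplify(simple, remove.multiple = TRUE, remove.loops = TRUE)
  deg <- igraph::degree(simple)
  comp <- igraph::components(network)
  structure(
    list(n_vertices = nv,
         n_edges = igraph::ecount(network),
         n_self_loops = sum(loops),
         n_components = comp$no,
         giant_component_size = if (nv == 0L) 0L else max(comp$csize),
         degree_sequence = deg,
         mean_neighbors = if (nv == 0L) NA_real_ else sum(deg) / nv),
    class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(
    "Network: %d vertices, %d edges (%d self-loop%s), %d components, giant = %d, mean neighbors = %.2f\n",
    x$n_vertices, x$n_edges, x$n_self_loops,
    if (x$n_self_loops == 1L) "" else "s",
    x$n_components, x$giant_component_size, x$mean_neighbors))
  invisible(x)
}

#' Topology summaries of phenotype-permuted null networks
#'
#' Shuffles the phenotype labels uniformly (case/control counts fixed),
#' recomputes all pairwise information gains, rebuilds the network at the
#' given threshold and summarizes it — once per permutation replicate.
#' These null summaries are the reference distribution against which the
#' real network's topology is judged.
#'
#' @param dataset A complete (imputed) [genotype_dataset()].
#' @param threshold Edge threshold in bits.
#' @param n_perms Number of permutation replicates (>= 1).
#' @param seed Integer seed.
#' @return List of \code{network_summary} objects, one per replicate.
#' @export
null_network_summaries <- function(dataset, threshold, n_perms, seed = 1L) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (n_perms < 1L) stop("'n_perms' must be >= 1")
  set.seed(seed)
  lapply(seq_len(n_perms), function(r) {
    ds <- dataset
    ds$phenotype <- sample(dataset$phenotype)
    summarize_network(build_network(all_pairs_ig(ds), threshold))
  })
}

#' Select the edge threshold by permutation contrast
#'
#' Grid-searches candidate thresholds and, at each, compares the real
#' network's giant-component size with its distribution across
#' phenotype-permuted null networks. The selected threshold maximizes the
#' z-score (real giant size minus null mean, over null standard deviation);
#' grid points with degenerate null variance are skipped with a warning.
#' Full per-threshold real and null summaries are returned as diagnostics,
#' including each point's mean null degree sequence, so the degree
#' distribution contrast can be inspected alongside the selection
#' statistic.
#'
#' @param dataset A complete (imputed) [genotype_dataset()].
#' @param threshold_grid Numeric vector of candidate thresholds; default
#'   \code{NULL} uses 50 evenly spaced quantiles of the upper tail (top
#'   decile) of the observed pairwise information-gain distribution.
#' @param n_perms Permutation replicates per grid point.
#' @param seed Integer seed.
#' @param scores Optionally, precomputed [all_pairs_ig()] scores.
#' @return List with \code{threshold} (selected value), \code{z} (its
#'   z-score) and \code{diagnostics} (a data.frame with one row per usable
#'   grid point: threshold, real giant size, null mean/sd, z).
#' @export
select_threshold <- function(dataset, threshold_grid = NULL, n_perms = 20L,
                             seed = 1L, scores = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (is.null(scores)) scores <- all_pairs_ig(dataset)
  if (is.null(threshold_grid)) {
    up <- scores$ig[upper.tri(scores$ig)]
    threshold_grid <- unique(stats::quantile(up, seq(0.90, 1, length.out = 51)[-51],
                                             names = FALSE))
  }
  if (length(threshold_grid) == 0L) stop("'threshold_grid' must be non-empty")
  threshold_grid <- sort(threshold_grid)

  # one shared stream of permuted phenotypes across the grid
  set.seed(seed)
  perms <- replicate(n_perms, sample(dataset$phenotype), simplify = FALSE)
  null_scores <- lapply(perms, function(ph) {
    ds <- dataset
    ds$phenotype <- ph
    all_pairs_ig(ds)
  })

  rows <- lapply(threshold_grid, function(t) {
    real <- summarize_network(build_network(scores, t))
    nulls <- vapply(null_scores, function(s)
      summarize_network(build_network(s, t))$giant_component_size, numeric(1))
    data.frame(threshold = t, real_giant = real$giant_component_size,
               real_edges = real$n_edges,
               null_mean = mean(nulls), null_sd = stats::sd(nulls))
  })
  diag <- do.call(rbind, rows)
  diag$z <- (diag$real_giant - diag$null_mean) / diag$null_sd
  usable <- is.finite(diag$z) & diag$null_sd > 0
  if (!any(usable)) {
    warning("all grid points have degenerate null variance; returning the smallest threshold")
    return(list(threshold = threshold_grid[1], z = NA_real_, diagnostics = diag))
  }
  if (any(!usable))
    warning(sum(!usable), " grid point(s) skipped for degenerate null variance")
  best <- which(diag$z == max(diag$z[usable]) & usable)[1]
  list(threshold = diag$threshold[best], z = diag$z[best], diagnostics = diag)
}
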