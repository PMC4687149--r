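# Independent oracle implementations used only to cross-check the package.
# These deliberately share no code with the functions they verify.

# plug-in entropy straight from a probability vector
oracle_entropy <- function(p) {
  p <- p[p > 0] / sum(p)
  -sum(p * log2(p))
}

# mutual information from the explicit joint contingency table
oracle_mi <- function(x, y) {
  joint <- table(x, y)
  oracle_entropy(rowSums(joint)) + oracle_entropy(colSums(joint)) -
    oracle_entropy(as.vector(joint))
}

# IG by direct counting over the 9-cell joint variable
oracle_ig <- function(a, b, c) {
  ab <- interaction(a, b, drop = TRUE)
  oracle_mi(ab, c) - oracle_mi(a, c) - oracle_mi(b, c)
}

# all-pairs IG as an explicit double loop (the slow reference path)
oracle_all_pairs_ig <- function(genotypes, phenotype) {
  p <- nrow(genotypes)
  out <- matrix(NA_real_, p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    out[i, j] <- out[j, i] <- oracle_ig(genotypes[i, ], genotypes[j, ], phenotype)
  }
  out
}

# MI between two discrete variables given their exact joint distribution
# (matrix of probabilities); used for analytic penetrance-model checks
oracle_mi_dist <- function(joint) {
  oracle_entropy(rowSums(joint)) + oracle_entropy(colSums(joint)) -
    oracle_entropy(as.vector(joint))
}

# connected components by union-find over an igraph edge list
oracle_components <- function(graph) {
  n <- igraph::vcount(graph)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  el <- igraph::as_edgelist(graph, names = FALSE)
  for (k in seq_len(nrow(el))) {
    ra <- find(el[k, 1]); rb <- find(el[k, 2])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(n), function(x) as.integer(find(x)), integer(1))
  sizes <- table(roots)
  list(n_components = length(sizes), giant = max(sizes))
}

# dyad counts via an explicit loop over the edge list
oracle_dyads <- function(graph, labels) {
  el <- igraph::as_edgelist(graph)
  m11 <- m10 <- m00 <- 0L
  M <- 0L
  for (k in seq_len(nrow(el))) {
    if (el[k, 1] == el[k, 2]) next
    M <- M + 1L
    s <- labels[el[k, 1]] + labels[el[k, 2]]
    if (s == 2) m11 <- m11 + 1L else if (s == 1) m10 <- m10 + 1L
    else m00 <- m00 + 1L
  }
  list(M = M, m11 = m11, m10 = m10, m00 = m00)
}

# exact permutation p-values by enumerating every n1-subset labeling
oracle_exact_p <- function(graph, labels) {
  vn <- igraph::V(graph)$name
  n1 <- sum(labels[vn] == 1)
  obs <- oracle_dyads(graph, labels)
  subsets <- utils::combn(vn, n1)
  ge_d <- ge_h <- 0L
  for (k in seq_len(ncol(subsets))) {
    lab <- stats::setNames(as.integer(vn %in% subsets[, k]), vn)
    d <- oracle_dyads(graph, lab)
    if (d$m11 >= obs$m11) ge_d <- ge_d + 1L
    if (d$m10 >= obs$m10) ge_h <- ge_h + 1L
  }
  c(p_D = ge_d / ncol(subsets), p_H = ge_h / ncol(subsets))
}

# small deterministic attributed graph builders for fixtures
make_graph <- function(edges, n_vertices = NULL) {
  vnames <- if (is.null(n_vertices)) sort(unique(as.vector(edges)))
            else sprintf("v%02d", seq_len(n_vertices))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  extra <- setdiff(vnames, igraph::V(g)$name)
  if (length(extra) > 0) g <- g + igraph::vertices(extra)
  g
}

# the 12-row published-style D/H reference table used in reproduction tests:
# printed per-category label and dyad counts for a 185-vertex network with
# 173 non-self-loop edges, with the printed expectations and ratios
dh_reference_rows <- function() {
  data.frame(
    term = c("nucleoplasm", "identical protein binding",
             "response to estrogen stimulus", "transcription DNA-dependent",
             "RNA biosynthetic process", "steroid binding", "axon",
             "negative regulation of DNA binding",
             "regulation of phagocytosis",
             "nucleotide-excision repair DNA gap filling",
             "regulation of sterol transport",
             "regulation of cholesterol transport"),
    n1  = c(30L, 27L, 10L, 9L, 9L, 8L, 6L, 5L, 3L, 3L, 3L, 3L),
    m11 = c(9L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 1L, 0L, 1L, 1L),
    m10 = c(38L, 56L, 29L, 25L, 25L, 12L, 7L, 11L, 7L, 12L, 5L, 5L),
    m11_expected = c(4.422, 3.568, 0.457, 0.366, 0.366, 0.285, 0.152,
                     0.102, 0.030, 0.030, 0.030, 0.030),
    m10_expected = c(47.265, 43.362, 17.788, 16.101, 16.101, 14.393,
                     10.917, 9.148, 5.550, 5.550, 5.550, 5.550),
    D = c(2.035, 0.280, 2.186, 5.466, 5.466, 7.027, 13.118, 19.676,
          32.794, 0, 32.794, 32.794),
    H = c(0.804, 1.291, 1.630, 1.553, 1.553, 0.834, 0.641, 1.202,
          1.261, 2.162, 0.901, 0.901),
    stringsAsFactors = FALSE)
}
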