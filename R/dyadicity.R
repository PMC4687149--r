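#' Count dyads of an attributed network
#'
#' A dyad is an edge together with its two end vertices, classified by the
#' endpoints' binary property values into (1-1), (1-0) and (0-0) types with
#' counts m11, m10, m00. Self-loops are excluded from the edge total M and
#' from every dyad count: a self-loop has a single end vertex and cannot
#' form a pair of distinct endpoint values, and the expected-count formulas
#' below are defined over distinct vertex pairs.
#'
#' @param network An undirected \pkg{igraph} graph with named vertices.
#' @param labels Named 0/1 vector covering every vertex.
#' @return A list of class \code{dyad_counts}: \code{N}, \code{M}
#'   (non-self-loop edges), \code{n1}, \code{n0}, \code{m11}, \code{m10},
#'   \code{m00}.
#' @export
count_dyads <- function(network, labels) {
  stopifnot(igraph::is_igraph(network))
  vn <- igraph::V(network)$name
  if (is.null(vn)) vn <- as.character(seq_len(igraph::vcount(network)))
  if (!all(vn %in% names(labels)))
    stop("missing label for vertex(es): ",
         paste(setdiff(vn, names(labels)), collapse = ", "))
  lab <- labels[vn]
  if (!all(lab %in% 0:1)) stop("labels must be 0/1")
  el <- igraph::as_edgelist(network)
  el <- el[el[, 1] != el[, 2], , drop = FALSE]
  l1 <- lab[el[, 1]]
  l2 <- lab[el[, 2]]
  structure(
    list(N = length(vn), M = nrow(el),
         n1 = sum(lab == 1L), n0 = sum(lab == 0L),
         m11 = sum(l1 == 1L & l2 == 1L),
         m10 = sum(l1 != l2),
         m00 = sum(l1 == 0L & l2 == 0L)),
    class = "dyad_counts")
}

#' Expected dyad counts under random label placement
#'
#' With n1 labels placed uniformly at random on N vertices of a network
#' with M (non-self-loop) edges, the expected counts of (1-1) and (1-0)
#' dyads are
#' \deqn{\bar m_{11} = \binom{n_1}{2} p, \qquad
#'       \bar m_{10} = n_1 (N - n_1)\, p, \qquad p = \frac{2M}{N(N-1)},}
#' where p is the average probability that two vertices are connected.
#'
#' @param N Vertex count (>= 2).
#' @param M Non-self-loop edge count.
#' @param n1 Number of labeled vertices, 0 <= n1 <= N.
#' @return Named numeric vector \code{c(m11_expected, m10_expected)}.
#' @export
expected_dyads <- function(N, M, n1) {
  if (N < 2) stop("'N' must be >= 2")
  stopifnot(M >= 0, n1 >= 0, n1 <= N)
  p <- 2 * M / (N * (N - 1))
  c(m11_expected = n1 * (n1 - 1) / 2 * p,
    m10_expected = n1 * (N - n1) * p)
}

#' Dyadicity of a binary vertex property
#'
#' D = m11 / m̄11: the observed count of (1-1) dyads over its expectation
#' under uniformly random placement of the n1 labels. D > 1 means vertices
#' sharing the property are connected to each other more often than chance.
#' Undefined (returned as \code{NA}) when n1 < 2, since no (1-1) dyad can
#' exist; D = 0 when m11 = 0 with n1 >= 2.
#'
#' @param counts A \code{dyad_counts} from [count_dyads()].
#' @return The ratio D, or \code{NA} if undefined.
#' @export
dyadicity <- function(counts) {
  stopifnot(inherits(counts, "dyad_counts"))
  if (counts$n1 < 2L) return(NA_real_)
  exp11 <- expected_dyads(counts$N, counts$M, counts$n1)[["m11_expected"]]
  if (exp11 == 0) return(if (counts$m11 == 0L) 0 else NA_real_)
  counts$m11 / exp11
}

#' Heterophilicity of a binary vertex property
#'
#' H = m10 / m̄10: the observed count of (1-0) dyads over its random-
#' placement expectation. H > 1 means labeled vertices connect across the
#' property boundary more often than chance. Undefined (\code{NA}) when
#' n1 = 0 or n1 = N, since no (1-0) dyad can exist.
#'
#' @inheritParams dyadicity
#' @return The ratio H, or \code{NA} if undefined.
#' @export
heterophilicity <- function(counts) {
  stopifnot(inherits(counts, "dyad_counts"))
  if (counts$n1 < 1L || counts$n1 >= counts$N) return(NA_real_)
  exp10 <- expected_dyads(counts$N, counts$M, counts$n1)[["m10_expected"]]
  if (exp10 == 0) return(if (counts$m10 == 0L) 0 else NA_real_)
  counts$m10 / exp10
}

# Internal fast core: observed and permuted (m11, m10) for one label set.
# Edge endpoints are passed as integer indices so the permutation loop is a
# couple of vectorized subscripts per replicate.
dh_perm_core <- function(e1, e2, N, n1, m11_obs, m10_obs, n_perms) {
  ge_d <- 0L
  ge_h <- 0L
  for (r in seq_len(n_perms)) {
    lab <- logical(N)
    lab[sample.int(N, n1)] <- TRUE
    a <- lab[e1]
    b <- lab[e2]
    if (sum(a & b) >= m11_obs) ge_d <- ge_d + 1L
    if (sum(xor(a, b)) >= m10_obs) ge_h <- ge_h + 1L
  }
  c(ge_d = ge_d, ge_h = ge_h)
}

#' Permutation significance of dyadicity and heterophilicity
#'
#' Shuffles the vertex labels uniformly at random with n1 held fixed and
#' recomputes both statistics from the same replicate stream. The p-value
#' is the plain fraction of replicates whose statistic is greater than or
#' equal to the observed value (ties count toward significance), so the
#' smallest reportable p is 1/n_perms. Because D and H share the fixed
#' denominators m̄11 and m̄10 across replicates, comparing dyad counts is
#' equivalent to comparing the ratios.
#'
#' @param network An undirected \pkg{igraph} graph with named vertices.
#' @param labels Named 0/1 vector covering every vertex.
#' @param n_perms Number of label shuffles (>= 1); the study default for
#'   final reporting is 1e5.
#' @param seed Integer seed.
#' @return Named numeric vector \code{c(p_D, p_H)}; an entry is \code{NA}
#'   when the corresponding statistic is undefined (n1 < 2 for D,
#'   n1 in \{0, N\} for H).
#' @export
permutation_test_dh <- function(network, labels, n_perms = 1000L, seed = 1L) {
  if (n_perms < 1L) stop("'n_perms' must be >= 1")
  obs <- count_dyads(network, labels)
  el <- igraph::as_edgelist(network, names = FALSE)
  el <- el[el[, 1] != el[, 2], , drop = FALSE]
  set.seed(seed)
  ge <- dh_perm_core(el[, 1], el[, 2], obs$N, obs$n1, obs$m11, obs$m10, n_perms)
  c(p_D = if (obs$n1 < 2L) NA_real_ else ge[["ge_d"]] / n_perms,
    p_H = if (obs$n1 < 1L || obs$n1 >= obs$N) NA_real_
          else ge[["ge_h"]] / n_perms)
}

#' Dyadicity/heterophilicity analysis of many gene categories
#'
#' For each category, the member set is intersected with the network's
#' vertices; categories with fewer than \code{min_members} in-network
#' members are excluded. Each retained category is analyzed independently
#' (categories may overlap; no multiplicity adjustment is applied): its
#' members define the binary vertex property, dyads are counted, expected
#' counts and the D and H ratios computed, and label-shuffling permutation
#' p-values estimated. Each category draws its permutations from its own
#' stream, pre-seeded from the master seed, so results are reproducible
#' category-by-category regardless of evaluation order.
#'
#' @param network An undirected \pkg{igraph} graph with named vertices
#'   (self-loops allowed; they are ignored in dyad counting).
#' @param categories Named list mapping category id to member gene ids
#'   (e.g. from [read_gmt()] or [generate_categories()]).
#' @param min_members Minimum in-network member count (default 3).
#' @param n_perms Permutation replicates per category (default 1000; use
#'   1e5 for publication-grade p-values).
#' @param seed Master integer seed.
#' @return A data.frame with one row per retained category and columns
#'   \code{term}, \code{n1}, \code{m11}, \code{m10}, \code{m11_expected},
#'   \code{m10_expected}, \code{D}, \code{H}, \code{p_D}, \code{p_H},
#'   \code{n_perms}.
#' @export
analyze_categories <- function(network, categories, min_members = 3L,
                               n_perms = 1000L, seed = 1L) {
  stopifnot(igraph::is_igraph(network))
  if (min_members < 1L) stop("'min_members' must be >= 1")
  if (length(categories) == 0L)
    return(empty_dh_table())
  vn <- igraph::V(network)$name
  set.seed(seed)
  cat_seeds <- sample.int(.Machine$integer.max, length(categories))

  rows <- vector("list", length(categories))
  for (k in seq_along(categories)) {
    members <- intersect(categories[[k]], vn)
    if (length(members) < min_members) next
    lab <- stats::setNames(as.integer(vn %in% members), vn)
    cnt <- count_dyads(network, lab)
    expd <- expected_dyads(cnt$N, cnt$M, cnt$n1)
    pv <- permutation_test_dh(network, lab, n_perms = n_perms,
                              seed = cat_seeds[k])
    rows[[k]] <- data.frame(
      term = names(categories)[k], n1 = cnt$n1, m11 = cnt$m11, m10 = cnt$m10,
      m11_expected = expd[["m11_expected"]], m10_expected = expd[["m10_expected"]],
      D = dyadicity(cnt), H = heterophilicity(cnt),
      p_D = pv[["p_D"]], p_H = pv[["p_H"]], n_perms = n_perms,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty_dh_table())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_dh_table <- function() {
  data.frame(term = character(), n1 = integer(), m11 = integer(),
             m10 = integer(), m11_expected = numeric(),
             m10_expected = numeric(), D = numeric(), H = numeric(),
             p_D = numeric(), p_H = numeric(), n_perms = integer(),
             stringsAsFactors = FALSE)
}
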