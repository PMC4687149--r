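#' Specification for a synthetic case-control genotype dataset
#'
#' Describes a dataset of independent biallelic SNPs under Hardy-Weinberg
#' proportions, optionally with missing calls injected uniformly at random
#' and with two-locus epistatic pairs planted through a penetrance model.
#' The defaults mirror the shape of a typical candidate-gene case-control
#' panel: on the order of a thousand SNPs from a few hundred genes, several
#' hundred cases and controls.
#'
#' @param n_snps,n_cases,n_controls Counts.
#' @param maf_range Interval within (0, 0.5\] from which per-SNP minor
#'   allele frequencies are drawn uniformly.
#' @param missing_rate Fraction in \[0, 0.5) of genotype calls set missing.
#' @param planted_pairs List of pairs created with [planted_pair()].
#' @param seed Integer seed; equal seeds give bit-identical datasets.
#' @return An object of class \code{genotype_spec}.
#' @export
genotype_spec <- function(n_snps = 1422L, n_cases = 491L, n_controls = 791L,
                          maf_range = c(0.05, 0.5), missing_rate = 0,
                          planted_pairs = list(), seed = 1L) {
  stopifnot(n_snps >= 1L, n_cases >= 1L, n_controls >= 1L)
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("'maf_range' must be an interval within (0, 0.5]")
  if (missing_rate < 0 || missing_rate >= 0.5)
    stop("'missing_rate' must be in [0, 0.5)")
  for (pp in planted_pairs) {
    if (!inherits(pp, "planted_pair")) stop("planted_pairs must be built with planted_pair()")
    if (pp$i == pp$j || pp$i > n_snps || pp$j > n_snps || pp$i < 1L || pp$j < 1L)
      stop("planted pair indices must be distinct and within 1..n_snps")
  }
  structure(
    list(n_snps = as.integer(n_snps), n_cases = as.integer(n_cases),
         n_controls = as.integer(n_controls), maf_range = maf_range,
         missing_rate = missing_rate, planted_pairs = planted_pairs,
         seed = as.integer(seed)),
    class = "genotype_spec")
}

#' Describe a planted two-locus epistatic pair
#'
#' @param i,j SNP indices (1-based, distinct).
#' @param model Penetrance model: \code{"xor"} (purely epistatic: disease
#'   risk depends on the parity of the two minor-allele counts, so each
#'   locus alone carries no information at MAF 0.5), \code{"threshold"}
#'   (risk jumps when the combined minor-allele count reaches 3; has both
#'   marginal and interaction effects) or \code{"multiplicative"} (risk
#'   scales with the product of the two dosages).
#' @param effect Effect size in \[0, 1\]; 0 is indistinguishable from noise,
#'   1 the strongest attainable signal for the model.
#' @param maf Minor allele frequency forced on both planted loci
#'   (default 0.5, which makes the XOR model perfectly marginal-free).
#' @return An object of class \code{planted_pair}.
#' @export
planted_pair <- function(i, j, model = c("xor", "threshold", "multiplicative"),
                         effect = 1, maf = 0.5) {
  model <- match.arg(model)
  if (effect < 0 || effect > 1) stop("'effect' must be in [0, 1]")
  structure(list(i = as.integer(i), j = as.integer(j), model = model,
                 effect = effect, maf = maf),
            class = "planted_pair")
}

#' 3x3 two-locus penetrance table
#'
#' Disease probability for each combination of minor-allele counts
#' (rows/columns 0, 1, 2) under the named model at baseline prevalence 1/2.
#'
#' @inheritParams planted_pair
#' @return 3x3 numeric matrix of penetrances in \[0, 1\].
#' @export
penetrance_table <- function(model = c("xor", "threshold", "multiplicative"),
                             effect = 1) {
  model <- match.arg(model)
  if (effect < 0 || effect > 1) stop("'effect' must be in [0, 1]")
  a <- matrix(rep(0:2, 3), 3, 3)
  b <- t(a)
  pen <- switch(model,
    xor = 0.5 + (effect / 2) * ifelse((a + b) %% 2 == 1, 1, -1),
    threshold = 0.5 - effect / 2 + effect * (a + b >= 3),
    multiplicative = pmin(1, 0.5 * (1 + effect)^(a * b) / (1 + effect)^2))
  dimnames(pen) <- list(0:2, 0:2)
  pen
}

#' Generate a synthetic case-control genotype dataset
#'
#' SNP genotypes are drawn independently per locus under Hardy-Weinberg
#' proportions from the spec's MAF range. If epistatic pairs are planted,
#' each sample receives a disease weight equal to the mean penetrance over
#' the planted pairs and exactly \code{n_cases} samples are drawn as cases
#' by weighted sampling without replacement, so the case/control counts are
#' exact and every non-planted SNP is phenotype-independent by construction.
#' Missing calls are then injected uniformly at random.
#'
#' @param spec A [genotype_spec()].
#' @return A [genotype_dataset()].
#' @export
generate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "genotype_spec"))
  set.seed(spec$seed)
  n <- spec$n_cases + spec$n_controls
  p <- spec$n_snps
  maf <- stats::runif(p, spec$maf_range[1], spec$maf_range[2])
  for (pp in spec$planted_pairs) maf[c(pp$i, pp$j)] <- pp$maf
  # Hardy-Weinberg genotype draws, one binomial row per SNP
  g <- matrix(stats::rbinom(p * n, 2L, rep(maf, times = n)), nrow = p)

  weight <- rep(0, n)
  for (pp in spec$planted_pairs) {
    pen <- penetrance_table(pp$model, pp$effect)
    weight <- weight + pen[cbind(g[pp$i, ] + 1L, g[pp$j, ] + 1L)]
  }
  if (length(spec$planted_pairs) > 0L) weight <- weight / length(spec$planted_pairs)
  else weight <- rep(1, n)
  phenotype <- integer(n)
  if (all(weight == weight[1])) {
    cases <- sample.int(n, spec$n_cases)
  } else {
    if (sum(weight > 0) < spec$n_cases)
      stop("penetrance model leaves fewer positive-risk samples than n_cases")
    cases <- sample.int(n, spec$n_cases, prob = weight)
  }
  phenotype[cases] <- 1L

  if (spec$missing_rate > 0) {
    miss <- stats::runif(p * n) < spec$missing_rate
    g[miss] <- NA_integer_
  }
  genotype_dataset(g, phenotype,
                   snp_ids = sprintf("snp%04d", seq_len(p)),
                   sample_ids = sprintf("s%04d", seq_len(n)))
}

#' Regenerate a phenotype from a planted two-locus penetrance table
#'
#' Overwrites the dataset's phenotype with independent Bernoulli draws from
#' the 3x3 penetrance table evaluated at SNPs \code{i} and \code{j}. Unlike
#' [generate_genotypes()] the case/control counts are random here; this is
#' the primitive for studying a single pair's signal in isolation.
#'
#' @param dataset A [genotype_dataset()] with no missing calls at SNPs
#'   \code{i}, \code{j}.
#' @param i,j SNP indices or ids.
#' @inheritParams planted_pair
#' @param seed Integer seed.
#' @return The dataset with a new phenotype.
#' @export
plant_epistatic_pair <- function(dataset, i, j,
                                 model = c("xor", "threshold", "multiplicative"),
                                 effect = 1, seed = 1L) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  model <- match.arg(model)
  gi <- dataset$genotypes[i, ]
  gj <- dataset$genotypes[j, ]
  if (anyNA(gi) || anyNA(gj)) stop("planted SNPs must have no missing calls")
  pen <- penetrance_table(model, effect)
  set.seed(seed)
  dataset$phenotype <- as.integer(stats::runif(length(gi)) <
                                    pen[cbind(gi + 1L, gj + 1L)])
  dataset
}

#' Generate a many-to-one SNP-to-gene map
#'
#' Every gene receives at least one SNP; the remaining SNPs are assigned to
#' genes uniformly at random.
#'
#' @param n_snps,n_genes Counts with \code{n_genes <= n_snps}.
#' @param seed Integer seed.
#' @param snp_ids,gene_ids Optional identifier vectors.
#' @return A data.frame with columns \code{snp_id}, \code{gene_id}.
#' @export
generate_snp_gene_map <- function(n_snps, n_genes, seed = 1L,
                                  snp_ids = sprintf("snp%04d", seq_len(n_snps)),
                                  gene_ids = sprintf("gene%03d", seq_len(n_genes))) {
  if (n_genes > n_snps) stop("'n_genes' must not exceed 'n_snps'")
  set.seed(seed)
  assign <- c(seq_len(n_genes),
              sample.int(n_genes, n_snps - n_genes, replace = TRUE))
  assign <- assign[sample.int(n_snps)]
  data.frame(snp_id = snp_ids, gene_id = gene_ids[assign],
             stringsAsFactors = FALSE)
}

#' Specification for an attributed random network
#'
#' @param n_vertices,n_edges Counts; \code{n_edges} must not exceed
#'   \eqn{\binom{n}{2}}.
#' @param n1 Number of vertices labeled 1.
#' @param regime \code{"random"} (uniform edge placement),
#'   \code{"dyadic"} (edges between two labeled vertices up-weighted by
#'   \code{strength}) or \code{"heterophilic"} (labeled-unlabeled edges
#'   up-weighted).
#' @param strength Excess-edge multiplier, >= 1.
#' @param seed Integer seed.
#' @return An object of class \code{network_spec}.
#' @export
network_spec <- function(n_vertices, n_edges, n1,
                         regime = c("random", "dyadic", "heterophilic"),
                         strength = 1, seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(n_vertices >= 2L, n1 >= 0L, n1 <= n_vertices, strength >= 1)
  if (n_edges > n_vertices * (n_vertices - 1) / 2)
    stop("'n_edges' exceeds the number of vertex pairs")
  structure(list(n_vertices = as.integer(n_vertices),
                 n_edges = as.integer(n_edges), n1 = as.integer(n1),
                 regime = regime, strength = strength, seed = as.integer(seed)),
            class = "network_spec")
}

#' Generate an attributed network with planted label structure
#'
#' Labels 1 are assigned to a uniform random subset of \code{n1} vertices.
#' Edges are then drawn without replacement from all vertex pairs with
#' sampling weight \code{strength} on 1-1 pairs (dyadic regime) or 1-0
#' pairs (heterophilic regime) and weight 1 elsewhere, so the expected
#' count of the favoured dyad type is inflated by roughly the strength
#' factor relative to uniform placement.
#'
#' @param spec A [network_spec()].
#' @return A list with \code{graph} (an \pkg{igraph} object with vertex
#'   names \code{v1..vN}) and \code{labels} (named 0/1 vector).
#' @export
generate_attributed_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(spec$seed)
  N <- spec$n_vertices
  labels <- integer(N)
  labels[sample.int(N, spec$n1)] <- 1L
  pairs <- t(utils::combn(N, 2L))
  w <- rep(1, nrow(pairs))
  l1 <- labels[pairs[, 1]]
  l2 <- labels[pairs[, 2]]
  if (spec$regime == "dyadic") w[l1 == 1L & l2 == 1L] <- spec$strength
  if (spec$regime == "heterophilic") w[l1 != l2] <- spec$strength
  chosen <- sample.int(nrow(pairs), spec$n_edges, prob = w)
  vnames <- sprintf("v%03d", seq_len(N))
  g <- igraph::graph_from_edgelist(
    cbind(vnames[pairs[chosen, 1]], vnames[pairs[chosen, 2]]),
    directed = FALSE)
  g <- g + igraph::vertices(setdiff(vnames, igraph::V(g)$name))
  names(labels) <- vnames
  list(graph = g, labels = labels[igraph::V(g)$name])
}

#' Generate overlapping gene categories
#'
#' Draws \code{n_categories} gene sets playing the role of functional
#' annotation terms; member sets are sampled without replacement within a
#' category and may overlap across categories (as functional categories
#' are not mutually exclusive). With \code{overlap_allowed = FALSE} the
#' categories are drawn disjoint and an error is raised if the requested
#' sizes cannot fit in the gene universe.
#'
#' @param genes Character vector of gene ids (non-empty).
#' @param n_categories Count.
#' @param size_range Integer interval within \[1, length(genes)\].
#' @param overlap_allowed Logical; default TRUE.
#' @param seed Integer seed.
#' @return A named list mapping category id to a character vector of member
#'   genes (a \code{category_assignment}).
#' @export
generate_categories <- function(genes, n_categories, size_range = c(3L, 50L),
                                overlap_allowed = TRUE, seed = 1L) {
  if (length(genes) == 0L) stop("'genes' must be non-empty")
  size_range <- as.integer(size_range)
  if (size_range[1] < 1L || size_range[2] > length(genes) ||
      size_range[1] > size_range[2])
    stop("'size_range' must lie within [1, length(genes)]")
  set.seed(seed)
  sizes <- size_range[1] +
    sample.int(size_range[2] - size_range[1] + 1L, n_categories,
               replace = TRUE) - 1L
  if (!overlap_allowed && sum(sizes) > length(genes))
    stop("disjoint categories of the requested sizes exceed the gene universe")
  pool <- genes
  out <- vector("list", n_categories)
  for (k in seq_len(n_categories)) {
    if (overlap_allowed) {
      out[[k]] <- sample(genes, sizes[k])
    } else {
      out[[k]] <- sample(pool, sizes[k])
      pool <- setdiff(pool, out[[k]])
    }
  }
  names(out) <- sprintf("CAT%04d", seq_len(n_categories))
  out
}
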