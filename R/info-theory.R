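#' Shannon entropy of a count table, in bits
#'
#' Plug-in (maximum-likelihood) entropy of the empirical distribution implied
#' by a table of non-negative counts. Base-2 logarithm; cells with zero count
#' contribute nothing (the 0 log 0 = 0 convention).
#'
#' @param counts Numeric vector (or table) of non-negative counts; must sum
#'   to a positive value.
#' @return Entropy in bits, a non-negative scalar.
#' @examples
#' entropy_bits(c(1, 1))     # 1 bit
#' entropy_bits(c(2, 1, 1))  # 1.5 bits
#' @export
entropy_bits <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L || any(counts < 0) || any(!is.finite(counts)))
    stop("'counts' must be finite and non-negative")
  n <- sum(counts)
  if (n <= 0) stop("'counts' must sum to a positive value")
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Mutual information between two discrete vectors, in bits
#'
#' Plug-in estimate I(x;y) = H(x) + H(y) - H(x,y) from the joint empirical
#' distribution. Symmetric in its arguments and non-negative up to floating
#' point rounding.
#'
#' @param x,y Vectors of equal positive length; treated as categorical.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) == 0L) stop("vectors must be non-empty")
  hx <- entropy_bits(table(x))
  hy <- entropy_bits(table(y))
  hxy <- entropy_bits(table(paste(x, y, sep = "\r")))
  max(hx + hy - hxy, 0)
}

#' Information gain of a SNP pair on a binary phenotype
#'
#' The epistasis score IG(A;B;C) = I(A,B;C) - I(A;C) - I(B;C), where (A,B)
#' is the joint variable over the observed genotype combinations (up to nine
#' cells for two three-level SNPs). Positive values indicate synergy: the
#' pair carries information about the phenotype beyond the sum of the two
#' marginal associations. Negative values (redundancy) are retained, not
#' clipped; thresholding happens at network construction.
#'
#' @param a,b Genotype vectors of one SNP each.
#' @param c Phenotype vector (same length).
#' @return Information gain in bits; may be negative.
#' @export
information_gain <- function(a, b, c) {
  n <- length(c)
  if (length(a) != n || length(b) != n) stop("'a', 'b', 'c' must have equal length")
  ab <- paste(a, b, sep = "\r")
  iab <- mi_signed(ab, c)
  iab - mi_signed(a, c) - mi_signed(b, c)
}

# unclamped MI: keeps IG exactly symmetric/consistent at rounding scale
mi_signed <- function(x, y) {
  entropy_bits(table(x)) + entropy_bits(table(y)) -
    entropy_bits(table(paste(x, y, sep = "\r")))
}

#' Drop SNPs exceeding a missing-data fraction
#'
#' Removes every SNP whose fraction of missing genotype calls exceeds
#' \code{max_missing_fraction} (strict inequality: a SNP at exactly the
#' threshold is retained). SNP order is preserved.
#'
#' @param dataset A [genotype_dataset()].
#' @param max_missing_fraction Fraction in \[0, 1); default 0.05.
#' @return The filtered [genotype_dataset()].
#' @export
filter_missingness <- function(dataset, max_missing_fraction = 0.05) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (max_missing_fraction < 0 || max_missing_fraction >= 1)
    stop("'max_missing_fraction' must be in [0, 1)")
  frac <- rowMeans(is.na(dataset$genotypes))
  keep <- frac <= max_missing_fraction
  dataset$genotypes <- dataset$genotypes[keep, , drop = FALSE]
  dataset$snp_ids <- dataset$snp_ids[keep]
  dataset
}

#' Impute missing genotypes with the per-SNP modal genotype
#'
#' Each missing call is replaced by that SNP's most frequent genotype across
#' all samples. Ties are broken toward the lowest genotype code, so the
#' result is deterministic.
#'
#' @param dataset A [genotype_dataset()].
#' @return The dataset with no missing genotypes.
#' @export
impute_mode <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  g <- dataset$genotypes
  miss_rows <- which(rowSums(is.na(g)) > 0L)
  for (i in miss_rows) {
    row <- g[i, ]
    obs <- row[!is.na(row)]
    if (length(obs) == 0L)
      stop("SNP '", dataset$snp_ids[i], "' has all genotypes missing")
    counts <- tabulate(obs + 1L, nbins = 3L)
    mode_code <- which.max(counts) - 1L  # which.max takes the first (lowest) on ties
    row[is.na(row)] <- mode_code
    g[i, ] <- row
  }
  dataset$genotypes <- g
  dataset
}

#' Score all SNP pairs by information gain
#'
#' Computes the full symmetric matrix of pairwise information-gain scores
#' IG(A;B;C) together with each SNP's marginal association I(A;C), on a
#' complete (imputed) genotype dataset. The joint-count computation is done
#' with dense cross-products of genotype indicator matrices, so all
#' \eqn{\binom{p}{2}} pairs are scored in a handful of matrix products
#' rather than an explicit pair loop.
#'
#' @param dataset A [genotype_dataset()] with no missing genotypes and at
#'   least two SNPs.
#' @return An object of class \code{interaction_scores}: a list with
#'   \code{snp_ids}, \code{main_effect} (per-SNP I(A;C), bits) and \code{ig}
#'   (symmetric p x p matrix of IG in bits, \code{NA} diagonal).
#' @export
all_pairs_ig <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  g <- dataset$genotypes
  p <- nrow(g)
  if (p < 2L) stop("at least two SNPs are required")
  if (anyNA(g)) stop("dataset contains missing genotypes; run impute_mode() first")
  y <- dataset$phenotype
  n <- length(y)
  hlp <- function(cnt) ifelse(cnt > 0, -(cnt / n) * log2(cnt / n), 0)

  # indicator matrices per genotype level and phenotype class
  idx1 <- y == 1L
  X <- lapply(0:2, function(l) t(g == l) * 1)          # n x p each
  X1 <- lapply(X, function(m) m[idx1, , drop = FALSE])
  X0 <- lapply(X, function(m) m[!idx1, , drop = FALSE])

  # joint entropies over all pairs: H(A,B) and H(A,B,C) as p x p matrices
  hab <- matrix(0, p, p)
  habc <- matrix(0, p, p)
  for (l in 1:3) for (m in 1:3) {
    c1 <- crossprod(X1[[l]], X1[[m]])
    c0 <- crossprod(X0[[l]], X0[[m]])
    hab <- hab + hlp(c1 + c0)
    habc <- habc + hlp(c1) + hlp(c0)
  }

  # per-SNP marginal entropies and H(A,C)
  cnt1 <- vapply(X1, colSums, numeric(p))              # p x 3, class 1
  cnt0 <- vapply(X0, colSums, numeric(p))
  ha <- rowSums(hlp(cnt1 + cnt0))
  hac <- rowSums(hlp(cnt1)) + rowSums(hlp(cnt0))
  hc <- entropy_bits(c(sum(idx1), n - sum(idx1)))

  main <- pmax(ha + hc - hac, 0)
  iab <- hab + hc - habc
  ig <- iab - outer(main, main, `+`)
  diag(ig) <- NA_real_
  dimnames(ig) <- list(dataset$snp_ids, dataset$snp_ids)
  structure(
    list(snp_ids = dataset$snp_ids,
         main_effect = stats::setNames(main, dataset$snp_ids),
         ig = ig),
    class = "interaction_scores")
}

#' @export
print.interaction_scores <- function(x, ...) {
  cat("Interaction scores:", length(x$snp_ids), "SNPs,",
      choose(length(x$snp_ids), 2), "pairs\n")
  up <- x$ig[upper.tri(x$ig)]
  cat(sprintf("  IG range: [%.4g, %.4g] bits; max main effect %.4g bits\n",
              min(up), max(up), max(x$main_effect)))
  invisible(x)
}
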