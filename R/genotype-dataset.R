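#' Case-control genotype dataset
#'
#' Container for a SNP x sample matrix of biallelic genotypes coded as
#' minor-allele counts (0/1/2, \code{NA} for missing calls) together with a
#' binary phenotype (1 = case, 0 = control).
#'
#' @param genotypes Integer matrix, rows = SNPs, columns = samples, values
#'   in \{0, 1, 2, NA\}.
#' @param phenotype Integer vector of 0/1, one per sample.
#' @param snp_ids,sample_ids Optional identifier vectors; defaults are
#'   generated.
#' @return An object of class \code{genotype_dataset}.
#' @export
genotype_dataset <- function(genotypes, phenotype,
                             snp_ids = rownames(genotypes),
                             sample_ids = colnames(genotypes)) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  ok <- is.na(genotypes) | genotypes %in% 0:2
  if (!all(ok)) stop("genotypes must be coded 0/1/2 or NA")
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != ncol(genotypes))
    stop("phenotype length must equal the number of samples")
  if (!all(phenotype %in% 0:1)) stop("phenotype must be binary 0/1")
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%04d", seq_len(nrow(genotypes)))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%04d", seq_len(ncol(genotypes)))
  if (anyDuplicated(snp_ids)) stop("duplicate SNP ids")
  dimnames(genotypes) <- list(snp_ids, sample_ids)
  structure(
    list(snp_ids = as.character(snp_ids),
         sample_ids = as.character(sample_ids),
         genotypes = genotypes,
         phenotype = phenotype),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("Genotype dataset:", nrow(x$genotypes), "SNPs x",
      ncol(x$genotypes), "samples (",
      sum(x$phenotype == 1L), "cases /", sum(x$phenotype == 0L), "controls )\n")
  mr <- mean(is.na(x$genotypes))
  if (mr > 0) cat(sprintf("  missing genotype calls: %.2f%%\n", 100 * mr))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)
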