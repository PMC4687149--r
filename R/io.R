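#' Read and write the genotype/phenotype text formats
#'
#' Genotypes travel as tab-separated text with one row per SNP: the first
#' column is the SNP id, the remaining columns one sample each (header row
#' of sample ids), values 0/1/2 with missing coded \code{NA}. The
#' phenotype is a two-column headerless TSV (sample id, 0/1 status).
#'
#' @param dataset A [genotype_dataset()].
#' @param genotype_file,phenotype_file Paths.
#' @return \code{write_genotypes} returns the paths invisibly;
#'   \code{read_genotypes} returns a [genotype_dataset()].
#' @name genotype_io
NULL

#' @rdname genotype_io
#' @export
write_genotypes <- function(dataset, genotype_file, phenotype_file) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  gt <- data.table::data.table(snp_id = dataset$snp_ids)
  gt <- cbind(gt, data.table::as.data.table(dataset$genotypes))
  data.table::fwrite(gt, genotype_file, sep = "\t", na = "NA", quote = FALSE)
  data.table::fwrite(
    data.table::data.table(sample_id = dataset$sample_ids,
                           status = dataset$phenotype),
    phenotype_file, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(c(genotype_file, phenotype_file))
}

#' @rdname genotype_io
#' @export
read_genotypes <- function(genotype_file, phenotype_file) {
  gt <- data.table::fread(genotype_file, sep = "\t", header = TRUE,
                          na.strings = "NA")
  snp_ids <- gt[[1]]
  g <- as.matrix(gt[, -1])
  ph <- data.table::fread(phenotype_file, sep = "\t", header = FALSE,
                          col.names = c("sample_id", "status"))
  if (!identical(as.character(ph$sample_id), colnames(g)))
    stop("phenotype sample ids do not match the genotype header")
  genotype_dataset(g, ph$status, snp_ids = snp_ids, sample_ids = ph$sample_id)
}

#' Read or write a SNP-to-gene map as two-column TSV
#'
#' @param file Path to a headered TSV with columns \code{snp_id},
#'   \code{gene_id}.
#' @param map A data.frame with those columns.
#' @return \code{read_snp_gene_map} returns the data.frame.
#' @name snp_gene_map_io
NULL

#' @rdname snp_gene_map_io
#' @export
read_snp_gene_map <- function(file) {
  map <- data.table::fread(file, sep = "\t", header = TRUE,
                           colClasses = "character")
  if (!all(c("snp_id", "gene_id") %in% names(map)))
    stop("map file must have columns 'snp_id' and 'gene_id'")
  as.data.frame(map[, c("snp_id", "gene_id")])
}

#' @rdname snp_gene_map_io
#' @export
write_snp_gene_map <- function(map, file) {
  data.table::fwrite(map[, c("snp_id", "gene_id")], file, sep = "\t",
                     quote = FALSE)
  invisible(file)
}

#' Read or write gene categories in GMT format
#'
#' GMT files carry one category per line: name, description, then the
#' tab-separated member genes. Lines with fewer than three fields (no
#' members) yield empty categories.
#'
#' @param file Path.
#' @param categories Named list of character vectors (category id to
#'   member genes).
#' @param descriptions Optional character vector of per-category
#'   descriptions; defaults to \code{"na"}.
#' @return \code{read_gmt} returns a named list of member-gene vectors.
#' @name gmt_io
NULL

#' @rdname gmt_io
#' @export
read_gmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in seq_along(lines)) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L)
      stop("malformed GMT line ", ln, ": fewer than two fields")
    out[[fields[1]]] <- if (length(fields) > 2L) fields[-(1:2)] else character()
  }
  out
}

#' @rdname gmt_io
#' @export
write_gmt <- function(categories, file, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(categories))
  lines <- vapply(seq_along(categories), function(k)
    paste(c(names(categories)[k], descriptions[k], categories[[k]]),
          collapse = "\t"), character(1))
  writeLines(lines, file)
  invisible(file)
}

#' Export a network for external viewers
#'
#' GraphML via \pkg{igraph}'s writer; SIF (simple interaction format, one
#' \code{source relation target} line per edge, as consumed by Cytoscape);
#' and a weighted edge-list TSV carrying the \code{ig} edge attribute when
#' present.
#'
#' @param network An \pkg{igraph} graph.
#' @param file Output path.
#' @param relation Interaction label used in the SIF file.
#' @return The path, invisibly.
#' @name network_export
NULL

#' @rdname network_export
#' @export
write_network_graphml <- function(network, file) {
  igraph::write_graph(network, file, format = "graphml")
  invisible(file)
}

#' @rdname network_export
#' @export
read_network_graphml <- function(file) {
  igraph::read_graph(file, format = "graphml")
}

#' @rdname network_export
#' @export
write_network_sif <- function(network, file, relation = "interacts") {
  el <- igraph::as_edgelist(network)
  lines <- if (nrow(el) == 0L) character() else
    paste(el[, 1], relation, el[, 2], sep = "\t")
  iso <- igraph::V(network)$name[igraph::degree(network) == 0]
  writeLines(c(lines, iso), file)
  invisible(file)
}

#' @rdname network_export
#' @export
write_edge_list <- function(network, file) {
  el <- igraph::as_edgelist(network)
  dt <- data.table::data.table(from = el[, 1], to = el[, 2])
  if (!is.null(igraph::E(network)$ig)) dt$ig_bits <- igraph::E(network)$ig
  data.table::fwrite(dt, file, sep = "\t", quote = FALSE)
  invisible(file)
}

#' Write pairwise interaction scores as TSV
#'
#' Emits a three-column table (snp_i, snp_j, ig_bits) over all unordered
#' pairs, and a companion per-SNP main-effect table (snp_id,
#' main_effect_bits).
#'
#' @param scores An \code{interaction_scores} object.
#' @param pairs_file,main_file Output paths.
#' @return The paths, invisibly.
#' @export
write_interaction_scores <- function(scores, pairs_file, main_file) {
  stopifnot(inherits(scores, "interaction_scores"))
  idx <- which(upper.tri(scores$ig), arr.ind = TRUE)
  data.table::fwrite(
    data.table::data.table(snp_i = scores$snp_ids[idx[, 1]],
                           snp_j = scores$snp_ids[idx[, 2]],
                           ig_bits = scores$ig[idx]),
    pairs_file, sep = "\t", quote = FALSE)
  data.table::fwrite(
    data.table::data.table(snp_id = scores$snp_ids,
                           main_effect_bits = unname(scores$main_effect)),
    main_file, sep = "\t", quote = FALSE)
  invisible(c(pairs_file, main_file))
}
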