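#' Pipeline configuration
#'
#' Bundles the input paths and analysis parameters for [run_sen_pipeline()].
#' Defaults follow the study conventions of this analysis family: SNPs with
#' more than 5\% missing calls dropped, remaining gaps mode-imputed,
#' categories retained from three in-network genes, and label permutations
#' for category significance (1e5 for publication-grade p-values; the
#' default here is smaller so exploratory runs stay fast).
#'
#' @param genotype_file,phenotype_file,map_file,categories_file Input paths
#'   (genotype/phenotype TSV, SNP-to-gene TSV, GMT).
#' @param out_dir Output directory; created if absent.
#' @param max_missing_fraction Per-SNP missingness cutoff (default 0.05).
#' @param threshold Fixed edge threshold in bits, or \code{NULL} to select
#'   one by permutation contrast ([select_threshold()]).
#' @param threshold_grid Candidate grid for selection (\code{NULL} =
#'   data-adaptive upper-tail quantiles).
#' @param n_perms_threshold Permutations per grid point.
#' @param n_perms_dh Label permutations per category.
#' @param min_members Minimum in-network category size (default 3).
#' @param seed Master seed; every stage derives its stream from it.
#' @return A list of class \code{sen_config}.
#' @export
sen_config <- function(genotype_file, phenotype_file, map_file,
                       categories_file, out_dir = "sen_out",
                       max_missing_fraction = 0.05,
                       threshold = NULL, threshold_grid = NULL,
                       n_perms_threshold = 20L, n_perms_dh = 1000L,
                       min_members = 3L, seed = 1L) {
  stopifnot(n_perms_threshold >= 1L, n_perms_dh >= 1L, min_members >= 1L)
  structure(
    list(genotype_file = genotype_file, phenotype_file = phenotype_file,
         map_file = map_file, categories_file = categories_file,
         out_dir = out_dir, max_missing_fraction = max_missing_fraction,
         threshold = threshold, threshold_grid = threshold_grid,
         n_perms_threshold = as.integer(n_perms_threshold),
         n_perms_dh = as.integer(n_perms_dh),
         min_members = as.integer(min_members), seed = as.integer(seed)),
    class = "sen_config")
}

#' Write or read a pipeline configuration as YAML
#'
#' @param config A [sen_config()].
#' @param file Path.
#' @return \code{read_sen_config} returns the \code{sen_config};
#'   round-tripping a config through YAML reproduces it exactly.
#' @name sen_config_io
NULL

#' @rdname sen_config_io
#' @export
write_sen_config <- function(config, file) {
  stopifnot(inherits(config, "sen_config"))
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname sen_config_io
#' @export
read_sen_config <- function(file) {
  raw <- yaml::read_yaml(file)
  do.call(sen_config, raw[!vapply(raw, is.null, logical(1))])
}

#' Run the full epistasis-network analysis
#'
#' Executes the whole chain: missingness filter, mode imputation, all-pairs
#' information gain, edge-threshold selection (or a fixed threshold),
#' SNP-network construction, collapse to the gene level, and the
#' dyadicity/heterophilicity analysis of every category. All intermediate
#' artifacts are written under \code{config$out_dir} (interaction scores,
#' SNP and gene networks in GraphML/SIF/edge-list form, network summaries,
#' the full-precision D/H table and a 3-decimal report), and a plain-text
#' log records every parameter and seed. Input paths are validated before
#' any work starts, so a missing file aborts with no partial output.
#'
#' @param config A [sen_config()].
#' @return A list with the imputed dataset, interaction scores, selected
#'   threshold, SNP- and gene-level graphs, their summaries and the D/H
#'   results table.
#' @export
run_sen_pipeline <- function(config) {
  stopifnot(inherits(config, "sen_config"))
  inputs <- c(config$genotype_file, config$phenotype_file,
              config$map_file, config$categories_file)
  absent <- inputs[!file.exists(inputs)]
  if (length(absent) > 0L)
    stop("input file(s) not found: ", paste(absent, collapse = ", "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "pipeline.log")
  log_line <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                                ..., "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  log_line("parameters: ", paste(sprintf(
    "%s=%s", names(unclass(config)),
    vapply(unclass(config), function(v)
      if (is.null(v)) "NULL" else paste(format(v), collapse = ","),
      character(1))), collapse = " "))

  stage <- function(name, expr) {
    log_line("stage ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ds <- stage("read", read_genotypes(config$genotype_file, config$phenotype_file))
  map <- stage("read", read_snp_gene_map(config$map_file))
  categories <- stage("read", read_gmt(config$categories_file))

  ds <- stage("filter", filter_missingness(ds, config$max_missing_fraction))
  log_line("filter: ", nrow(ds$genotypes), " SNPs retained")
  ds <- stage("impute", impute_mode(ds))
  scores <- stage("score", all_pairs_ig(ds))
  write_interaction_scores(scores,
                           file.path(config$out_dir, "pair_ig.tsv"),
                           file.path(config$out_dir, "main_effects.tsv"))

  if (is.null(config$threshold)) {
    sel <- stage("select_threshold",
                 select_threshold(ds, config$threshold_grid,
                                  n_perms = config$n_perms_threshold,
                                  seed = config$seed + 1L, scores = scores))
    threshold <- sel$threshold
    utils::write.table(sel$diagnostics,
                       file.path(config$out_dir, "threshold_diagnostics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    log_line("selected threshold ", format(threshold), " (z = ",
             format(sel$z), ")")
  } else {
    threshold <- config$threshold
    log_line("fixed threshold ", format(threshold))
  }

  snp_net <- stage("network", build_network(scores, threshold))
  write_network_graphml(snp_net, file.path(config$out_dir, "snp_network.graphml"))
  write_network_sif(snp_net, file.path(config$out_dir, "snp_network.sif"))
  write_edge_list(snp_net, file.path(config$out_dir, "snp_network_edges.tsv"))
  snp_summary <- summarize_network(snp_net)
  log_line("snp network: ", snp_summary$n_vertices, " vertices, ",
           snp_summary$n_edges, " edges, giant ",
           snp_summary$giant_component_size)

  gene_net <- stage("collapse", collapse_to_genes(snp_net, map))
  write_network_graphml(gene_net, file.path(config$out_dir, "gene_network.graphml"))
  write_network_sif(gene_net, file.path(config$out_dir, "gene_network.sif"))
  write_edge_list(gene_net, file.path(config$out_dir, "gene_network_edges.tsv"))
  gene_summary <- component_stats(gene_net)
  log_line("gene network: ", gene_summary$n_vertices, " vertices, ",
           gene_summary$n_edges, " edges (", gene_summary$n_self_loops,
           " self-loops), giant ", gene_summary$giant_component_size)

  dh <- stage("dyadicity",
              analyze_categories(gene_net, categories,
                                 min_members = config$min_members,
                                 n_perms = config$n_perms_dh,
                                 seed = config$seed + 2L))
  write_dh_results(dh, config$out_dir)
  log_line("dyadicity: ", nrow(dh), " categories analyzed")

  list(dataset = ds, scores = scores, threshold = threshold,
       snp_network = snp_net, snp_summary = snp_summary,
       gene_network = gene_net, gene_summary = gene_summary,
       dh_results = dh)
}

#' Dyadicity/heterophilicity analysis of a stored network
#'
#' Loads a gene network (GraphML) and a GMT category file and runs
#' [analyze_categories()] — the entry point for analyzing any attributed
#' network without redoing the genotype stages, e.g. re-deriving a
#' published D/H table from its network and memberships.
#'
#' @param network_file GraphML path, or an \pkg{igraph} object.
#' @param categories_file GMT path, or a named list of member vectors.
#' @inheritParams analyze_categories
#' @return The D/H results data.frame (see [analyze_categories()]).
#' @export
run_dh_analysis <- function(network_file, categories_file, min_members = 3L,
                            n_perms = 1000L, seed = 1L) {
  g <- if (igraph::is_igraph(network_file)) network_file
       else read_network_graphml(network_file)
  categories <- if (is.list(categories_file)) categories_file
                else read_gmt(categories_file)
  analyze_categories(g, categories, min_members = min_members,
                     n_perms = n_perms, seed = seed)
}

# Full-precision table plus a 3-decimal human-readable report.
write_dh_results <- function(dh, out_dir) {
  utils::write.table(dh, file.path(out_dir, "dh_results_full.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  report <- dh
  num <- c("m11_expected", "m10_expected", "D", "H", "p_D", "p_H")
  report[num] <- lapply(report[num], function(v) sprintf("%.3f", v))
  utils::write.table(report, file.path(out_dir, "dh_results.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}
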