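#' Assemble a run configuration
#'
#' @param ... Configuration fields; see Details.
#'
#' @details Recognized fields (all optional unless a command requires
#'   them): `counts`, `taxonomy` (input paths), `rank` (default
#'   `"genus"`), `prevalence` (fraction, default 0.3), `method` (default
#'   `"mb"`), `threshold` (correlation cutoff, default 0.3),
#'   `n_bootstrap` (default 100), `seed` (default 1), `out_dir` (default
#'   `"mdmnet_out"`), `fasta`, `blast`, `genes`, `keywords` (paths for
#'   the hub/mining commands), `n_per_class` (default 5), `simulate`
#'   (list of [community_spec()] arguments).
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  defaults <- list(rank = "genus", prevalence = 0.3, method = "mb",
                   threshold = 0.3, n_bootstrap = 100, seed = 1,
                   out_dir = "mdmnet_out", n_per_class = 5)
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file whose keys are [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Write a run configuration to YAML
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
}

# 31-bit polynomial rolling hash of the analysis-relevant configuration,
# for provenance headers.  Path fields are excluded so identical analyses
# in different directories produce identical output bytes.
config_hash <- function(config) {
  keep <- setdiff(names(config), c("counts", "taxonomy", "out_dir",
                                   "blast", "genes", "keywords", "fasta",
                                   "query_lengths"))
  cfg <- unclass(config)[sort(keep)]
  bytes <- utf8ToInt(yaml::as.yaml(cfg))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

run_provenance <- function(config, extra = list()) {
  c(list(version = as.character(utils::packageVersion("mdmnet")),
         config = config_hash(config), seed = config$seed), extra)
}

load_config_table <- function(config) {
  if (is.null(config$counts)) stop("config field 'counts' is required")
  read_otu_table(config$counts, config$taxonomy)
}

#' Simulate a community dataset from a config
#'
#' Writes the count table (with taxonomy column), the planted edge list,
#' and the planted Unknown labels under `out_dir`.
#'
#' @param config A `run_config` whose `simulate` field holds
#'   [community_spec()] arguments.
#' @return Invisibly, the generated dataset.
#' @export
run_simulate <- function(config) {
  args <- config$simulate
  if (is.null(args)) args <- list()
  if (is.null(args$seed)) args$seed <- config$seed
  spec <- do.call(community_spec, args)
  sim <- generate_community(spec)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(sim$table, file.path(config$out_dir, "counts.tsv"))
  write_tsv_with_header(
    data.frame(source = sim$truth$edges[, 1],
               target = sim$truth$edges[, 2], stringsAsFactors = FALSE),
    file.path(config$out_dir, "planted_edges.tsv"),
    run_provenance(config))
  write_tsv_with_header(
    data.frame(otu_id = names(sim$truth$unknown),
               unknown = sim$truth$unknown,
               hub = names(sim$truth$unknown) %in% sim$truth$hubs,
               stringsAsFactors = FALSE),
    file.path(config$out_dir, "planted_labels.tsv"),
    run_provenance(config))
  invisible(sim)
}

#' Build a network and its centralities from a config
#'
#' Prevalence-filters the input table, infers the network, and writes the
#' edge list, node attributes and centrality table under `out_dir`.
#'
#' @param config A `run_config`.
#' @return Invisibly, list with `network`, `centralities`, `summary`.
#' @export
run_build <- function(config) {
  table <- load_config_table(config)
  filt <- filter_by_prevalence(table, min_fraction = config$prevalence)
  if (nrow(filt$counts) == 0) {
    stop("no OTUs pass the prevalence filter", call. = FALSE)
  }
  net <- build_network(filt, method = config$method,
                       threshold = config$threshold, seed = config$seed)
  net$provenance <- c(run_provenance(config), net$provenance)
  cent <- centralities(net)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(net, file.path(config$out_dir, "edges.tsv"))
  write_node_attributes(net, file.path(config$out_dir, "nodes.tsv"))
  write_centralities(cent, file.path(config$out_dir, "centralities.tsv"),
                     rank = config$rank)
  if (!is.null(net$lambda)) {
    message("selected lambda: ", format(net$lambda))
  }
  invisible(list(network = net, centralities = cent,
                 summary = network_summary(net)))
}

#' Run the Original / Without-Unknown / Bootstrap comparison from a config
#'
#' @param config A `run_config`.
#' @return Invisibly, the `mdm_comparison`.
#' @export
run_compare <- function(config) {
  table <- load_config_table(config)
  filt <- filter_by_prevalence(table, min_fraction = config$prevalence)
  res <- mdm_compare(filt, rank = config$rank, method = config$method,
                     n_bootstrap = config$n_bootstrap, seed = config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_comparison(res, file.path(config$out_dir, "comparison.tsv"),
                   file.path(config$out_dir, "comparison_boxplot.tsv"))
  write_tsv_with_header(comparison_arrows(res),
                        file.path(config$out_dir, "comparison_arrows.tsv"),
                        run_provenance(config))
  invisible(res)
}

#' Rank hubs (and optionally export top hub sequences) from a config
#'
#' @param config A `run_config`; if its `fasta` field is set, the top
#'   Known/Unknown hub sequences are exported to `out_dir/top_hubs.fasta`.
#' @return Invisibly, list with `ranking` and `ttest`.
#' @export
run_hubs <- function(config) {
  built <- run_build(config)
  ranking <- rank_hubs(built$centralities, rank = config$rank)
  known <- ranking$ranking$hub_score[!ranking$ranking$unknown]
  unknown <- ranking$ranking$hub_score[ranking$ranking$unknown]
  ttest <- if (length(known) >= 2 && length(unknown) >= 2) {
    hub_score_ttest(known, unknown)
  }
  write_hub_ranking(ranking, file.path(config$out_dir, "hub_ranking.tsv"))
  if (!is.null(config$fasta)) {
    export_top_hub_sequences(ranking, config$fasta,
                             file.path(config$out_dir, "top_hubs.fasta"),
                             n_per_class = config$n_per_class)
  }
  invisible(list(ranking = ranking, ttest = ttest))
}

#' Mine scaffold gene tables for putative adaptation operons from a config
#'
#' Filters the BLAST hits (95/95), restricts the gene table to scaffolds
#' hit by a retained BLAST match and carrying at least 50 genes, and runs
#' the operon caller.
#'
#' @param config A `run_config` with `blast`, `genes` and `keywords`
#'   paths (and optionally `query_lengths`, a 2-column TSV id/length).
#' @return Invisibly, the [mine_operons()] result.
#' @export
run_mine <- function(config) {
  for (f in c("blast", "genes", "keywords")) {
    if (is.null(config[[f]])) stop("config field '", f, "' is required")
    if (!file.exists(config[[f]])) {
      stop("file not found: ", config[[f]], call. = FALSE)
    }
  }
  qlen <- NULL
  if (!is.null(config$query_lengths)) {
    ql <- utils::read.delim(config$query_lengths,
                            stringsAsFactors = FALSE)
    qlen <- stats::setNames(ql[[2]], ql[[1]])
  }
  hits <- filter_hits(parse_blast_tabular(config$blast, qlen))
  genes <- read_gene_table(config$genes)
  genes <- genes[genes$scaffold_id %in% hits$subject_id, , drop = FALSE]
  terms <- read_keywords(config$keywords)
  mined <- mine_operons(genes, terms)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(mined$operons)) {
    write_tsv_with_header(mined$operons,
                          file.path(config$out_dir, "operons.tsv"),
                          run_provenance(config))
    write_tsv_with_header(mined$scaffold_summary,
                          file.path(config$out_dir,
                                    "scaffold_summary.tsv"),
                          run_provenance(config))
  }
  invisible(mined)
}

#' Prevalence-threshold sweep from a config
#'
#' @param config A `run_config`; optional `fractions` field (default 15%
#'   to 40% by 5%).
#' @return Invisibly, the [threshold_sweep()] result.
#' @export
run_sweep <- function(config) {
  table <- load_config_table(config)
  fractions <- config$fractions
  if (is.null(fractions)) fractions <- seq(0.15, 0.40, by = 0.05)
  sw <- threshold_sweep(table, fractions = fractions, rank = config$rank,
                        method = config$method,
                        n_bootstrap = config$n_bootstrap,
                        seed = config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(sw$stability)) {
    write_tsv_with_header(sw$stability,
                          file.path(config$out_dir,
                                    "sweep_stability.tsv"),
                          run_provenance(config))
  }
  invisible(sw)
}
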