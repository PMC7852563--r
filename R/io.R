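#' Read an OTU count table with taxonomy
#'
#' Reads a tab-separated OTU table (rows OTUs, columns samples, first column
#' the OTU id) and a taxonomy TSV with columns `otu_id` and `lineage`.
#'
#' @param counts_path Path to the count TSV.
#' @param taxonomy_path Path to the taxonomy TSV; if `NULL`, the count table
#'   must carry a final `taxonomy` column holding the lineage strings.
#' @param environment Optional environment tag.
#' @return A `community_table`.
#' @export
read_otu_table <- function(counts_path, taxonomy_path = NULL,
                           environment = NA_character_) {
  raw <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  ids <- as.character(raw[[1]])
  raw <- raw[, -1, drop = FALSE]
  if (is.null(taxonomy_path)) {
    tax_col <- which(tolower(names(raw)) == "taxonomy")
    if (!length(tax_col)) stop("no taxonomy column and no taxonomy file")
    lineages <- stats::setNames(as.character(raw[[tax_col]]), ids)
    raw <- raw[, -tax_col, drop = FALSE]
  } else {
    tax <- utils::read.delim(taxonomy_path, stringsAsFactors = FALSE)
    lineages <- stats::setNames(as.character(tax$lineage),
                                as.character(tax$otu_id))
  }
  counts <- as.matrix(raw)
  rownames(counts) <- ids
  community_table(counts, lineages[ids], environment)
}

#' Write an OTU count table (with taxonomy column) to TSV
#'
#' @param table A `community_table`.
#' @param path Output path.
#' @export
write_otu_table <- function(table, path) {
  df <- data.frame(otu_id = otu_ids(table), table$counts,
                   taxonomy = vapply(table$taxonomy, render_lineage,
                                     character(1)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a BIOM-format OTU table
#'
#' Reads a BIOM 1.0/2.x file via the biomformat package, taking taxonomy
#' from the observation metadata `taxonomy` field.
#'
#' @param path Path to a `.biom` file.
#' @param environment Optional environment tag.
#' @return A `community_table`.
#' @export
read_biom_table <- function(path, environment = NA_character_) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("the biomformat package is required to read BIOM files")
  }
  b <- biomformat::read_biom(path)
  counts <- as.matrix(biomformat::biom_data(b))
  md <- biomformat::observation_metadata(b)
  lineages <- if (is.data.frame(md)) {
    apply(md, 1, paste, collapse = ";")
  } else {
    vapply(md, function(m) paste(unlist(m), collapse = ";"), character(1))
  }
  community_table(counts, lineages[rownames(counts)], environment)
}

#' Read a sample-to-environment mapping file
#'
#' Tab-separated, columns `sample_id` and `environment` (any further
#' columns, e.g. latitude/longitude, are carried along unused).
#'
#' @param path Path to the mapping TSV.
#' @return data.frame.
#' @export
read_mapping <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

provenance_header <- function(provenance) {
  items <- vapply(names(provenance), function(k) {
    paste0(k, "=", paste(format(provenance[[k]]), collapse = ","))
  }, character(1))
  paste0("# mdmnet ", paste(items, collapse = " "))
}

write_tsv_with_header <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(provenance_header(provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a network as an edge-list TSV
#'
#' Columns: `source`, `target`, `weight`, `method`.  A provenance comment
#' header records the inference settings.
#'
#' @param net A `cooccurrence_network`.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net$graph)
  w <- igraph::edge_attr(net$graph, "weight")
  if (is.null(w)) w <- rep(1, nrow(el))
  df <- data.frame(source = el[, 1], target = el[, 2], weight = w,
                   method = net$method, stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, net$provenance)
}

#' Write node attributes (labels and Unknown flags per rank) to TSV
#'
#' @param net A `cooccurrence_network`.
#' @param path Output path.
#' @export
write_node_attributes <- function(net, path) {
  write_tsv_with_header(net$nodes, path, net$provenance)
}

#' Write a network in GraphML format
#'
#' @param net A `cooccurrence_network`.
#' @param path Output path.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
}

#' Read/write BLAST tabular (outfmt 6) files
#'
#' `write_blast_tabular()` writes hits back in the 13-column dialect
#' (standard 12 plus query coverage) accepted by [parse_blast_tabular()].
#'
#' @param hits data.frame of BLAST hits.
#' @param path Output path.
#' @export
write_blast_tabular <- function(hits, path) {
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "qstart", "qend", "sstart", "send",
            "e_value", "bitscore", "query_coverage")
  utils::write.table(hits[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a scaffold gene table
#'
#' Tab-separated with columns `scaffold_id`, `gene_id`, `start`, `end`,
#' `strand`, `product`.  Coordinates are 1-based inclusive.
#'
#' @param path Path to the TSV.
#' @return data.frame of gene records.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("scaffold_id", "gene_id", "start", "end", "strand", "product")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("gene table missing columns: ", paste(missing, collapse = ", "))
  }
  validate_genes(df)
  df
}

#' Read gene records from a GFF3 file
#'
#' Convenience reader: takes `gene`/`CDS` features, using the attributes'
#' `product` (falling back to `Name`) as the annotation and `ID` as the
#' gene id.
#'
#' @param path Path to a GFF3 file.
#' @param feature_types Feature types to keep.
#' @return data.frame of gene records.
#' @export
read_genes_gff3 <- function(path, feature_types = c("gene", "CDS")) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- fields[vapply(fields, length, integer(1)) == 9L]
  rows <- lapply(fields, function(f) {
    if (!f[3] %in% feature_types) return(NULL)
    attrs <- strsplit(f[9], ";", fixed = TRUE)[[1]]
    kv <- strsplit(attrs, "=", fixed = TRUE)
    vals <- stats::setNames(vapply(kv, function(x) x[2], character(1)),
                            vapply(kv, function(x) x[1], character(1)))
    product <- if (!is.na(vals["product"])) vals[["product"]]
               else if (!is.na(vals["Name"])) vals[["Name"]] else ""
    data.frame(scaffold_id = f[1],
               gene_id = if (!is.na(vals["ID"])) vals[["ID"]] else f[9],
               start = as.integer(f[4]), end = as.integer(f[5]),
               strand = f[7], product = utils::URLdecode(product),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  validate_genes(df)
  df
}

#' Read an adaptation keyword list
#'
#' Plain text, one term per line; blank lines and `#` comments ignored.
#' The package ships a starter list at
#' `system.file("extdata", "adaptation_keywords.txt", package = "mdmnet")`.
#'
#' @param path Path to the keyword file.
#' @return Character vector of terms.
#' @export
read_keywords <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  } else {
    writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  }
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path Path to the FASTA file.
#' @return Named character vector (names are the first whitespace-delimited
#'   token of each header).
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    s <- Biostrings::readDNAStringSet(path)
    stats::setNames(as.character(s), sub("\\s.*$", "", names(s)))
  } else {
    lines <- readLines(path)
    idx <- cumsum(startsWith(lines, ">"))
    headers <- sub("\\s.*$", "", sub("^>", "", lines[startsWith(lines, ">")]))
    seqs <- vapply(split(lines[!startsWith(lines, ">")],
                         idx[!startsWith(lines, ">")]),
                   paste, character(1), collapse = "")
    stats::setNames(unname(seqs), headers)
  }
}
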