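validate_genes <- function(genes) {
  if (is.null(genes) || nrow(genes) == 0) return(invisible(genes))
  if (any(genes$start < 1)) stop("gene start coordinates must be >= 1")
  if (any(genes$start > genes$end)) stop("gene start must be <= end")
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  invisible(genes)
}

#' Parse BLAST tabular (outfmt 6) results
#'
#' Reads 12-column standard outfmt 6, or the 13-column dialect whose last
#' column is the query coverage.  Without a coverage column, coverage is
#' computed as `100 * (|qend - qstart| + 1) / query_length`, which is
#' orientation-independent (minus-strand hits have `qstart > qend`).
#'
#' @param path Path to the tabular file.
#' @param query_lengths Named numeric vector of query sequence lengths;
#'   required when the file has no coverage column.
#' @return data.frame of hits: `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `qstart`, `qend`, `sstart`, `send`, `e_value`, `bitscore`,
#'   `query_coverage`.
#' @export
parse_blast_tabular <- function(path, query_lengths = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  bad <- which(!nf %in% c(12L, 13L))
  if (length(bad)) {
    stop("malformed BLAST tabular line ", bad[1], ": expected 12 or 13 ",
         "columns, found ", nf[bad[1]])
  }
  m <- do.call(rbind, fields)
  hits <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                     percent_identity = as.numeric(m[, 3]),
                     alignment_length = as.integer(m[, 4]),
                     mismatches = as.integer(m[, 5]),
                     gap_opens = as.integer(m[, 6]),
                     qstart = as.integer(m[, 7]),
                     qend = as.integer(m[, 8]),
                     sstart = as.integer(m[, 9]),
                     send = as.integer(m[, 10]),
                     e_value = as.numeric(m[, 11]),
                     bitscore = as.numeric(m[, 12]),
                     stringsAsFactors = FALSE)
  if (ncol(m) == 13L) {
    hits$query_coverage <- as.numeric(m[, 13])
  } else {
    if (is.null(query_lengths)) {
      stop("no query-coverage column and no query_lengths supplied")
    }
    len <- query_lengths[hits$query_id]
    if (any(is.na(len))) {
      stop("query_lengths missing for: ",
           paste(unique(hits$query_id[is.na(len)]), collapse = ", "))
    }
    hits$query_coverage <- 100 * (abs(hits$qend - hits$qstart) + 1) / len
  }
  hits
}

#' Filter BLAST hits on identity and coverage
#'
#' Inclusive thresholds: a hit at exactly 95% identity and 95% coverage is
#' retained under the defaults.
#'
#' @param hits data.frame from [parse_blast_tabular()].
#' @param min_identity Minimum percent identity (default 95).
#' @param min_coverage Minimum percent query coverage (default 95).
#' @return Filtered data.frame.
#' @export
filter_hits <- function(hits, min_identity = 95, min_coverage = 95) {
  hits[hits$percent_identity >= min_identity &
         hits$query_coverage >= min_coverage, , drop = FALSE]
}

#' Keep only gene-rich scaffolds
#'
#' Retains scaffolds carrying at least `min_genes` genes (inclusive,
#' default 50), so downstream operon calls have enough genomic context.
#'
#' @param genes data.frame of gene records (possibly many scaffolds), or a
#'   named list of per-scaffold data.frames.
#' @param min_genes Minimum gene count per scaffold.
#' @return Same shape as the input, restricted to retained scaffolds.
#' @export
filter_scaffolds <- function(genes, min_genes = 50) {
  if (is.data.frame(genes)) {
    counts <- table(genes$scaffold_id)
    keep <- names(counts)[counts >= min_genes]
    genes[genes$scaffold_id %in% keep, , drop = FALSE]
  } else {
    genes[vapply(genes, nrow, integer(1)) >= min_genes]
  }
}

#' Flag hypothetical and adaptation genes
#'
#' A gene is hypothetical when its product annotation contains (case-
#' insensitively) any of the `hypothetical_terms`; it is an adaptation gene
#' when the product matches any term of the adaptation keyword list.  A
#' gene may carry both flags.
#'
#' @param genes data.frame of gene records.
#' @param adaptation_terms Nonempty character vector of keywords (see
#'   [read_keywords()] and the packaged
#'   `extdata/adaptation_keywords.txt`).
#' @param hypothetical_terms Substrings marking unannotated genes.
#' @return `genes` with logical columns `hypothetical` and `adaptation`
#'   added.  Attribute `"scaffold_summary"` tallies both flags per
#'   scaffold.
#' @export
flag_genes <- function(genes, adaptation_terms,
                       hypothetical_terms = c("hypothetical",
                                              "unknown function", "DUF")) {
  if (length(adaptation_terms) == 0) {
    stop("adaptation keyword list is empty")
  }
  match_any <- function(terms) {
    hit <- rep(FALSE, nrow(genes))
    for (term in terms) {
      hit <- hit | grepl(term, genes$product, ignore.case = TRUE,
                         fixed = FALSE)
    }
    hit
  }
  genes$hypothetical <- match_any(hypothetical_terms)
  genes$adaptation <- match_any(adaptation_terms)
  summ <- do.call(rbind, lapply(split(genes, genes$scaffold_id),
    function(d) {
      data.frame(scaffold_id = d$scaffold_id[1], n_genes = nrow(d),
                 n_hypothetical = sum(d$hypothetical),
                 n_adaptation = sum(d$adaptation),
                 stringsAsFactors = FALSE)
    }))
  rownames(summ) <- NULL
  attr(genes, "scaffold_summary") <- summ
  genes
}

# intergenic gap between two genes on a shared axis: 0 when they overlap,
# otherwise the number of bases strictly between them
intergenic_gap <- function(start_a, end_a, start_b, end_b) {
  pmax(0, pmax(start_a, start_b) - pmin(end_a, end_b) - 1)
}

#' Cluster same-strand genes into operons by intergenic distance
#'
#' Per strand, genes sorted by start coordinate are chained: consecutive
#' genes belong to the same operon when the intergenic gap between them
#' (`start_next - end_prev - 1`, floored at 0) is at most `max_gap`.  This
#' equals cutting a single-linkage dendrogram over the gap distances at
#' `max_gap`.  Singleton operons are permitted; genes on opposite strands
#' are never merged.
#'
#' @param genes data.frame of gene records from a single scaffold.
#' @param max_gap Maximum intergenic gap in bp (inclusive, default 5000).
#' @return `genes` with an `operon_id` column
#'   (`<scaffold>:<strand>:<index>`); ordered by strand then start.
#'   Overlapping same-strand genes are clipped to gap 0 with a warning.
#' @export
cluster_operons <- function(genes, max_gap = 5000) {
  if (length(unique(genes$scaffold_id)) > 1) {
    stop("cluster_operons expects genes from a single scaffold")
  }
  validate_genes(genes)
  pieces <- lapply(split(genes, genes$strand), function(d) {
    d <- d[order(d$start, d$end, d$gene_id), , drop = FALSE]
    if (nrow(d) > 1) {
      gap_raw <- d$start[-1] - d$end[-nrow(d)] - 1
      if (any(gap_raw < 0)) {
        warning("overlapping same-strand genes; gap clipped to 0")
      }
      gap <- pmax(0, gap_raw)
      breaks <- c(TRUE, gap > max_gap)
    } else {
      breaks <- TRUE
    }
    d$operon_id <- paste(d$scaffold_id, d$strand, cumsum(breaks),
                         sep = ":")
    d
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# the window_genes nearest same-operon neighbors of gene i (by intergenic
# gap, ties by genomic order distance then id), each within max_gap
neighbor_window <- function(d, i, window_genes, max_gap) {
  others <- setdiff(seq_len(nrow(d)), i)
  if (!length(others)) return(integer(0))
  gaps <- intergenic_gap(d$start[i], d$end[i], d$start[others],
                         d$end[others])
  ord <- order(gaps, abs(others - i), d$gene_id[others])
  nearest <- others[ord][seq_len(min(window_genes, length(others)))]
  gap_sel <- gaps[ord][seq_len(min(window_genes, length(others)))]
  nearest[gap_sel <= max_gap]
}

#' Call putative adaptation operons
#'
#' An operon is a putative adaptation operon when it contains at least one
#' hypothetical gene that has at least one adaptation-flagged gene among
#' its `window_genes` nearest same-operon neighbors (nearest by intergenic
#' gap, each neighbor within `max_gap`).
#'
#' @param genes Output of [cluster_operons()] on genes that carry the
#'   `hypothetical`/`adaptation` flags from [flag_genes()].
#' @param window_genes Neighbor-window size (default 10).
#' @param max_gap Maximum neighbor gap in bp (default 5000).
#' @return data.frame, one row per operon: `scaffold_id`, `operon_id`,
#'   `strand`, `n_genes`, `n_hypothetical`, `n_adaptation`,
#'   `is_putative_adaptation`, `members` (gene ids, comma-joined in
#'   coordinate order).
#' @export
call_putative_adaptation_operons <- function(genes, window_genes = 10,
                                             max_gap = 5000) {
  if (!all(c("operon_id", "hypothetical", "adaptation") %in% names(genes))) {
    stop("genes must carry operon_id (cluster_operons) and ",
         "hypothetical/adaptation flags (flag_genes)")
  }
  ops <- lapply(split(genes, genes$operon_id), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    flagged <- FALSE
    hyp_idx <- which(d$hypothetical)
    for (i in hyp_idx) {
      nb <- neighbor_window(d, i, window_genes, max_gap)
      if (any(d$adaptation[nb])) {
        flagged <- TRUE
        break
      }
    }
    data.frame(scaffold_id = d$scaffold_id[1], operon_id = d$operon_id[1],
               strand = d$strand[1], n_genes = nrow(d),
               n_hypothetical = sum(d$hypothetical),
               n_adaptation = sum(d$adaptation),
               is_putative_adaptation = flagged,
               members = paste(d$gene_id, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, ops)
  rownames(out) <- NULL
  out[order(out$scaffold_id, out$strand,
            as.integer(sub(".*:", "", out$operon_id))), , drop = FALSE]
}

#' Mine scaffolds for putative adaptation operons
#'
#' Convenience wrapper: filters to gene-rich scaffolds, flags hypothetical
#' and adaptation genes, clusters each scaffold's genes into operons, and
#' calls putative adaptation operons.
#'
#' @param genes data.frame of gene records (any number of scaffolds).
#' @param adaptation_terms Keyword list.
#' @param min_genes Scaffold gene-count filter (default 50).
#' @param max_gap,window_genes See [cluster_operons()] and
#'   [call_putative_adaptation_operons()].
#' @param hypothetical_terms See [flag_genes()].
#' @return List with `operons` (all scaffolds combined), `genes` (flagged,
#'   clustered) and `scaffold_summary` (per-scaffold gene/operon tallies).
#' @export
mine_operons <- function(genes, adaptation_terms, min_genes = 50,
                         max_gap = 5000, window_genes = 10,
                         hypothetical_terms = c("hypothetical",
                                                "unknown function",
                                                "DUF")) {
  genes <- filter_scaffolds(genes, min_genes)
  if (nrow(genes) == 0) {
    return(list(operons = NULL, genes = genes, scaffold_summary = NULL))
  }
  genes <- flag_genes(genes, adaptation_terms, hypothetical_terms)
  clustered <- do.call(rbind, lapply(split(genes, genes$scaffold_id),
                                     cluster_operons, max_gap = max_gap))
  rownames(clustered) <- NULL
  operons <- call_putative_adaptation_operons(clustered, window_genes,
                                              max_gap)
  summ <- do.call(rbind, lapply(split(operons, operons$scaffold_id),
    function(d) {
      data.frame(scaffold_id = d$scaffold_id[1],
                 n_operons = nrow(d),
                 n_putative_adaptation = sum(d$is_putative_adaptation),
                 n_hypothetical = sum(d$n_hypothetical),
                 n_adaptation = sum(d$n_adaptation),
                 stringsAsFactors = FALSE)
    }))
  rownames(summ) <- NULL
  list(operons = operons, genes = clustered, scaffold_summary = summ)
}
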