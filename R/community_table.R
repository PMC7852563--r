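#' Construct a community table
#'
#' Container for an OTU-by-sample count matrix with per-OTU taxonomy.
#'
#' @param counts Nonnegative integer matrix, OTUs in rows and samples in
#'   columns; `rownames` are OTU ids and `colnames` sample ids.
#' @param taxonomy Either a named character vector of lineage strings (names
#'   are OTU ids) or a named list of `taxonomy_assignment` objects covering
#'   every row of `counts`.
#' @param environment Optional free-text environment tag (e.g.
#'   `"hot springs"`).
#' @return A `community_table`: list with `counts`, `taxonomy` (named list of
#'   assignments) and `environment`.
#' @export
community_table <- function(counts, taxonomy, environment = NA_character_) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stop("counts must have OTU row names and sample column names")
  }
  if (nrow(counts) == 0 && is.null(rownames(counts))) {
    rownames(counts) <- character(0)
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate OTU ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(counts != round(counts))) stop("counts must be integral")

  if (is.character(taxonomy)) {
    if (is.null(names(taxonomy))) names(taxonomy) <- rownames(counts)
    taxonomy <- lapply(stats::setNames(names(taxonomy), names(taxonomy)),
                       function(id) parse_lineage(taxonomy[[id]], id))
  }
  missing <- setdiff(rownames(counts), names(taxonomy))
  if (length(missing)) {
    stop("taxonomy missing for OTUs: ", paste(utils::head(missing, 5),
                                              collapse = ", "))
  }
  taxonomy <- taxonomy[rownames(counts)]
  structure(list(counts = counts, taxonomy = taxonomy,
                 environment = environment),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat("<community_table> ", nrow(x$counts), " OTUs x ", ncol(x$counts),
      " samples", if (!is.na(x$environment)) paste0(" [", x$environment, "]"),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.community_table <- function(x) dim(x$counts)

otu_ids <- function(table) rownames(table$counts)
sample_ids <- function(table) colnames(table$counts)

# subset rows (OTUs), keeping taxonomy aligned
subset_otus <- function(table, keep) {
  community_table(table$counts[keep, , drop = FALSE],
                  table$taxonomy[rownames(table$counts)[keep]],
                  table$environment)
}

#' Per-OTU prevalence
#'
#' Prevalence is the fraction of samples in which an OTU has a nonzero
#' count.  Also returns the prevalence curve: the number of OTUs present in
#' at least k samples, for k = 1..n.
#'
#' @param table A `community_table`.
#' @return List with `fraction` (named numeric), `n_nonzero` (named
#'   integer), `n_samples` and `curve` (integer vector of length
#'   `n_samples`).
#' @export
prevalence <- function(table) {
  n <- ncol(table$counts)
  if (n < 1) stop("table has no samples")
  nz <- rowSums(table$counts > 0)
  curve <- vapply(seq_len(n), function(k) sum(nz >= k), integer(1))
  list(fraction = nz / n, n_nonzero = as.integer(nz), n_samples = n,
       curve = curve)
}

#' Filter OTUs by prevalence
#'
#' Retains OTUs present (nonzero) in at least a given number of samples.
#' With the fractional form, the sample cutoff is
#' `ceiling(min_fraction * n_samples)` and the comparison is inclusive, so a
#' 40% threshold over 260 samples keeps OTUs present in >= 104 samples.
#'
#' @param table A `community_table`.
#' @param min_fraction Proportion of samples in `[0, 1]`.
#' @param min_samples Integer sample cutoff.  Exactly one of the two
#'   threshold forms must be given.
#' @return Filtered `community_table`; attribute `"retained_fraction"`
#'   records the fraction of input OTUs kept.
#' @export
filter_by_prevalence <- function(table, min_fraction = NULL,
                                 min_samples = NULL) {
  if (is.null(min_fraction) == is.null(min_samples)) {
    stop("give exactly one of min_fraction or min_samples")
  }
  if (!is.null(min_fraction)) {
    if (min_fraction < 0 || min_fraction > 1) {
      stop("min_fraction must be in [0, 1]")
    }
    min_samples <- ceiling(min_fraction * ncol(table$counts))
  }
  nz <- rowSums(table$counts > 0)
  keep <- which(nz >= min_samples)
  out <- subset_otus(table, keep)
  attr(out, "retained_fraction") <- length(keep) / nrow(table$counts)
  attr(out, "prevalence_cutoff") <- min_samples
  out
}

#' Drop OTUs with a low total count
#'
#' Replicates upstream singleton removal: OTUs whose total count over all
#' samples falls below `min_total` are removed (default 2, i.e. singletons).
#'
#' @param table A `community_table`.
#' @param min_total Minimum total count.
#' @return Filtered `community_table`.
#' @export
filter_min_total <- function(table, min_total = 2) {
  subset_otus(table, which(rowSums(table$counts) >= min_total))
}

#' Remove OTUs whose lineage matches a blacklist
#'
#' Drops OTUs whose rendered lineage matches any of the given patterns
#' (case-insensitive regular expressions).  Typical use removes Archaea,
#' chloroplast and mitochondrial sequences before a Bacteria-focused
#' analysis.
#'
#' @param table A `community_table`.
#' @param patterns Character vector of regular expressions.
#' @return Filtered `community_table`.
#' @export
filter_lineage_blacklist <- function(table,
                                     patterns = c("archaea", "chloroplast",
                                                  "mitochondri")) {
  lineages <- vapply(table$taxonomy, render_lineage, character(1))
  hit <- Reduce(`|`, lapply(patterns, function(p) {
    grepl(p, lineages, ignore.case = TRUE)
  }))
  subset_otus(table, which(!hit))
}

#' Relabel (or aggregate) a table at a taxonomic rank
#'
#' At each "taxonomic level" the analysis keeps OTU-level nodes and only
#' changes the Known/Unknown display label each node carries; rows are not
#' merged (`aggregate = "relabel"`, the default).  `aggregate = "sum"`
#' instead sums counts of rows sharing a lineage truncated at `rank`.
#'
#' @param table A `community_table`.
#' @param rank Rank name.
#' @param aggregate `"relabel"` or `"sum"`.
#' @return For `"relabel"`, the input table with a `"rank_labels"` attribute
#'   (display label per OTU, `"Unknown"` where flagged).  For `"sum"`, a new
#'   `community_table` with one row per truncated lineage.
#' @export
collapse_to_rank <- function(table, rank, aggregate = c("relabel", "sum")) {
  aggregate <- match.arg(aggregate)
  labels <- rank_label(table$taxonomy, rank)
  if (aggregate == "relabel") {
    attr(table, "rank_labels") <- stats::setNames(labels, otu_ids(table))
    attr(table, "rank") <- rank
    return(table)
  }
  ranks <- mdm_ranks()
  upto <- seq_len(match(rank, ranks))
  key <- vapply(table$taxonomy, function(a) {
    if (a$unknown_at[[rank]]) {
      # truncate at the shallowest Unknown rank so Unknowns under different
      # known parents stay distinct
      first_u <- which(a$unknown_at[upto])[1]
      paste(c(a$rank_labels[seq_len(max(first_u - 1, 0))], "Unknown"),
            collapse = ";")
    } else {
      paste(a$rank_labels[upto], collapse = ";")
    }
  }, character(1))
  groups <- split(seq_len(nrow(table$counts)), key)
  counts <- t(vapply(groups, function(rows) {
    colSums(table$counts[rows, , drop = FALSE])
  }, numeric(ncol(table$counts))))
  rownames(counts) <- names(groups)
  # representative taxonomy: first member, truncated flags preserved
  taxonomy <- lapply(stats::setNames(names(groups), names(groups)), function(k) {
    rep_assign <- table$taxonomy[[groups[[k]][1]]]
    rep_assign$otu_id <- k
    rep_assign
  })
  community_table(counts, taxonomy, table$environment)
}

#' OTU sharing across environments
#'
#' For every nonempty subset of the input tables, counts the OTU ids present
#' (nonzero in at least one sample) in exactly that subset of environments —
#' the counts behind a Venn diagram of shared OTUs.  Environment-unique OTUs
#' are additionally split Known/Unknown at `rank`.
#'
#' @param tables List of `community_table`s (>= 2), named by environment.
#' @param rank Rank at which to split environment-unique OTUs (default
#'   genus).
#' @return List with `membership` (data.frame: one row per nonempty subset,
#'   columns `subset`, `n`) and `unique_split` (data.frame per environment:
#'   `environment`, `n_unique`, `n_known`, `n_unknown`).
#' @export
shared_otus <- function(tables, rank = "genus") {
  if (length(tables) < 2) stop("need at least two tables")
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- paste0("env", seq_along(tables))
  }
  present <- lapply(tables, function(t) {
    otu_ids(t)[rowSums(t$counts > 0) > 0]
  })
  all_ids <- unique(unlist(present))
  member <- vapply(present, function(ids) all_ids %in% ids,
                   logical(length(all_ids)))
  if (length(all_ids) == 1L) member <- matrix(member, nrow = 1)
  key <- apply(member, 1, function(row) {
    paste(names(tables)[row], collapse = "&")
  })
  tab <- table(key)
  membership <- data.frame(subset = names(tab), n = as.integer(tab),
                           row.names = NULL, stringsAsFactors = FALSE)

  unique_split <- do.call(rbind, lapply(names(tables), function(env) {
    uniq <- all_ids[key == env]
    u <- if (length(uniq)) {
      unknown_mask(tables[[env]]$taxonomy[uniq], rank)
    } else logical(0)
    data.frame(environment = env, n_unique = length(uniq),
               n_known = sum(!u), n_unknown = sum(u),
               stringsAsFactors = FALSE)
  }))
  list(membership = membership, unique_split = unique_split)
}

#' Fisher test for Unknown-fraction enrichment between two environments
#'
#' Tests whether one environment's unique-OTU pool is enriched in Unknown
#' taxa relative to another's, via a two-sided Fisher exact test on the
#' 2x2 table of (Unknown, Known) OTU counts.
#'
#' @param table_a,table_b `community_table`s.
#' @param rank Rank at which Unknown status is read.
#' @return List with `odds_ratio`, `p_value`, and the 2x2 `counts` matrix.
#' @export
unknown_enrichment <- function(table_a, table_b, rank = "genus") {
  ua <- unknown_mask(table_a$taxonomy, rank)
  ub <- unknown_mask(table_b$taxonomy, rank)
  m <- matrix(c(sum(ua), sum(!ua), sum(ub), sum(!ub)), nrow = 2,
              dimnames = list(c("unknown", "known"), c("a", "b")))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("degenerate margin in enrichment table; p = 1")
    return(list(odds_ratio = NA_real_, p_value = 1, counts = m))
  }
  ft <- stats::fisher.test(m)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, counts = m)
}
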