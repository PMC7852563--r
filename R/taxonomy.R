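#' Supported taxonomic ranks
#'
#' The six ranks at which Unknown ("microbial dark matter") status is
#' tracked, ordered from the most to the least inclusive.
#'
#' @return Character vector `c("domain", "phylum", "class", "order",
#'   "family", "genus")`.
#' @export
mdm_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus")
}

#' Default Unknown tokens
#'
#' Labels that mark a rank as taxonomically unassigned.  Matching is
#' case-insensitive and treats underscores and spaces as equivalent, so
#' `"Ambiguous_taxa"` and `"ambiguous taxa"` both match.
#'
#' @return Character vector of the six default tokens.
#' @export
unknown_tokens <- function() {
  c("uncultured", "uncultured bacterium", "unknown", "unassigned",
    "ambiguous taxa", "na")
}

# canonical form used for token comparison: lower case, underscores -> spaces,
# surrounding whitespace removed
canonical_label <- function(x) {
  x <- gsub("_", " ", tolower(trimws(x)))
  gsub("[[:space:]]+", " ", x)
}

# strip SILVA-style rank prefixes: "D_0__Bacteria", "k__Bacteria", "p__..."
strip_rank_prefix <- function(x) {
  sub("^[A-Za-z]_?[0-9]*__", "", x)
}

#' Parse a taxonomy lineage string
#'
#' Splits a delimited lineage into per-rank labels and flags each rank as
#' Unknown when its label is missing, empty, or matches one of the Unknown
#' tokens.  Unknown status then propagates downward: an OTU that cannot be
#' classified at some rank is Unknown at that rank and every rank below it,
#' whatever the deeper labels say.
#'
#' @param lineage Lineage string, e.g.
#'   `"Bacteria;Proteobacteria;Gammaproteobacteria;..."`.  SILVA-style rank
#'   prefixes (`"D_0__"`, `"k__"`) are stripped before comparison.
#' @param otu_id Identifier attached to the returned assignment.
#' @param delimiter Field separator (default `";"`).
#' @param tokens Unknown tokens; see [unknown_tokens()].
#' @param ranks Rank names, most inclusive first.  Lineages with more fields
#'   than ranks are an error; missing trailing fields are treated as Unknown.
#' @return A `taxonomy_assignment`: list with `otu_id`, `rank_labels`
#'   (named character) and `unknown_at` (named logical, monotone downward).
#' @examples
#' a <- parse_lineage("Bacteria;Proteobacteria;uncultured", "otu1")
#' a$unknown_at
#' @export
parse_lineage <- function(lineage, otu_id, delimiter = ";",
                          tokens = unknown_tokens(), ranks = mdm_ranks()) {
  stopifnot(length(lineage) == 1L, length(otu_id) == 1L)
  fields <- if (is.na(lineage) || !nzchar(trimws(lineage))) character(0)
            else strsplit(lineage, delimiter, fixed = TRUE)[[1]]
  if (length(fields) > length(ranks)) {
    stop("lineage has ", length(fields), " fields but only ",
         length(ranks), " ranks are configured: '", lineage, "'")
  }
  labels <- rep(NA_character_, length(ranks))
  names(labels) <- ranks
  labels[seq_along(fields)] <- trimws(strip_rank_prefix(fields))

  canon_tokens <- canonical_label(tokens)
  unknown <- vapply(labels, function(lab) {
    is.na(lab) || !nzchar(lab) || canonical_label(lab) %in% canon_tokens
  }, logical(1))
  # propagate downward: unknown at r => unknown at every rank below r
  unknown <- as.logical(cummax(unknown))
  names(unknown) <- ranks

  structure(list(otu_id = otu_id, rank_labels = labels, unknown_at = unknown),
            class = "taxonomy_assignment")
}

#' Render a taxonomy assignment back into a lineage string
#'
#' Inverse of [parse_lineage()] up to prefix stripping: re-parsing the
#' rendered string reproduces the same Unknown flags.
#'
#' @param assignment A `taxonomy_assignment`.
#' @param delimiter Field separator.
#' @return Lineage string; missing labels render as `"NA"`.
#' @export
render_lineage <- function(assignment, delimiter = ";") {
  lab <- assignment$rank_labels
  lab[is.na(lab) | !nzchar(lab)] <- "NA"
  paste(lab, collapse = delimiter)
}

#' @export
print.taxonomy_assignment <- function(x, ...) {
  cat("<taxonomy_assignment>", x$otu_id, "\n")
  flag <- ifelse(x$unknown_at, "U", "K")
  cat(paste0("  ", names(x$rank_labels), " [", flag, "]: ",
             ifelse(is.na(x$rank_labels), "NA", x$rank_labels),
             collapse = "\n"), "\n")
  invisible(x)
}

#' Unknown indicator vector at a rank
#'
#' @param assignments List of `taxonomy_assignment` objects.
#' @param rank One of [mdm_ranks()].
#' @return Logical vector aligned with `assignments`.
#' @export
unknown_mask <- function(assignments, rank) {
  if (!rank %in% mdm_ranks()) {
    stop("unsupported rank '", rank, "'; expected one of: ",
         paste(mdm_ranks(), collapse = ", "))
  }
  vapply(assignments, function(a) a$unknown_at[[rank]], logical(1),
         USE.NAMES = FALSE)
}

#' Display label for each OTU at a rank
#'
#' The lineage label at `rank`, replaced by `"Unknown"` wherever the OTU is
#' flagged Unknown at that rank.
#'
#' @inheritParams unknown_mask
#' @param rank Rank name.
#' @return Character vector.
#' @export
rank_label <- function(assignments, rank) {
  u <- unknown_mask(assignments, rank)
  lab <- vapply(assignments, function(a) a$rank_labels[[rank]], character(1),
                USE.NAMES = FALSE)
  ifelse(u | is.na(lab), "Unknown", lab)
}
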