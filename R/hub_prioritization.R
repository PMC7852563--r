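#' Rank taxa by hub score
#'
#' Orders nodes by hub score (descending), breaking ties by degree
#' (descending) then lexicographic OTU id so the ranking is deterministic.
#' Also reports the proportion of Unknown taxa among the top 20 hubs.
#'
#' @param cent A centrality table ([centralities()]) carrying the per-rank
#'   Unknown columns.
#' @param rank Rank at which Known/Unknown is read.
#' @param top_n Window for the Unknown-proportion summary (default 20).
#' @return `hub_ranking`: list with `ranking` (data.frame: `position`,
#'   `otu_id`, `hub_score`, `degree`, `unknown`, `label`),
#'   `top_unknown_proportion`, `rank`, `top_n`.
#' @export
rank_hubs <- function(cent, rank = "genus", top_n = 20) {
  ucol <- paste0("unknown_", rank)
  lcol <- paste0("label_", rank)
  if (!ucol %in% names(cent)) {
    stop("centrality table lacks Unknown flags at rank ", rank)
  }
  ord <- order(-cent$hub_score, -cent$degree, cent$otu_id)
  ranking <- data.frame(position = seq_along(ord),
                        otu_id = cent$otu_id[ord],
                        hub_score = cent$hub_score[ord],
                        degree = cent$degree[ord],
                        unknown = cent[[ucol]][ord],
                        label = cent[[lcol]][ord],
                        stringsAsFactors = FALSE)
  top <- utils::head(ranking, top_n)
  structure(list(ranking = ranking,
                 top_unknown_proportion = mean(top$unknown),
                 rank = rank, top_n = top_n),
            class = "hub_ranking")
}

#' @export
print.hub_ranking <- function(x, ...) {
  cat("<hub_ranking> ", nrow(x$ranking), " nodes; ",
      round(100 * x$top_unknown_proportion), "% Unknown among top ",
      x$top_n, "\n", sep = "")
  print(utils::head(x$ranking, 10))
  invisible(x)
}

#' t-test comparing Known and Unknown hub scores
#'
#' Two-sample two-sided t-test on hub-score values.  The Welch
#' (unequal-variance) variant is the default; the classic pooled test is
#' available via `var_equal = TRUE`.
#'
#' @param known_scores,unknown_scores Numeric vectors (each of length
#'   >= 2).
#' @param var_equal Use the pooled-variance test.
#' @return List with `t`, `p_value`, `df`, `mean_known`, `mean_unknown`.
#' @export
hub_score_ttest <- function(known_scores, unknown_scores,
                            var_equal = FALSE) {
  if (length(known_scores) < 2 || length(unknown_scores) < 2) {
    stop("both groups need at least 2 values")
  }
  if (stats::sd(known_scores) == 0 && stats::sd(unknown_scores) == 0) {
    same <- mean(known_scores) == mean(unknown_scores)
    return(list(t = if (same) 0 else Inf, p_value = if (same) 1 else 0,
                df = NA_real_, mean_known = mean(known_scores),
                mean_unknown = mean(unknown_scores), degenerate = TRUE))
  }
  tt <- stats::t.test(known_scores, unknown_scores, var.equal = var_equal)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_known = mean(known_scores),
       mean_unknown = mean(unknown_scores), degenerate = FALSE)
}

#' Export the top Known and Unknown hub sequences to FASTA
#'
#' Writes the representative sequences of the `n_per_class` highest-ranked
#' Known and Unknown hubs (by hub score) for downstream metagenome
#' screening.  Headers are the OTU ids.
#'
#' @param ranking A `hub_ranking`.
#' @param sequences Named character vector of sequences (or a FASTA path
#'   read via [read_fasta()]).
#' @param path Output FASTA path.
#' @param n_per_class Sequences per Known/Unknown class (default 5).
#' @return Invisibly, the exported ids.  Fewer than `n_per_class` taxa in a
#'   class triggers a warning; a missing sequence is an error.
#' @export
export_top_hub_sequences <- function(ranking, sequences, path,
                                     n_per_class = 5) {
  if (length(sequences) == 1 && is.character(sequences) &&
      file.exists(sequences)) {
    sequences <- read_fasta(sequences)
  }
  df <- ranking$ranking
  pick <- function(unknown) {
    ids <- df$otu_id[df$unknown == unknown]
    if (length(ids) < n_per_class) {
      warning("only ", length(ids), " ",
              if (unknown) "Unknown" else "Known",
              " taxa available (wanted ", n_per_class, ")")
    }
    utils::head(ids, n_per_class)
  }
  ids <- c(pick(FALSE), pick(TRUE))
  missing <- setdiff(ids, names(sequences))
  if (length(missing)) {
    stop("no sequence for: ", paste(missing, collapse = ", "))
  }
  write_fasta(sequences[ids], path)
  invisible(ids)
}

#' Write a hub ranking to TSV
#'
#' @param ranking A `hub_ranking`.
#' @param path Output path.
#' @export
write_hub_ranking <- function(ranking, path) {
  write_tsv_with_header(ranking$ranking, path,
                        list(rank = ranking$rank, top_n = ranking$top_n))
}
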