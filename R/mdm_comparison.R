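#' Re-infer the network after removing Unknown taxa
#'
#' Drops every OTU flagged Unknown at `rank` from the count table and
#' re-runs full network inference with identical parameters and seed (not a
#' subgraph deletion), so the Without-Unknown network reflects what the
#' community structure looks like when dark-matter taxa never enter the
#' model.
#'
#' @param table A prevalence-filtered `community_table`.
#' @param rank Rank at which Unknown status is read.
#' @param method,... Forwarded to [build_network()].
#' @return A `cooccurrence_network`; if the table has no Unknown OTUs at
#'   `rank` the Original network is returned with attribute
#'   `"no_unknowns"`.
#' @export
without_unknown_network <- function(table, rank = "genus", method = "mb",
                                    ...) {
  u <- unknown_mask(table$taxonomy, rank)
  if (all(u)) stop("every OTU is Unknown at rank ", rank)
  if (!any(u)) {
    net <- build_network(table, method = method, ...)
    attr(net, "no_unknowns") <- TRUE
    return(net)
  }
  build_network(subset_otus(table, which(!u)), method = method, ...)
}

#' Bootstrap null networks
#'
#' Each replicate removes a uniformly random subset of Known OTUs equal in
#' size to the Unknown count at `rank`, then re-infers the network with the
#' same parameters.  Replicate removal draws derive deterministically from
#' `seed`, so the same master seed reproduces the full ensemble.
#'
#' @param table A prevalence-filtered `community_table`.
#' @param rank Rank name.
#' @param method,... Forwarded to [build_network()].
#' @param n_reps Number of replicates (default 100).
#' @param seed Master seed for the removal draws.
#' @return List of `cooccurrence_network`s of length `n_reps`.
#' @export
bootstrap_networks <- function(table, rank = "genus", method = "mb",
                               n_reps = 100, seed = 1, ...) {
  u <- unknown_mask(table$taxonomy, rank)
  n_unknown <- sum(u)
  known_idx <- which(!u)
  if (length(known_idx) < n_unknown) {
    stop("fewer Known than Unknown OTUs at rank ", rank)
  }
  rng <- local_rng(seed)
  lapply(seq_len(n_reps), function(rep) {
    drop <- if (n_unknown > 0) {
      rng(function() sample(known_idx, n_unknown))
    } else integer(0)
    keep <- setdiff(seq_len(nrow(table$counts)), drop)
    build_network(subset_otus(table, keep), method = method, ...)
  })
}

# direction of a significant shift, read from mean ranks in the pooled
# ordering (the quantity the rank-sum test actually compares; medians of
# heavily tied centrality distributions are often equal even under a clear
# stochastic ordering)
rank_shift <- function(a, b) {
  r <- rank(c(a, b))
  mean(r[length(a) + seq_along(b)]) - mean(r[seq_along(a)])
}

holm_direction <- function(shift, holm_p, alpha = 0.05) {
  if (is.na(holm_p) || holm_p >= alpha || is.na(shift) || shift == 0) {
    return("none")
  }
  if (shift < 0) "decrease" else "increase"
}

#' Compare centrality distributions across network types
#'
#' Two-sided Wilcoxon rank-sum tests on node-level centralities for the
#' three contrasts Original vs Without-Unknown, Without-Unknown vs
#' Bootstrap, and Original vs Bootstrap, with Holm adjustment applied
#' across the three contrasts within each metric.  Direction is read from
#' the median difference when the adjusted p falls below `alpha`.
#'
#' @param original,without Centrality tables ([centralities()]) of the
#'   Original and Without-Unknown networks.
#' @param bootstrap_pool Pooled centrality table of all bootstrap
#'   replicates (rows from every replicate stacked).
#' @param metrics Metrics to compare.
#' @param alpha Significance level for the direction call.
#' @return data.frame: `metric`, `contrast`, `n_a`, `n_b`, `raw_p`,
#'   `holm_p`, `median_a`, `median_b`, `direction`.  Contrasts with a group
#'   of fewer than 3 usable values get `NA` p-values.
#' @export
compare_centralities <- function(original, without, bootstrap_pool,
                                 metrics = c("degree", "betweenness",
                                             "closeness"),
                                 alpha = 0.05) {
  groups <- list(original = original, without = without,
                 bootstrap = bootstrap_pool)
  contrasts <- list(c("original", "without"),
                    c("without", "bootstrap"),
                    c("original", "bootstrap"))
  rows <- list()
  for (metric in metrics) {
    vals <- lapply(groups, function(g) {
      v <- g[[metric]]
      v[!is.na(v)]
    })
    res <- lapply(contrasts, function(ct) {
      a <- vals[[ct[1]]]; b <- vals[[ct[2]]]
      p <- if (length(a) < 3 || length(b) < 3) NA_real_ else {
        suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
      }
      # identical distributions give a degenerate statistic; report p = 1
      if (!is.na(p) && is.nan(p)) p <- 1
      list(contrast = paste(ct, collapse = "_vs_"), n_a = length(a),
           n_b = length(b), raw_p = p,
           median_a = stats::median(a), median_b = stats::median(b),
           shift = if (length(a) && length(b)) rank_shift(a, b)
                   else NA_real_)
    })
    raw <- vapply(res, function(x) x$raw_p, numeric(1))
    holm <- stats::p.adjust(raw, method = "holm")
    for (k in seq_along(res)) {
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, contrast = res[[k]]$contrast,
        n_a = res[[k]]$n_a, n_b = res[[k]]$n_b,
        raw_p = raw[k], holm_p = holm[k],
        median_a = res[[k]]$median_a, median_b = res[[k]]$median_b,
        direction = holm_direction(res[[k]]$shift, holm[k], alpha),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the Original / Without-Unknown / Bootstrap comparison
#'
#' The package's core experiment: infer the Original network on the
#' prevalence-filtered table, re-infer after removing all Unknown OTUs at
#' `rank`, build `n_bootstrap` null networks that each remove an equal
#' number of random Known OTUs, compute node centralities for every
#' network, and compare the three distributions per metric with Wilcoxon
#' tests under Holm adjustment.  The inference seed is held fixed across
#' all networks so differences reflect node removal, not subsampling noise.
#'
#' @param table A prevalence-filtered `community_table`.
#' @param rank Rank name.
#' @param method Inference method (see [build_network()]).
#' @param n_bootstrap Number of bootstrap replicates (default 100).
#' @param seed Master seed: drives the bootstrap removal draws and the
#'   (fixed) inference seed.
#' @param metrics Metrics to compare.
#' @param reuse_lambda For `method = "mb"`, refit the Without-Unknown and
#'   Bootstrap networks at the penalty StARS selected for the Original
#'   instead of re-running StARS on each reduced table.  The default
#'   (`FALSE`) re-selects the penalty each time — full re-inference with
#'   identical settings.  `TRUE` gives a controlled variant that holds
#'   the regularization pressure constant, preventing StARS from
#'   compensating for the removal by densifying the refit; see the
#'   methods vignette for the trade-off.
#' @param ... Forwarded to [build_network()].
#' @return `mdm_comparison` list: `comparison` (the test table),
#'   `networks` (original, without), `centralities` (original, without,
#'   bootstrap pool with `replicate` column), `bootstrap_summaries`
#'   (per-replicate medians), `rank`, `seed`.
#' @export
mdm_compare <- function(table, rank = "genus", method = "mb",
                        n_bootstrap = 100, seed = 1,
                        metrics = c("degree", "betweenness", "closeness"),
                        reuse_lambda = FALSE, ...) {
  original_net <- build_network(table, method = method, seed = seed, ...)
  lam <- if (method == "mb" && reuse_lambda) original_net$lambda
  without_net <- without_unknown_network(table, rank, method = method,
                                         seed = seed, lambda = lam, ...)
  boots <- bootstrap_networks(table, rank, method = method,
                              n_reps = n_bootstrap, seed = seed,
                              lambda = lam, ...)
  cent_o <- centralities(original_net)
  cent_w <- centralities(without_net)
  cent_b <- do.call(rbind, lapply(seq_along(boots), function(i) {
    ci <- centralities(boots[[i]])
    ci$replicate <- i
    ci
  }))
  boot_medians <- do.call(rbind, lapply(split(cent_b, cent_b$replicate),
    function(d) {
      data.frame(replicate = d$replicate[1],
                 degree = stats::median(d$degree),
                 betweenness = stats::median(d$betweenness),
                 closeness = stats::median(d$closeness, na.rm = TRUE))
    }))
  comparison <- compare_centralities(cent_o, cent_w, cent_b,
                                     metrics = metrics)
  structure(list(comparison = comparison,
                 networks = list(original = original_net,
                                 without = without_net),
                 centralities = list(original = cent_o, without = cent_w,
                                     bootstrap = cent_b),
                 bootstrap_summaries = boot_medians,
                 rank = rank, seed = seed),
            class = "mdm_comparison")
}

#' @export
print.mdm_comparison <- function(x, ...) {
  cat("<mdm_comparison> rank=", x$rank, "\n", sep = "")
  print(x$comparison[, c("metric", "contrast", "holm_p", "direction")])
  invisible(x)
}

#' Arrow summary of a comparison
#'
#' Collapses the Original vs Without-Unknown contrast per metric into the
#' conventional arrow notation: a significant (Holm-adjusted p < `alpha`)
#' decrease after Unknown removal prints as an up arrow for the Unknowns'
#' contribution ("removing them lowers the metric"), shown here directly as
#' `"down"`/`"up"`/`"ns"` for the Without-Unknown network relative to
#' Original.
#'
#' @param result An `mdm_comparison` (or its `comparison` data.frame).
#' @param alpha Significance level.
#' @return data.frame: `metric`, `arrow`, `holm_p`.
#' @export
comparison_arrows <- function(result, alpha = 0.05) {
  df <- if (inherits(result, "mdm_comparison")) result$comparison else result
  sub <- df[df$contrast == "original_vs_without", ]
  data.frame(metric = sub$metric,
             arrow = vapply(seq_len(nrow(sub)), function(i) {
               switch(sub$direction[i], decrease = "down", up = "up",
                      increase = "up", "ns")
             }, character(1)),
             holm_p = sub$holm_p, stringsAsFactors = FALSE)
}

#' Write comparison results to TSV
#'
#' @param result An `mdm_comparison`.
#' @param path Output path for the long-format table.
#' @param boxplot_path Optional path for per-node metric values (one row
#'   per node per network type), ready for boxplots.
#' @export
write_comparison <- function(result, path, boxplot_path = NULL) {
  df <- cbind(rank = result$rank, result$comparison)
  write_tsv_with_header(df, path, list(seed = result$seed,
                                       rank = result$rank))
  if (!is.null(boxplot_path)) {
    pieces <- lapply(names(result$centralities), function(type) {
      d <- result$centralities[[type]]
      data.frame(network = type, otu_id = d$otu_id, degree = d$degree,
                 betweenness = d$betweenness, closeness = d$closeness,
                 stringsAsFactors = FALSE)
    })
    write_tsv_with_header(do.call(rbind, pieces), boxplot_path,
                          list(seed = result$seed, rank = result$rank))
  }
  invisible(path)
}

#' Prevalence-threshold sensitivity sweep
#'
#' Re-runs the full Original / Without-Unknown / Bootstrap comparison at a
#' range of prevalence fractions (default 15% to 40% in 5% steps) and
#' reports how stable each metric's direction call is across thresholds.
#'
#' @param table An unfiltered `community_table`.
#' @param fractions Prevalence fractions to test.
#' @param rank Rank name.
#' @param min_otus Fractions leaving fewer than this many OTUs are skipped.
#' @param ... Forwarded to [mdm_compare()].
#' @return List with `results` (named list of `mdm_comparison` per
#'   fraction; skipped fractions are `NULL`), `stability` (data.frame:
#'   `metric`, `direction`, `n_fractions`, `n_agree`).
#' @export
threshold_sweep <- function(table, fractions = seq(0.15, 0.40, by = 0.05),
                            rank = "genus", min_otus = 10, ...) {
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]")
  }
  results <- stats::setNames(vector("list", length(fractions)),
                             sprintf("%.0f%%", 100 * fractions))
  for (i in seq_along(fractions)) {
    filt <- filter_by_prevalence(table, min_fraction = fractions[i])
    if (nrow(filt$counts) < min_otus) {
      message("skipping fraction ", fractions[i], ": only ",
              nrow(filt$counts), " OTUs retained")
      next
    }
    results[[i]] <- mdm_compare(filt, rank = rank, ...)
  }
  done <- !vapply(results, is.null, logical(1))
  arrows <- lapply(results[done], comparison_arrows)
  stability <- NULL
  if (length(arrows)) {
    metrics <- unique(arrows[[1]]$metric)
    stability <- do.call(rbind, lapply(metrics, function(m) {
      dirs <- vapply(arrows, function(a) a$arrow[a$metric == m],
                     character(1))
      mode_dir <- names(sort(table(dirs), decreasing = TRUE))[1]
      data.frame(metric = m, direction = mode_dir,
                 n_fractions = length(dirs),
                 n_agree = sum(dirs == mode_dir),
                 stringsAsFactors = FALSE)
    }))
  }
  list(results = results, stability = stability)
}
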