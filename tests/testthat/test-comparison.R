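test_that("Holm adjustment matches the step-down formula", {
  # worked example
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), "holm"),
               c(0.03, 0.04, 0.04))
  # random vectors against the direct formula
  set.seed(17)
  for (i in 1:100) {
    p <- runif(sample(2:8, 1))
    adj <- stats::p.adjust(p, "holm")
    expect_equal(adj, oracle_holm(p), tolerance = 1e-12)
    expect_true(all(adj >= p & adj <= 1))
    # smallest p gets the Bonferroni factor
    expect_equal(adj[which.min(p)],
                 min(1, length(p) * min(p)))
  }
})

test_that("Wilcoxon rank-sum p-values match exhaustive enumeration", {
  set.seed(23)
  for (i in 1:25) {
    m <- sample(3:8, 1)
    n <- sample(3:8, 1)
    vals <- sample(seq_len(100), m + n)  # tie-free
    x <- vals[seq_len(m)]
    y <- vals[m + seq_len(n)]
    expect_equal(stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 oracle_wilcoxon(x, y), tolerance = 1e-10)
  }
})

test_that("compare_centralities handles identical and degenerate groups", {
  mk_cent <- function(vals) {
    data.frame(otu_id = sprintf("o%02d", seq_along(vals)), degree = vals,
               betweenness = vals, closeness = vals,
               stringsAsFactors = FALSE)
  }
  same <- mk_cent(c(1, 2, 3, 4, 5))
  res <- compare_centralities(same, same, same, metrics = "degree")
  expect_true(all(res$raw_p == 1))
  expect_true(all(res$direction == "none"))

  # a group under 3 values: NA p
  res2 <- compare_centralities(same, mk_cent(c(1, 2)), same,
                               metrics = "degree")
  expect_true(is.na(res2$raw_p[res2$contrast == "original_vs_without"]))

  # clear shift is detected with the right direction
  res3 <- compare_centralities(mk_cent(10:20), mk_cent(0:10),
                               mk_cent(10:20), metrics = "degree")
  ow <- res3[res3$contrast == "original_vs_without", ]
  expect_lt(ow$holm_p, 0.05)
  expect_equal(ow$direction, "decrease")
  expect_true(all(res3$holm_p >= res3$raw_p, na.rm = TRUE))
})

test_that("without_unknown_network removes Unknowns and re-infers", {
  # no Unknowns: identical to the original
  tab <- toy_table(p = 8, n = 60, seed = 3)
  net <- without_unknown_network(tab, "genus", method = "pearson",
                                 threshold = 0.5)
  expect_true(isTRUE(attr(net, "no_unknowns")))
  expect_equal(igraph::vcount(net$graph), 8)

  # all-Unknown: error
  tabu <- toy_table(p = 4, n = 30, seed = 4, unknown = 1:4)
  expect_error(without_unknown_network(tabu, "genus"), "every OTU")

  # Unknown rows are absent from the rebuilt network
  tab2 <- toy_table(p = 8, n = 60, seed = 5, unknown = c(2, 5))
  net2 <- without_unknown_network(tab2, "genus", method = "pearson",
                                  threshold = 0.5)
  expect_equal(igraph::vcount(net2$graph), 6)
  expect_false(any(c("OTU_02", "OTU_05") %in%
                     igraph::V(net2$graph)$name))
})

test_that("bootstrap ensembles are deterministic and sized correctly", {
  tab <- toy_table(p = 10, n = 60, seed = 6, unknown = c(1, 4, 7))
  b1 <- bootstrap_networks(tab, "genus", method = "pearson", n_reps = 5,
                           seed = 42, threshold = 0.5)
  b2 <- bootstrap_networks(tab, "genus", method = "pearson", n_reps = 5,
                           seed = 42, threshold = 0.5)
  for (k in 1:5) {
    expect_equal(sort(igraph::V(b1[[k]]$graph)$name),
                 sort(igraph::V(b2[[k]]$graph)$name))
    # replicate node count = total - unknown count
    expect_equal(igraph::vcount(b1[[k]]$graph), 7)
    # unknowns are never removed
    expect_true(all(c("OTU_01", "OTU_04", "OTU_07") %in%
                      igraph::V(b1[[k]]$graph)$name))
  }
  # replicates differ from each other (removal draws vary)
  sets <- vapply(b1, function(n) {
    paste(sort(igraph::V(n$graph)$name), collapse = ",")
  }, character(1))
  expect_gt(length(unique(sets)), 1)

  # zero Unknowns: every replicate equals the original node set
  tab0 <- toy_table(p = 6, n = 40, seed = 7)
  b0 <- bootstrap_networks(tab0, "genus", method = "pearson", n_reps = 3,
                           seed = 1, threshold = 0.5)
  for (n in b0) expect_equal(igraph::vcount(n$graph), 6)

  # more Unknowns than Knowns: error
  tabm <- toy_table(p = 5, n = 40, seed = 8, unknown = 1:3)
  expect_error(bootstrap_networks(tabm, "genus"), "fewer Known")
})

test_that("mdm_compare produces a coherent comparison object", {
  sim <- generate_community(community_spec(n_taxa = 24, n_samples = 100,
                                           depth = 1e4, seed = 9,
                                           unknown_fraction = 0.25))
  filt <- filter_by_prevalence(sim$table, min_fraction = 0.3)
  res <- mdm_compare(filt, rank = "genus", method = "pearson",
                     n_bootstrap = 4, seed = 9, threshold = 0.35)
  expect_s3_class(res, "mdm_comparison")
  expect_equal(nrow(res$comparison), 9)  # 3 metrics x 3 contrasts
  expect_true(all(res$comparison$holm_p >= res$comparison$raw_p,
                  na.rm = TRUE))
  expect_equal(max(res$centralities$bootstrap$replicate), 4)
  # arrows are consistent with the table
  arr <- comparison_arrows(res)
  for (k in seq_len(nrow(arr))) {
    row <- res$comparison[res$comparison$contrast == "original_vs_without" &
                            res$comparison$metric == arr$metric[k], ]
    if (arr$arrow[k] == "ns") {
      expect_true(is.na(row$holm_p) || row$holm_p >= 0.05 ||
                    row$direction == "none")
    } else {
      expect_lt(row$holm_p, 0.05)
    }
  }
  # determinism of the full pipeline under a fixed seed
  res2 <- mdm_compare(filt, rank = "genus", method = "pearson",
                      n_bootstrap = 4, seed = 9, threshold = 0.35)
  expect_equal(res$comparison, res2$comparison)
})

test_that("threshold_sweep runs per fraction and reports stability", {
  sim <- generate_community(community_spec(n_taxa = 20, n_samples = 80,
                                           depth = 1e4, seed = 10,
                                           unknown_fraction = 0.25))
  sw <- threshold_sweep(sim$table, fractions = c(0.2, 0.3),
                        rank = "genus", method = "pearson",
                        n_bootstrap = 2, seed = 10, threshold = 0.35)
  expect_equal(names(sw$results), c("20%", "30%"))
  expect_false(any(vapply(sw$results, is.null, logical(1))))
  expect_equal(sw$stability$n_fractions, rep(2, 3))
  expect_error(threshold_sweep(sim$table, fractions = c(0, 0.5)),
               "fractions")

  # a fraction leaving too few OTUs is skipped with a note
  expect_message(
    sw2 <- threshold_sweep(sim$table, fractions = c(0.99, 0.3),
                           rank = "genus", method = "pearson",
                           n_bootstrap = 2, seed = 10, threshold = 0.35),
    "skipping")
  expect_null(sw2$results[["99%"]])
})
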