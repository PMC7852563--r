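mk_genes <- function(starts, ends, strands, products = NULL,
                     scaffold = "scf") {
  n <- length(starts)
  if (is.null(products)) products <- rep("protein", n)
  data.frame(scaffold_id = scaffold,
             gene_id = sprintf("g%03d", seq_len(n)),
             start = as.integer(starts), end = as.integer(ends),
             strand = strands, product = products,
             stringsAsFactors = FALSE)
}

test_that("BLAST tabular parsing handles both dialects and orientation", {
  path <- withr::local_tempfile(fileext = ".txt")
  lines <- c(
    paste("q1", "scf1", "97.5", "1510", "38", "0", "1", "1510", "100",
          "1609", "0.0", "2700", sep = "\t"),
    paste("q1", "scf2", "99.0", "1400", "14", "0", "1510", "111", "5",
          "1404", "0.0", "2500", sep = "\t"))
  writeLines(lines, path)
  hits <- parse_blast_tabular(path, query_lengths = c(q1 = 1510))
  expect_equal(hits$query_coverage[1], 100)
  # minus-strand hit: same absolute span
  expect_equal(hits$query_coverage[2], 100 * 1400 / 1510)

  # 13-column dialect: verbatim coverage
  writeLines(paste(lines[1], "93.7", sep = "\t"), path)
  expect_equal(parse_blast_tabular(path)$query_coverage, 93.7)

  # malformed line reports the line number
  writeLines(c(lines[1], "q1\tscf1\tbroken"), path)
  expect_error(parse_blast_tabular(path, c(q1 = 1510)), "line 2")
  writeLines(lines[1], path)
  expect_error(parse_blast_tabular(path), "query_lengths")
})

test_that("hit filtering is inclusive at 95/95", {
  hits <- data.frame(percent_identity = c(97, 94.9, 95, 99),
                     query_coverage = c(98, 99, 95, 94.99))
  kept <- filter_hits(hits)
  expect_equal(which(hits$percent_identity %in%
                       kept$percent_identity &
                       hits$query_coverage %in% kept$query_coverage),
               c(1, 3))
})

test_that("scaffold filtering is inclusive at 50 genes", {
  g98 <- mk_genes(seq(1, by = 2000, length.out = 98),
                  seq(1000, by = 2000, length.out = 98),
                  rep("+", 98), scaffold = "big")
  g50 <- mk_genes(seq(1, by = 2000, length.out = 50),
                  seq(1000, by = 2000, length.out = 50),
                  rep("+", 50), scaffold = "edge")
  g49 <- mk_genes(seq(1, by = 2000, length.out = 49),
                  seq(1000, by = 2000, length.out = 49),
                  rep("+", 49), scaffold = "small")
  all_genes <- rbind(g98, g50, g49)
  kept <- filter_scaffolds(all_genes)
  expect_setequal(unique(kept$scaffold_id), c("big", "edge"))
})

test_that("gene flagging matches substrings case-insensitively", {
  genes <- mk_genes(c(1, 2000, 4000), c(1000, 3000, 5000), rep("+", 3),
                    products = c("hypothetical protein", "rubrerythrin",
                                 "Ferritin-Like Protein"))
  flagged <- flag_genes(genes, adaptation_terms = c("rubrerythrin",
                                                    "ferritin"))
  expect_equal(flagged$hypothetical, c(TRUE, FALSE, FALSE))
  expect_equal(flagged$adaptation, c(FALSE, TRUE, TRUE))
  summ <- attr(flagged, "scaffold_summary")
  expect_equal(summ$n_adaptation, 2)
  expect_error(flag_genes(genes, character(0)), "empty")
})

test_that("operon clustering respects the gap rule and strands", {
  # gap 4999 joins, 5001 splits
  g <- mk_genes(c(1, 6000), c(1000, 7000), c("+", "+"))
  expect_equal(g$start[2] - g$end[1] - 1, 4999)
  cl <- cluster_operons(g)
  expect_equal(length(unique(cl$operon_id)), 1)

  g2 <- mk_genes(c(1, 6002), c(1000, 7000), c("+", "+"))
  expect_equal(g2$start[2] - g2$end[1] - 1, 5001)
  expect_equal(length(unique(cluster_operons(g2)$operon_id)), 2)

  # adjacent genes on opposite strands never merge
  g3 <- mk_genes(c(1, 1100), c(1000, 2000), c("+", "-"))
  expect_equal(length(unique(cluster_operons(g3)$operon_id)), 2)

  # overlapping same-strand genes: clipped to gap 0, one operon, warning
  g4 <- mk_genes(c(1, 500), c(1000, 1500), c("+", "+"))
  expect_warning(cl4 <- cluster_operons(g4), "overlap")
  expect_equal(length(unique(cl4$operon_id)), 1)
})

test_that("adaptation calling honors the neighbor window cap", {
  # hypothetical gene at one end, adaptation gene 11 genes away within one
  # operon: not flagged at window 10, flagged at window 11
  n <- 12
  g <- mk_genes(seq(1, by = 450, length.out = n),
                seq(400, by = 450, length.out = n),
                rep("+", n),
                products = c("hypothetical protein", rep("x protein", 10),
                             "rubrerythrin"))
  cl <- cluster_operons(g)
  expect_equal(length(unique(cl$operon_id)), 1)
  fl <- flag_genes(cl, "rubrerythrin")
  expect_false(call_putative_adaptation_operons(
    fl, window_genes = 10)$is_putative_adaptation)
  expect_true(call_putative_adaptation_operons(
    fl, window_genes = 11)$is_putative_adaptation)

  # operon of only hypothetical genes is never flagged
  g2 <- mk_genes(c(1, 1200), c(1000, 2200), c("+", "+"),
                 products = rep("hypothetical protein", 2))
  fl2 <- flag_genes(cluster_operons(g2), "rubrerythrin")
  expect_false(call_putative_adaptation_operons(fl2)$is_putative_adaptation)

  # the motif of a hypothetical flanked by oxidative-stress genes fires
  g3 <- mk_genes(c(1, 1200, 2400, 3600), c(1000, 2200, 3400, 4600),
                 rep("+", 4),
                 products = c("hypothetical protein", "Fe-S oxidoreductase",
                              "rubrerythrin",
                              "DNA-binding ferritin-like protein"))
  fl3 <- flag_genes(cluster_operons(g3),
                    c("rubrerythrin", "ferritin", "oxidoreductase"))
  expect_true(call_putative_adaptation_operons(fl3)$is_putative_adaptation)
})

test_that("clustering and adaptation calls match brute-force oracles on
          random scaffolds", {
  for (seed in 1:60) {
    genes <- random_gene_table(sample(3:40, 1), seed = seed)
    cl <- suppressWarnings(cluster_operons(genes))
    oracle <- oracle_cluster_operons(genes)
    # same partition: compare memberships gene-by-gene after aligning ids
    got <- stats::setNames(cl$operon_id, cl$gene_id)
    expect_equal(unname(got[genes$gene_id]), oracle)

    flags <- call_putative_adaptation_operons(cl, window_genes = 5,
                                              max_gap = 5000)
    want <- oracle_adaptation_flags(genes, oracle, window_genes = 5)
    expect_equal(stats::setNames(flags$is_putative_adaptation,
                                 flags$operon_id)[names(want)],
                 want)
    # memberships partition the gene set
    expect_setequal(cl$gene_id, genes$gene_id)
  }
})

test_that("operon counts are monotone in the gap and window parameters", {
  genes <- random_gene_table(30, seed = 99)
  n_ops <- vapply(c(1000, 3000, 5000, 8000), function(gap) {
    length(unique(suppressWarnings(
      cluster_operons(genes, max_gap = gap))$operon_id))
  }, numeric(1))
  expect_true(all(diff(n_ops) <= 0))

  cl <- suppressWarnings(cluster_operons(genes))
  n_flagged <- vapply(c(1, 3, 6, 12), function(w) {
    sum(call_putative_adaptation_operons(cl, window_genes = w)$
          is_putative_adaptation)
  }, numeric(1))
  expect_true(all(diff(n_flagged) >= 0))
})

test_that("mine_operons runs the full chain on a multi-scaffold table", {
  sc1 <- generate_scaffold(scaffold_spec("scfA", n_genes = 60, seed = 1))
  sc2 <- generate_scaffold(scaffold_spec("scfB", n_genes = 40, seed = 2))
  genes <- rbind(sc1$genes, sc2$genes)
  res <- mine_operons(genes, read_keywords(
    system.file("extdata", "adaptation_keywords.txt", package = "mdmnet")))
  # scfB (40 genes) is dropped by the 50-gene filter
  expect_equal(unique(res$operons$scaffold_id), "scfA")
  expect_true(all(res$operons$n_genes >= 1))
  # flagged operons always contain both gene classes
  flagged <- res$operons[res$operons$is_putative_adaptation, ]
  expect_true(all(flagged$n_hypothetical >= 1 & flagged$n_adaptation >= 1))
})
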