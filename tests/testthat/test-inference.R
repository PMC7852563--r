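test_that("CLR transform centers every sample and handles pseudocounts", {
  tab <- toy_table(p = 4, n = 6)
  clr <- clr_transform(tab)
  expect_true(all(abs(rowSums(clr)) < 1e-9 * 4))

  # constant sample row maps to zero
  counts <- matrix(1, 4, 1, dimnames = list(paste0("o", 1:4), "s1"))
  tabc <- community_table(counts, stats::setNames(rep("B", 4),
                                                  rownames(counts)))
  expect_equal(unname(unclass(clr_transform(tabc, 5))[1, ]), rep(0, 4))

  # hand-computed: (1,2,4) at pseudocount 0 -> (-ln2, 0, ln2)
  counts2 <- matrix(c(1, 2, 4), 3, 1,
                    dimnames = list(paste0("o", 1:3), "s1"))
  tab2 <- community_table(counts2, stats::setNames(rep("B", 3),
                                                   rownames(counts2)))
  expect_equal(unname(unclass(clr_transform(tab2, 0))[1, ]),
               c(-log(2), 0, log(2)))

  # CLR at pseudocount 0 is invariant to per-sample count rescaling
  tab3 <- toy_table(p = 5, n = 4, seed = 2)
  tab3$counts <- tab3$counts + 1  # strictly positive
  scaled <- tab3
  scaled$counts <- tab3$counts * 3L
  expect_equal(unclass(clr_transform(tab3, 0)),
               unclass(clr_transform(scaled, 0)), tolerance = 1e-12)

  # zero counts with nonpositive pseudocount is an error
  withz <- toy_table(p = 3, n = 20, seed = 3)
  withz$counts[1, 1] <- 0L
  expect_error(clr_transform(withz, 0), "pseudocount")
})

test_that("mb_neighborhoods matches the lasso closed form", {
  # full shrinkage: lam >= max |cor| gives empty neighborhoods
  set.seed(21)
  x <- matrix(rnorm(200 * 5), 200, 5)
  colnames(x) <- paste0("v", 1:5)
  lam_max <- max(abs(cor(x)[upper.tri(diag(5))]))
  nb <- mb_neighborhoods(x, lam_max + 0.01)
  expect_true(all(lengths(nb) == 0))

  # perfectly coupled pair + independent column at small lam
  z <- rnorm(300)
  xx <- cbind(a = z, b = z + rnorm(300, sd = 1e-3), c = rnorm(300))
  nb2 <- mb_neighborhoods(xx, 0.3)
  expect_equal(nb2$a, "b")
  expect_equal(nb2$b, "a")
  expect_equal(length(nb2$c), 0L)

  # orthogonal design: support given by soft thresholding, nested in lam
  set.seed(33)
  q <- qr.Q(qr(matrix(rnorm(100 * 4), 100, 4))) * sqrt(100)
  beta <- c(0.8, 0.4, 0.1)
  y <- q[, 1:3] %*% beta
  xs <- q[, 1:3]
  colnames(xs) <- paste0("p", 1:3)
  for (lam in c(0.9, 0.6, 0.3, 0.05)) {
    dat <- cbind(xs, y = as.vector(scale(y) / sqrt(99 / 100)))
    supp <- mdmnet:::lasso_path_support(
      mdmnet:::standardize_cols(dat[, 1:3]),
      mdmnet:::standardize_cols(dat)[, 4], lam)
    # soft-threshold closed form on the standardized response
    cors <- cor(dat[, 1:3], dat[, 4])
    expect_equal(unname(supp[, 1]), unname(abs(cors[, 1]) > lam + 1e-8),
                 label = paste("lam", lam))
  }

  expect_error(mb_neighborhoods(matrix(c(1, NA, 2, 3), 2, 2), 0.1),
               "non-finite")
})

test_that("symmetrize applies or/and rules", {
  nb <- list(a = "b", b = character(0), c = character(0))
  expect_equal(symmetrize(nb, "or"), cbind("a", "b"))
  expect_equal(nrow(symmetrize(nb, "and")), 0)

  # symmetric neighborhoods agree under both rules; and-edges are a subset
  set.seed(12)
  ids <- paste0("n", 1:8)
  nb2 <- lapply(stats::setNames(ids, ids), function(i) {
    sample(setdiff(ids, i), sample(0:3, 1))
  })
  or_edges <- apply(symmetrize(nb2, "or"), 1, paste, collapse = "|")
  and_edges <- apply(symmetrize(nb2, "and"), 1, paste, collapse = "|")
  expect_true(all(and_edges %in% or_edges))
})

test_that("StARS selects stable graphs and reports its instability path", {
  # degenerate variability: identical samples give zero instability and
  # the densest penalty
  counts <- matrix(rep(c(5L, 9L, 2L, 7L, 4L, 8L), 40), 6, 40,
                   dimnames = list(paste0("o", 1:6), paste0("s", 1:40)))
  tabd <- community_table(counts, stats::setNames(rep("B", 6),
                                                  rownames(counts)))
  path <- c(0.5, 0.25, 0.1)
  net <- suppressWarnings(
    stars_select(tabd, stars_config(lambda_path = path, seed = 1)))
  expect_equal(net$stars$instability, rep(0, 3))
  expect_equal(net$lambda, 0.1)

  # independent noise: selected networks stay near-empty across seeds
  for (s in 1:3) {
    set.seed(s + 100)
    counts <- matrix(rpois(10 * 150, exp(rnorm(10 * 150, log(30), 0.5))),
                     10, 150,
                     dimnames = list(paste0("o", 1:10), paste0("s", 1:150)))
    tabn <- community_table(counts, stats::setNames(rep("B", 10),
                                                    rownames(counts)))
    # pure-noise data can legitimately fail the instability bound at
    # every penalty; either way the selected graph must stay near-empty
    netn <- suppressWarnings(build_network(tabn, method = "mb", seed = s))
    expect_lte(igraph::ecount(netn$graph), 3)
  }

  # instability bounds and monotonized curve
  expect_true(all(net$stars$instability >= 0 &
                    net$stars$instability <= 0.5))
  sim <- generate_community(community_spec(n_taxa = 20, n_samples = 100,
                                           depth = 1e4, seed = 2))
  net2 <- build_network(filter_by_prevalence(sim$table, min_fraction = 0.3),
                        method = "mb", seed = 2)
  d <- net2$stars$monotone_instability
  expect_true(all(diff(d) >= 0))  # nondecreasing toward denser penalties
  expect_lte(net2$stars$monotone_instability[net2$stars$selected_index],
             0.05)
})

test_that("StARS recovers a planted hub graph", {
  f1s <- numeric(3)
  for (s in 1:3) {
    sim <- generate_community(community_spec(n_taxa = 40, n_samples = 200,
                                             depth = 2e4, seed = s))
    filt <- filter_by_prevalence(sim$table, min_fraction = 0.3)
    net <- build_network(filt, method = "mb", seed = s)
    f1s[s] <- edge_f1(net, sim$truth$edges)$f1
  }
  expect_gt(mean(f1s), 0.5)
})

test_that("sparcc output is a proper correlation estimate", {
  # symmetry / unit diagonal / clipping
  sim <- generate_community(community_spec(n_taxa = 20, n_samples = 150,
                                           depth = 1e4, seed = 4,
                                           topology = "random"))
  r <- sparcc(sim$table, n_iterations = 5, seed = 1)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 20))
  expect_true(all(abs(r) <= 1))

  # independent components: off-diagonal correlations stay small
  set.seed(8)
  counts <- matrix(rpois(20 * 400, exp(rnorm(20 * 400, log(200), 1))),
                   20, 400,
                   dimnames = list(paste0("o", 1:20), paste0("s", 1:400)))
  tabi <- community_table(counts, stats::setNames(rep("B", 20),
                                                  rownames(counts)))
  ri <- sparcc(tabi, n_iterations = 5, seed = 2)
  expect_lt(max(abs(ri[upper.tri(ri)])), 0.25)

  # a planted co-varying pair attains the largest |r|
  set.seed(9)
  base <- exp(rnorm(400, log(200), 1))
  counts2 <- rbind(o1 = rpois(400, base), o2 = rpois(400, base * 2),
                   matrix(rpois(8 * 400, exp(rnorm(8 * 400, log(200), 1))),
                          8, 400, dimnames = list(paste0("o", 3:10), NULL)))
  colnames(counts2) <- paste0("s", 1:400)
  tabp <- community_table(counts2, stats::setNames(rep("B", 10),
                                                   rownames(counts2)))
  rp <- sparcc(tabp, n_iterations = 5, seed = 3)
  off <- abs(rp)
  diag(off) <- 0
  expect_equal(sort(unname(which(off == max(off), arr.ind = TRUE)[1, ])),
               c(1, 2))
  expect_error(sparcc(toy_table(p = 3)), "at least 4")
})

test_that("correlation networks equal brute-force thresholding", {
  r <- matrix(c(1, 0.45, -0.2, 0.05, 0.31,
                0.45, 1, 0.6, -0.33, 0.1,
                -0.2, 0.6, 1, 0.25, -0.4,
                0.05, -0.33, 0.25, 1, 0.02,
                0.31, 0.1, -0.4, 0.02, 1), 5, 5,
              dimnames = list(paste0("t", 1:5), paste0("t", 1:5)))
  net <- correlation_network(r, threshold = 0.3)
  got <- apply(igraph::as_edgelist(net$graph), 1, paste, collapse = "|")
  want <- character(0)
  for (i in 1:4) for (j in (i + 1):5) {
    if (abs(r[i, j]) >= 0.3) {
      want <- c(want, paste(paste0("t", i), paste0("t", j), sep = "|"))
    }
  }
  expect_setequal(got, want)

  # threshold 1 on |r|<1 off-diagonals: empty; threshold 0: complete
  expect_equal(igraph::ecount(correlation_network(r, 1)$graph), 0)
  expect_equal(igraph::ecount(correlation_network(r, 0)$graph), 10)
  expect_error(correlation_network(matrix(c(1, 0.2, 0.3, 1), 2, 2)),
               "symmetric")

  # p-value gating
  p <- matrix(1, 5, 5)
  p[1, 2] <- p[2, 1] <- 0.001
  netp <- correlation_network(r, threshold = 0.3, pvalues = p)
  expect_equal(igraph::ecount(netp$graph), 1)
})

test_that("build_network dispatches and accounts selected vs connected
          nodes", {
  sim <- generate_community(community_spec(n_taxa = 20, n_samples = 100,
                                           depth = 1e4, seed = 6))
  filt <- filter_by_prevalence(sim$table, min_fraction = 0.3)
  net_mb <- build_network(filt, method = "mb", seed = 6)
  direct <- stars_select(filt, stars_config(seed = 6))
  expect_equal(igraph::as_edgelist(net_mb$graph),
               igraph::as_edgelist(direct$graph))

  summ <- network_summary(net_mb)
  expect_lte(summ$connected, summ$selected)
  expect_equal(summ$edge_node_ratio, summ$edges / summ$connected)
  expect_error(build_network(filt, method = "nope"))

  netp <- build_network(filt, method = "pearson", threshold = 0.3)
  expect_equal(netp$method, "pearson")
  expect_gt(igraph::ecount(netp$graph), 0)
  expect_true(all(abs(igraph::E(netp$graph)$weight) >= 0.3))
})
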