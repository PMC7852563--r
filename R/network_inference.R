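#' Centered log-ratio transform of a count table
#'
#' Maps each sample's counts to `log(x + pseudocount)` centered by the
#' sample's mean log value, removing the compositional closure that makes
#' naive correlations on relative abundances spurious.  Every output row
#' (sample) sums to zero.
#'
#' @param table A `community_table`.
#' @param pseudocount Positive value added to every count before the log
#'   (default 1, appropriate for integer counts).  A pseudocount of 0 is
#'   allowed only when the table has no zeros.
#' @return `clr_matrix`: numeric matrix, samples in rows and OTUs in
#'   columns, with attribute `"pseudocount"`.
#' @export
clr_transform <- function(table, pseudocount = 1) {
  x <- t(table$counts)  # samples x OTUs
  if (pseudocount <= 0 && any(x == 0)) {
    stop("nonpositive pseudocount with zero counts present")
  }
  lx <- log(x + pseudocount)
  out <- lx - rowMeans(lx)
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("clr_matrix", class(out))
  out
}

# columns to zero mean and unit variance, variance with denominator n so
# that the lasso KKT threshold for an all-zero solution equals the maximum
# absolute correlation; constant columns become all-zero
standardize_cols <- function(x) {
  x <- sweep(x, 2, colMeans(x))
  s <- sqrt(colMeans(x^2))
  s[s == 0] <- 1
  sweep(x, 2, s, "/")
}

# lasso support of y ~ X at a decreasing penalty path; returns a logical
# matrix (ncol(X) x length(path)).  Uses coordinate descent via glmnet; the
# single-predictor case is solved by the soft-threshold closed form.
lasso_path_support <- function(x, y, path) {
  p <- ncol(x)
  if (stats::sd(y) == 0) return(matrix(FALSE, p, length(path)))
  if (p == 1L) {
    c1 <- mean(x[, 1] * y)
    return(matrix(abs(c1) > path, nrow = 1))
  }
  fit <- glmnet::glmnet(x, y, family = "gaussian", lambda = path,
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-8)
  beta <- as.matrix(fit$beta)
  supp <- beta != 0
  # glmnet can drop trailing path values on early saturation; pad
  if (ncol(supp) < length(path)) {
    supp <- cbind(supp, matrix(supp[, ncol(supp)], p,
                               length(path) - ncol(supp)))
  }
  supp
}

#' Meinshausen-Buhlmann neighborhood selection at a fixed penalty
#'
#' Estimates the conditional-dependence neighborhood of each OTU by an
#' L1-penalized least-squares regression of its (standardized) CLR column
#' on all other columns.  The support of each regression is that OTU's
#' neighborhood.
#'
#' @param clr A `clr_matrix` (samples x OTUs) or any numeric matrix.
#' @param lam Positive penalty.  At `lam >=` the maximum absolute empirical
#'   correlation all neighborhoods are empty.
#' @return Named list of character vectors: the neighbors of each OTU.
#' @export
mb_neighborhoods <- function(clr, lam) {
  x <- unclass(clr)
  if (any(!is.finite(x))) stop("non-finite values in CLR matrix")
  n <- nrow(x); p <- ncol(x)
  if (n < 2 || p < 2) stop("need at least 2 samples and 2 OTUs")
  ids <- colnames(x)
  if (is.null(ids)) ids <- paste0("V", seq_len(p))
  xs <- standardize_cols(x)
  out <- lapply(seq_len(p), function(j) {
    supp <- lasso_path_support(xs[, -j, drop = FALSE], xs[, j], lam)
    ids[-j][supp[, 1]]
  })
  names(out) <- ids
  out
}

#' Symmetrize directed neighborhoods into an undirected edge set
#'
#' @param neighborhoods Named list as returned by [mb_neighborhoods()].
#' @param rule `"or"` (edge if either node selects the other; default) or
#'   `"and"` (both must select each other).
#' @return Two-column character matrix of edges (each once, `i < j` by
#'   position in the node list).
#' @export
symmetrize <- function(neighborhoods, rule = c("or", "and")) {
  rule <- match.arg(rule)
  ids <- names(neighborhoods)
  idx <- stats::setNames(seq_along(ids), ids)
  pairs <- matrix(FALSE, length(ids), length(ids))
  for (j in seq_along(ids)) {
    ks <- idx[neighborhoods[[j]]]
    pairs[j, ks] <- TRUE
  }
  adj <- if (rule == "or") pairs | t(pairs) else pairs & t(pairs)
  which_up <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  cbind(ids[which_up[, 1]], ids[which_up[, 2]])
}

#' StARS configuration
#'
#' @param lambda_path Strictly decreasing positive penalties; `NULL` (the
#'   default) builds a 30-value log-spaced path from the maximum absolute
#'   off-diagonal correlation of the standardized CLR data down to 1% of it.
#' @param beta Instability threshold (default 0.05).
#' @param n_subsamples Number of random subsamples (default 20).
#' @param subsample_size Rows per subsample; default
#'   `min(floor(10 * sqrt(n)), floor(0.8 * n))`.
#' @param n_lambda Path length when `lambda_path` is `NULL`.
#' @param lambda_min_ratio Smallest path value as a fraction of the largest.
#' @param seed Integer seed for the subsample draws.
#' @return `stars_config` list.
#' @export
stars_config <- function(lambda_path = NULL, beta = 0.05, n_subsamples = 20,
                         subsample_size = NULL, n_lambda = 30,
                         lambda_min_ratio = 0.01, seed = 1) {
  if (!is.null(lambda_path)) {
    if (any(diff(lambda_path) >= 0) || any(lambda_path <= 0)) {
      stop("lambda_path must be strictly decreasing and positive")
    }
  }
  if (beta <= 0 || beta >= 0.5) stop("beta must be in (0, 0.5)")
  structure(list(lambda_path = lambda_path, beta = beta,
                 n_subsamples = n_subsamples,
                 subsample_size = subsample_size, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio, seed = seed),
            class = "stars_config")
}

default_lambda_path <- function(xs, n_lambda, min_ratio) {
  r <- stats::cor(xs)
  lam_max <- max(abs(r[upper.tri(r)]))
  if (!is.finite(lam_max) || lam_max <= 0) lam_max <- 1
  exp(seq(log(lam_max), log(lam_max * min_ratio), length.out = n_lambda))
}

# symmetrized ("or") edge indicators over the upper triangle for every
# penalty in the path; returns logical matrix (n_pairs x n_lambda)
mb_edge_indicators <- function(xs, path, rule = "or") {
  p <- ncol(xs)
  nl <- length(path)
  sel <- matrix(FALSE, p * p, nl)  # directed: row (j-1)*p + k means j -> k
  for (j in seq_len(p)) {
    supp <- lasso_path_support(xs[, -j, drop = FALSE], xs[, j], path)
    rows <- (j - 1L) * p + seq_len(p)[-j]
    sel[rows, ] <- supp
  }
  up <- which(upper.tri(matrix(0, p, p)))
  i <- ((up - 1L) %% p) + 1L
  j <- ((up - 1L) %/% p) + 1L
  fwd <- sel[(i - 1L) * p + j, , drop = FALSE]  # i selects j
  bwd <- sel[(j - 1L) * p + i, , drop = FALSE]  # j selects i
  if (rule == "or") fwd | bwd else fwd & bwd
}

#' Infer an MB network with StARS model selection
#'
#' Runs Meinshausen-Buhlmann neighborhood selection over a penalty path on
#' repeated random subsamples of the samples, measures per-edge selection
#' instability, and refits on the full data at the least-penalized value
#' whose monotonized total instability stays at or below `beta`.
#'
#' For each penalty the edge-presence frequency `theta` over subsamples
#' gives a per-pair instability `2 * theta * (1 - theta)`; the total
#' instability is its mean over all node pairs, monotonized from the sparse
#' end of the path.
#'
#' @param table A prevalence-filtered `community_table`.
#' @param cfg A [stars_config()].
#' @param pseudocount CLR pseudocount.
#' @param rule Symmetrization rule, `"or"` (default) or `"and"`.
#' @return A `cooccurrence_network` with method `"mb"`; its `stars` element
#'   carries the path, raw and monotonized instabilities, and a
#'   `no_lambda_met_beta` flag set when even the sparsest penalty exceeds
#'   `beta` (the sparsest penalty is then used).
#' @export
stars_select <- function(table, cfg = stars_config(), pseudocount = 1,
                         rule = c("or", "and")) {
  rule <- match.arg(rule)
  clr <- clr_transform(table, pseudocount)
  x <- unclass(clr)
  n <- nrow(x); p <- ncol(x)
  if (p < 2) stop("need at least 2 OTUs after filtering")
  xs_full <- standardize_cols(x)
  path <- cfg$lambda_path
  if (is.null(path)) {
    path <- default_lambda_path(xs_full, cfg$n_lambda, cfg$lambda_min_ratio)
  }
  b <- cfg$subsample_size
  if (is.null(b)) b <- min(floor(10 * sqrt(n)), floor(0.8 * n))
  if (b >= n) b <- n - 1L
  if (b < 2) stop("subsample size too small")

  n_pairs <- p * (p - 1L) / 2L
  freq <- matrix(0, n_pairs, length(path))
  rng <- local_rng(cfg$seed)
  for (s in seq_len(cfg$n_subsamples)) {
    rows <- rng(function() sample.int(n, b))
    xs <- standardize_cols(x[rows, , drop = FALSE])
    freq <- freq + mb_edge_indicators(xs, path, rule)
  }
  theta <- freq / cfg$n_subsamples
  xi <- 2 * theta * (1 - theta)
  instability <- colMeans(xi)
  monotone <- cummax(instability)  # path is decreasing: sparse -> dense
  ok <- which(monotone <= cfg$beta)
  flag <- length(ok) == 0L
  sel_idx <- if (flag) 1L else max(ok)
  if (flag) {
    warning("no penalty met the instability bound; using the sparsest")
  }
  lam <- path[sel_idx]

  nb <- mb_neighborhoods(clr, lam)
  edges <- symmetrize(nb, rule)
  net <- new_network(edges, table, method = "mb",
                     provenance = list(method = "mb", lambda = lam,
                                       beta = cfg$beta,
                                       n_subsamples = cfg$n_subsamples,
                                       subsample_size = b, seed = cfg$seed,
                                       pseudocount = pseudocount,
                                       rule = rule))
  net$lambda <- lam
  net$stars <- list(lambda_path = path, instability = instability,
                    monotone_instability = monotone,
                    selected_index = sel_idx,
                    selected_instability = monotone[sel_idx],
                    no_lambda_met_beta = flag)
  net
}

#' SparCC correlation estimate
#'
#' Classic SparCC: per-sample taxon fractions are drawn from a Dirichlet
#' posterior of the counts, the log-ratio variation matrix
#' `t_ij = var(log(x_i / x_j))` is formed, basis variances are solved from
#' the sparsity-approximated linear system, and basis correlations follow
#' as `(w_i + w_j - t_ij) / (2 sqrt(w_i w_j))`.  The most strongly
#' correlated pair above `exclusion_threshold` is iteratively excluded and
#' the system re-solved; the final estimate averages over `n_iterations`
#' Dirichlet draws.
#'
#' @param table A `community_table` with at least 4 OTUs.
#' @param n_iterations Number of Dirichlet fraction draws averaged.
#' @param exclusion_threshold Absolute-correlation level above which the
#'   strongest pair is excluded from the basis-variance system.
#' @param exclusion_rounds Maximum exclusion iterations per draw.
#' @param seed Integer seed.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
sparcc <- function(table, n_iterations = 20, exclusion_threshold = 0.1,
                   exclusion_rounds = 10, seed = 1) {
  counts <- table$counts  # OTUs x samples
  p <- nrow(counts)
  if (p < 4) stop("SparCC needs at least 4 OTUs")
  rng <- local_rng(seed)
  acc <- matrix(0, p, p)
  for (it in seq_len(n_iterations)) {
    frac <- rng(function() {
      apply(counts + 1, 2, function(a) {
        g <- stats::rgamma(length(a), shape = a, rate = 1)
        g / sum(g)
      })
    })  # OTUs x samples
    acc <- acc + sparcc_once(log(frac), exclusion_threshold,
                             exclusion_rounds)
  }
  r <- acc / n_iterations
  r <- (r + t(r)) / 2
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- 1
  dimnames(r) <- list(rownames(counts), rownames(counts))
  r
}

sparcc_once <- function(logf, exclusion_threshold, exclusion_rounds) {
  p <- nrow(logf)
  tv <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    d <- logf[(i + 1):p, , drop = FALSE] -
      matrix(logf[i, ], p - i, ncol(logf), byrow = TRUE)
    v <- apply(d, 1, stats::var)
    tv[i, (i + 1):p] <- v
    tv[(i + 1):p, i] <- v
  }
  m <- matrix(1, p, p)
  diag(m) <- p - 1
  tw <- tv
  for (round in seq_len(exclusion_rounds + 1L)) {
    w <- solve(m, rowSums(tw))
    if (any(w <= 0)) {
      warning("negative basis variance clipped")
      w[w <= 0] <- .Machine$double.eps
    }
    rho <- (outer(w, w, "+") - tv) / (2 * sqrt(outer(w, w, "*")))
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    if (round > exclusion_rounds) break
    cand <- abs(rho)
    cand[lower.tri(cand, diag = TRUE)] <- 0
    cand[m == 0] <- 0  # already excluded
    mx <- max(cand)
    if (mx <= exclusion_threshold) break
    ij <- which(cand == mx, arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    m[i, j] <- m[j, i] <- 0
    m[i, i] <- m[i, i] - 1
    m[j, j] <- m[j, j] - 1
    tw[i, j] <- tw[j, i] <- 0
    if (m[i, i] < 2 || m[j, j] < 2) break  # system degenerating
  }
  rho
}

#' Pearson correlations (with t-test p-values) on CLR data
#'
#' @param table A `community_table`.
#' @param pseudocount CLR pseudocount.
#' @return List with `r` (correlation matrix), `p` (two-sided p-values) and
#'   `n` (sample count).
#' @export
pearson_correlation <- function(table, pseudocount = 1) {
  x <- unclass(clr_transform(table, pseudocount))
  r <- stats::cor(x)
  n <- nrow(x)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  list(r = r, p = p, n = n)
}

#' Threshold a correlation matrix into a network
#'
#' @param corr Symmetric correlation matrix with unit diagonal; row/column
#'   names are the node ids.
#' @param threshold Absolute-correlation cutoff (inclusive).  The cutoff
#'   the original analyses used is not recoverable, so the default 0.3 is a
#'   documented convention, not a reproduction.
#' @param pvalues Optional matrix of p-values; edges additionally require
#'   `p <= alpha`.
#' @param alpha Significance level for `pvalues`.
#' @param table Optional `community_table` supplying node taxonomy.
#' @param method Method tag recorded on the network.
#' @return A `cooccurrence_network` with signed correlation edge weights.
#' @export
correlation_network <- function(corr, threshold = 0.3, pvalues = NULL,
                                alpha = 0.05, table = NULL,
                                method = "pearson") {
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-8))) {
    stop("correlation matrix must be symmetric")
  }
  keep <- abs(corr) >= threshold
  if (!is.null(pvalues)) keep <- keep & (pvalues <= alpha)
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  ids <- rownames(corr)
  if (is.null(ids)) ids <- paste0("V", seq_len(nrow(corr)))
  edges <- cbind(ids[idx[, 1]], ids[idx[, 2]])
  net <- new_network(edges, table, method = method, node_ids = ids,
                     provenance = list(method = method,
                                       threshold = threshold,
                                       alpha = if (is.null(pvalues)) NA
                                               else alpha))
  if (nrow(idx)) {
    igraph::E(net$graph)$weight <- corr[idx]
  }
  net$threshold <- threshold
  net
}

# assemble a cooccurrence_network from an edge matrix plus node metadata
new_network <- function(edges, table = NULL, method, provenance = list(),
                        node_ids = NULL) {
  if (is.null(node_ids)) node_ids <- otu_ids(table)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = node_ids, stringsAsFactors = FALSE))
  nodes <- data.frame(otu_id = node_ids, stringsAsFactors = FALSE)
  if (!is.null(table)) {
    for (r in mdm_ranks()) {
      nodes[[paste0("label_", r)]] <- rank_label(table$taxonomy[node_ids], r)
      nodes[[paste0("unknown_", r)]] <-
        unknown_mask(table$taxonomy[node_ids], r)
    }
  }
  structure(list(graph = g, nodes = nodes, method = method,
                 provenance = provenance),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("<cooccurrence_network> method=", x$method, ", ",
      igraph::vcount(x$graph), " nodes, ", igraph::ecount(x$graph),
      " edges\n", sep = "")
  invisible(x)
}

#' Infer a co-occurrence network
#'
#' Dispatch wrapper over the supported inference methods, recording
#' provenance (method, penalty/threshold, prevalence cutoff, seed).
#'
#' @param table A prevalence-filtered `community_table`.
#' @param method `"mb"` (CLR + neighborhood selection with StARS; default),
#'   `"sparcc"` or `"pearson"`.
#' @param threshold Absolute-correlation cutoff for the correlation methods.
#' @param seed Seed forwarded to StARS subsampling / SparCC resampling.
#' @param cfg Optional [stars_config()] for `method = "mb"` (overrides
#'   `seed`).
#' @param lambda Optional fixed penalty for `method = "mb"`: skips StARS
#'   and fits the neighborhoods at this value directly (used to hold the
#'   regularization constant across the networks of a controlled
#'   comparison).
#' @param pseudocount CLR pseudocount.
#' @param ... Further arguments to the underlying method.
#' @return A `cooccurrence_network`.
#' @export
build_network <- function(table, method = c("mb", "sparcc", "pearson"),
                          threshold = 0.3, seed = 1, cfg = NULL,
                          lambda = NULL, pseudocount = 1, ...) {
  method <- match.arg(method)
  net <- switch(method,
    mb = {
      if (!is.null(lambda)) {
        clr <- clr_transform(table, pseudocount)
        edges <- symmetrize(mb_neighborhoods(clr, lambda), "or")
        fixed <- new_network(edges, table, method = "mb",
                             provenance = list(method = "mb",
                                               lambda = lambda,
                                               fixed_lambda = TRUE,
                                               pseudocount = pseudocount))
        fixed$lambda <- lambda
        fixed
      } else {
        if (is.null(cfg)) cfg <- stars_config(seed = seed)
        stars_select(table, cfg, pseudocount = pseudocount, ...)
      }
    },
    sparcc = {
      r <- sparcc(table, seed = seed, ...)
      correlation_network(r, threshold = threshold, table = table,
                          method = "sparcc")
    },
    pearson = {
      pc <- pearson_correlation(table, pseudocount)
      correlation_network(pc$r, threshold = threshold, pvalues = pc$p,
                          table = table, method = "pearson")
    })
  cutoff <- attr(table, "prevalence_cutoff")
  net$provenance$prevalence_cutoff <- if (is.null(cutoff)) NA else cutoff
  net$provenance$seed <- seed
  net
}

#' Node and edge accounting for a network
#'
#' "Selected" nodes are all OTUs that entered inference; "connected" nodes
#' are those with at least one edge.  The edge-to-node ratio uses connected
#' nodes.
#'
#' @param net A `cooccurrence_network`.
#' @return One-row data.frame: `selected`, `connected`, `edges`,
#'   `edge_node_ratio`.
#' @export
network_summary <- function(net) {
  deg <- igraph::degree(net$graph)
  connected <- sum(deg > 0)
  edges <- igraph::ecount(net$graph)
  data.frame(selected = igraph::vcount(net$graph), connected = connected,
             edges = edges,
             edge_node_ratio = if (connected > 0) edges / connected else NA)
}

# run fn under a private RNG stream seeded once; successive calls continue
# the stream without touching the global session RNG state
local_rng <- function(seed) {
  state <- NULL
  set_up <- FALSE
  function(fn) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    if (!set_up) {
      set.seed(seed)
      set_up <<- TRUE
    } else {
      assign(".Random.seed", state, envir = globalenv())
    }
    res <- fn()
    state <<- get(".Random.seed", globalenv())
    res
  }
}
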