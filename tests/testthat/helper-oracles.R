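# Independent brute-force oracles used to validate the package's
# implementations.  These deliberately share no code with the package:
# centralities come from hand-rolled BFS and a dense eigensolver, the
# statistics from exhaustive enumeration, and operon calling from an O(n^2)
# pairwise-gap construction.

# all-pairs BFS distances and shortest-path counts on an adjacency matrix
oracle_bfs <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0
    sigma[s, s] <- 1
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] > 0)) {
          if (is.infinite(dist[s, w])) {
            dist[s, w] <- d
            nxt <- c(nxt, w)
          }
          if (dist[s, w] == d) sigma[s, w] <- sigma[s, w] + sigma[s, v]
        }
      }
      frontier <- unique(nxt)
    }
  }
  list(dist = dist, sigma = sigma)
}

# degree / betweenness / closeness / hub score via dense independent
# computation
oracle_centralities <- function(adj) {
  n <- nrow(adj)
  bfs <- oracle_bfs(adj)
  dist <- bfs$dist
  sigma <- bfs$sigma
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s < t && s != v && t != v && is.finite(dist[s, t])) {
          if (dist[s, v] + dist[v, t] == dist[s, t]) {
            btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
          }
        }
      }
    }
  }
  cls <- vapply(seq_len(n), function(v) {
    d <- dist[v, -v]
    d <- d[is.finite(d)]
    if (!length(d)) NA_real_ else 1 / sum(d)
  }, numeric(1))
  hub <- if (any(adj > 0)) {
    e <- eigen(adj, symmetric = TRUE)
    v <- abs(e$vectors[, which.max(e$values)])
    v / max(v)
  } else rep(0, n)
  list(degree = rowSums(adj > 0), betweenness = btw, closeness = cls,
       hub_score = hub)
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
# (tie-free data, group sizes small)
oracle_wilcoxon <- function(x, y) {
  m <- length(x)
  n <- length(y)
  vals <- c(x, y)
  stopifnot(!anyDuplicated(vals))
  u_obs <- sum(outer(x, y, ">"))
  combos <- utils::combn(m + n, m)
  us <- apply(combos, 2, function(ix) {
    a <- vals[ix]
    b <- vals[-ix]
    sum(outer(a, b, ">"))
  })
  p <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  p
}

# exact two-sided Fisher p: sum of hypergeometric probabilities not larger
# than the observed table's (same convention as fisher.test)
oracle_fisher <- function(m) {
  a <- m[1, 1]
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Holm step-down from the definition
oracle_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[ord[i]]))
    adj[ord[i]] <- running
  }
  adj
}

# O(n^2) operon memberships: threshold the full pairwise intergenic-gap
# matrix per strand and take connected components
oracle_cluster_operons <- function(genes, max_gap = 5000) {
  out <- rep(NA_character_, nrow(genes))
  for (st in unique(genes$strand)) {
    idx <- which(genes$strand == st)
    k <- length(idx)
    comp <- seq_len(k)
    if (k > 1) {
      for (i in seq_len(k - 1)) {
        for (j in (i + 1):k) {
          gi <- genes[idx[i], ]; gj <- genes[idx[j], ]
          gap <- max(0, max(gi$start, gj$start) -
                        min(gi$end, gj$end) - 1)
          if (gap <= max_gap) {
            old <- comp[j]; new <- comp[i]
            comp[comp == old] <- new
          }
        }
      }
    }
    # canonical component labels in order of leftmost start
    starts <- vapply(unique(comp), function(cc) {
      min(genes$start[idx[comp == cc]])
    }, numeric(1))
    relabel <- match(comp, unique(comp)[order(starts)])
    out[idx] <- paste(genes$scaffold_id[idx], st, relabel, sep = ":")
  }
  out
}

# exhaustive putative-adaptation flags per operon membership
oracle_adaptation_flags <- function(genes, membership, window_genes = 10,
                                    max_gap = 5000) {
  flags <- logical(0)
  for (op in unique(membership)) {
    d <- genes[membership == op, , drop = FALSE]
    d <- d[order(d$start, d$end), , drop = FALSE]
    hit <- FALSE
    for (i in which(d$hypothetical)) {
      others <- setdiff(seq_len(nrow(d)), i)
      if (!length(others)) next
      gaps <- vapply(others, function(j) {
        max(0, max(d$start[i], d$start[j]) - min(d$end[i], d$end[j]) - 1)
      }, numeric(1))
      ord <- order(gaps, abs(others - i), d$gene_id[others])
      sel <- utils::head(ord, window_genes)
      near <- others[sel][gaps[sel] <= max_gap]
      if (any(d$adaptation[near])) {
        hit <- TRUE
        break
      }
    }
    flags[op] <- hit
  }
  flags
}

# random gene table on one scaffold, mixing strands, gap scales chosen to
# straddle the 5000-bp rule
random_gene_table <- function(n_genes, scaffold_id = "scf", seed = 1) {
  set.seed(seed)
  pos <- c("+" = 1L, "-" = 1L)
  rows <- lapply(seq_len(n_genes), function(i) {
    st <- sample(c("+", "-"), 1)
    gap <- sample(c(sample(0:5000, 1), sample(4500:5500, 1),
                    sample(5001:20000, 1)), 1)
    len <- sample(200:2000, 1)
    start <- pos[[st]] + gap
    pos[st] <<- start + len
    data.frame(scaffold_id = scaffold_id,
               gene_id = sprintf("%s_g%03d", scaffold_id, i),
               start = start, end = start + len - 1L, strand = st,
               product = sample(c("hypothetical protein", "rubrerythrin",
                                  "ABC transporter", "catalase",
                                  "DNA gyrase"), 1),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$hypothetical <- grepl("hypothetical", df$product)
  df$adaptation <- df$product %in% c("rubrerythrin", "catalase")
  df
}

# small deterministic community for fast tests
toy_table <- function(p = 6, n = 10, seed = 1, unknown = integer(0)) {
  set.seed(seed)
  counts <- matrix(rpois(p * n, lambda = 20), p, n)
  ids <- sprintf("OTU_%02d", seq_len(p))
  rownames(counts) <- ids
  colnames(counts) <- sprintf("S%02d", seq_len(n))
  lineages <- vapply(seq_len(p), function(i) {
    genus <- if (i %in% unknown) "uncultured" else sprintf("Genus_%02d", i)
    paste("Bacteria", "Proteobacteria", "Gammaproteobacteria",
          sprintf("Order_%02d", i), sprintf("Family_%02d", i), genus,
          sep = ";")
  }, character(1))
  names(lineages) <- ids
  community_table(counts, lineages, environment = "toy")
}

# build a cooccurrence_network directly from an edge list (test fixture)
toy_network <- function(edges, nodes, unknown = rep(FALSE, length(nodes))) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  df <- data.frame(otu_id = nodes, stringsAsFactors = FALSE)
  for (r in mdm_ranks()) {
    df[[paste0("label_", r)]] <- ifelse(unknown, "Unknown",
                                        paste0("Taxon_", nodes))
    df[[paste0("unknown_", r)]] <- unknown
  }
  structure(list(graph = g, nodes = df, method = "fixture",
                 provenance = list()),
            class = "cooccurrence_network")
}
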