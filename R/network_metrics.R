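#' Node centralities of a co-occurrence network
#'
#' Degree, betweenness (unnormalized shortest-path counts, endpoints
#' excluded), closeness (within the node's connected component: reciprocal
#' of the summed distances to reachable nodes; undefined for isolated
#' nodes), and Kleinberg hub score (principal eigenvector of the adjacency
#' matrix, scaled so the maximum entry is 1).  All computed on the
#' unweighted graph.
#'
#' @param net A `cooccurrence_network` with at least one node.
#' @return data.frame: `otu_id`, per-rank label/Unknown columns carried from
#'   the network, `degree`, `betweenness`, `closeness` (`NA` for isolated
#'   nodes), `hub_score`, `isolated`.
#' @export
centralities <- function(net) {
  g <- net$graph
  if (igraph::vcount(g) == 0) stop("empty graph")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA,
                             normalized = FALSE)
  cls <- suppressWarnings(igraph::closeness(g, mode = "all", weights = NA))
  hub <- hub_scores(g)
  out <- net$nodes
  out$degree <- as.integer(deg[out$otu_id])
  out$betweenness <- unname(btw[out$otu_id])
  out$closeness <- unname(cls[out$otu_id])
  out$hub_score <- unname(hub[out$otu_id])
  out$isolated <- out$degree == 0
  out$closeness[out$isolated] <- NA_real_
  attr(out, "provenance") <- net$provenance
  out
}

#' Kleinberg hub scores of an undirected graph
#'
#' For an undirected graph the hub score equals the authority score: the
#' principal eigenvector of the adjacency matrix, scaled so its maximum
#' entry is 1.  Computed by power iteration from an all-ones start vector
#' to a tolerance of 1e-10; graphs on which the iteration oscillates or
#' stalls (near-bipartite spectra, tied component eigenvalues) fall back
#' to a dense symmetric eigensolver.
#'
#' @param g An igraph graph.
#' @return Named numeric vector in `[0, 1]`, zero for a graph with no
#'   edges.
#' @export
hub_scores <- function(g) {
  n <- igraph::vcount(g)
  ids <- igraph::V(g)$name
  if (igraph::ecount(g) == 0) {
    return(stats::setNames(rep(0, n), ids))
  }
  a <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  x <- rep(1 / sqrt(n), n)
  converged <- FALSE
  for (it in seq_len(1000)) {
    y <- as.vector(a %*% x)
    ny <- sqrt(sum(y^2))
    if (ny == 0) break
    y <- y / ny
    if (max(abs(y - x)) < 1e-10) {
      x <- y
      converged <- TRUE
      break
    }
    x <- y
  }
  if (!converged) {
    e <- eigen(as.matrix(a), symmetric = TRUE)
    x <- abs(e$vectors[, which.max(e$values)])
  }
  x <- abs(x)
  stats::setNames(x / max(x), ids)
}

#' Write a centrality table to TSV
#'
#' @param cent Output of [centralities()].
#' @param path Output path.
#' @param rank Rank whose label/Unknown columns to include.
#' @export
write_centralities <- function(cent, path, rank = "genus") {
  df <- cent[, c("otu_id", paste0("label_", rank), paste0("unknown_", rank),
                 "degree", "betweenness", "closeness", "hub_score")]
  names(df)[2:3] <- c("rank_label", "unknown")
  write_tsv_with_header(df, path, attr(cent, "provenance"))
}

#' Edge composition by Known/Unknown status
#'
#' Classifies every edge by its endpoints' Known (K) / Unknown (U) status at
#' a rank, and tallies edges per pair of rank labels (the data behind
#' class-neighborhood bar graphs).
#'
#' @param net A `cooccurrence_network`.
#' @param rank Rank name.
#' @return List with `kk`, `ku`, `uu` counts (summing to the edge count) and
#'   `class_pairs` (data.frame `label_a`, `label_b`, `n`, labels sorted
#'   within pair).
#' @export
edge_composition <- function(net, rank = "genus") {
  el <- igraph::as_edgelist(net$graph)
  u <- stats::setNames(net$nodes[[paste0("unknown_", rank)]],
                       net$nodes$otu_id)
  lab <- stats::setNames(net$nodes[[paste0("label_", rank)]],
                         net$nodes$otu_id)
  if (nrow(el) == 0) {
    return(list(kk = 0L, ku = 0L, uu = 0L,
                class_pairs = data.frame(label_a = character(0),
                                         label_b = character(0),
                                         n = integer(0))))
  }
  ua <- u[el[, 1]]; ub <- u[el[, 2]]
  kk <- sum(!ua & !ub); uu <- sum(ua & ub); ku <- sum(xor(ua, ub))
  key <- apply(cbind(lab[el[, 1]], lab[el[, 2]]), 1, function(x) {
    paste(sort(x), collapse = "\t")
  })
  tab <- table(key)
  parts <- strsplit(names(tab), "\t", fixed = TRUE)
  class_pairs <- data.frame(
    label_a = vapply(parts, `[`, character(1), 1),
    label_b = vapply(parts, `[`, character(1), 2),
    n = as.integer(tab), row.names = NULL, stringsAsFactors = FALSE)
  list(kk = kk, ku = ku, uu = uu, class_pairs = class_pairs)
}

#' Within-class edge enrichment by label permutation
#'
#' For each rank label (class), the observed fraction of its incident edges
#' that stay within the class, compared against a null built by shuffling
#' node labels over the fixed graph.
#'
#' @param net A `cooccurrence_network`.
#' @param rank Rank name.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @return data.frame: `label`, `n_nodes`, `observed` (within-class
#'   fraction), `p` (permutation p-value, `(1 + #\{perm >= obs\}) /
#'   (n_perm + 1)`).  Classes with fewer than 2 nodes are excluded.
#' @export
within_class_enrichment <- function(net, rank = "genus", n_perm = 1000,
                                    seed = 1) {
  el <- igraph::as_edgelist(net$graph)
  labels <- stats::setNames(net$nodes[[paste0("label_", rank)]],
                            net$nodes$otu_id)
  classes <- names(which(table(labels) >= 2))
  if (length(unique(labels)) < 1) stop("no classes present")
  frac_by_class <- function(lab_vec) {
    la <- lab_vec[el[, 1]]; lb <- lab_vec[el[, 2]]
    vapply(classes, function(cl) {
      touch <- la == cl | lb == cl
      if (!any(touch)) return(NA_real_)
      sum(la == cl & lb == cl) / sum(touch)
    }, numeric(1))
  }
  obs <- frac_by_class(labels)
  if (length(unique(labels)) == 1L) {
    return(data.frame(label = classes,
                      n_nodes = as.integer(table(labels)[classes]),
                      observed = obs, p = 1, stringsAsFactors = FALSE))
  }
  exceed <- rep(0L, length(classes))
  valid <- rep(0L, length(classes))
  rng <- local_rng(seed)
  for (i in seq_len(n_perm)) {
    perm <- rng(function() stats::setNames(sample(labels), names(labels)))
    f <- frac_by_class(perm)
    ok <- !is.na(f) & !is.na(obs)
    exceed[ok] <- exceed[ok] + (f[ok] >= obs[ok])
    valid[ok] <- valid[ok] + 1L
  }
  data.frame(label = classes,
             n_nodes = as.integer(table(labels)[classes]),
             observed = unname(obs),
             p = unname((1 + exceed) / (valid + 1)),
             stringsAsFactors = FALSE)
}

#' Fragmentation under successive hub removal
#'
#' Deletes the listed nodes one at a time (simple subgraph deletion, no
#' re-inference) and tracks how the network falls apart.
#'
#' @param net A `cooccurrence_network`.
#' @param nodes_to_remove Ordered character vector of node ids.
#' @return data.frame, one row per removal step: `removed`, `n_components`,
#'   `largest_component`, `edges`.  Attribute `"baseline"` holds the
#'   pre-removal values.
#' @export
hub_removal_fragmentation <- function(net, nodes_to_remove) {
  g <- net$graph
  missing <- setdiff(nodes_to_remove, igraph::V(g)$name)
  if (length(missing)) {
    stop("unknown node id(s): ", paste(missing, collapse = ", "))
  }
  snapshot <- function(g) {
    comp <- igraph::components(g)
    c(n_components = comp$no,
      largest_component = if (comp$no > 0) max(comp$csize) else 0,
      edges = igraph::ecount(g))
  }
  base <- snapshot(g)
  rows <- vector("list", length(nodes_to_remove))
  for (i in seq_along(nodes_to_remove)) {
    g <- igraph::delete_vertices(g, nodes_to_remove[i])
    rows[[i]] <- snapshot(g)
  }
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(data.frame(removed = nodes_to_remove,
                          stringsAsFactors = FALSE), out)
  attr(out, "baseline") <- base
  out
}
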