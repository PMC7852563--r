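# run expr with a temporary RNG state seeded at `seed`, restoring the
# session RNG afterwards
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

#' Specification for a synthetic community
#'
#' Describes a community with a planted sparse conditional-dependence graph
#' whose inverse-covariance structure, Unknown labels and count sparsity
#' are all known, so network inference and the downstream comparison can
#' be validated against ground truth.
#'
#' @param n_taxa Number of OTUs.
#' @param n_samples Number of samples.
#' @param depth Sequencing depth (total count) per sample.
#' @param topology Planted graph: `"hub"` (a few high-degree nodes plus a
#'   sparse background), `"band"` (chain with second-neighbor links) or
#'   `"random"` (Erdos-Renyi).
#' @param n_hubs Number of hub nodes for the hub topology.
#' @param edge_strength Magnitude of the off-diagonal precision entries;
#'   sets the partial-correlation effect size.
#' @param unknown_fraction Fraction of taxa labeled Unknown (at genus).
#' @param plant_unknown_hubs If `TRUE`, Unknown labels fall on hub nodes
#'   with probability `hub_unknown_prob`; if `FALSE` labels are uniform
#'   (the null mode for type-I checks).
#' @param hub_unknown_prob Probability a hub is labeled Unknown when
#'   planting (default 0.8).
#' @param target_sparsity Desired fraction of zero counts; the generator
#'   calibrates the spread of taxon base abundances to reach it.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A `community_spec` list.
#' @export
community_spec <- function(n_taxa = 50, n_samples = 400, depth = 5e4,
                           topology = c("hub", "band", "random"),
                           n_hubs = 4, edge_strength = 0.38,
                           unknown_fraction = 0.2,
                           plant_unknown_hubs = TRUE,
                           hub_unknown_prob = 0.8,
                           target_sparsity = 0.15, seed = 1) {
  topology <- match.arg(topology)
  if (unknown_fraction < 0 || unknown_fraction > 1) {
    stop("unknown_fraction must be in [0, 1]")
  }
  structure(list(n_taxa = n_taxa, n_samples = n_samples, depth = depth,
                 topology = topology, n_hubs = n_hubs,
                 edge_strength = edge_strength,
                 unknown_fraction = unknown_fraction,
                 plant_unknown_hubs = plant_unknown_hubs,
                 hub_unknown_prob = hub_unknown_prob,
                 target_sparsity = target_sparsity, seed = seed),
            class = "community_spec")
}

planted_adjacency <- function(spec) {
  p <- spec$n_taxa
  adj <- matrix(FALSE, p, p)
  if (spec$topology == "hub") {
    # half the non-hub nodes attach round-robin to the hubs, keeping hub
    # degrees balanced: partial correlations at a degree-d node are bounded
    # by 1/sqrt(d), so unbounded hub degrees would force vanishing edge
    # effects.  A sparse background among the remaining nodes keeps the
    # graph from being a pure star forest.
    hubs <- seq_len(spec$n_hubs)
    leaves <- setdiff(seq_len(p), hubs)
    attached <- sample(leaves, floor(length(leaves) / 2))
    for (k in seq_along(attached)) {
      h <- hubs[(k - 1) %% spec$n_hubs + 1]
      adj[h, attached[k]] <- adj[attached[k], h] <- TRUE
    }
    for (i in leaves) {
      for (j in leaves) {
        if (j > i && stats::runif(1) < 1 / p) {
          adj[i, j] <- adj[j, i] <- TRUE
        }
      }
    }
  } else if (spec$topology == "band") {
    for (i in seq_len(p - 1)) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
    for (i in seq_len(p - 2)) adj[i, i + 2] <- adj[i + 2, i] <- TRUE
  } else {
    prob <- 2 / p
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) {
        if (stats::runif(1) < prob) adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  adj
}

precision_from_adjacency <- function(adj, strength) {
  p <- nrow(adj)
  omega <- diag(p)
  omega[adj] <- -strength
  ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 0.05) omega <- omega + diag(0.05 - ev, p)
  if (min(eigen(omega, symmetric = TRUE,
                only.values = TRUE)$values) <= 0) {
    stop("planted precision matrix is not positive definite")
  }
  omega
}

# spread of per-taxon base log-abundances giving the target zero fraction:
# the expected zero fraction E[exp(-depth * pi)] is monotone in the spread,
# so a bisection on the fixed latent draw suffices
calibrate_mu_scale <- function(mu0, z, depth, target) {
  zero_frac <- function(s) {
    eta <- sweep(z, 2, s * mu0, "+")
    pim <- exp(eta - apply(eta, 1, max))
    pim <- pim / rowSums(pim)
    mean(exp(-depth * pim))
  }
  if (zero_frac(0) >= target) return(0)
  lo <- 0; hi <- 12
  if (zero_frac(hi) < target) return(hi)
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    if (zero_frac(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate a synthetic community with known structure
#'
#' Logistic-normal-multinomial model: a latent multivariate normal draw
#' with covariance equal to the inverse of the planted precision matrix is
#' shifted by per-taxon base abundances, mapped through a softmax to
#' per-sample compositions, and sampled as multinomial counts at the
#' specified depth.  Zeros arise naturally from depth and composition; the
#' base-abundance spread is calibrated so the realized zero fraction
#' approximates `target_sparsity`.
#'
#' @param spec A [community_spec()].
#' @return List with `table` (a `community_table`) and `truth`: `adjacency`
#'   (planted logical matrix), `edges` (two-column id matrix), `hubs`
#'   (hub OTU ids), `unknown` (named logical), `precision`, `mu`
#'   (base log abundances).
#' @export
generate_community <- function(spec) {
  with_seed(spec$seed, {
    p <- spec$n_taxa; n <- spec$n_samples
    adj <- planted_adjacency(spec)
    omega <- precision_from_adjacency(adj, spec$edge_strength)
    sigma <- stats::cov2cor(solve(omega))
    ch <- chol(sigma)
    z <- matrix(stats::rnorm(n * p), n, p) %*% ch
    mu0 <- stats::rnorm(p)
    s <- calibrate_mu_scale(mu0, z, spec$depth, spec$target_sparsity)
    eta <- sweep(z, 2, s * mu0, "+")
    pim <- exp(eta - apply(eta, 1, max))
    pim <- pim / rowSums(pim)
    counts <- apply(pim, 1, function(pr) {
      stats::rmultinom(1, spec$depth, pr)[, 1]
    })  # taxa x samples
    ids <- sprintf("OTU_%03d", seq_len(p))
    rownames(counts) <- ids
    colnames(counts) <- sprintf("S%03d", seq_len(n))

    hubs <- if (spec$topology == "hub") seq_len(spec$n_hubs) else integer(0)
    n_unknown <- round(spec$unknown_fraction * p)
    unknown <- rep(FALSE, p)
    if (n_unknown > 0) {
      if (spec$plant_unknown_hubs && length(hubs)) {
        planted <- hubs[stats::runif(length(hubs)) < spec$hub_unknown_prob]
        planted <- utils::head(planted, n_unknown)
        rest <- setdiff(seq_len(p), planted)
        extra <- sample(rest, n_unknown - length(planted))
        unknown[c(planted, extra)] <- TRUE
      } else {
        unknown[sample(seq_len(p), n_unknown)] <- TRUE
      }
    }
    phyla <- c("Proteobacteria", "Firmicutes", "Bacteroidetes",
               "Actinobacteria")
    lineages <- vapply(seq_len(p), function(i) {
      ph <- phyla[(i - 1) %% length(phyla) + 1]
      genus <- if (unknown[i]) "uncultured" else sprintf("Genus_%03d", i)
      paste("Bacteria", ph, paste0("Class_", (i - 1) %% 6 + 1),
            sprintf("Order_%03d", i), sprintf("Family_%03d", i), genus,
            sep = ";")
    }, character(1))
    names(lineages) <- ids
    table <- community_table(counts, lineages, environment = "synthetic")
    eidx <- which(upper.tri(adj) & adj, arr.ind = TRUE)
    list(table = table,
         truth = list(adjacency = adj,
                      edges = cbind(ids[eidx[, 1]], ids[eidx[, 2]]),
                      hubs = ids[hubs],
                      unknown = stats::setNames(unknown, ids),
                      precision = omega, mu = s * mu0))
  })
}

#' Compare an inferred edge set with a planted graph
#'
#' @param net A `cooccurrence_network`.
#' @param truth_edges Two-column id matrix of planted edges.  Only edges
#'   between nodes present in the network are scored.
#' @return List with `precision`, `recall`, `f1`, `tp`, `fp`, `fn`.
#' @export
edge_f1 <- function(net, truth_edges) {
  nodes <- igraph::V(net$graph)$name
  canon <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  el <- igraph::as_edgelist(net$graph)
  est <- if (nrow(el)) canon(el[, 1], el[, 2]) else character(0)
  keep <- truth_edges[, 1] %in% nodes & truth_edges[, 2] %in% nodes
  tru <- if (any(keep)) {
    canon(truth_edges[keep, 1], truth_edges[keep, 2])
  } else character(0)
  tp <- length(intersect(est, tru))
  fp <- length(setdiff(est, tru))
  fn <- length(setdiff(tru, est))
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else 0
  list(precision = prec, recall = rec, f1 = f1, tp = tp, fp = fp, fn = fn)
}

#' Specification for a synthetic scaffold
#'
#' Gene coordinates are laid out left to right independently on each
#' strand; genes within a planted operon are separated by gaps drawn from
#' `intra_gap` (at most the operon gap rule allows), and consecutive
#' operons on a strand by gaps from `inter_gap` (strictly larger), so the
#' planted memberships are exactly recoverable by [cluster_operons()].
#'
#' @param scaffold_id Scaffold identifier.
#' @param n_genes Total genes (>= 1); default 60.
#' @param gene_len Range of gene lengths in bp.
#' @param intra_gap Range of within-operon intergenic gaps (must stay at or
#'   below `max_gap`).
#' @param inter_gap Range of between-operon gaps (must exceed `max_gap`).
#' @param max_gap Operon gap rule the layout honors (default 5000).
#' @param operon_size Range of planted operon sizes (genes).
#' @param p_hypothetical,p_adaptation Per-gene probabilities of drawing a
#'   hypothetical / adaptation product annotation.
#' @param templates Optional list of explicit operon templates, each a list
#'   with `strand` (`"+"`/`"-"`) and `products` (character vector); planted
#'   before the random filler operons.
#' @param seed Integer seed.
#' @return A `scaffold_spec` list.
#' @export
scaffold_spec <- function(scaffold_id = "scaffold_1", n_genes = 60,
                          gene_len = c(300, 1500), intra_gap = c(50, 2000),
                          inter_gap = c(5500, 9000), max_gap = 5000,
                          operon_size = c(1, 8), p_hypothetical = 0.3,
                          p_adaptation = 0.15, templates = NULL,
                          seed = 1) {
  if (max(intra_gap) > max_gap) stop("intra_gap must not exceed max_gap")
  if (min(inter_gap) <= max_gap) stop("inter_gap must exceed max_gap")
  structure(list(scaffold_id = scaffold_id, n_genes = n_genes,
                 gene_len = gene_len, intra_gap = intra_gap,
                 inter_gap = inter_gap, max_gap = max_gap,
                 operon_size = operon_size,
                 p_hypothetical = p_hypothetical,
                 p_adaptation = p_adaptation, templates = templates,
                 seed = seed),
            class = "scaffold_spec")
}

filler_products <- c("ABC transporter permease", "DNA polymerase III",
                     "ribosomal protein L3", "elongation factor Tu",
                     "glycosyltransferase", "histidine kinase",
                     "MFS transporter", "tRNA ligase")
adaptation_products <- c("rubrerythrin", "DNA-binding ferritin-like protein",
                         "Fe-S oxidoreductase", "peroxide stress regulator",
                         "catalase", "superoxide dismutase",
                         "cold shock protein", "heat shock protein Hsp20",
                         "trehalose synthase", "osmoprotectant transporter")

#' Generate a synthetic scaffold gene table with planted operons
#'
#' @param spec A [scaffold_spec()].
#' @return List with `genes` (gene-record data.frame) and `truth`:
#'   `operon_of` (named integer, planted operon per gene id),
#'   `n_operons`, and per-gene planted `hypothetical`/`adaptation` flags.
#' @export
generate_scaffold <- function(spec) {
  with_seed(spec$seed, {
    blocks <- list()
    remaining <- spec$n_genes
    for (tpl in spec$templates) {
      k <- length(tpl$products)
      if (k > remaining) stop("templates exceed n_genes")
      blocks[[length(blocks) + 1L]] <-
        list(strand = tpl$strand, products = tpl$products)
      remaining <- remaining - k
    }
    while (remaining > 0) {
      k <- min(remaining,
               sample(spec$operon_size[1]:spec$operon_size[2], 1))
      prods <- vapply(seq_len(k), function(i) {
        u <- stats::runif(1)
        if (u < spec$p_hypothetical) "hypothetical protein"
        else if (u < spec$p_hypothetical + spec$p_adaptation) {
          sample(adaptation_products, 1)
        } else sample(filler_products, 1)
      }, character(1))
      blocks[[length(blocks) + 1L]] <-
        list(strand = sample(c("+", "-"), 1), products = prods)
      remaining <- remaining - k
    }
    pos <- c("+" = 1L, "-" = 1L)
    last_block_on <- c("+" = FALSE, "-" = FALSE)
    rows <- list()
    gene_no <- 0L
    for (b in seq_along(blocks)) {
      blk <- blocks[[b]]
      st <- blk$strand
      if (last_block_on[st]) {
        pos[st] <- pos[st] +
          sample(spec$inter_gap[1]:spec$inter_gap[2], 1)
      }
      for (i in seq_along(blk$products)) {
        if (i > 1) {
          pos[st] <- pos[st] +
            sample(spec$intra_gap[1]:spec$intra_gap[2], 1)
        }
        len <- sample(spec$gene_len[1]:spec$gene_len[2], 1)
        gene_no <- gene_no + 1L
        rows[[gene_no]] <- data.frame(
          scaffold_id = spec$scaffold_id,
          gene_id = sprintf("%s_g%03d", spec$scaffold_id, gene_no),
          start = pos[[st]], end = pos[[st]] + len - 1L, strand = st,
          product = blk$products[i], operon_truth = b,
          stringsAsFactors = FALSE)
        pos[st] <- pos[st] + len  # next gene starts after this end + gap
      }
      last_block_on[st] <- TRUE
    }
    genes <- do.call(rbind, rows)
    truth <- list(
      operon_of = stats::setNames(genes$operon_truth, genes$gene_id),
      n_operons = length(blocks),
      hypothetical = stats::setNames(
        grepl("hypothetical", genes$product, ignore.case = TRUE),
        genes$gene_id),
      adaptation = stats::setNames(
        genes$product %in% adaptation_products, genes$gene_id))
    genes$operon_truth <- NULL
    validate_genes(genes)
    list(genes = genes, truth = truth)
  })
}

#' Generate synthetic BLAST hits with a planted pass/fail composition
#'
#' Emits outfmt-6-valid rows where exactly `n_above` hits meet the 95/95
#' identity/coverage rule and `n_below` fail at least one of the two, so
#' [filter_hits()] counts are predictable.
#'
#' @param scaffold_ids Subject ids to draw from.
#' @param query_ids Query ids to draw from.
#' @param n_above,n_below Number of hits above / below the thresholds.
#' @param min_identity,min_coverage Thresholds the composition is planted
#'   around (default 95/95).
#' @param query_length Nominal query length used for coordinates.
#' @param seed Integer seed.
#' @return data.frame of hits (13-column dialect) with a logical
#'   `planted_above` attribute.
#' @export
generate_blast_hits <- function(scaffold_ids, query_ids, n_above = 30,
                                n_below = 70, min_identity = 95,
                                min_coverage = 95, query_length = 1500,
                                seed = 1) {
  with_seed(seed, {
    n <- n_above + n_below
    above <- c(rep(TRUE, n_above), rep(FALSE, n_below))
    identity <- numeric(n); coverage <- numeric(n)
    for (i in seq_len(n)) {
      if (above[i]) {
        identity[i] <- stats::runif(1, min_identity, 100)
        coverage[i] <- stats::runif(1, min_coverage, 100)
      } else {
        fail <- sample(c("id", "cov", "both"), 1)
        identity[i] <- if (fail %in% c("id", "both")) {
          stats::runif(1, 70, min_identity - 0.1)
        } else stats::runif(1, min_identity, 100)
        coverage[i] <- if (fail %in% c("cov", "both")) {
          stats::runif(1, 40, min_coverage - 0.1)
        } else stats::runif(1, min_coverage, 100)
      }
    }
    alen <- pmax(50L, as.integer(round(coverage / 100 * query_length)))
    hits <- data.frame(
      query_id = sample(query_ids, n, replace = TRUE),
      subject_id = sample(scaffold_ids, n, replace = TRUE),
      percent_identity = round(identity, 2),
      alignment_length = alen,
      mismatches = as.integer(round((100 - identity) / 100 * alen)),
      gap_opens = 0L, qstart = 1L, qend = alen,
      sstart = 1000L, send = 1000L + alen - 1L,
      e_value = 1e-30, bitscore = round(2 * alen * identity / 100, 1),
      query_coverage = round(coverage, 2), stringsAsFactors = FALSE)
    attr(hits, "planted_above") <- above
    hits
  })
}
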