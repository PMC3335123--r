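#' Construct a gene partition
#'
#' A partition assigns every gene to exactly one cluster. Stored as a tibble
#' (`gene`, `cluster`) with the detection method, cluster count, and — when
#' a network is supplied — the partition's Newman-Girvan modularity as
#' attributes.
#'
#' @param gene Character vector of gene identifiers (unique).
#' @param cluster Cluster labels, same length as `gene`.
#' @param method Label describing how the partition was produced.
#' @param net Optional network on which to compute modularity.
#' @return A tibble of class `gene_partition`.
#' @export
gene_partition <- function(gene, cluster, method = "manual", net = NULL) {
  stopifnot(length(gene) == length(cluster))
  if (anyDuplicated(gene)) stop("genes must be assigned exactly once", call. = FALSE)
  out <- tibble(gene = as.character(gene), cluster = as.character(cluster))
  class(out) <- c("gene_partition", class(out))
  attr(out, "method") <- method
  attr(out, "n_clusters") <- length(unique(out$cluster))
  attr(out, "modularity") <- if (!is.null(net)) modularity_q(net, out) else NA_real_
  out
}

#' Louvain community detection
#'
#' Greedy multi-level modularity optimization. The node processing order is
#' randomized under `seed` (results are deterministic for a fixed seed and
#' typically stable in modularity across seeds).
#'
#' @param net A non-empty `igraph` network.
#' @param seed Integer seed.
#' @return A [gene_partition()] with its modularity attribute set.
#' @export
louvain_partition <- function(net, seed = 1L) {
  assert_network(net)
  if (igraph::vcount(net) == 0) stop("empty network", call. = FALSE)
  set.seed(as.integer(seed))
  perm <- sample(igraph::vcount(net))
  shuffled <- igraph::permute(net, perm)
  comm <- igraph::cluster_louvain(shuffled)
  membership <- igraph::membership(comm)
  gene_partition(
    gene = igraph::V(shuffled)$name,
    cluster = sprintf("L%d", as.integer(membership)),
    method = "louvain",
    net = net
  )
}

#' Markov clustering (MCL)
#'
#' Simulates stochastic flow on the graph: the column-stochastic adjacency
#' matrix (self-loops of weight 1 added) is alternately squared (expansion)
#' and taken to an entrywise power with column renormalization (inflation)
#' until the matrix change falls below `tol` or `max_iter` is reached.
#' Clusters are read from the attractor structure of the limit matrix
#' (connected components of its non-zero pattern). Fully deterministic.
#'
#' @param net A non-empty `igraph` network.
#' @param inflation Inflation exponent (> 1); larger values give finer
#'   clusters. Default 2.
#' @param max_iter Iteration cap (default 200).
#' @param tol Convergence tolerance on the max entry change (default 1e-8).
#' @return A [gene_partition()]; attribute `converged` reports whether the
#'   flow converged within the cap.
#' @export
mcl_partition <- function(net, inflation = 2, max_iter = 200, tol = 1e-8) {
  assert_network(net)
  nv <- igraph::vcount(net)
  if (nv == 0) stop("empty network", call. = FALSE)
  if (inflation <= 1) stop("`inflation` must exceed 1", call. = FALSE)
  adj <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  m <- adj + Matrix::Diagonal(nv)
  m <- normalize_columns(m)
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    m2 <- m %*% m                      # expansion
    m2@x <- m2@x^inflation             # inflation
    m2 <- Matrix::drop0(m2, tol = 1e-12)
    m2 <- normalize_columns(m2)
    delta <- max(abs(m2 - m))
    m <- m2
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge within ", max_iter, " iterations",
            call. = FALSE)
  }
  pattern <- m + Matrix::t(m)
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    pattern > 0, mode = "undirected", diag = FALSE))
  gene_partition(
    gene = igraph::V(net)$name,
    cluster = sprintf("M%d", as.integer(comp$membership)),
    method = sprintf("mcl(inflation=%g)", inflation),
    net = net
  ) -> out
  attr(out, "converged") <- converged
  out
}

normalize_columns <- function(m) {
  cs <- Matrix::colSums(m)
  cs[cs == 0] <- 1
  m %*% Matrix::Diagonal(x = 1 / cs)
}

#' Filter annotation terms by in-universe size
#'
#' Restricts every term's gene set to the given universe, then drops terms
#' whose restricted size falls below `min_size` or above `max_size`
#' (boundaries inclusive: sizes of exactly 5 and 50 are kept under the
#' defaults). Size filtering after restriction keeps term specificity
#' meaningful for the genes actually under study.
#'
#' @param cat An [annotation_catalog()].
#' @param universe Character vector of gene identifiers.
#' @param min_size,max_size Size bounds (defaults 5 and 50).
#' @return A filtered `annotation_catalog`.
#' @export
filter_terms <- function(cat, universe, min_size = 5, max_size = 50) {
  stopifnot(inherits(cat, "annotation_catalog"))
  universe <- unique(as.character(universe))
  restricted <- lapply(cat$genes, intersect, universe)
  sizes <- lengths(restricted)
  keep <- sizes >= min_size & sizes <= max_size
  out <- cat[keep, ]
  out$genes <- restricted[keep]
  out$n_genes <- sizes[keep]
  out
}

# gene -> character vector of term ids, per namespace
gene_term_index <- function(cat) {
  ns <- ifelse(is.na(cat$namespace), "default", cat$namespace)
  long <- tidyr::unnest(
    tibble(term_id = cat$term_id, namespace = ns, gene = cat$genes),
    "gene"
  )
  split(long, long$namespace)
}

#' Functional similarity of co-clustered genes
#'
#' For gene pairs that fall in the same cluster of a partition and both
#' carry at least one annotation term, computes the Jaccard coefficient of
#' the two term sets (common terms over total terms) and averages, per
#' annotation namespace. By default all same-cluster pairs of network genes
#' are scored (`pairs = "all"`); `pairs = "edges"` restricts to pairs that
#' are also network edges. Pairs with an unannotated endpoint are excluded
#' rather than scored 0; a namespace with no eligible pair reports `NA`
#' with a zero pair count.
#'
#' @param net An `igraph` network; clusters are restricted to its genes.
#' @param p A [gene_partition()] over the network's genes.
#' @param cat A (filtered) [annotation_catalog()].
#' @param pairs `"all"` (every same-cluster pair, default) or `"edges"`
#'   (same-cluster pairs joined by a network edge).
#' @return A tibble with columns `namespace`, `mean_jaccard`, `n_pairs`.
#' @export
pairwise_functional_jaccard <- function(net, p, cat,
                                        pairs = c("all", "edges")) {
  pairs <- match.arg(pairs)
  assert_network(net)
  stopifnot(inherits(p, "gene_partition"), inherits(cat, "annotation_catalog"))
  cl <- setNames(p$cluster, p$gene)
  if (pairs == "edges") {
    et <- edge_tibble(net)
    same <- !is.na(cl[et$from]) & !is.na(cl[et$to]) & cl[et$from] == cl[et$to]
    et <- et[same, , drop = FALSE]
  } else {
    genes <- intersect(igraph::V(net)$name, p$gene)
    sets <- split(genes, cl[genes])
    et <- dplyr::bind_rows(lapply(sets, function(g) {
      if (length(g) < 2) return(NULL)
      idx <- combn(sort(g), 2)
      tibble(from = idx[1, ], to = idx[2, ])
    }))
    if (is.null(et) || nrow(et) == 0) {
      et <- tibble(from = character(), to = character())
    }
  }
  by_ns <- gene_term_index(cat)
  rows <- lapply(names(by_ns), function(ns) {
    terms <- split(by_ns[[ns]]$term_id, by_ns[[ns]]$gene)
    a <- terms[et$from]
    b <- terms[et$to]
    ok <- !vapply(a, is.null, logical(1)) & !vapply(b, is.null, logical(1))
    if (!any(ok)) {
      return(tibble(namespace = ns, mean_jaccard = NA_real_, n_pairs = 0L))
    }
    j <- mapply(function(x, y) {
      length(intersect(x, y)) / length(union(x, y))
    }, a[ok], b[ok])
    tibble(namespace = ns, mean_jaccard = mean(j), n_pairs = sum(ok))
  })
  dplyr::bind_rows(rows)
}

#' Functional coherence of a partition against random partitions
#'
#' Compares the mean within-cluster functional Jaccard of a real partition
#' to `n_random` size-matched random partitions (gene labels permuted
#' across cluster slots, cluster sizes preserved exactly). Reports the fold
#' ratio (real over mean random) and the empirical p-value (fraction of
#' random partitions whose mean is at least the real one), per namespace.
#' A zero random mean yields an infinite fold, flagged by `fold_infinite`.
#'
#' @param net An `igraph` network.
#' @param p A [gene_partition()].
#' @param cat A (filtered) [annotation_catalog()].
#' @param n_random Number of random partitions (default 100).
#' @param seed Integer seed.
#' @param pairs Pair convention, see [pairwise_functional_jaccard()].
#' @return A tibble with columns `namespace`, `real_mean`, `random_mean`,
#'   `fold`, `fold_infinite`, `p_empirical`, `n_random`.
#' @export
coherence_vs_random <- function(net, p, cat, n_random = 100, seed = 1L,
                                pairs = c("all", "edges")) {
  pairs <- match.arg(pairs)
  real <- pairwise_functional_jaccard(net, p, cat, pairs = pairs)
  rand_means <- matrix(NA_real_, nrow = n_random, ncol = nrow(real),
                       dimnames = list(NULL, real$namespace))
  for (r in seq_len(n_random)) {
    pr <- random_partition(p, seed = as.integer(seed) + r)
    jr <- pairwise_functional_jaccard(net, pr, cat, pairs = pairs)
    rand_means[r, jr$namespace] <- jr$mean_jaccard
  }
  rows <- lapply(seq_len(nrow(real)), function(i) {
    ns <- real$namespace[i]
    rm <- rand_means[, ns]
    rmean <- mean(rm, na.rm = TRUE)
    fold <- if (isTRUE(rmean == 0)) Inf else real$mean_jaccard[i] / rmean
    tibble(
      namespace = ns,
      real_mean = real$mean_jaccard[i],
      random_mean = rmean,
      fold = fold,
      fold_infinite = is.infinite(fold),
      p_empirical = mean(rm >= real$mean_jaccard[i], na.rm = TRUE),
      n_random = n_random
    )
  })
  dplyr::bind_rows(rows)
}

#' Hypergeometric enrichment of a gene cluster
#'
#' For a cluster of \eqn{n} genes and a functional category with \eqn{K}
#' genes inside a reference of \eqn{N} genes, the enrichment p-value is the
#' hypergeometric upper tail \eqn{P(X \ge k)} of the observed overlap
#' \eqn{k}. P-values are Benjamini-Hochberg adjusted across the terms
#' tested for this cluster. Terms with no gene in the reference are
#' skipped.
#'
#' @param cluster Character vector of genes (must be a subset of
#'   `reference`).
#' @param cat An [annotation_catalog()] (typically [filter_terms()] output).
#' @param reference Character vector: the gene universe (all genes in the
#'   network under study).
#' @return A tibble with columns `term_id`, `term_name`, `namespace`,
#'   `n` (cluster size), `K` (in-reference term size), `k` (overlap),
#'   `p_value`, `q_value`, sorted by p-value.
#' @export
hypergeometric_enrichment <- function(cluster, cat, reference) {
  stopifnot(inherits(cat, "annotation_catalog"))
  cluster <- unique(as.character(cluster))
  reference <- unique(as.character(reference))
  if (!all(cluster %in% reference)) {
    stop("cluster genes must all belong to the reference set", call. = FALSE)
  }
  N <- length(reference)
  n <- length(cluster)
  rows <- lapply(seq_len(nrow(cat)), function(i) {
    term_genes <- intersect(cat$genes[[i]], reference)
    K <- length(term_genes)
    if (K == 0) return(NULL)
    k <- length(intersect(cluster, term_genes))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(term_id = cat$term_id[i], term_name = cat$term_name[i],
           namespace = cat$namespace[i], n = n, K = K, k = k, p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(dplyr::mutate(out, q_value = numeric(0)))
  out$q_value <- p.adjust(out$p_value, method = "BH")
  dplyr::arrange(out, .data$p_value)
}

#' Enrichment across all sufficiently large clusters of a partition
#'
#' Runs [hypergeometric_enrichment()] for every cluster above `min_size`
#' genes. Adjustment is per cluster by default (each cluster's terms
#' corrected together); `adjust = "global"` recorrects across all clusters.
#'
#' @param p A [gene_partition()].
#' @param cat An [annotation_catalog()].
#' @param reference Gene universe; defaults to all genes in the partition.
#' @param min_size Only clusters with strictly more genes are tested
#'   (default 10).
#' @param adjust `"per_cluster"` (default) or `"global"`.
#' @return A tibble of enrichment rows with a leading `cluster` column.
#' @export
enrich_clusters <- function(p, cat, reference = NULL, min_size = 10,
                            adjust = c("per_cluster", "global")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(p, "gene_partition"))
  reference <- reference %||% p$gene
  sets <- split(p$gene, p$cluster)
  sets <- sets[lengths(sets) > min_size]
  rows <- lapply(names(sets), function(cl) {
    res <- hypergeometric_enrichment(sets[[cl]], cat, reference)
    if (nrow(res) == 0) return(NULL)
    dplyr::mutate(res, cluster = cl, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  if (adjust == "global" && nrow(out) > 0) {
    out$q_value <- p.adjust(out$p_value, method = "BH")
  }
  out
}
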