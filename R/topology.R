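#' Per-node topology profile
#'
#' Degree, betweenness centrality (unnormalized shortest-path pair counts,
#' with equal-length paths split evenly), and local clustering coefficient
#' (`2 * links among neighbours / (k (k - 1))`; nodes of degree < 2 score 0).
#'
#' @param net A non-empty `igraph` network.
#' @return A tibble with columns `gene`, `degree`, `betweenness`,
#'   `clustering`.
#' @export
topology_profile <- function(net) {
  assert_network(net)
  if (igraph::vcount(net) == 0) stop("empty network", call. = FALSE)
  cl <- igraph::transitivity(net, type = "local", isolates = "zero")
  tibble(
    gene = igraph::V(net)$name,
    degree = as.numeric(igraph::degree(net)),
    betweenness = as.numeric(igraph::betweenness(net, directed = FALSE,
                                                 normalized = FALSE)),
    clustering = as.numeric(cl)
  )
}

#' Global graph metrics
#'
#' The summary row used to characterize each network: node and edge counts,
#' average degree (`2|E|/|V|`), average clustering coefficient (mean local
#' coefficient over all nodes, degree < 2 counted as 0), diameter of the
#' largest connected component, fraction of nodes in that component, and
#' degree assortativity (Pearson correlation of endpoint degrees over the
#' edge list, both orientations). Assortativity is undefined (NA) when all
#' degrees are equal.
#'
#' @param net A non-empty `igraph` network.
#' @return A one-row tibble with columns `n_nodes`, `n_edges`,
#'   `average_degree`, `average_clustering`, `diameter`, `giant_fraction`,
#'   `assortativity`.
#' @export
global_metrics <- function(net) {
  assert_network(net)
  nv <- igraph::vcount(net)
  if (nv == 0) stop("empty network", call. = FALSE)
  ne <- igraph::ecount(net)
  comps <- igraph::components(net)
  giant_id <- which.max(comps$csize)
  giant <- igraph::induced_subgraph(net, which(comps$membership == giant_id))
  diam <- if (igraph::ecount(giant) >= 1) {
    as.numeric(igraph::diameter(giant, directed = FALSE, weights = NA))
  } else {
    NA_real_
  }
  assort <- suppressWarnings(igraph::assortativity_degree(net, directed = FALSE))
  if (is.nan(assort)) assort <- NA_real_
  tibble(
    n_nodes = nv,
    n_edges = ne,
    average_degree = 2 * ne / nv,
    average_clustering = avg_clustering(net),
    diameter = diam,
    giant_fraction = max(comps$csize) / nv,
    assortativity = assort
  )
}

#' Newman-Girvan modularity of a partition
#'
#' \eqn{Q = \sum_c \left( e_c/|E| - (d_c / 2|E|)^2 \right)} where \eqn{e_c}
#' counts intra-cluster edges and \eqn{d_c} the total degree inside cluster
#' \eqn{c}.
#'
#' @param net An `igraph` network.
#' @param p A [gene_partition()] covering every node of `net`.
#' @return Modularity Q.
#' @export
modularity_q <- function(net, p) {
  assert_network(net)
  stopifnot(inherits(p, "gene_partition"))
  idx <- match(igraph::V(net)$name, p$gene)
  if (anyNA(idx)) {
    stop("partition misses node(s): ",
         paste(head(igraph::V(net)$name[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  membership <- as.integer(factor(p$cluster[idx]))
  igraph::modularity(net, membership)
}

#' Wilcoxon rank-sum comparison of two metric distributions
#'
#' Two-sided rank-sum test with midranks for ties. Small problems (up to
#' 2e5 group assignments) are solved by exact enumeration of all
#' reassignments; larger ones use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return A one-row tibble with `statistic` (rank sum of `a`), `p_value`
#'   and `method`.
#' @export
ranksum_compare <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  n1 <- length(a)
  n2 <- length(b)
  ranks <- rank(c(a, b))
  w <- sum(ranks[seq_len(n1)])
  if (choose(n1 + n2, n1) <= 2e5) {
    sums <- combn(ranks, n1, sum)
    p <- min(1, 2 * min(mean(sums <= w + 1e-9), mean(sums >= w - 1e-9)))
    method <- "exact enumeration"
  } else {
    mu <- n1 * (n1 + n2 + 1) / 2
    ties <- table(ranks)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- 2 * pnorm(-z)
    method <- "normal approximation"
  }
  tibble(statistic = w, p_value = p, method = method)
}

#' Topology against degree-preserving random graphs
#'
#' Compares a network's global topology to `n_reps` Maslov-Sneppen
#' rewirings: mean betweenness, average clustering, assortativity, diameter
#' (largest component), modularity of a Louvain partition, and mean degree.
#' Reports a z-score per metric. The rewiring preserves degrees exactly, so
#' the mean-degree null has zero spread and its z-score is NA by
#' construction; structured networks typically show large z-scores for
#' betweenness, clustering, assortativity, and modularity.
#'
#' @param net An `igraph` network.
#' @param n_reps Number of rewired replicates (default 200).
#' @param seed Integer seed.
#' @return A tibble with columns `metric`, `observed`, `null_mean`,
#'   `null_sd`, `z`.
#' @export
topology_vs_null <- function(net, n_reps = 200, seed = 1L) {
  assert_network(net)
  metric_row <- function(g, s) {
    gm <- global_metrics(g)
    part <- louvain_partition(g, seed = s)
    c(
      mean_degree = gm$average_degree,
      mean_betweenness = mean(igraph::betweenness(g, directed = FALSE)),
      average_clustering = gm$average_clustering,
      assortativity = gm$assortativity,
      diameter = gm$diameter,
      modularity = attr(part, "modularity")
    )
  }
  observed <- metric_row(net, as.integer(seed))
  draws <- matrix(NA_real_, nrow = n_reps, ncol = length(observed),
                  dimnames = list(NULL, names(observed)))
  for (r in seq_len(n_reps)) {
    g <- maslov_sneppen(net, seed = as.integer(seed) + 104729L + r)
    draws[r, ] <- metric_row(g, as.integer(seed))
  }
  null_mean <- colMeans(draws)
  null_sd <- apply(draws, 2, sd)
  tibble(
    metric = names(observed),
    observed = as.numeric(observed),
    null_mean = as.numeric(null_mean),
    null_sd = as.numeric(null_sd),
    z = ifelse(null_sd > 0, (observed - null_mean) / null_sd, NA_real_)
  )
}
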