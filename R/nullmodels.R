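#' Maslov-Sneppen degree-preserving rewiring
#'
#' Randomizes a network's wiring while keeping every node's degree exactly:
#' each swap attempt draws two distinct edges and exchanges endpoints;
#' attempts that would create a self-loop or multi-edge are rejected and
#' leave the graph unchanged. Attempts — not successes — count toward
#' `n_swaps`, whose default is four times the edge count. Graphs admitting
#' no valid swap at all (e.g. a triangle) come back unchanged and flagged
#' `saturated`.
#'
#' @param net An `igraph` network with at least 2 edges.
#' @param n_swaps Number of swap attempts (default `4 * ecount(net)`).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so callers can manage their own streams).
#' @return A rewired `igraph` network with identical degree sequence,
#'   carrying attributes `swap_attempts`, `swap_successes`, `saturated`.
#' @export
maslov_sneppen <- function(net, n_swaps = NULL, seed = NULL) {
  assert_network(net)
  m <- igraph::ecount(net)
  if (m < 2) stop("rewiring needs at least 2 edges", call. = FALSE)
  if (is.null(n_swaps)) n_swaps <- 4 * m
  if (!is.null(seed)) set.seed(as.integer(seed))
  el <- igraph::as_edgelist(net, names = FALSE)
  res <- ms_rewire_cpp(as.integer(el[, 1]), as.integer(el[, 2]),
                       igraph::vcount(net), as.numeric(n_swaps))
  out <- igraph::graph_from_edgelist(cbind(res$from, res$to), directed = FALSE)
  out <- igraph::add_vertices(out, max(0, igraph::vcount(net) - igraph::vcount(out)))
  igraph::V(out)$name <- igraph::V(net)$name
  gname <- igraph::graph_attr(net, "name")
  if (!is.null(gname)) out <- igraph::set_graph_attr(out, "name", gname)
  # degree preservation is an invariant, not a hope
  stopifnot(identical(igraph::degree(out), igraph::degree(net)))
  attr(out, "swap_attempts") <- n_swaps
  attr(out, "swap_successes") <- res$successes
  attr(out, "saturated") <- res$successes == 0 && n_swaps > 0
  out
}

new_null_distribution <- function(statistic, samples) {
  structure(
    list(statistic = statistic, samples = as.numeric(samples),
         mean = mean(samples), sd = sd(samples), n_reps = length(samples)),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> ", x$statistic, ": mean ",
      signif(x$mean, 4), ", sd ", signif(x$sd, 4),
      " over ", x$n_reps, " randomizations\n", sep = "")
  invisible(x)
}

#' Randomized-intersection null distribution
#'
#' For each repetition every input network is independently rewired with the
#' Maslov-Sneppen model (4x its edge count swap attempts), the rewired
#' networks are intersected, and the intersection's link count and gene
#' count (distinct endpoints of the surviving shared links) are recorded.
#' The resulting distributions quantify how many shared genes and links
#' arise by chance among networks with the observed degree sequences.
#'
#' @param nets List of at least 2 `igraph` networks.
#' @param n_reps Number of randomization repetitions (default 200).
#' @param seed Integer seed; each (network, repetition) pair draws from its
#'   own derived stream, so results do not depend on evaluation order.
#' @param n_swaps Swap attempts per rewiring (default 4x each network's
#'   edge count).
#' @return A list with `genes` and `links`, each a `null_distribution`.
#' @export
intersection_null <- function(nets, n_reps = 200, seed = 1L, n_swaps = NULL) {
  stopifnot(is.list(nets), length(nets) >= 2)
  lapply(nets, assert_network)
  genes <- numeric(n_reps)
  links <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    rewired <- lapply(seq_along(nets), function(k) {
      maslov_sneppen(nets[[k]], n_swaps = n_swaps,
                     seed = as.integer(seed) + 7919L * r + 131L * k)
    })
    inter <- intersect_networks(rewired, quiet = TRUE)
    genes[r] <- igraph::vcount(inter)
    links[r] <- igraph::ecount(inter)
  }
  list(
    genes = new_null_distribution("shared genes", genes),
    links = new_null_distribution("shared links", links)
  )
}

#' Z-score of an observation against a null distribution
#'
#' @param observed Observed value.
#' @param null A `null_distribution` (or any list with `mean` and `sd`).
#' @return `(observed - mean) / sd`.
#' @export
null_zscore <- function(observed, null) {
  if (is.null(null$sd) || is.na(null$sd) || null$sd == 0) {
    stop("null distribution has zero spread; z-score undefined", call. = FALSE)
  }
  (observed - null$mean) / null$sd
}

#' Size-matched random partition
#'
#' Permutes gene labels uniformly at random across the cluster slots of an
#' existing partition, preserving the multiset of cluster sizes exactly (and
#' leaving the underlying network untouched). This is the null model for
#' functional-coherence comparisons: random clusters with identical numbers
#' of genes.
#'
#' @param p A [gene_partition()].
#' @param seed Optional integer seed.
#' @return A `gene_partition` with the same cluster sizes and permuted
#'   membership.
#' @export
random_partition <- function(p, seed = NULL) {
  stopifnot(inherits(p, "gene_partition"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  shuffled <- p
  shuffled$gene <- sample(p$gene)
  attr(shuffled, "method") <- paste0(attr(p, "method") %||% "partition",
                                     "+permuted")
  attr(shuffled, "modularity") <- NA_real_
  shuffled
}
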