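#' Intersect networks into a consensus network
#'
#' The consensus (conserved) network keeps exactly the edges present in
#' every input network; its node set is the set of endpoints of the
#' surviving edges (node labels shared without any shared edge carry no
#' co-expression evidence and are dropped). The operation is associative,
#' commutative, and idempotent.
#'
#' @param nets List of at least 2 `igraph` networks.
#' @param name Name for the consensus network.
#' @param quiet Suppress the empty-intersection warning.
#' @return An `igraph` network (possibly empty, with a warning).
#' @export
intersect_networks <- function(nets, name = "consensus", quiet = FALSE) {
  stopifnot(is.list(nets), length(nets) >= 2)
  lapply(nets, assert_network)
  keys <- lapply(nets, edge_keys)
  shared <- Reduce(intersect, keys)
  if (length(shared) == 0) {
    if (!quiet) warning("networks share no edges; consensus is empty",
                        call. = FALSE)
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(igraph::set_graph_attr(g, "name", name))
  }
  el <- do.call(rbind, strsplit(shared, "|", fixed = TRUE))
  gene_network(el, name = name)
}

#' Pairwise and all-way overlap between networks
#'
#' Counts shared gene labels and shared links for every pair of networks,
#' plus the all-way intersection (whose gene count follows the consensus
#' convention: endpoints of edges shared by all networks).
#'
#' @param nets Named list of at least 2 `igraph` networks (names default to
#'   `net1`, `net2`, ...).
#' @return A tibble with columns `network_a`, `network_b`, `shared_genes`,
#'   `shared_links`; the final row (`all`, `all`) holds the all-way counts.
#' @export
pairwise_overlap <- function(nets) {
  stopifnot(is.list(nets), length(nets) >= 2)
  lapply(nets, assert_network)
  if (is.null(names(nets))) names(nets) <- paste0("net", seq_along(nets))
  keys <- lapply(nets, edge_keys)
  nodes <- lapply(nets, function(g) igraph::V(g)$name)
  pairs <- combn(seq_along(nets), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    tibble(
      network_a = names(nets)[i],
      network_b = names(nets)[j],
      shared_genes = length(intersect(nodes[[i]], nodes[[j]])),
      shared_links = length(intersect(keys[[i]], keys[[j]]))
    )
  })
  cons <- intersect_networks(nets, quiet = TRUE)
  rows[[length(rows) + 1L]] <- tibble(
    network_a = "all", network_b = "all",
    shared_genes = igraph::vcount(cons),
    shared_links = igraph::ecount(cons)
  )
  dplyr::bind_rows(rows)
}

#' Project networks onto principal components of their degree profiles
#'
#' Forms the networks-by-common-genes degree matrix (common genes = node
#' labels present in every network), centres each gene column, and projects
#' every network onto the first two principal axes (singular value
#' decomposition; no variance scaling, since degrees share a scale and
#' scaling would erase connectivity-magnitude differences). Component signs
#' are fixed by making each axis's largest-magnitude loading positive, so
#' coordinates are fully deterministic.
#'
#' @param nets Named list of at least 3 `igraph` networks.
#' @return A tibble of class `degree_pca` with columns `network`, `PC1`,
#'   `PC2`, carrying attributes `explained_variance` (fractions per
#'   component) and `common_genes`.
#' @export
degree_profile_pca <- function(nets) {
  stopifnot(is.list(nets), length(nets) >= 3)
  lapply(nets, assert_network)
  if (is.null(names(nets))) names(nets) <- paste0("net", seq_along(nets))
  common <- Reduce(intersect, lapply(nets, function(g) igraph::V(g)$name))
  if (length(common) < 2) {
    stop("fewer than 2 genes common to all networks", call. = FALSE)
  }
  deg <- t(vapply(nets, function(g) {
    as.numeric(igraph::degree(g)[common])
  }, numeric(length(common))))
  pc <- prcomp(deg, center = TRUE, scale. = FALSE)
  rot <- pc$rotation
  scores <- pc$x
  for (k in seq_len(min(2, ncol(rot)))) {
    if (rot[which.max(abs(rot[, k])), k] < 0) {
      rot[, k] <- -rot[, k]
      scores[, k] <- -scores[, k]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  out <- tibble(
    network = names(nets),
    PC1 = unname(scores[, 1]),
    PC2 = if (ncol(scores) >= 2) unname(scores[, 2]) else 0
  )
  attr(out, "explained_variance") <- ev
  attr(out, "common_genes") <- common
  class(out) <- c("degree_pca", class(out))
  out
}

#' Best-match Jaccard overlap between two partitions
#'
#' For every cluster of `p1` with more than `min_size` genes, reports the
#' maximal Jaccard coefficient \eqn{|A \cap B| / |A \cup B|} over the
#' clusters of `p2`. Used to quantify how well gene modules are preserved
#' between two consensus networks (for instance with and without normal
#' samples).
#'
#' @param p1,p2 [gene_partition()] objects (gene universes may differ).
#' @param min_size Only `p1` clusters with strictly more genes are scored.
#' @return A tibble with columns `cluster`, `size`, `best_match`, `jaccard`.
#' @export
partition_overlap_jaccard <- function(p1, p2, min_size = 10) {
  stopifnot(inherits(p1, "gene_partition"), inherits(p2, "gene_partition"))
  sets1 <- split(p1$gene, p1$cluster)
  sets1 <- sets1[lengths(sets1) > min_size]
  sets2 <- split(p2$gene, p2$cluster)
  if (length(sets1) == 0) {
    return(tibble(cluster = character(), size = integer(),
                  best_match = character(), jaccard = numeric()))
  }
  rows <- lapply(names(sets1), function(cl) {
    a <- sets1[[cl]]
    j <- vapply(sets2, function(b) {
      length(intersect(a, b)) / length(union(a, b))
    }, numeric(1))
    best <- which.max(j)
    tibble(cluster = cl, size = length(a),
           best_match = names(sets2)[best], jaccard = unname(j[best]))
  })
  dplyr::bind_rows(rows)
}

#' Map a gene set into a reference interactome
#'
#' Intersects a gene set with the nodes of a reference network (for
#' instance a protein-protein interaction network) and extracts the induced
#' subnetwork among the mapped genes.
#'
#' @param reference Reference `igraph` network.
#' @param genes Non-empty character vector of gene identifiers.
#' @return A list with `mapped` (genes found in the reference),
#'   `subnetwork` (reference edges with both endpoints mapped),
#'   `mapped_fraction`, and `n_interactions`.
#' @export
map_gene_set <- function(reference, genes) {
  assert_network(reference, "reference")
  genes <- unique(as.character(genes))
  if (length(genes) == 0) stop("empty gene set", call. = FALSE)
  mapped <- intersect(genes, igraph::V(reference)$name)
  sub <- igraph::induced_subgraph(reference, mapped)
  list(
    mapped = mapped,
    subnetwork = sub,
    mapped_fraction = length(mapped) / length(genes),
    n_interactions = igraph::ecount(sub)
  )
}
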