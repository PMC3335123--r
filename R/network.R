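#' Build a gene network from an edge table
#'
#' Networks are represented as undirected simple [igraph][igraph::igraph]
#' graphs whose vertex names are gene identifiers. Construction always
#' simplifies: self-loops are dropped (with a message counting them) and
#' duplicate or reversed-duplicate edges collapse to a single undirected edge.
#'
#' @param edges Two-column data frame, matrix, or tibble of gene-id pairs.
#' @param nodes Optional character vector of additional node labels to carry
#'   as isolated vertices (by default only edge endpoints become nodes).
#' @param name Optional network name, stored as the graph attribute `name`.
#' @return An undirected simple `igraph` graph.
#' @examples
#' g <- gene_network(data.frame(from = c("a", "b"), to = c("b", "c")))
#' igraph::vcount(g)
#' @export
gene_network <- function(edges, nodes = NULL, name = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) {
    stop("`edges` must have two columns of gene identifiers", call. = FALSE)
  }
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  loops <- a == b
  if (any(loops)) {
    message("dropped ", sum(loops), " self-loop(s)")
    a <- a[!loops]
    b <- b[!loops]
  }
  verts <- unique(c(a, b, as.character(nodes)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = verts
  )
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (!is.null(name)) g <- igraph::set_graph_attr(g, "name", name)
  g
}

#' Edge table of a network
#'
#' Returns the edge set as a tibble with endpoints ordered lexicographically
#' within each row and rows sorted, so two graphs with equal edge sets yield
#' identical tables.
#'
#' @param net An `igraph` network with named vertices.
#' @return A tibble with columns `from` and `to`.
#' @export
edge_tibble <- function(net) {
  stopifnot(igraph::is_igraph(net))
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) == 0) {
    return(tibble(from = character(), to = character()))
  }
  swap <- el[, 1] > el[, 2]
  el[swap, ] <- el[swap, 2:1]
  out <- tibble(from = el[, 1], to = el[, 2])
  dplyr::arrange(out, .data$from, .data$to)
}

# canonical sorted "a|b" keys for undirected edges, used for set operations
edge_keys <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) == 0) return(character())
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|"))
}

assert_network <- function(net, arg = "net") {
  if (!igraph::is_igraph(net)) {
    stop("`", arg, "` must be an igraph network", call. = FALSE)
  }
  if (is.null(igraph::V(net)$name)) {
    stop("`", arg, "` must have named vertices (gene ids)", call. = FALSE)
  }
  invisible(net)
}
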