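#' Pairwise Pearson correlation matrix of gene expression
#'
#' Computes the product-moment correlation between every pair of gene
#' expression vectors (rows). Genes with constant expression have undefined
#' correlations and are excluded with a message; an all-constant matrix is
#' an error.
#'
#' @param m Expression matrix (genes x samples) with gene rownames, or a
#'   data frame whose first column holds gene ids.
#' @return Symmetric correlation matrix with unit diagonal and attribute
#'   `n_samples`; excluded constant genes are listed in attribute
#'   `excluded_genes`.
#' @export
correlation_matrix <- function(m) {
  m <- as_expression_matrix(m)
  if (ncol(m) < 3) stop("need at least 3 samples for correlations", call. = FALSE)
  sds <- apply(m, 1, sd)
  constant <- sds == 0 | is.na(sds)
  if (all(constant)) stop("all genes have constant expression", call. = FALSE)
  if (any(constant)) {
    message("excluding ", sum(constant), " constant gene(s)")
    m <- m[!constant, , drop = FALSE]
  }
  r <- cor(t(m))
  diag(r) <- 1
  attr(r, "n_samples") <- ncol(m)
  attr(r, "excluded_genes") <- rownames(m)[constant][FALSE] # placeholder shape
  attr(r, "excluded_genes") <- names(which(constant))
  class(r) <- c("correlation_matrix", class(r))
  r
}

# accept matrix or gene-column data frame
as_expression_matrix <- function(m) {
  if (is.matrix(m)) {
    stopifnot(!is.null(rownames(m)))
    return(m)
  }
  if (is.data.frame(m)) {
    ids <- as.character(m[[1]])
    out <- as.matrix(m[, -1, drop = FALSE])
    rownames(out) <- ids
    return(out)
  }
  stop("expression input must be a matrix or data frame", call. = FALSE)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact t reference distribution:
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on \eqn{n-2} degrees of freedom.
#' Boundary correlations (|r| = 1) return p = 0 and are flagged in the
#' `boundary` attribute.
#'
#' @param r Correlation value(s) in \[-1, 1\].
#' @param n Sample count (at least 3).
#' @return Two-sided p-value(s), same length as `r`.
#' @export
pcc_pvalue <- function(r, n) {
  stopifnot(all(abs(r) <= 1 + 1e-12), n >= 3)
  r <- pmin(1, pmax(-1, r))
  boundary <- abs(r) == 1
  p <- numeric(length(r))
  t <- r[!boundary] * sqrt(n - 2) / sqrt(1 - r[!boundary]^2)
  p[!boundary] <- 2 * pt(-abs(t), df = n - 2)
  p[boundary] <- 0
  attr(p, "boundary") <- boundary
  p
}

#' Threshold a correlation matrix into a relevance network
#'
#' Gene pairs correlated above `tau` become edges of an undirected,
#' unweighted network. `mode = "signed"` (default) keeps pairs with
#' \eqn{r \ge \tau}; `mode = "absolute"` keeps \eqn{|r| \ge \tau}. Genes
#' left without any edge are excluded from the node set.
#'
#' @param c A [correlation_matrix()] (or any symmetric matrix with gene
#'   dimnames).
#' @param tau Correlation threshold in \[0, 1\].
#' @param mode `"signed"` or `"absolute"`.
#' @param name Optional network name.
#' @return An `igraph` network.
#' @export
build_network <- function(c, tau, mode = c("signed", "absolute"), name = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(c), tau >= 0, tau <= 1)
  vals <- if (mode == "absolute") abs(c) else c
  idx <- which(upper.tri(vals) & vals >= tau, arr.ind = TRUE)
  genes <- rownames(c)
  el <- cbind(genes[idx[, 1]], genes[idx[, 2]])
  if (nrow(el) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    if (!is.null(name)) g <- igraph::set_graph_attr(g, "name", name)
    return(g)
  }
  gene_network(el, name = name)
}

#' Scan correlation thresholds against degree-preserving nulls
#'
#' The automated threshold-selection procedure: over a grid of correlation
#' cutoffs in \[0.50, 1.0\], build the real network, record its average
#' clustering coefficient, rewire it `rewires` times with the
#' Maslov-Sneppen model (4x the edge count swap attempts each) and record
#' the mean clustering coefficient of the rewired graphs. Structured data
#' yield a positive difference (real minus random) because thresholding
#' correlated modules creates triangles that rewiring destroys; the selected
#' cutoff is the first local maximum of that difference (see
#' [select_threshold()]).
#'
#' Grid points whose network has fewer than 3 edges record a difference of
#' zero and are flagged.
#'
#' @param m Expression matrix (genes x samples), or a precomputed
#'   [correlation_matrix()].
#' @param grid_step Grid spacing (default 0.01).
#' @param grid Optional explicit threshold grid inside \[0.5, 1\];
#'   overrides `grid_step`.
#' @param rewires Rewired replicates per grid point.
#' @param mode Thresholding mode, see [build_network()].
#' @param seed Integer seed for the rewirings.
#' @return A tibble of class `threshold_scan` with columns `threshold`,
#'   `n_nodes`, `n_edges`, `c_real`, `c_rand`, `diff`, `flagged`.
#' @export
threshold_scan <- function(m, grid_step = 0.01, grid = NULL, rewires = 10,
                           mode = c("signed", "absolute"), seed = 1L) {
  mode <- match.arg(mode)
  cmat <- if (inherits(m, "correlation_matrix")) m else correlation_matrix(m)
  if (is.null(grid)) {
    grid <- seq(0.5, 1, by = grid_step)
  }
  if (any(grid < 0.5 - 1e-9) || any(grid > 1 + 1e-9)) {
    stop("threshold grid must lie within [0.50, 1.0]", call. = FALSE)
  }
  grid <- sort(unique(grid))
  set.seed(as.integer(seed))
  rows <- lapply(grid, function(tau) {
    g <- build_network(cmat, tau, mode = mode)
    ne <- igraph::ecount(g)
    if (ne < 3) {
      return(tibble(threshold = tau, n_nodes = igraph::vcount(g),
                    n_edges = ne, c_real = NA_real_, c_rand = NA_real_,
                    diff = 0, flagged = TRUE))
    }
    c_real <- avg_clustering(g)
    c_rand <- mean(vapply(seq_len(rewires), function(i) {
      avg_clustering(maslov_sneppen(g))
    }, numeric(1)))
    tibble(threshold = tau, n_nodes = igraph::vcount(g), n_edges = ne,
           c_real = c_real, c_rand = c_rand, diff = c_real - c_rand,
           flagged = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  if (all(out$flagged)) {
    stop("no grid threshold yields a network with 3 or more edges",
         call. = FALSE)
  }
  class(out) <- c("threshold_scan", class(out))
  out
}

# mean local clustering coefficient, nodes of degree < 2 counted as 0
avg_clustering <- function(g) {
  if (igraph::vcount(g) == 0) return(NA_real_)
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Select the correlation threshold from a scan
#'
#' Picks the smallest grid point that is an interior local maximum of the
#' real-minus-random clustering difference: strictly above its left
#' neighbour and at least its right neighbour (endpoints are ineligible).
#' If no interior local maximum exists, falls back on the argmax of the
#' difference and flags it.
#'
#' @param scan A [threshold_scan()].
#' @return A list with `threshold`, `diff` (its difference value) and
#'   `fallback` (logical).
#' @export
select_threshold <- function(scan) {
  stopifnot(inherits(scan, "threshold_scan"))
  d <- scan$diff
  k <- length(d)
  if (k < 3 || length(unique(d)) == 1) {
    stop("degenerate scan: no usable difference curve", call. = FALSE)
  }
  for (i in 2:(k - 1)) {
    if (d[i - 1] < d[i] && d[i] >= d[i + 1]) {
      return(list(threshold = scan$threshold[i], diff = d[i], fallback = FALSE))
    }
  }
  i <- which.max(d)
  list(threshold = scan$threshold[i], diff = d[i], fallback = TRUE)
}
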