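#' Tidy a power-law fit
#'
#' @param x A [powerlaw_fit()] object.
#' @param ... Unused.
#' @return One row per fitted quantity (`alpha`, `xmin`).
#' @method tidy powerlaw_fit
#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble(term = c("alpha", "xmin"), estimate = c(x$alpha, x$xmin))
}

#' One-row summary of a power-law fit
#'
#' @param x A [powerlaw_fit()] object.
#' @param ... Unused.
#' @method glance powerlaw_fit
#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble(alpha = x$alpha, xmin = x$xmin, n_tail = x$n_tail, n = x$n,
         ks_distance = x$ks_distance, p_value = x$p_value, n_boot = x$n_boot)
}

#' Tidy a null distribution into its samples
#'
#' @param x A `null_distribution`.
#' @param ... Unused.
#' @method tidy null_distribution
#' @export
tidy.null_distribution <- function(x, ...) {
  tibble(rep = seq_len(x$n_reps), value = x$samples)
}

#' One-row summary of a null distribution
#'
#' @param x A `null_distribution`.
#' @param ... Unused.
#' @method glance null_distribution
#' @export
glance.null_distribution <- function(x, ...) {
  tibble(statistic = x$statistic, mean = x$mean, sd = x$sd, n_reps = x$n_reps)
}

#' Gene-to-cluster table of a partition
#'
#' @param x A [gene_partition()].
#' @param ... Unused.
#' @method tidy gene_partition
#' @export
tidy.gene_partition <- function(x, ...) {
  tibble(gene = x$gene, cluster = x$cluster)
}

#' One-row summary of a partition
#'
#' @param x A [gene_partition()].
#' @param ... Unused.
#' @method glance gene_partition
#' @export
glance.gene_partition <- function(x, ...) {
  sizes <- table(x$cluster)
  tibble(
    method = attr(x, "method") %||% NA_character_,
    n_genes = nrow(x),
    n_clusters = length(sizes),
    largest_cluster = max(sizes),
    smallest_cluster = min(sizes),
    modularity = attr(x, "modularity") %||% NA_real_
  )
}

#' Scan table of a threshold scan
#'
#' @param x A [threshold_scan()].
#' @param ... Unused.
#' @method tidy threshold_scan
#' @export
tidy.threshold_scan <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "threshold_scan")
  as_tibble(out)
}

#' One-row summary of a threshold scan
#'
#' Includes the selected threshold (first interior local maximum of the
#' real-minus-random clustering difference).
#'
#' @param x A [threshold_scan()].
#' @param ... Unused.
#' @method glance threshold_scan
#' @export
glance.threshold_scan <- function(x, ...) {
  sel <- select_threshold(x)
  tibble(
    n_grid = nrow(x),
    grid_min = min(x$threshold),
    grid_max = max(x$threshold),
    selected_threshold = sel$threshold,
    selected_diff = sel$diff,
    fallback = sel$fallback
  )
}
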