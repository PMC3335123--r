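#' Describe planted co-expression modules
#'
#' Helper building the module table used by [synthetic_config()]. Each row
#' plants one module: a block of genes driven by a shared latent factor so
#' that the expected pairwise Pearson correlation within the block equals
#' `within_corr`.
#'
#' @param size Integer vector of module sizes (genes per module).
#' @param within_corr Target within-module Pearson correlation, in (0, 1].
#'   Recycled against `size`.
#' @param condition `"all"` (factor active in every sample, the default) or
#'   `"normal"` (factor active only in the designated normal samples, so the
#'   module's co-expression is contributed by normal tissue).
#' @return A tibble with columns `size`, `within_corr`, `condition`.
#' @export
modules_spec <- function(size, within_corr, condition = "all") {
  stopifnot(length(size) >= 1)
  out <- tibble(
    size = as.integer(size),
    within_corr = as.numeric(within_corr),
    condition = as.character(condition)
  )
  if (any(out$size < 2)) {
    stop("module sizes must be at least 2", call. = FALSE)
  }
  if (any(out$within_corr <= 0 | out$within_corr > 1)) {
    stop("`within_corr` must lie in (0, 1]", call. = FALSE)
  }
  if (!all(out$condition %in% c("all", "normal"))) {
    stop("`condition` must be \"all\" or \"normal\"", call. = FALSE)
  }
  out
}

#' Configuration for the multi-study synthetic expression generator
#'
#' Defines a set of studies sharing a common catalogue of planted
#' co-expression modules. Shared modules use identical gene labels in every
#' study (their within-module edges are the ground truth a consensus analysis
#' should recover); private modules are re-planted with study-specific labels
#' in each study and can never recur across studies; remaining genes are
#' independent noise present in all studies under common labels.
#'
#' Defaults emulate a three-study design of moderately sized cohorts
#' (100 samples each) with strongly co-expressed modules
#' (within-module correlation 0.9) embedded among independent genes.
#'
#' @param n_studies Number of studies (at least 2).
#' @param n_genes Genes per study matrix; must accommodate all modules.
#' @param n_samples Samples per study (at least 4).
#' @param shared_modules Module table from [modules_spec()]; planted with the
#'   same gene labels in every study.
#' @param private_modules Module table re-planted per study with
#'   study-specific labels. `NULL` for none.
#' @param noise_sd Standard deviation of the independent noise added to
#'   module genes and used for non-module genes.
#' @param n_normal Number of leading samples per study designated "normal";
#'   modules with `condition = "normal"` co-express only within these.
#' @param seed Integer seed; every generated object is a deterministic
#'   function of the configuration.
#' @return A list of class `synthetic_config`.
#' @examples
#' cfg <- synthetic_config(n_studies = 3, n_genes = 60, n_samples = 50,
#'                         shared_modules = modules_spec(10, 0.9))
#' @export
synthetic_config <- function(n_studies = 3,
                             n_genes = 150,
                             n_samples = 100,
                             shared_modules = modules_spec(c(20, 15), 0.9),
                             private_modules = modules_spec(15, 0.9),
                             noise_sd = 1,
                             n_normal = 0,
                             seed = 1L) {
  stopifnot(n_studies >= 2, n_samples >= 4, n_genes >= 1, noise_sd >= 0)
  empty_spec <- tibble(size = integer(), within_corr = numeric(),
                       condition = character())
  if (is.null(shared_modules)) shared_modules <- empty_spec
  if (is.null(private_modules)) private_modules <- empty_spec
  used <- sum(shared_modules$size) + sum(private_modules$size)
  if (used > n_genes) {
    stop("module sizes sum to ", used, " which exceeds n_genes = ", n_genes,
         call. = FALSE)
  }
  if (n_normal < 0 || n_normal > n_samples) {
    stop("`n_normal` must lie in [0, n_samples]", call. = FALSE)
  }
  if (any(c(shared_modules$condition, private_modules$condition) == "normal") &&
      n_normal < 4) {
    stop("modules with condition \"normal\" require n_normal >= 4",
         call. = FALSE)
  }
  structure(
    list(
      n_studies = as.integer(n_studies),
      n_genes = as.integer(n_genes),
      n_samples = as.integer(n_samples),
      shared_modules = shared_modules,
      private_modules = private_modules,
      noise_sd = as.numeric(noise_sd),
      n_normal = as.integer(n_normal),
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# gene labels for one study's rows, in matrix order
study_gene_labels <- function(config, study_index) {
  sm <- config$shared_modules
  pm <- config$private_modules
  shared <- unlist(lapply(seq_len(nrow(sm)), function(i) {
    sprintf("GS%d_%d", i, seq_len(sm$size[i]))
  }))
  private <- unlist(lapply(seq_len(nrow(pm)), function(k) {
    sprintf("GP%d.%d_%d", study_index, k, seq_len(pm$size[k]))
  }))
  n_noise <- config$n_genes - length(shared) - length(private)
  noise <- if (n_noise > 0) sprintf("N%d", seq_len(n_noise)) else character()
  c(shared, private, noise)
}

# latent-factor block: expected pairwise PCC equals rho
# (weight w with w^2/(w^2 + sd^2) = rho; rho = 1 or sd = 0 collapse to the
# factor itself, giving exact unit correlations)
module_block <- function(size, rho, n_samples, noise_sd, active) {
  f <- rnorm(n_samples)
  if (rho >= 1 || noise_sd == 0) {
    block <- matrix(rep(f, each = size), nrow = size)
    if (!all(active)) {
      block[, !active] <- rnorm(size * sum(!active))
    }
    return(block)
  }
  w <- noise_sd * sqrt(rho / (1 - rho))
  eps <- matrix(rnorm(size * n_samples, sd = noise_sd), nrow = size)
  block <- matrix(rep(w * f, each = size), nrow = size) + eps
  if (!all(active)) {
    # outside the active samples the factor is silent: independent noise only
    block[, !active] <- eps[, !active]
  }
  block
}

#' Generate one study's expression matrix
#'
#' Draws a genes-by-samples matrix under the factor model described in
#' [synthetic_config()]. Each study uses its own random stream derived from
#' `(seed, study_index)`, so adding studies never perturbs earlier ones.
#'
#' @param config A [synthetic_config()].
#' @param study_index Which study to generate (1-based).
#' @return Numeric matrix (genes x samples) with gene-id rownames, sample-id
#'   colnames, and attributes `study_name` and `sample_condition`.
#' @export
generate_study <- function(config, study_index) {
  stopifnot(inherits(config, "synthetic_config"),
            study_index >= 1, study_index <= config$n_studies)
  set.seed(config$seed + 100003L * as.integer(study_index))
  n <- config$n_samples
  active_all <- rep(TRUE, n)
  condition <- rep(c("normal", "tumour"),
                   c(config$n_normal, n - config$n_normal))
  blocks <- list()
  specs <- rbind(config$shared_modules, config$private_modules)
  for (i in seq_len(nrow(specs))) {
    active <- if (specs$condition[i] == "normal") condition == "normal" else active_all
    blocks[[i]] <- module_block(specs$size[i], specs$within_corr[i], n,
                                config$noise_sd, active)
  }
  n_module_genes <- sum(specs$size)
  n_noise <- config$n_genes - n_module_genes
  if (n_noise > 0) {
    blocks[[length(blocks) + 1L]] <-
      matrix(rnorm(n_noise * n, sd = config$noise_sd), nrow = n_noise)
  }
  m <- do.call(rbind, blocks)
  rownames(m) <- study_gene_labels(config, study_index)
  colnames(m) <- sprintf("st%d_s%03d", study_index, seq_len(n))
  attr(m, "study_name") <- paste0("study", study_index)
  attr(m, "sample_condition") <- condition
  m
}

#' Generate all studies plus the planted ground truth
#'
#' @param config A [synthetic_config()].
#' @return A list with `studies` (named list of expression matrices) and
#'   `truth`, a `planted_truth` object holding module membership and the
#'   expected consensus edge set (all within-module pairs of shared modules).
#' @export
generate_multi_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  studies <- lapply(seq_len(config$n_studies), function(s) generate_study(config, s))
  names(studies) <- vapply(studies, attr, character(1), "study_name")

  sm <- config$shared_modules
  pm <- config$private_modules
  membership <- list()
  for (i in seq_len(nrow(sm))) {
    membership[[length(membership) + 1L]] <- tibble(
      gene = sprintf("GS%d_%d", i, seq_len(sm$size[i])),
      module_id = sprintf("S%d", i),
      shared = TRUE,
      condition = sm$condition[i]
    )
  }
  for (s in seq_len(config$n_studies)) {
    for (k in seq_len(nrow(pm))) {
      membership[[length(membership) + 1L]] <- tibble(
        gene = sprintf("GP%d.%d_%d", s, k, seq_len(pm$size[k])),
        module_id = sprintf("P%d.%d", s, k),
        shared = FALSE,
        condition = pm$condition[k]
      )
    }
  }
  membership <- dplyr::bind_rows(membership)

  edges <- membership |>
    dplyr::filter(.data$shared) |>
    dplyr::group_by(.data$module_id) |>
    dplyr::reframe(as_pair_tibble(.data$gene)) |>
    dplyr::select("from", "to")

  truth <- structure(
    list(membership = membership, edges = edges),
    class = "planted_truth"
  )
  list(studies = studies, truth = truth)
}

# all unordered pairs of a gene vector, lexicographically oriented
as_pair_tibble <- function(genes) {
  if (length(genes) < 2) return(tibble(from = character(), to = character()))
  p <- combn(sort(genes), 2)
  tibble(from = p[1, ], to = p[2, ])
}

#' Annotation catalogue matched to a planted truth
#'
#' Emits one functional term per planted module (its exact gene set) plus
#' optional random "noise" terms with sizes drawn uniformly in \[5, 50\],
#' sampled from the planted gene universe. Used to test that partitions
#' recovering the planted modules score higher functional coherence than
#' size-matched random partitions.
#'
#' @param truth A `planted_truth` from [generate_multi_study()].
#' @param n_noise_terms Number of random terms to add.
#' @param seed Integer seed for the noise terms.
#' @param namespace Namespace label stored on every term.
#' @return An [annotation_catalog()] tibble.
#' @export
generate_annotations <- function(truth, n_noise_terms = 0, seed = 1L,
                                 namespace = "synthetic") {
  stopifnot(inherits(truth, "planted_truth"), nrow(truth$membership) > 0)
  mods <- split(truth$membership$gene, truth$membership$module_id)
  cat <- annotation_catalog(
    term_id = names(mods),
    term_name = paste0("planted module ", names(mods)),
    genes = unname(mods),
    namespace = namespace
  )
  if (n_noise_terms > 0) {
    set.seed(as.integer(seed))
    universe <- unique(truth$membership$gene)
    sizes <- sample(5:min(50, length(universe)), n_noise_terms, replace = TRUE)
    noise <- annotation_catalog(
      term_id = sprintf("RAND%d", seq_len(n_noise_terms)),
      term_name = sprintf("random term %d", seq_len(n_noise_terms)),
      genes = lapply(sizes, function(k) sample(universe, k)),
      namespace = namespace
    )
    cat <- dplyr::bind_rows(cat, noise)
  }
  cat
}

#' Sample integer degrees from a discrete power law
#'
#' Draws from \eqn{p(x) \propto x^{-\alpha}} for integer \eqn{x \ge x_{min}},
#' normalized by the Hurwitz zeta function, via inverse-CDF lookup. Far tail
#' quantiles beyond the lookup table fall back on the continuous
#' approximation \eqn{x = \lfloor (x_{min}-1/2)(1-u)^{-1/(\alpha-1)} + 1/2 \rfloor}.
#'
#' @param alpha Scaling exponent, must exceed 1 (else non-normalizable).
#' @param xmin Lower cut-off of the support (integer, at least 1).
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Integer vector of length `n`, all values `>= xmin`.
#' @export
sample_powerlaw_degrees <- function(alpha, xmin = 1L, n, seed = 1L) {
  if (alpha <= 1) {
    stop("`alpha` must exceed 1 for a normalizable discrete power law",
         call. = FALSE)
  }
  stopifnot(xmin >= 1, n >= 1)
  xmin <- as.integer(xmin)
  set.seed(as.integer(seed))
  u <- runif(n)
  z <- hurwitz_zeta(alpha, xmin)
  # grow the CDF table until it covers the largest uniform draw
  width <- 1024L
  repeat {
    xs <- xmin:(xmin + width - 1L)
    cdf <- cumsum(xs^(-alpha)) / z
    if (max(u) <= cdf[width] || width >= 2^20) break
    width <- width * 2L
  }
  idx <- findInterval(u, cdf, left.open = TRUE) + 1L
  out <- xmin + idx - 1L
  over <- idx > width
  if (any(over)) {
    out[over] <- as.integer(floor(
      (xmin - 0.5) * (1 - u[over])^(-1 / (alpha - 1)) + 0.5
    ))
  }
  out
}
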