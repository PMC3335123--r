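pipeline_defaults <- function() {
  list(
    synthetic = NULL,    # list of synthetic_config() arguments
    studies = NULL,      # list of {path, name} for expression TSVs
    samples = list(keep = NULL),  # e.g. "tumour" to drop normal samples
    inference = list(mode = "signed", threshold = NULL, grid_step = 0.01,
                     rewires = 10, seed = 11L),
    consensus_null = list(n_reps = 200L, seed = 21L),
    powerlaw = list(n_boot = 1000L, seed = 41L),
    clustering = list(method = "louvain", inflation = 2, seed = 51L),
    annotations = list(gmt = NULL, n_noise_terms = 0L, seed = 61L,
                       min_size = 5L, max_size = 50L),
    coherence = list(n_random = 100L, seed = 71L),
    enrichment = list(min_cluster_size = 10L, adjust = "per_cluster")
  )
}

#' Assemble a pipeline configuration
#'
#' Merges user settings over the documented defaults. Accepts either a
#' nested list or a path to a YAML file with the same structure. Exactly
#' one of `synthetic` (arguments for [synthetic_config()]) or `studies`
#' (expression table paths) must be supplied.
#'
#' @param config Nested list or YAML file path.
#' @return A validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  merged <- utils::modifyList(pipeline_defaults(), config)
  if (is.null(merged$synthetic) == is.null(merged$studies)) {
    stop("supply exactly one of `synthetic` or `studies`", call. = FALSE)
  }
  structure(merged, class = c("pipeline_config", "list"))
}

as_modules_spec <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) return(x)
  # YAML list of {size, within_corr, condition}
  modules_spec(
    size = vapply(x, function(m) as.integer(m$size), integer(1)),
    within_corr = vapply(x, function(m) as.numeric(m$within_corr), numeric(1)),
    condition = vapply(x, function(m) m$condition %||% "all", character(1))
  )
}

stage_log <- function(stage, t0, ...) {
  message(sprintf("[%s] %s (%.1fs)", stage, paste0(...),
                  as.numeric(proc.time()[3] - t0)))
}

#' Run the full consensus co-expression analysis
#'
#' Orchestrates the complete study: load or simulate expression matrices;
#' infer a relevance network per study (automated threshold selection
#' unless a fixed threshold is configured); intersect into the consensus
#' network; measure the randomized-intersection null and z-scores; compute
#' global topology per network; fit the consensus degree distribution to a
#' discrete power law; partition the consensus network; score functional
#' coherence against size-matched random partitions; run hypergeometric
#' enrichment per cluster. Deterministic under the configured seeds.
#'
#' @param config A [pipeline_config()] (or anything it accepts).
#' @param out_dir Optional directory; when given, every table, network, and
#'   a JSON manifest of all parameters and summary numbers are written
#'   there.
#' @return A list with elements `networks`, `thresholds`, `consensus`,
#'   `overlap`, `null`, `zscores`, `metrics`, `powerlaw`, `partition`,
#'   `coherence`, `enrichment`, `truth` (synthetic runs only), and
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  t0 <- proc.time()[3]
  truth <- NULL

  if (!is.null(cfg$synthetic)) {
    syn <- cfg$synthetic
    syn$shared_modules <- as_modules_spec(syn$shared_modules)
    syn$private_modules <- as_modules_spec(syn$private_modules)
    scfg <- do.call(synthetic_config, syn)
    gen <- generate_multi_study(scfg)
    studies <- gen$studies
    truth <- gen$truth
    stage_log("simulate", t0, length(studies), " studies of ",
              scfg$n_genes, " genes x ", scfg$n_samples, " samples")
  } else {
    studies <- lapply(cfg$studies, function(s) {
      read_expression_table(s$path, study_name = s$name %||% basename(s$path))
    })
    names(studies) <- vapply(studies, attr, character(1), "study_name")
    stage_log("load", t0, length(studies), " expression tables")
  }

  if (!is.null(cfg$samples$keep)) {
    studies <- lapply(studies, function(m) {
      cond <- attr(m, "sample_condition")
      if (is.null(cond)) return(m)
      kept <- m[, cond %in% cfg$samples$keep, drop = FALSE]
      attr(kept, "study_name") <- attr(m, "study_name")
      attr(kept, "sample_condition") <- cond[cond %in% cfg$samples$keep]
      kept
    })
    stage_log("subset", t0, "kept condition: ",
              paste(cfg$samples$keep, collapse = ","))
  }

  inf <- cfg$inference
  thresholds <- list()
  networks <- list()
  for (nm in names(studies)) {
    cmat <- correlation_matrix(studies[[nm]])
    if (!is.null(inf$threshold)) {
      tau <- inf$threshold
      thresholds[[nm]] <- tibble(network = nm, threshold = tau,
                                 fallback = NA, fixed = TRUE)
    } else {
      scan <- threshold_scan(cmat, grid_step = inf$grid_step,
                             rewires = inf$rewires, mode = inf$mode,
                             seed = inf$seed)
      sel <- select_threshold(scan)
      tau <- sel$threshold
      thresholds[[nm]] <- tibble(network = nm, threshold = tau,
                                 fallback = sel$fallback, fixed = FALSE)
    }
    networks[[nm]] <- build_network(cmat, tau, mode = inf$mode, name = nm)
    stage_log("infer", t0, nm, ": tau = ", format(tau), ", ",
              igraph::ecount(networks[[nm]]), " edges")
  }
  thresholds <- dplyr::bind_rows(thresholds)

  consensus <- intersect_networks(networks, quiet = TRUE)
  overlap <- pairwise_overlap(networks)
  stage_log("consensus", t0, igraph::vcount(consensus), " genes, ",
            igraph::ecount(consensus), " links")

  nullres <- NULL
  zscores <- NULL
  if (cfg$consensus_null$n_reps > 0 &&
      all(vapply(networks, igraph::ecount, numeric(1)) >= 2)) {
    nullres <- intersection_null(networks, n_reps = cfg$consensus_null$n_reps,
                                 seed = cfg$consensus_null$seed)
    zscores <- tibble(
      statistic = c("genes", "links"),
      observed = c(igraph::vcount(consensus), igraph::ecount(consensus)),
      null_mean = c(nullres$genes$mean, nullres$links$mean),
      null_sd = c(nullres$genes$sd, nullres$links$sd),
      z = c(
        if (nullres$genes$sd > 0) null_zscore(igraph::vcount(consensus), nullres$genes) else NA_real_,
        if (nullres$links$sd > 0) null_zscore(igraph::ecount(consensus), nullres$links) else NA_real_
      )
    )
    stage_log("null", t0, cfg$consensus_null$n_reps, " randomized intersections")
  }

  all_nets <- c(networks, list(consensus = consensus))
  metrics <- dplyr::bind_rows(lapply(names(all_nets), function(nm) {
    g <- all_nets[[nm]]
    if (igraph::vcount(g) == 0) return(NULL)
    dplyr::mutate(global_metrics(g), network = nm, .before = 1)
  }))
  stage_log("topology", t0, nrow(metrics), " network summaries")

  pl <- NULL
  if (igraph::vcount(consensus) >= 10) {
    pl <- tryCatch(
      powerlaw_fit(igraph::degree(consensus),
                   n_boot = cfg$powerlaw$n_boot, seed = cfg$powerlaw$seed),
      error = function(e) {
        stage_log("powerlaw", t0, "skipped: ", conditionMessage(e))
        NULL
      }
    )
    if (!is.null(pl)) {
      stage_log("powerlaw", t0, "alpha = ", signif(pl$alpha, 3),
                ", xmin = ", pl$xmin, ", p = ", format(pl$p_value))
    }
  }

  partition <- NULL
  coherence <- NULL
  enrichment <- NULL
  if (igraph::ecount(consensus) >= 3) {
    partition <- switch(
      cfg$clustering$method,
      louvain = louvain_partition(consensus, seed = cfg$clustering$seed),
      mcl = mcl_partition(consensus, inflation = cfg$clustering$inflation),
      stop("unknown clustering method: ", cfg$clustering$method, call. = FALSE)
    )
    stage_log("partition", t0, attr(partition, "n_clusters"),
              " clusters, Q = ", signif(attr(partition, "modularity"), 3))

    cat <- if (!is.null(cfg$annotations$gmt)) {
      read_gmt(cfg$annotations$gmt)
    } else if (!is.null(truth)) {
      generate_annotations(truth, n_noise_terms = cfg$annotations$n_noise_terms,
                           seed = cfg$annotations$seed)
    } else {
      NULL
    }
    if (!is.null(cat)) {
      fcat <- filter_terms(cat, igraph::V(consensus)$name,
                           min_size = cfg$annotations$min_size,
                           max_size = cfg$annotations$max_size)
      if (nrow(fcat) > 0) {
        coherence <- coherence_vs_random(consensus, partition, fcat,
                                         n_random = cfg$coherence$n_random,
                                         seed = cfg$coherence$seed)
        enrichment <- enrich_clusters(partition, fcat,
                                      reference = igraph::V(consensus)$name,
                                      min_size = cfg$enrichment$min_cluster_size,
                                      adjust = cfg$enrichment$adjust)
        stage_log("function", t0, nrow(fcat), " terms after size filter")
      }
    }
  }

  manifest <- list(
    package = "consnet",
    version = as.character(utils::packageVersion("consnet")),
    config = unclass(cfg),
    summary = list(
      studies = names(studies),
      thresholds = as.list(setNames(thresholds$threshold, thresholds$network)),
      consensus_genes = igraph::vcount(consensus),
      consensus_links = igraph::ecount(consensus),
      zscores = if (!is.null(zscores)) as.list(setNames(zscores$z, zscores$statistic)),
      powerlaw = if (!is.null(pl)) list(alpha = pl$alpha, xmin = pl$xmin,
                                        p_value = pl$p_value),
      n_clusters = if (!is.null(partition)) attr(partition, "n_clusters"),
      modularity = if (!is.null(partition)) attr(partition, "modularity")
    )
  )

  result <- list(
    networks = networks, thresholds = thresholds, consensus = consensus,
    overlap = overlap, null = nullres, zscores = zscores, metrics = metrics,
    powerlaw = pl, partition = partition, coherence = coherence,
    enrichment = enrichment, truth = truth, manifest = manifest
  )

  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, out_dir)
    stage_log("write", t0, "outputs in ", out_dir)
  }
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(out_dir, paste0(...))
  for (nm in names(result$networks)) {
    write_edge_list(result$networks[[nm]], path(nm, ".edges"))
  }
  if (igraph::ecount(result$consensus) > 0) {
    write_edge_list(result$consensus, path("consensus.edges"))
  }
  readr::write_tsv(result$thresholds, path("thresholds.tsv"), progress = FALSE)
  readr::write_tsv(result$overlap, path("overlap.tsv"), progress = FALSE)
  readr::write_tsv(result$metrics, path("metrics.tsv"), progress = FALSE)
  if (!is.null(result$zscores)) {
    readr::write_tsv(result$zscores, path("null_zscores.tsv"), progress = FALSE)
  }
  if (!is.null(result$powerlaw)) {
    readr::write_tsv(glance(result$powerlaw), path("powerlaw.tsv"),
                     progress = FALSE)
  }
  if (!is.null(result$partition)) {
    readr::write_tsv(tidy(result$partition), path("partition.tsv"),
                     progress = FALSE)
  }
  if (!is.null(result$coherence)) {
    readr::write_tsv(result$coherence, path("coherence.tsv"), progress = FALSE)
  }
  if (!is.null(result$enrichment)) {
    readr::write_tsv(result$enrichment, path("enrichment.tsv"), progress = FALSE)
  }
  jsonlite::write_json(result$manifest, path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}
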