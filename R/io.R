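#' Read a gene expression table
#'
#' Expects a delimited text file (tab or comma) with a header row of sample
#' identifiers and one gene (or probe) per row, first column holding the row
#' identifier and the remaining columns numeric log-scale intensities.
#'
#' @param path File path.
#' @param study_name Optional study label stored on the result.
#' @return Numeric matrix (genes x samples) with `study_name` and
#'   `has_duplicates` attributes. Duplicate row identifiers are retained
#'   (pending [collapse_probes_median()]) and flagged.
#' @export
read_expression_table <- function(path, study_name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("empty expression file: ", path, call. = FALSE)
  delim <- if (grepl("\t", first)) "\t" else ","
  header <- strsplit(first, delim, fixed = TRUE)[[1]][-1]
  if (anyDuplicated(header)) {
    stop("duplicate sample ids: ",
         paste(unique(header[duplicated(header)]), collapse = ", "),
         call. = FALSE)
  }
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE)
  if (ncol(df) < 2) stop("expression table needs id + sample columns", call. = FALSE)
  ids <- as.character(df[[1]])
  samples <- colnames(df)[-1]
  body <- df[, -1, drop = FALSE]
  numeric_ok <- vapply(body, is.numeric, logical(1))
  if (!all(numeric_ok)) {
    # locate offending rows for an identifying error
    bad_rows <- unique(unlist(lapply(body[!numeric_ok], function(col) {
      which(is.na(suppressWarnings(as.numeric(as.character(col)))))
    })))
    stop("non-numeric expression values in row(s): ",
         paste(head(ids[bad_rows], 10), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  attr(m, "study_name") <- study_name %||% basename(path)
  attr(m, "has_duplicates") <- anyDuplicated(ids) > 0
  m
}

#' Write an expression matrix as TSV
#'
#' First column `gene`, then one column per sample. Round-trips losslessly
#' through [read_expression_table()].
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_expression_table <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- tibble::as_tibble(m, rownames = "gene")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Collapse probe-level rows to genes by the median
#'
#' Where several probes map to one gene, each sample's value becomes the
#' median of that gene's probe intensities (the mean of the two central
#' values for even probe counts — the standard `median` convention).
#' Single-probe genes pass through unchanged.
#'
#' @param m Probe-level matrix (probes x samples).
#' @param probe_map Data frame with columns `probe_id` and `gene_id`
#'   (many probes to one gene).
#' @return Gene-level matrix with unique gene rownames, rows ordered by
#'   first appearance of each gene among the probes.
#' @export
collapse_probes_median <- function(m, probe_map) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  probe_map <- as.data.frame(probe_map)
  if (!all(c("probe_id", "gene_id") %in% colnames(probe_map))) {
    colnames(probe_map)[1:2] <- c("probe_id", "gene_id")
  }
  if (anyDuplicated(probe_map$probe_id)) {
    stop("probe map assigns some probes to more than one gene", call. = FALSE)
  }
  idx <- match(rownames(m), probe_map$probe_id)
  if (anyNA(idx)) {
    stop("unmapped probe id(s): ",
         paste(head(rownames(m)[is.na(idx)], 10), collapse = ", "),
         call. = FALSE)
  }
  gene <- probe_map$gene_id[idx]
  groups <- split(seq_len(nrow(m)), factor(gene, levels = unique(gene)))
  out <- vapply(groups, function(rows) {
    if (length(rows) == 1L) m[rows, ] else apply(m[rows, , drop = FALSE], 2, median)
  }, numeric(ncol(m)))
  out <- t(out)
  colnames(out) <- colnames(m)
  attr(out, "study_name") <- attr(m, "study_name")
  attr(out, "has_duplicates") <- FALSE
  out
}

#' Read a two-column edge list into a network
#'
#' Lines are whitespace- or tab-delimited gene-id pairs; blank lines and
#' `#` comments are skipped. A first line whose two fields look like column
#' labels (`from`/`to`, `source`/`target`, `gene1`/`gene2`, `node1`/`node2`)
#' is treated as a header. Self-loops are dropped with a message; duplicate
#' and reversed-duplicate pairs collapse to one undirected edge.
#'
#' @param path File path.
#' @param name Optional network name.
#' @return An undirected simple `igraph` network.
#' @export
read_edge_list <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("empty edge list: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "[\t ]+")
  bad <- which(lengths(fields) != 2)
  if (length(bad) > 0) {
    stop("malformed edge at line ", lineno[bad[1]], ": ", lines[bad[1]],
         call. = FALSE)
  }
  el <- do.call(rbind, fields)
  header_like <- c("from", "to", "source", "target", "gene1", "gene2",
                   "node1", "node2", "a", "b", "gene_a", "gene_b")
  if (nrow(el) > 0 && all(tolower(el[1, ]) %in% header_like)) {
    el <- el[-1, , drop = FALSE]
  }
  if (nrow(el) == 0) stop("edge list has a header but no edges: ", path,
                          call. = FALSE)
  gene_network(el, name = name %||% basename(path))
}

#' Write a network as a two-column edge list
#'
#' Tab-separated, endpoints lexicographically ordered, no header; round-trips
#' exactly through [read_edge_list()] (isolated vertices are not preserved by
#' the format).
#'
#' @param net An `igraph` network.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  assert_network(net)
  et <- edge_tibble(net)
  readr::write_tsv(et, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Construct an annotation catalogue
#'
#' A catalogue maps functional terms (for instance Gene Ontology Biological
#' Process terms or pathway identifiers) to gene sets. Stored as a tibble
#' with a list-column of gene sets so it composes with the usual verbs.
#'
#' @param term_id Unique term identifiers.
#' @param term_name Human-readable term names.
#' @param genes List of character vectors (one gene set per term); duplicate
#'   genes within a set are removed.
#' @param namespace Namespace label per term (e.g. `"BP"`, `"CC"`,
#'   `"pathway"`), recycled.
#' @return A tibble of class `annotation_catalog` with columns `term_id`,
#'   `term_name`, `namespace`, `n_genes`, `genes`.
#' @export
annotation_catalog <- function(term_id, term_name = term_id, genes,
                               namespace = NA_character_) {
  stopifnot(length(term_id) == length(genes))
  if (anyDuplicated(term_id)) {
    stop("term ids must be unique", call. = FALSE)
  }
  genes <- lapply(genes, function(g) unique(as.character(g)))
  if (any(lengths(genes) == 0)) {
    stop("gene sets must be non-empty", call. = FALSE)
  }
  out <- tibble(
    term_id = as.character(term_id),
    term_name = as.character(term_name),
    namespace = rep_len(as.character(namespace), length(term_id)),
    n_genes = lengths(genes),
    genes = genes
  )
  class(out) <- c("annotation_catalog", class(out))
  out
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated `term`, `description`,
#' then gene identifiers. Empty gene fields are skipped with a message;
#' duplicate genes within a line count once.
#'
#' @param path File path.
#' @param namespace Namespace label applied to every term in the file.
#' @return An [annotation_catalog()].
#' @export
read_gmt <- function(path, namespace = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    stop("GMT line ", bad[1], " has fewer than 3 fields", call. = FALSE)
  }
  n_empty <- 0L
  genes <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    empty <- !nzchar(trimws(g))
    n_empty <<- n_empty + sum(empty)
    unique(g[!empty])
  })
  if (n_empty > 0) message("skipped ", n_empty, " empty gene field(s)")
  annotation_catalog(
    term_id = vapply(fields, `[[`, character(1), 1),
    term_name = vapply(fields, `[[`, character(1), 2),
    genes = genes,
    namespace = namespace
  )
}

#' Write an annotation catalogue as GMT
#'
#' @param cat An [annotation_catalog()].
#' @param path Output path.
#' @export
write_gmt <- function(cat, path) {
  stopifnot(inherits(cat, "annotation_catalog"))
  lines <- vapply(seq_len(nrow(cat)), function(i) {
    paste(c(cat$term_id[i], cat$term_name[i], cat$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
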