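# graph fixtures built in code

clique_edges <- function(ids) {
  p <- combn(ids, 2)
  cbind(p[1, ], p[2, ])
}

make_clique <- function(n, prefix = "g", offset = 0) {
  gene_network(clique_edges(paste0(prefix, seq_len(n) + offset)))
}

# n_cliques cliques of `size` nodes joined into a ring by single bridges
ring_of_cliques <- function(n_cliques = 4, size = 5, prefix = "g") {
  blocks <- lapply(seq_len(n_cliques) - 1, function(k) {
    clique_edges(paste0(prefix, k * size + seq_len(size)))
  })
  last <- seq_len(n_cliques) * size
  first <- (seq_len(n_cliques) - 1) * size + 1
  bridges <- cbind(paste0(prefix, last),
                   paste0(prefix, first[c(2:n_cliques, 1)]))
  gene_network(rbind(do.call(rbind, blocks), bridges))
}

# ring of cliques with heterogeneous sizes: modular AND degree-assortative,
# so every structure metric has a non-degenerate rewired null
mixed_clique_ring <- function(sizes = c(4, 5, 6, 7, 8), prefix = "g") {
  offs <- cumsum(c(0, head(sizes, -1)))
  blocks <- mapply(function(s, o) clique_edges(paste0(prefix, o + seq_len(s))),
                   sizes, offs, SIMPLIFY = FALSE)
  last <- cumsum(sizes)
  first <- offs + 1
  bridges <- cbind(paste0(prefix, last),
                   paste0(prefix, first[c(2:length(sizes), 1)]))
  gene_network(rbind(do.call(rbind, blocks), bridges))
}

# ten planted 10-gene modules as cliques; with many modules a random label
# permutation co-clusters mostly cross-module gene pairs, and a 100-gene
# universe keeps the random [5,50]-sized noise terms from annotating most
# of it (the size filter presumes terms much smaller than the universe),
# so planted partitions separate cleanly from size-matched random ones
planted_function_fixture <- function(seed = 8, n_noise_terms = 4) {
  cfg <- synthetic_config(n_studies = 2, n_genes = 100, n_samples = 20,
                          shared_modules = modules_spec(rep(10, 10), 0.9),
                          private_modules = NULL, seed = seed)
  truth <- generate_multi_study(cfg)$truth
  mem <- truth$membership
  net <- gene_network(do.call(rbind, lapply(split(mem$gene, mem$module_id),
                                            clique_edges)))
  planted <- gene_partition(mem$gene, mem$module_id, method = "truth",
                            net = net)
  cat <- generate_annotations(truth, n_noise_terms = n_noise_terms,
                              seed = seed + 1)
  list(truth = truth, net = net, partition = planted, catalog = cat)
}

er_network <- function(n, m, seed, prefix = "g") {
  set.seed(seed)
  g <- igraph::sample_gnm(n, m)
  igraph::V(g)$name <- paste0(prefix, seq_len(n))
  g
}

path_network <- function(ids) {
  gene_network(cbind(ids[-length(ids)], ids[-1]))
}

# documented location for the user-supplied consensus edge-list export
# (supplementary co-expression network exported from XLS to two-column TSV)
conserved_net_path <- function() {
  system.file("extdata", "conserved_net_edges.tsv", package = "consnet")
}
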