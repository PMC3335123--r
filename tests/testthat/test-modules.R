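test_that("Louvain recovers planted communities and their modularity", {
  two <- gene_network(rbind(clique_edges(paste0("a", 1:5)),
                            clique_edges(paste0("b", 1:5))))
  p <- louvain_partition(two, seed = 1)
  expect_equal(attr(p, "n_clusters"), 2)
  expect_equal(attr(p, "modularity"), 0.5)
  # a complete graph cannot be improved by splitting
  k6 <- make_clique(6)
  expect_equal(attr(louvain_partition(k6, seed = 1), "n_clusters"), 1)
  # ring of 4 bridged 5-cliques: the cliques are the communities
  ring <- ring_of_cliques(4, 5)
  pr <- louvain_partition(ring, seed = 2)
  expect_equal(attr(pr, "n_clusters"), 4)
  sets <- split(pr$gene, pr$cluster)
  expect_setequal(vapply(sets, length, integer(1)), rep(5L, 4))
})

test_that("Louvain is deterministic per seed and stable in modularity across seeds", {
  g <- ring_of_cliques(4, 5)
  p1 <- louvain_partition(g, seed = 5)
  p2 <- louvain_partition(g, seed = 5)
  expect_identical(tidy(p1), tidy(p2))
  qs <- vapply(1:10, function(s) {
    attr(louvain_partition(g, seed = s), "modularity")
  }, numeric(1))
  expect_lt(diff(range(qs)), 0.02)
})

test_that("stored partition modularity agrees with the modularity operation", {
  g <- ring_of_cliques(3, 4)
  for (p in list(louvain_partition(g, seed = 1), mcl_partition(g))) {
    expect_equal(attr(p, "modularity"), modularity_q(g, p), tolerance = 1e-10)
  }
})

test_that("MCL splits flow-separated structures", {
  two_tri <- gene_network(rbind(clique_edges(paste0("a", 1:3)),
                                clique_edges(paste0("b", 1:3))))
  p <- mcl_partition(two_tri)
  expect_equal(attr(p, "n_clusters"), 2)
  # two 4-cliques joined by a single bridge split at the bridge
  bridged <- gene_network(rbind(clique_edges(paste0("a", 1:4)),
                                clique_edges(paste0("b", 1:4)),
                                c("a4", "b1")))
  pb <- mcl_partition(bridged, inflation = 2)
  expect_equal(attr(pb, "n_clusters"), 2)
  sets <- split(pb$gene, pb$cluster)
  expect_setequal(vapply(sets, function(s) paste(sort(substr(s, 1, 1)), collapse = ""),
                         character(1)),
                  c("aaaa", "bbbb"))
  expect_error(mcl_partition(bridged, inflation = 1), "inflation")
})

test_that("higher inflation never coarsens MCL partitions on fixed fixtures", {
  fixtures <- list(ring_of_cliques(3, 5), ring_of_cliques(4, 4),
                   er_network(25, 60, seed = 17))
  for (g in fixtures) {
    counts <- vapply(c(1.5, 2, 3, 4), function(inf) {
      attr(mcl_partition(g, inflation = inf), "n_clusters")
    }, integer(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("term filtering counts sizes in-universe with inclusive bounds", {
  universe <- paste0("g", 1:100)
  cat <- annotation_catalog(
    term_id = c("small", "atMin", "atMax", "big", "bigOutside"),
    genes = list(paste0("g", 1:4), paste0("g", 1:5), paste0("g", 1:50),
                 paste0("g", 1:60),
                 c(paste0("g", 1:40), paste0("x", 1:20)))
  )
  kept <- filter_terms(cat, universe)
  expect_setequal(kept$term_id, c("atMin", "atMax", "bigOutside"))
  # 60 genes but only 40 in-universe: kept because size is counted in-universe
  expect_equal(kept$n_genes[kept$term_id == "bigOutside"], 40L)
})

test_that("edge-wise functional Jaccard follows the set arithmetic", {
  net <- gene_network(rbind(c("u", "v"), c("u", "w")))
  p <- gene_partition(c("u", "v", "w"), c("c1", "c1", "c2"))
  # terms(u) = {A,B,C}; terms(v) = {A,B,D}; w unannotated
  cat <- annotation_catalog(
    term_id = c("A", "B", "C", "D"),
    genes = list(c("u", "v"), c("u", "v"), "u", "v"),
    namespace = "BP"
  )
  res <- pairwise_functional_jaccard(net, p, cat)
  expect_equal(res$n_pairs, 1L)          # u-w crosses clusters, v-w no edge
  expect_equal(res$mean_jaccard, 2 / 4)  # {A,B} shared of {A,B,C,D}
  # identical annotation sets score 1, disjoint sets 0
  cat1 <- annotation_catalog(c("A", "B", "C"), genes = rep(list(c("u", "v")), 3))
  expect_equal(pairwise_functional_jaccard(net, p, cat1)$mean_jaccard, 1)
  cat0 <- annotation_catalog(c("A", "B"), genes = list("u", "v"))
  expect_equal(pairwise_functional_jaccard(net, p, cat0)$mean_jaccard, 0)
  # no annotated same-cluster edge: flagged as NA, not zero
  catw <- annotation_catalog("A", genes = list("w"))
  res_na <- pairwise_functional_jaccard(net, p, catw)
  expect_true(is.na(res_na$mean_jaccard))
  expect_equal(res_na$n_pairs, 0L)
})

test_that("planted annotations give high coherence folds; independent ones do not", {
  fx <- planted_function_fixture(seed = 8)
  res <- coherence_vs_random(fx$net, fx$partition, fx$catalog,
                             n_random = 40, seed = 10)
  expect_gt(res$fold, 2)
  expect_lt(res$p_empirical, 0.05)

  # annotations drawn independently of the partition: fold hovers around 1
  folds <- vapply(1:20, function(s) {
    set.seed(9000 + s)
    rand_cat <- annotation_catalog(
      term_id = sprintf("R%d", 1:8),
      genes = lapply(1:8, function(i) sample(fx$truth$membership$gene, 8)),
      namespace = "null"
    )
    coherence_vs_random(fx$net, fx$partition, rand_cat, n_random = 20,
                        seed = 100 + s)$fold
  }, numeric(1))
  expect_gt(mean(folds), 0.8)
  expect_lt(mean(folds), 1.25)
})

test_that("hypergeometric p-values match exhaustive tail enumeration", {
  # closed case: N=10, K=5, n=4, k=4 -> C(5,4)C(5,0)/C(10,4) = 5/210
  ref <- paste0("g", 1:10)
  cat <- annotation_catalog("T", genes = list(paste0("g", 1:5)))
  res <- hypergeometric_enrichment(paste0("g", 1:4), cat, ref)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)

  # randomized small fixtures against a from-scratch enumeration oracle
  tail_oracle <- function(N, K, n, k) {
    js <- k:min(n, K)
    sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
  }
  set.seed(33)
  for (rep in 1:20) {
    N <- sample(8:20, 1)
    refs <- paste0("g", 1:N)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    term <- sample(refs, K)
    cluster <- sample(refs, N)[1:n]
    cat_i <- annotation_catalog("T", genes = list(term))
    got <- hypergeometric_enrichment(cluster, cat_i, refs)
    k <- length(intersect(cluster, term))
    expect_equal(got$p_value, tail_oracle(N, K, n, k), tolerance = 1e-12)
    expect_lte(got$k, min(got$n, got$K))
  }

  # forced overlap: cluster = reference makes every term's p exactly 1
  catm <- annotation_catalog(c("T1", "T2"),
                             genes = list(paste0("g", 1:5), paste0("g", 3:9)))
  all_ref <- hypergeometric_enrichment(ref, catm, ref)
  expect_true(all(all_ref$p_value == 1))
  expect_true(all(all_ref$k == all_ref$K))
})

test_that("Benjamini-Hochberg adjustment keeps its fixed point and monotonicity", {
  ref <- paste0("g", 1:30)
  # identical gene sets -> identical p-values -> q = p (BH fixed point)
  cat <- annotation_catalog(paste0("T", 1:4),
                            genes = rep(list(paste0("g", 1:6)), 4))
  res <- hypergeometric_enrichment(paste0("g", 1:5), cat, ref)
  expect_equal(res$q_value, res$p_value)
  # q ordering follows p ordering
  set.seed(44)
  cat2 <- annotation_catalog(paste0("U", 1:8),
                             genes = lapply(1:8, function(i) sample(ref, 5 + i)))
  res2 <- hypergeometric_enrichment(paste0("g", 1:8), cat2, ref)
  expect_true(all(diff(res2$q_value[order(res2$p_value)]) >= -1e-12))
  expect_true(all(res2$q_value >= res2$p_value - 1e-12))
})

test_that("enrichment p-values are super-uniform under label permutation", {
  ref <- paste0("g", 1:40)
  term <- paste0("g", 1:10)
  cat <- annotation_catalog("T", genes = list(term))
  set.seed(55)
  ps <- vapply(1:1000, function(i) {
    cl <- sample(ref, 8)
    hypergeometric_enrichment(cl, cat, ref)$p_value
  }, numeric(1))
  expect_lte(mean(ps <= 0.05), 0.08)
  expect_lte(mean(ps <= 0.2), 0.25)
})

test_that("cluster-wise enrichment respects the size floor and global adjustment", {
  cfg <- synthetic_config(n_studies = 2, n_genes = 40, n_samples = 20,
                          shared_modules = modules_spec(c(15, 12), 0.9),
                          private_modules = NULL, seed = 12)
  truth <- generate_multi_study(cfg)$truth
  p <- gene_partition(truth$membership$gene, truth$membership$module_id)
  cat <- generate_annotations(truth, n_noise_terms = 3, seed = 13)
  res <- enrich_clusters(p, cat, min_size = 10)
  expect_setequal(unique(res$cluster), c("S1", "S2"))  # both exceed 10 genes
  # each planted cluster is most enriched for its own term
  top <- dplyr::slice_min(dplyr::group_by(res, cluster), p_value, n = 1)
  expect_equal(sort(top$term_id), sort(unique(res$cluster)))
  resg <- enrich_clusters(p, cat, min_size = 10, adjust = "global")
  expect_true(all(resg$q_value >= resg$p_value - 1e-12))
})
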