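test_that("zero-noise limit gives exact unit within-module correlations", {
  cfg <- synthetic_config(n_studies = 2, n_genes = 10, n_samples = 20,
                          shared_modules = modules_spec(10, 1.0),
                          private_modules = NULL, noise_sd = 0, seed = 7)
  m <- generate_study(cfg, 1)
  r <- cor(t(m))
  expect_true(all(abs(r - 1) < 1e-12))
  # rank-1 block: every gene identical to the latent factor
  expect_equal(qr(m)$rank, 1)
})

test_that("factor model calibrates the expected within-module correlation", {
  # closed-form oracle: with weight w = sd * sqrt(rho/(1-rho)), the model
  # correlation is w^2/(w^2 + sd^2) = rho; Monte-Carlo average should sit
  # within +/-0.05 of the target at n = 100 samples
  rho <- 0.8
  means <- vapply(1:50, function(s) {
    cfg <- synthetic_config(n_studies = 2, n_genes = 22, n_samples = 100,
                            shared_modules = modules_spec(20, rho),
                            private_modules = NULL, seed = s)
    m <- generate_study(cfg, 1)
    r <- cor(t(m[sprintf("GS1_%d", 1:20), ]))
    mean(r[upper.tri(r)])
  }, numeric(1))
  expect_lt(abs(mean(means) - rho), 0.05)
})

test_that("genes in different modules are uncorrelated on average", {
  vals <- vapply(1:50, function(s) {
    cfg <- synthetic_config(n_studies = 2, n_genes = 10, n_samples = 50,
                            shared_modules = modules_spec(c(5, 5), 0.9),
                            private_modules = NULL, seed = 1000 + s)
    m <- generate_study(cfg, 1)
    cor(m["GS1_1", ], m["GS2_1", ])
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("multi-study generation shares labels, plants truth, and is deterministic", {
  cfg <- synthetic_config(n_studies = 3, n_genes = 20, n_samples = 30,
                          shared_modules = modules_spec(10, 0.9),
                          private_modules = NULL, seed = 11)
  gen1 <- generate_multi_study(cfg)
  gen2 <- generate_multi_study(cfg)
  # one shared module of 10 -> C(10,2) = 45 expected consensus edges
  expect_equal(nrow(gen1$truth$edges), 45)
  shared_genes <- gen1$truth$membership$gene
  for (m in gen1$studies) expect_true(all(shared_genes %in% rownames(m)))
  # byte-identical under a fixed seed
  expect_identical(gen1$studies, gen2$studies)
  expect_identical(gen1$truth, gen2$truth)
})

test_that("private module labels never collide across studies", {
  cfg <- synthetic_config(n_studies = 3, n_genes = 40, n_samples = 20,
                          shared_modules = modules_spec(10, 0.9),
                          private_modules = modules_spec(c(8, 6), 0.8),
                          seed = 2)
  gen <- generate_multi_study(cfg)
  priv <- gen$truth$membership[!gen$truth$membership$shared, ]
  expect_equal(anyDuplicated(priv$gene), 0L)
  # each study's matrix contains its own private genes and nobody else's
  for (s in 1:3) {
    own <- priv$gene[grepl(sprintf("^GP%d\\.", s), priv$gene)]
    other <- setdiff(priv$gene, own)
    expect_true(all(own %in% rownames(gen$studies[[s]])))
    expect_false(any(other %in% rownames(gen$studies[[s]])))
  }
})

test_that("module sizes exceeding the gene budget are a configuration error", {
  expect_error(
    synthetic_config(n_genes = 10, shared_modules = modules_spec(c(8, 8), 0.9),
                     private_modules = NULL),
    "exceeds"
  )
})

test_that("generated annotation catalogs mirror the planted modules", {
  cfg <- synthetic_config(n_studies = 2, n_genes = 25, n_samples = 20,
                          shared_modules = modules_spec(c(10, 8), 0.9),
                          private_modules = NULL, seed = 3)
  truth <- generate_multi_study(cfg)$truth
  cat0 <- generate_annotations(truth, n_noise_terms = 0)
  expect_equal(nrow(cat0), 2)  # one term per planted module
  sizes <- sort(cat0$n_genes)
  expect_equal(sizes, c(8L, 10L))
  # a size-10 module passes the default <5 / >50 size filter
  kept <- filter_terms(cat0, truth$membership$gene)
  expect_true("S1" %in% kept$term_id)
  # noise terms respect the [5, 50] size range
  catn <- generate_annotations(truth, n_noise_terms = 10, seed = 4)
  noise <- catn[grepl("^RAND", catn$term_id), ]
  expect_equal(nrow(noise), 10)
  expect_true(all(noise$n_genes >= 5 & noise$n_genes <= 50))
})

test_that("planted partitions score higher functional Jaccard than size-matched random ones", {
  fx <- planted_function_fixture(seed = 5)
  real <- pairwise_functional_jaccard(fx$net, fx$partition,
                                      fx$catalog)$mean_jaccard
  rand <- vapply(1:20, function(s) {
    pairwise_functional_jaccard(fx$net, random_partition(fx$partition, seed = s),
                                fx$catalog)$mean_jaccard
  }, numeric(1))
  expect_true(all(real > rand))
})

test_that("discrete power-law sampler has the right support and mass at the origin", {
  d <- sample_powerlaw_degrees(2.5, xmin = 1, n = 10000, seed = 42)
  expect_true(all(d >= 1))
  # zeta-function oracle by partial summation: P(X = 1) = 1/zeta(2.5)
  zeta25 <- sum((1:200000)^(-2.5))
  expect_lt(abs(mean(d == 1) - 1 / zeta25), 0.02)
  # support shifts with xmin
  d3 <- sample_powerlaw_degrees(2.0, xmin = 3, n = 500, seed = 1)
  expect_true(all(d3 >= 3))
  # determinism
  expect_identical(d, sample_powerlaw_degrees(2.5, xmin = 1, n = 10000, seed = 42))
  expect_error(sample_powerlaw_degrees(1.0, 1, 10), "alpha")
})
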