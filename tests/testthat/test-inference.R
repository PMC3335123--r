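test_that("correlation matrix reproduces hand-computed coefficients", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4), c = c(4, 3, 2, 1))
  colnames(m) <- paste0("s", 1:4)
  r <- correlation_matrix(m)
  # product-moment formula by hand: cov = 1.0, sd_a = sd_b -> r = 0.8
  expect_equal(r["a", "b"], 0.8, tolerance = 1e-12)
  expect_equal(r["a", "c"], -1, tolerance = 1e-12)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_equal(attr(r, "n_samples"), 4)
  # perfect linear pair
  m2 <- rbind(x = c(1, 2, 3), y = c(2, 4, 6))
  colnames(m2) <- paste0("s", 1:3)
  expect_equal(correlation_matrix(m2)["x", "y"], 1)
})

test_that("correlation is invariant to per-gene affine rescaling", {
  set.seed(31)
  m <- matrix(rnorm(80), nrow = 8,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
  scaled <- m * runif(8, 0.5, 3) + rnorm(8)
  expect_equal(correlation_matrix(scaled)[, ], correlation_matrix(m)[, ],
               tolerance = 1e-12)
})

test_that("constant genes are excluded; degenerate inputs error", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5), c = c(2, 1, 4, 3))
  colnames(m) <- paste0("s", 1:4)
  expect_message(r <- correlation_matrix(m), "constant")
  expect_false("b" %in% rownames(r))
  expect_error(correlation_matrix(m[, 1:2]), "3 samples")
  allc <- rbind(a = rep(1, 4), b = rep(2, 4))
  colnames(allc) <- paste0("s", 1:4)
  expect_error(correlation_matrix(allc), "constant")
})

test_that("correlation p-values match an independent quadrature oracle", {
  expect_equal(pcc_pvalue(0, 10)[1], 1)
  p1 <- pcc_pvalue(1, 10)
  expect_equal(p1[1], 0)
  expect_true(attr(p1, "boundary"))
  # r = 0.5, n = 12: numerically integrate the t density on 10 df
  tval <- 0.5 * sqrt(10) / sqrt(1 - 0.25)
  oracle <- 2 * stats::integrate(function(x) stats::dt(x, df = 10),
                                 tval, Inf, rel.tol = 1e-10)$value
  expect_equal(pcc_pvalue(0.5, 12)[1], oracle, tolerance = 1e-6)
})

test_that("network construction matches brute-force pair enumeration", {
  set.seed(5)
  m <- matrix(rnorm(4 * 12), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:12)))
  r <- correlation_matrix(m)
  for (tau in c(0, 0.2, 0.5)) {
    g <- build_network(r, tau)
    expected <- 0L
    for (i in 1:3) for (j in (i + 1):4) {
      if (r[i, j] >= tau) expected <- expected + 1L
    }
    expect_equal(igraph::ecount(g), expected)
  }
  # absolute mode picks up strong negative correlations too
  ga <- build_network(r, 0.2, mode = "absolute")
  expect_gte(igraph::ecount(ga), igraph::ecount(build_network(r, 0.2)))
})

test_that("thresholding is monotone and prunes isolated genes", {
  set.seed(6)
  m <- matrix(rnorm(10 * 15), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:15)))
  r <- correlation_matrix(m)
  taus <- c(0.1, 0.3, 0.5, 0.7)
  nets <- lapply(taus, function(t) build_network(r, t))
  for (k in seq_len(length(taus) - 1)) {
    expect_true(all(edge_keys(nets[[k + 1]]) %in% edge_keys(nets[[k]])))
  }
  # every node retained has at least one edge
  for (g in nets) {
    if (igraph::vcount(g) > 0) expect_true(all(igraph::degree(g) >= 1))
  }
  # a single perfectly correlated pair at tau = 1
  m2 <- rbind(x = c(1, 2, 3, 5), y = c(2, 4, 6, 10), z = c(5, 1, 4, 2))
  colnames(m2) <- paste0("s", 1:4)
  g1 <- build_network(correlation_matrix(m2), 1)
  expect_equal(igraph::ecount(g1), 1)
  expect_setequal(igraph::V(g1)$name, c("x", "y"))
})

test_that("threshold scan honours grid bounds and flags sparse points", {
  cfg <- synthetic_config(n_studies = 2, n_genes = 40, n_samples = 30,
                          shared_modules = modules_spec(12, 0.75),
                          private_modules = NULL, seed = 21)
  m <- generate_study(cfg, 1)
  scan <- threshold_scan(m, grid = seq(0.5, 1, 0.1), rewires = 3, seed = 2)
  expect_gte(min(scan$threshold), 0.5)
  expect_lte(max(scan$threshold), 1.0)
  expect_true(all(scan$diff[scan$flagged] == 0))
  expect_true(all(scan$c_real[!scan$flagged] >= 0 &
                    scan$c_real[!scan$flagged] <= 1))
  expect_error(threshold_scan(m, grid = c(0.3, 0.6)), "within")
})

test_that("planted structure yields a positive clustering difference below the module correlation", {
  # module correlation 0.75 among 12 genes plus 28 noise genes at 30
  # samples: below the module correlation the real network mixes module
  # triangles with sporadic noise edges, which rewiring destroys
  diffs <- vapply(1:3, function(s) {
    cfg <- synthetic_config(n_studies = 2, n_genes = 40, n_samples = 30,
                            shared_modules = modules_spec(12, 0.75),
                            private_modules = NULL, seed = 100 + s)
    m <- generate_study(cfg, 1)
    scan <- threshold_scan(m, grid = c(0.55, 0.65), rewires = 5, seed = s)
    max(scan$diff)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("pure-noise data show no clustering excess anywhere on the grid", {
  worst <- vapply(1:10, function(s) {
    cfg <- synthetic_config(n_studies = 2, n_genes = 30, n_samples = 50,
                            shared_modules = NULL, private_modules = NULL,
                            seed = 500 + s)
    m <- generate_study(cfg, 1)
    scan <- tryCatch(
      threshold_scan(m, grid = seq(0.5, 0.7, 0.1), rewires = 5, seed = s),
      error = function(e) NULL
    )
    if (is.null(scan)) 0 else max(abs(scan$diff))
  }, numeric(1))
  expect_lt(mean(worst), 0.05)
})

test_that("threshold selection takes the first interior local maximum", {
  fake <- function(diff, grid = seq(0.5, by = 0.1, length.out = length(diff))) {
    out <- tibble::tibble(threshold = grid, n_nodes = 10, n_edges = 10,
                          c_real = NA_real_, c_rand = NA_real_,
                          diff = diff, flagged = FALSE)
    class(out) <- c("threshold_scan", class(out))
    out
  }
  # enumeration oracle: first k with d[k-1] < d[k] >= d[k+1] is index 2
  sel <- select_threshold(fake(c(0.10, 0.20, 0.15, 0.30, 0.05)))
  expect_equal(sel$threshold, 0.6)
  expect_false(sel$fallback)
  # strictly increasing curve: fall back on the last grid point
  sel2 <- select_threshold(fake(c(0.1, 0.2, 0.3, 0.4)))
  expect_equal(sel2$threshold, 0.8)
  expect_true(sel2$fallback)
  # a single interior peak is found
  sel3 <- select_threshold(fake(c(0.0, 0.1, 0.5, 0.1, 0.0)))
  expect_equal(sel3$threshold, 0.7)
  # flat curves are degenerate
  expect_error(select_threshold(fake(rep(0.2, 5))), "degenerate")
})
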