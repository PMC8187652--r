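test_that("signature construction enforces set arithmetic and validity", {
  ba <- build_ba_signature(up = c("h1", "h2"), down = "h3",
                           epithelial = c("h1", "h3"))
  expect_identical(ba$up_genes, "h1")
  expect_identical(ba$down_genes, "h3")
  # epithelial superset: identity on both components
  ba2 <- build_ba_signature(c("h1", "h2"), "h3", c("h1", "h2", "h3"))
  expect_setequal(ba2$up_genes, c("h1", "h2"))
  # empty down component is valid
  ba3 <- build_ba_signature("h1", character(), "h1")
  expect_length(ba3$down_genes, 0)
  expect_error(build_ba_signature("h1", "h2", epithelial = "h9"), "threshold")
  expect_error(signature_definition("S", "g1", "g1"), "disjoint")
  expect_error(signature_definition("S", character()), "non-empty")
})

test_that("correlation-distance clustering is symmetric and merges twins first", {
  x <- toy_two_pair_matrix()
  cl <- cluster_genes(x, clustering_config(k_range = 2:3))
  d <- cl$dist
  expect_equal(d, t(d), tolerance = 1e-12)
  expect_true(all(diag(d) < 1e-12))
  # identical profiles sit at distance ~0 and merge first
  twins <- rbind(x, a2 = x["a", ] * 2 + 1)  # perfectly correlated with a
  cl2 <- cluster_genes(twins, clustering_config(k_range = 2:4))
  expect_lt(cl2$dist["a", "a2"], 1e-12)
  expect_identical(cl2$tree$merge[1, ],
                   -match(c("a", "a2"), cl2$tree$labels))
  expect_error(cluster_genes(rbind(x, flat = rep(1, 5))), "flat")
})

test_that("the silhouette-optimal cut matches exhaustive search on toys", {
  x <- toy_two_pair_matrix()
  cl <- cluster_genes(x, clustering_config(k_range = 2:3))
  expect_equal(cl$k, 2)
  expect_identical(partition_signature(cl$labels, names(cl$labels)),
                   "a,b|c,d")
  oracle <- best_partition_bruteforce(cl$dist)
  expect_identical(partition_signature(oracle, rownames(cl$dist)),
                   partition_signature(cl$labels, names(cl$labels)))
  # a 6-gene toy with three tight pairs
  set.seed(31)
  u <- rnorm(8); v <- rnorm(8); w <- rnorm(8)
  y <- rbind(a = u, b = u + rnorm(8, 0, 0.05),
             c = v, d = v + rnorm(8, 0, 0.05),
             e = w, f = w + rnorm(8, 0, 0.05))
  cl6 <- cluster_genes(y, clustering_config(k_range = 2:5))
  oracle6 <- best_partition_bruteforce(cl6$dist)
  expect_identical(partition_signature(cl6$labels, names(cl6$labels)),
                   partition_signature(oracle6, rownames(cl6$dist)))
})

test_that("the anchor-containing cluster becomes the WA signature", {
  sc <- simulate_cohort(sim_config(seed = 32, cohort_n = 500,
                                   wa_within_cor = 0.9, wa_block_size = 8))
  cands <- c(sc$truth$wa_block_genes, sc$truth$ba_up_genes)
  wa <- build_wa_signature(cands, sc$cohort)
  expect_setequal(wa$up_genes, sc$truth$wa_block_genes)
  # anchor must be present in the candidate set
  expect_error(build_wa_signature(sc$truth$ba_up_genes, sc$cohort), "AXIN2")
  # perfectly correlated candidates collapse to one cluster = whole input
  base <- seq_len(6)
  x <- rbind(AXIN2 = base, g1 = 2 * base + 1, g2 = 0.5 * base - 3)
  one <- build_wa_signature(rownames(x), x)
  expect_setequal(one$up_genes, rownames(x))
})

test_that("the packaged default WA signature carries the eight module genes", {
  wa <- wa_default_signature()
  expect_setequal(wa$up_genes, c("MACC1", "KRT23", "FGFR4", "RPS6KA6",
                                 "PROX1", "ASCL2", "AXIN2", "RASSF10"))
  expect_length(wa$down_genes, 0)
})

test_that("scoring matches hand arithmetic on a 3-gene toy", {
  expr <- rbind(g1 = c(1, 3), g2 = c(5, 1), g3 = c(2, 4))
  colnames(expr) <- c("s1", "s2")
  sig <- signature_definition("toy", up_genes = c("g1", "g2"),
                              down_genes = "g3")
  sc <- score_signature(expr, sig)
  # per-gene z over two samples is +/- 1/sqrt(2); up-mean cancels, down
  # contributes -/+ 1/sqrt(2)
  expect_equal(sc$score, c(1 / sqrt(2), -1 / sqrt(2)), tolerance = 1e-12)
  expect_equal(attr(sc, "n_up_used"), 2)
  expect_equal(attr(sc, "n_down_used"), 1)
})

test_that("scores cancel when up and down coincide and centre to zero", {
  set.seed(33)
  expr <- matrix(rnorm(50), 5, 10,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  # test-only object bypassing the disjointness check on purpose
  sig <- structure(list(name = "degenerate", up_genes = rownames(expr),
                        down_genes = rownames(expr), scoring_scale = "zscore",
                        provenance = ""), class = "signature_definition")
  sc <- score_signature(expr, sig)
  expect_equal(sc$score, rep(0, 10), tolerance = 1e-12)
  # z-scored genes centre: scores sum to ~0 across samples
  sig2 <- signature_definition("up", rownames(expr)[1:3])
  expect_equal(sum(score_signature(expr, sig2)$score), 0, tolerance = 1e-10)
})

test_that("z-score scoring is invariant to per-gene affine transforms", {
  set.seed(34)
  expr <- matrix(rnorm(80), 8, 10,
                 dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
  sig <- signature_definition("S", paste0("g", 1:4), paste0("g", 5:6))
  s1 <- score_signature(expr, sig)
  expr2 <- expr * runif(8, 0.5, 4) + rnorm(8, 0, 10)
  s2 <- score_signature(expr2, sig)
  expect_equal(s1$score, s2$score, tolerance = 1e-10)
  # permuting samples permutes scores identically
  perm <- sample(ncol(expr))
  s3 <- score_signature(expr[, perm], sig)
  expect_equal(s3$score, s1$score[perm], tolerance = 1e-12)
})

test_that("missing genes are skipped, with a warning below 80% coverage", {
  expr <- matrix(rnorm(30), 3, 10,
                 dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:10)))
  sig <- signature_definition("S", c("g1", "g2", "gX", "gY", "gZ"))
  expect_warning(sc <- score_signature(expr, sig), "40%")
  expect_equal(attr(sc, "n_up_used"), 2)
  expect_error(score_signature(expr, signature_definition("S", "nope")),
               "no up gene")
})

test_that("planted BA program drives the BA score", {
  sc <- simulate_cohort(sim_config(seed = 35))
  sig <- signature_definition("BA", sc$truth$ba_up_genes,
                              sc$truth$ba_down_genes)
  scores <- score_signature(sc$cohort, sig)
  expect_gte(cor(scores$score, sc$truth$latent$ba), 0.8)
})
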