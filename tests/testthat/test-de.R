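test_that("library normalization matches the closed form", {
  counts <- matrix(c(10L, 20L, 10L, 20L), 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  norm <- normalize_library_size(counts)
  expect_equal(unname(norm$size_factors), c(1, 1))
  # single sample: 2 genes with counts (999999, 1); hand arithmetic
  one <- matrix(c(999999L, 1L), 2, dimnames = list(c("g1", "g2"), "s1"))
  n1 <- normalize_library_size(one)
  expect_equal(n1$log2_cpm["g1", "s1"], log2(999999 + 1), tolerance = 1e-10)
  expect_equal(n1$log2_cpm["g2", "s1"], 1, tolerance = 1e-10)
  # zero count maps to zero under the +1 offset
  z <- matrix(c(0L, 5L), 2, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(normalize_library_size(z)$log2_cpm["g1", "s1"], 0)
  # all-zero sample is rejected by name
  bad <- matrix(c(1L, 0L, 0L, 0L), 2,
                dimnames = list(c("g1", "g2"), c("ok", "empty")))
  expect_error(normalize_library_size(bad), "empty")
})

test_that("count_matrix enforces its invariants", {
  m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(count_matrix(m, c("control", "treated"), c("b1", "b1")),
               "condition")
  expect_error(count_matrix(m - 3, c("control", "case"), c("b1", "b1")),
               "non-negative")
  ok <- count_matrix(m, c("control", "case"), c("b1", "b1"))
  expect_s3_class(ok, "count_matrix")
})

test_that("fit_de rejects confounded designs with a diagnostic", {
  sim <- simulate_mouse_counts(small_cfg(seed = 1))
  m <- sim$matrix
  m$samples$batch <- ifelse(m$samples$condition == "case", "b2", "b1")
  expect_error(fit_de(m), "confounded")
})

test_that("a permutation-null gene gets near-zero logFC and large p", {
  set.seed(42)
  base <- rnbinom(5, mu = 200, size = 10)
  counts <- rbind(
    null_gene = c(base, sample(base)),
    filler1 = rnbinom(10, mu = 150, size = 10),
    filler2 = rnbinom(10, mu = 300, size = 10)
  )
  colnames(counts) <- paste0("s", 1:10)
  m <- count_matrix(counts, rep(c("control", "case"), each = 5),
                    rep(c("b1", "b2"), 5))
  res <- fit_de(m)
  row <- res[res$gene_id == "null_gene", ]
  expect_lt(abs(row$log2_fold_change), 0.5)
  expect_gt(row$p_value, 0.05)
})

test_that("estimated logFC agrees with a composition-corrected moment oracle", {
  sim <- simulate_mouse_counts(sim_config(seed = 11, planted_lfc = 4,
                                          n_samples_per_group = 5))
  res <- fit_de(sim$matrix)
  planted <- c(sim$truth$de_up_genes, sim$truth$de_down_genes)
  est <- abs(res$log2_fold_change[match(planted, res$gene_id)])
  expect_lt(abs(median(est, na.rm = TRUE) - 4), 0.5)
  # independent oracle: DESeq-style median-of-ratios scaling + group means
  counts <- sim$matrix$counts
  geo <- exp(rowMeans(log(counts + 0.5)))
  sf <- apply(sweep(counts, 1, geo, "/"), 2, median)
  y <- sweep(counts, 2, sf, "/")
  case <- sim$matrix$samples$condition == "case"
  up <- sim$truth$de_up_genes
  oracle <- log2(rowMeans(y[up, case]) / rowMeans(y[up, !case]))
  fitted <- res$log2_fold_change[match(up, res$gene_id)]
  expect_lt(median(abs(fitted - oracle)), 0.3)
})

test_that("low-count genes are reported untested", {
  sim <- simulate_mouse_counts(small_cfg(seed = 3))
  m <- sim$matrix
  m$counts[1, ] <- 0L
  m$counts[2, ] <- c(1L, rep(0L, ncol(m$counts) - 1))
  res <- fit_de(m)
  expect_false(res$tested[1])
  expect_false(res$tested[2])
  expect_true(is.na(res$p_value[1]))
})

test_that("the DE filter applies strict thresholds on both axes", {
  res <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    log2_fold_change = c(3, -3, 3, 1, 2),
    p_value = c(1e-6, 1e-6, 1e-4, 1e-9, 1e-9),
    tested = TRUE, stringsAsFactors = FALSE
  )
  f <- filter_de(res)
  expect_identical(f$up, "g1")
  expect_identical(f$down, "g2")
  # logFC exactly at the threshold is excluded (g5)
  expect_false("g5" %in% f$up)
  # empty input
  empty <- filter_de(res[0, ])
  expect_identical(empty, list(up = character(), down = character()))
})

test_that("relaxing a threshold never removes a gene (monotonicity)", {
  sim <- simulate_mouse_counts(small_cfg(seed = 12, n_genes = 400))
  res <- fit_de(sim$matrix)
  tight <- filter_de(res, de_config(lfc_threshold = 2, p_threshold = 1e-5))
  loose_p <- filter_de(res, de_config(lfc_threshold = 2, p_threshold = 1e-3))
  loose_l <- filter_de(res, de_config(lfc_threshold = 1, p_threshold = 1e-5))
  expect_true(all(tight$up %in% loose_p$up))
  expect_true(all(tight$down %in% loose_p$down))
  expect_true(all(tight$up %in% loose_l$up))
  expect_true(all(tight$down %in% loose_l$down))
  expect_length(intersect(tight$up, tight$down), 0)
})

test_that("contrast combination follows the declared policies", {
  a <- list(up = c("g1", "g2"), down = "g4")
  b <- list(up = c("g2", "g3"), down = "g1")
  uc <- combine_contrasts(a, b)
  expect_setequal(uc$up, c("g2", "g3"))
  expect_setequal(uc$down, "g4")
  it <- combine_contrasts(list(up = c("g1", "g2"), down = character()),
                          list(up = "g2", down = character()),
                          policy = "intersection")
  expect_identical(it$up, "g2")
  # idempotence
  expect_identical(combine_contrasts(a, a), list(up = a$up, down = a$down))
  # within-contrast conflicts are an upstream bug
  expect_error(combine_contrasts(list(up = "g1", down = "g1"), b), "upstream")
})

test_that("the batch covariate absorbs planted batch effects", {
  base <- sim_config(seed = 13, n_genes = 600, batch_effect_sd = 0)
  withb <- sim_config(seed = 13, n_genes = 600, batch_effect_sd = 1)
  f0 <- filter_de(fit_de(simulate_mouse_counts(base)$matrix))
  f1 <- filter_de(fit_de(simulate_mouse_counts(withb)$matrix))
  expect_gt(jaccard(f0$up, f1$up), 0.9)
  expect_gt(jaccard(f0$down, f1$down), 0.9)
})
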