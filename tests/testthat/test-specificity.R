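test_that("ortholog mapping keeps only unambiguous high-confidence pairs", {
  map <- data.frame(
    mouse_gene = c("mA", "mB", "mC", "mC", "mD", "mE"),
    human_gene = c("hA", "hB", "hC1", "hC2", "hD", "hD"),
    confidence = c("high", "low", "high", "high", "high", "high"),
    stringsAsFactors = FALSE
  )
  # empty input
  empty <- map_orthologs(character(), map)
  expect_length(empty$human_genes, 0)
  expect_equal(nrow(empty$dropped), 0)
  # low-confidence-only record is dropped with its reason
  r1 <- map_orthologs(c("mA", "mB"), map)
  expect_identical(r1$human_genes, "hA")
  expect_identical(r1$dropped$reason[r1$dropped$mouse_gene == "mB"],
                   "low-confidence-only")
  # one mouse -> two high-confidence human genes: ambiguous
  r2 <- map_orthologs("mC", map)
  expect_length(r2$human_genes, 0)
  expect_identical(r2$dropped$reason, "ambiguous")
  # two mouse -> one human: many-to-one collision
  r3 <- map_orthologs(c("mD", "mE"), map)
  expect_length(r3$human_genes, 0)
  expect_true(all(r3$dropped$reason == "many-to-one"))
  # absent gene goes to the report, not an error
  r4 <- map_orthologs("mZ", map)
  expect_identical(r4$dropped$reason, "unmapped")
})

test_that("pseudobulk aggregation sums counts and conserves the grand total", {
  counts <- rbind(g1 = c(2L, 0L, 5L, 1L, 1L, 1L),
                  g2 = c(0L, 0L, 0L, 7L, 0L, 2L))
  cells <- data.frame(
    cell_id = paste0("c", 1:6),
    sample_id = c("s1", "s1", "s1", "s2", "s2", "s2"),
    cell_type = c("epithelial", "epithelial", "epithelial",
                  "stroma", "stroma", "stroma"),
    stringsAsFactors = FALSE
  )
  colnames(counts) <- cells$cell_id
  pb <- aggregate_pseudobulk(counts, cells$cell_type, cells$sample_id)
  # 3 cells with gene counts 2, 0, 5 -> pseudobulk entry 7
  unit_epi <- pb$units$unit_id[pb$units$cell_type == "epithelial"]
  expect_equal(unname(pb$counts["g1", unit_epi]), 7)
  expect_equal(sum(pb$counts), sum(counts))
  # one cell per unit: pseudobulk equals the cell table
  pb1 <- aggregate_pseudobulk(counts, paste0("t", 1:6), rep("s1", 6))
  expect_equal(sort(as.vector(pb1$counts["g1", ])), sort(counts["g1", ]),
               ignore_attr = TRUE)
  # unlabeled cells are rejected by id
  expect_error(aggregate_pseudobulk(counts, c(NA, cells$cell_type[-1]),
                                    cells$sample_id), "c1")
})

test_that("grand-total conservation holds on simulated cell data", {
  cd <- simulate_cell_counts(small_cfg(seed = 21))
  pb <- aggregate_pseudobulk(cd$counts, cd$cells$cell_type, cd$cells$sample_id)
  expect_identical(sum(pb$counts), sum(cd$counts))
})

test_that("a flat gene is non-specific and config defaults match the rule", {
  cfg <- specificity_config()
  expect_equal(cfg$margin_counts, 1)
  expect_equal(cfg$alpha, 0.01)
  counts <- rbind(flat = rep(50L, 12), var = c(rep(400L, 6), rep(2L, 6)))
  cells <- data.frame(
    cell_id = paste0("c", 1:12),
    sample_id = rep(paste0("s", 1:3), 4),
    cell_type = rep(c("epithelial", "stroma"), each = 6),
    stringsAsFactors = FALSE
  )
  colnames(counts) <- cells$cell_id
  pb <- aggregate_pseudobulk(counts, cells$cell_type, cells$sample_id)
  calls <- classify_specificity(pb)
  expect_identical(calls$label[calls$gene_id == "flat"], "non-specific")
  expect_identical(calls$label[calls$gene_id == "var"], "epithelial")
})

test_that("cell types with fewer than 2 samples are rejected by name", {
  counts <- rbind(g1 = c(5L, 5L, 5L), g2 = c(1L, 2L, 3L))
  colnames(counts) <- paste0("c", 1:3)
  pb <- aggregate_pseudobulk(counts, c("epithelial", "epithelial", "stroma"),
                             c("s1", "s2", "s1"))
  expect_error(classify_specificity(pb), "stroma")
})

test_that("planted specificity is recovered with few errors", {
  cfg <- sim_config(seed = 22, n_genes = 600, specificity_fold = 8,
                    cells_per_sample_per_type = 200, n_samples_sc = 4)
  cd <- simulate_cell_counts(cfg)
  pb <- aggregate_pseudobulk(cd$counts, cd$cells$cell_type, cd$cells$sample_id)
  calls <- classify_specificity(pb)
  truth <- cd$truth$specificity_labels
  got <- calls$label[match(names(truth), calls$gene_id)]
  epi <- truth == "epithelial"
  ns <- truth == "non-specific"
  expect_gte(mean(got[epi] == "epithelial"), 0.9)
  expect_lte(mean(got[ns] != "non-specific"), 0.02)
  # uniqueness: at most one specific label per gene, asserted on every call
  expect_true(all(table(calls$gene_id) == 1))
})

test_that("tightening the rule never grows a specific set", {
  cd <- simulate_cell_counts(small_cfg(seed = 23))
  pb <- aggregate_pseudobulk(cd$counts, cd$cells$cell_type, cd$cells$sample_id)
  base <- classify_specificity(pb, specificity_config(1, 0.01))
  hard_m <- classify_specificity(pb, specificity_config(5, 0.01))
  hard_a <- classify_specificity(pb, specificity_config(1, 0.001))
  spec_set <- function(calls) calls$gene_id[calls$label != "non-specific"]
  expect_true(all(spec_set(hard_m) %in% spec_set(base)))
  expect_true(all(spec_set(hard_a) %in% spec_set(base)))
})

test_that("with 2 samples per type the classifier degrades to non-specific", {
  cfg <- sim_config(seed = 24, n_genes = 300, n_samples_sc = 2,
                    cells_per_sample_per_type = 100)
  cd <- simulate_cell_counts(cfg)
  pb <- aggregate_pseudobulk(cd$counts, cd$cells$cell_type, cd$cells$sample_id)
  calls <- classify_specificity(pb)
  truth <- cd$truth$specificity_labels
  got <- calls$label[match(names(truth), calls$gene_id)]
  specific <- got != "non-specific"
  # anything still called specific must carry the true label: the
  # underpowered test loses sensitivity, not correctness
  expect_true(all(got[specific] == truth[specific]))
})

test_that("partitioning covers the input exactly once", {
  calls <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    label = c("epithelial", "stroma", "non-specific"),
    stringsAsFactors = FALSE
  )
  p <- partition_epithelial(calls)
  expect_identical(p$epithelial, "g1")
  expect_identical(p$non_epithelial, "g2")
  expect_identical(p$non_specific, "g3")
  expect_setequal(c(p$epithelial, p$non_epithelial, p$non_specific),
                  calls$gene_id)
  all_ns <- partition_epithelial(data.frame(
    gene_id = c("a", "b"), label = "non-specific", stringsAsFactors = FALSE))
  expect_length(all_ns$epithelial, 0)
  expect_setequal(all_ns$non_specific, c("a", "b"))
})
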