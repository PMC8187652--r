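# Shared fixtures and independent oracles used across the suite.

jaccard <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

# Small configurations keep unit tests fast; acceptance tests use the
# package defaults (the study conditions).
small_cfg <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_genes = 300L, cells_per_sample_per_type = 60L,
         cohort_n = 120L),
    list(...)
  )
  do.call(sim_config, args)
}

# Enumerate all partitions of n elements as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  rec <- function(codes, max_used) {
    if (length(codes) == n) {
      out[[length(out) + 1]] <<- codes
      return(invisible())
    }
    for (k in seq_len(max_used + 1)) {
      rec(c(codes, k), max(max_used, k))
    }
  }
  rec(integer(), 0L)
  out
}

# Mean silhouette width of a partition, written from the definition
# (independent of cluster::silhouette); singletons get width 0.
mean_silhouette_bruteforce <- function(labels, d) {
  n <- length(labels)
  widths <- vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1) return(0)
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(d[i, which(labels == cl)])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(widths)
}

# Best partition (>= 2 clusters) of a small gene set by exhaustive search
# over mean silhouette width.
best_partition_bruteforce <- function(d) {
  n <- nrow(d)
  parts <- Filter(function(p) {
    k <- length(unique(p))
    k >= 2 && k <= n - 1
  }, all_partitions(n))
  scores <- vapply(parts, mean_silhouette_bruteforce, numeric(1), d = d)
  parts[[which.max(scores)]]
}

# Canonical form of a set partition for comparison.
partition_signature <- function(labels, ids) {
  blocks <- split(ids, labels)
  blocks <- lapply(blocks, sort)
  paste(sort(vapply(blocks, paste, "", collapse = ",")), collapse = "|")
}

# Deterministic 4-gene toy: two tight pairs with near-zero cross correlation.
toy_two_pair_matrix <- function() {
  u <- c(1, 2, 3, 4, 5)
  v <- c(3, -2, 4, -1, 2)
  x <- rbind(
    a = u,
    b = u + c(0.02, -0.03, 0.01, 0.03, -0.02),
    c = v,
    d = v + c(-0.05, 0.04, 0.03, -0.02, 0.05)
  )
  colnames(x) <- paste0("s", 1:5)
  x
}

# Tiny hand-checkable pseudobulk: 2 genes, 2 types x 3 samples.
toy_pseudobulk <- function(counts) {
  cells <- data.frame(
    cell_id = paste0("c", seq_len(ncol(counts))),
    sample_id = rep(paste0("s", 1:3), times = 2),
    cell_type = rep(c("epithelial", "stroma"), each = 3),
    stringsAsFactors = FALSE
  )
  colnames(counts) <- cells$cell_id
  aggregate_pseudobulk(counts, cells$cell_type, cells$sample_id)
}
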