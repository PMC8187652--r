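#' Construct a labelled count matrix
#'
#' @param counts Integer gene x sample matrix with unique row names (gene
#'   ids) and column names (sample ids); all entries non-negative integers.
#' @param condition Per-sample label, one of "control"/"case".
#' @param batch Per-sample batch label.
#'
#' @return An object of class `count_matrix`: a list with `counts` and a
#'   `samples` data frame (sample_id, condition, batch).
#' @export
count_matrix <- function(counts, condition, batch) {
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop("count_matrix: counts must have unique gene-id row names", call. = FALSE)
  }
  if (is.null(colnames(counts))) {
    stop("count_matrix: counts must have sample-id column names", call. = FALSE)
  }
  if (length(condition) != ncol(counts) || length(batch) != ncol(counts)) {
    stop("count_matrix: one condition and one batch label per sample required",
         call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("count_matrix: counts must be non-negative integers", call. = FALSE)
  }
  if (!all(condition %in% c("control", "case"))) {
    stop("count_matrix: condition labels must be 'control' or 'case'",
         call. = FALSE)
  }
  structure(list(
    counts = counts,
    samples = data.frame(
      sample_id = colnames(counts),
      condition = as.character(condition),
      batch = as.character(batch),
      stringsAsFactors = FALSE
    )
  ), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d case / %d control; batches: %s)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$samples$condition == "case"),
              sum(x$samples$condition == "control"),
              paste(unique(x$samples$batch), collapse = ", ")))
  invisible(x)
}

#' Library-size normalization
#'
#' Computes per-sample size factors (total library count scaled so the
#' geometric mean of the factors is 1) and a log2-CPM matrix,
#' `log2(1e6 * count / library + 1)`.
#'
#' @param m A [count_matrix()] or a bare count matrix.
#' @return A list with `size_factors`, `lib_sizes` and `log2_cpm`.
#' @export
normalize_library_size <- function(m) {
  counts <- if (inherits(m, "count_matrix")) m$counts else m
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    bad <- colnames(counts)[lib <= 0]
    stop(sprintf("normalize_library_size: sample(s) with zero total count: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  sf <- lib / exp(mean(log(lib)))
  log2_cpm <- log2(sweep(counts, 2, lib, "/") * 1e6 + 1)
  list(size_factors = sf, lib_sizes = lib, log2_cpm = log2_cpm)
}

#' Differential-expression filter configuration
#'
#' Defaults are the signature-derivation filter: absolute log2 fold change
#' strictly greater than 2 at an unadjusted p-value strictly below 1e-5,
#' after excluding genes with fewer than 10 total counts.
#'
#' @param lfc_threshold Positive log2 fold-change threshold (strict).
#' @param p_threshold Unadjusted p-value threshold (strict).
#' @param min_total_count Genes with total count below this are not tested.
#' @return A list of class `de_config`.
#' @export
de_config <- function(lfc_threshold = 2, p_threshold = 1e-5,
                      min_total_count = 10L) {
  if (lfc_threshold <= 0 || p_threshold <= 0) {
    stop("de_config: thresholds must be positive", call. = FALSE)
  }
  structure(list(lfc_threshold = lfc_threshold, p_threshold = p_threshold,
                 min_total_count = as.integer(min_total_count)),
            class = "de_config")
}

# Method-of-moments NB dispersion per gene, pooled over design cells, then
# squeezed halfway toward the across-gene median (per-gene estimates from
# 2-3 replicates per cell are too noisy to treat as known: unmoderated they
# make the LRT anticonservative), floored at 1e-4. Counts are first
# rescaled to a common library size.
.mom_dispersion <- function(counts, groups, floor = 1e-4) {
  lib <- colSums(counts)
  y <- sweep(counts, 2, mean(lib) / lib, "*")
  phi <- rep(floor, nrow(counts))
  cells <- split(seq_len(ncol(y)), groups)
  cells <- cells[vapply(cells, length, 1L) >= 2]
  if (length(cells) > 0) {
    est <- vapply(cells, function(j) {
      m <- rowMeans(y[, j, drop = FALSE])
      v <- apply(y[, j, drop = FALSE], 1, stats::var)
      ifelse(m > 0, (v - m) / m^2, NA_real_)
    }, numeric(nrow(y)))
    est <- if (is.matrix(est)) rowMeans(est, na.rm = TRUE) else est
    est <- ifelse(is.finite(est), est, floor)
    mid <- stats::median(pmax(est, floor))
    phi <- pmax((pmax(est, floor) + mid) / 2, floor)
  }
  phi
}

#' Fit the per-gene condition model
#'
#' Per gene, a negative-binomial generalized linear model with log link,
#' offsets equal to the log of the TMM-scaled effective library size
#' (composition-robust) and covariates batch + condition, fitted with
#' edgeR's GLM machinery using a fixed per-gene method-of-moments dispersion
#' squeezed halfway toward the across-gene median and floored at 1e-4.
#' The reported log2 fold change is the unshrunk
#' case-vs-control coefficient; the p-value comes from a likelihood-ratio
#' test of the condition term. Genes below `min_total_count` total counts
#' are excluded from testing and reported with `tested = FALSE`.
#'
#' @param m A [count_matrix()].
#' @param cfg A [de_config()].
#' @return A data frame with columns `gene_id`, `log2_fold_change`,
#'   `p_value`, `tested` (one row per input gene, input order).
#' @export
fit_de <- function(m, cfg = de_config()) {
  stopifnot(inherits(m, "count_matrix"))
  cond <- factor(m$samples$condition, levels = c("control", "case"))
  batch <- factor(m$samples$batch)
  if (any(table(cond) < 2)) {
    stop("fit_de: need >= 2 samples in each condition", call. = FALSE)
  }
  tab <- table(batch, cond)
  if (nlevels(batch) > 1 && all(rowSums(tab > 0) < 2)) {
    stop(paste("fit_de: design is confounded - each batch contains only one",
               "condition, so batch and condition effects cannot be separated"),
         call. = FALSE)
  }

  counts <- m$counts
  tested <- rowSums(counts) >= cfg$min_total_count
  out <- data.frame(
    gene_id = rownames(counts),
    log2_fold_change = NA_real_,
    p_value = NA_real_,
    tested = tested,
    stringsAsFactors = FALSE
  )
  if (!any(tested)) return(out)

  ct <- counts[tested, , drop = FALSE]
  groups <- interaction(batch, cond, drop = TRUE)
  phi <- .mom_dispersion(ct, groups)
  design <- if (nlevels(batch) > 1) {
    stats::model.matrix(~ batch + cond)
  } else {
    stats::model.matrix(~ cond)
  }
  y <- edgeR::DGEList(counts = ct, lib.size = colSums(counts))
  # TMM factors guard the condition coefficient against composition bias
  # (strong planted DE shifts raw library totals between conditions)
  y <- edgeR::calcNormFactors(y, method = "TMM")
  fit <- edgeR::glmFit(y, design = design, dispersion = phi, prior.count = 0.125)
  lrt <- edgeR::glmLRT(fit, coef = "condcase")
  out$log2_fold_change[tested] <- lrt$table$logFC
  out$p_value[tested] <- lrt$table$PValue
  out
}

#' Apply the signature-derivation DE filter
#'
#' Strict thresholds on both axes: up-regulated genes have
#' `log2_fold_change > lfc_threshold` and `p_value < p_threshold`;
#' down-regulated genes the mirror image. Untested genes never pass.
#'
#' @param results Data frame from [fit_de()].
#' @param cfg A [de_config()].
#' @return A list with character vectors `up` and `down` (disjoint).
#' @export
filter_de <- function(results, cfg = de_config()) {
  if (is.null(results) || nrow(results) == 0) {
    return(list(up = character(), down = character()))
  }
  ok <- results$tested & is.finite(results$log2_fold_change) &
    is.finite(results$p_value) & results$p_value < cfg$p_threshold
  up <- results$gene_id[ok & results$log2_fold_change > cfg$lfc_threshold]
  down <- results$gene_id[ok & results$log2_fold_change < -cfg$lfc_threshold]
  list(up = up, down = down)
}

#' Merge the up/down sets of two contrasts
#'
#' Default policy "union-consistent": a gene is up if it is up in either
#' contrast and down in neither; symmetrically for down. Policy
#' "intersection" keeps only genes called in both contrasts, same direction.
#'
#' @param sets_a,sets_b Lists with `up` and `down` character vectors, from
#'   the same gene universe.
#' @param policy "union-consistent" (default) or "intersection".
#' @return A list with merged `up` and `down` sets.
#' @export
combine_contrasts <- function(sets_a, sets_b,
                              policy = c("union-consistent", "intersection")) {
  policy <- match.arg(policy)
  for (s in list(sets_a, sets_b)) {
    clash <- intersect(s$up, s$down)
    if (length(clash) > 0) {
      stop(sprintf("combine_contrasts: gene(s) in both up and down of one contrast (upstream bug): %s",
                   paste(clash, collapse = ", ")), call. = FALSE)
    }
  }
  if (policy == "union-consistent") {
    all_up <- union(sets_a$up, sets_b$up)
    all_down <- union(sets_a$down, sets_b$down)
    list(up = setdiff(all_up, all_down), down = setdiff(all_down, all_up))
  } else {
    list(up = intersect(sets_a$up, sets_b$up),
         down = intersect(sets_a$down, sets_b$down))
  }
}
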