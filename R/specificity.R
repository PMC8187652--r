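#' Map mouse genes to unambiguous high-confidence human orthologs
#'
#' Keeps only high-confidence ortholog records, then drops every mouse gene
#' that is absent from the map, has only low-confidence records, maps to
#' more than one high-confidence human gene, or whose human gene is also hit
#' by another mouse gene (many-to-one collision). Each dropped gene is
#' reported with its reason.
#'
#' @param genes Character vector of mouse gene ids.
#' @param map Ortholog table: data frame with columns `mouse_gene`,
#'   `human_gene`, `confidence` ("high"/"low"); no duplicate pairs.
#' @return A list with `human_genes` (deduplicated character vector) and
#'   `dropped` (data frame: mouse_gene, reason).
#' @export
map_orthologs <- function(genes, map) {
  stopifnot(is.data.frame(map),
            all(c("mouse_gene", "human_gene", "confidence") %in% names(map)))
  if (nrow(map) == 0) stop("map_orthologs: empty ortholog map", call. = FALSE)
  if (anyDuplicated(map[, c("mouse_gene", "human_gene")])) {
    stop("map_orthologs: duplicate (mouse, human) pairs in map", call. = FALSE)
  }
  genes <- unique(genes)
  if (length(genes) == 0) {
    return(list(human_genes = character(),
                dropped = data.frame(mouse_gene = character(),
                                     reason = character(),
                                     stringsAsFactors = FALSE)))
  }
  hi <- map[map$confidence == "high", , drop = FALSE]
  # map-wide ambiguity/collision structure
  mouse_hits <- table(hi$mouse_gene)
  human_hits <- table(hi$human_gene)

  reason <- character(0)
  dropped_gene <- character(0)
  kept <- character(0)
  for (g in genes) {
    rec <- hi[hi$mouse_gene == g, , drop = FALSE]
    if (!g %in% map$mouse_gene) {
      dropped_gene <- c(dropped_gene, g); reason <- c(reason, "unmapped")
    } else if (nrow(rec) == 0) {
      dropped_gene <- c(dropped_gene, g); reason <- c(reason, "low-confidence-only")
    } else if (nrow(rec) > 1) {
      dropped_gene <- c(dropped_gene, g); reason <- c(reason, "ambiguous")
    } else if (human_hits[rec$human_gene] > 1) {
      dropped_gene <- c(dropped_gene, g); reason <- c(reason, "many-to-one")
    } else {
      kept <- c(kept, rec$human_gene)
    }
  }
  list(
    human_genes = unique(kept),
    dropped = data.frame(mouse_gene = dropped_gene, reason = reason,
                         stringsAsFactors = FALSE)
  )
}

#' Aggregate cell-level counts into pseudobulk
#'
#' Sums raw counts over all cells sharing a (sample, cell type) pair. The
#' grand total is conserved exactly.
#'
#' @param counts Gene x cell integer matrix.
#' @param cell_types Per-cell type label (length = ncol(counts)).
#' @param samples Per-cell sample label.
#' @return A list of class `pseudobulk`: `counts` (gene x unit matrix) and
#'   `units` (data frame: unit_id, sample_id, cell_type).
#' @export
aggregate_pseudobulk <- function(counts, cell_types, samples) {
  stopifnot(length(cell_types) == ncol(counts),
            length(samples) == ncol(counts))
  bad <- is.na(cell_types) | is.na(samples)
  if (any(bad)) {
    ids <- colnames(counts)[bad]
    if (is.null(ids)) ids <- which(bad)
    stop(sprintf("aggregate_pseudobulk: unlabeled cell(s): %s",
                 paste(utils::head(ids, 10), collapse = ", ")), call. = FALSE)
  }
  grp <- paste(samples, cell_types, sep = "||")
  pb <- t(rowsum(t(counts), group = grp, reorder = TRUE))
  units <- do.call(rbind, strsplit(colnames(pb), "||", fixed = TRUE))
  units <- data.frame(unit_id = colnames(pb), sample_id = units[, 1],
                      cell_type = units[, 2], stringsAsFactors = FALSE)
  colnames(pb) <- units$unit_id
  structure(list(counts = pb, units = units), class = "pseudobulk")
}

#' Specificity-classification configuration
#'
#' Defaults encode the packaged rule: a gene is specific to a cell type if
#' its mean raw pseudobulk count there exceeds every other type by at least
#' 1 count and every pairwise replicate-level test is significant at
#' p < 0.01.
#'
#' @param margin_counts Required difference of per-sample mean raw
#'   pseudobulk counts (>= 0).
#' @param alpha Per-pair significance level, in (0, 1).
#' @return A list of class `specificity_config`.
#' @export
specificity_config <- function(margin_counts = 1, alpha = 0.01) {
  if (margin_counts < 0) stop("specificity_config: 'margin_counts' must be >= 0",
                              call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("specificity_config: 'alpha' must lie in (0, 1)",
                                     call. = FALSE)
  structure(list(margin_counts = margin_counts, alpha = alpha),
            class = "specificity_config")
}

.welch_p <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1)
}

#' Classify genes as cell-type specific from pseudobulk profiles
#'
#' For each gene, the candidate type is the one with the highest mean raw
#' pseudobulk count across samples. The gene is labelled specific to that
#' type only if (a) its mean exceeds every other type's mean by at least
#' `margin_counts` raw counts and (b) a two-sided Welch t-test on per-sample
#' log2-CPM pseudobulk values is significant at `alpha` against every other
#' type. Otherwise it is "non-specific". With a positive margin at most one
#' type can qualify, so labels are unique by construction.
#'
#' @param pb A `pseudobulk` object from [aggregate_pseudobulk()].
#' @param cfg A [specificity_config()].
#' @return A data frame with columns `gene_id`, `label`, `min_margin`
#'   (candidate mean minus best other mean) and `max_p` (largest pairwise
#'   p-value; NA when the margin already failed).
#' @export
classify_specificity <- function(pb, cfg = specificity_config()) {
  stopifnot(inherits(pb, "pseudobulk"))
  types <- unique(pb$units$cell_type)
  n_samp <- table(pb$units$cell_type)
  if (any(n_samp < 2)) {
    stop(sprintf("classify_specificity: cell type(s) with < 2 samples: %s",
                 paste(names(n_samp)[n_samp < 2], collapse = ", ")),
         call. = FALSE)
  }
  norm <- normalize_library_size(pb$counts)
  lcpm <- norm$log2_cpm

  idx_by_type <- split(seq_len(ncol(pb$counts)), pb$units$cell_type)
  mean_raw <- vapply(idx_by_type,
                     function(j) rowMeans(pb$counts[, j, drop = FALSE]),
                     numeric(nrow(pb$counts)))
  if (!is.matrix(mean_raw)) {
    mean_raw <- matrix(mean_raw, nrow = 1, dimnames = list(NULL, names(idx_by_type)))
  }

  genes <- rownames(pb$counts)
  label <- rep("non-specific", length(genes))
  min_margin <- numeric(length(genes))
  max_p <- rep(NA_real_, length(genes))

  top <- max.col(mean_raw, ties.method = "first")
  for (i in seq_along(genes)) {
    t_star <- colnames(mean_raw)[top[i]]
    others <- setdiff(colnames(mean_raw), t_star)
    margins <- mean_raw[i, t_star] - mean_raw[i, others]
    min_margin[i] <- min(margins)
    if (min_margin[i] < cfg$margin_counts) next
    x <- lcpm[i, idx_by_type[[t_star]]]
    ps <- vapply(others, function(u) .welch_p(x, lcpm[i, idx_by_type[[u]]]),
                 numeric(1))
    max_p[i] <- max(ps)
    if (all(is.finite(ps)) && max_p[i] < cfg$alpha) label[i] <- t_star
  }
  data.frame(gene_id = genes, label = label, min_margin = min_margin,
             max_p = max_p, stringsAsFactors = FALSE)
}

#' Partition specificity calls into epithelial / non-epithelial / non-specific
#'
#' @param calls Data frame from [classify_specificity()].
#' @return A list with character vectors `epithelial`, `non_epithelial`
#'   (specific to any other type) and `non_specific`; the three sets
#'   partition the input genes.
#' @export
partition_epithelial <- function(calls) {
  stopifnot(is.data.frame(calls), all(c("gene_id", "label") %in% names(calls)))
  list(
    epithelial = calls$gene_id[calls$label == "epithelial"],
    non_epithelial = calls$gene_id[!calls$label %in% c("epithelial", "non-specific")],
    non_specific = calls$gene_id[calls$label == "non-specific"]
  )
}
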