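#' Construct a signature definition
#'
#' A signature is a named up-gene set, an optional down-gene set, and a
#' scoring convention. The score of a sample is the mean expression of the
#' up genes minus the mean expression of the down genes, computed on the
#' chosen scale (see [score_signature()]).
#'
#' @param name Signature name.
#' @param up_genes Non-empty character vector.
#' @param down_genes Character vector, possibly empty; disjoint from
#'   `up_genes`.
#' @param scoring_scale "zscore" (default) or "log-expression".
#' @param provenance Free-text note on how the signature was built.
#' @return A list of class `signature_definition`.
#' @export
signature_definition <- function(name, up_genes, down_genes = character(),
                                 scoring_scale = c("zscore", "log-expression"),
                                 provenance = "") {
  scoring_scale <- match.arg(scoring_scale)
  up_genes <- unique(as.character(up_genes))
  down_genes <- unique(as.character(down_genes))
  if (length(up_genes) == 0) {
    stop("signature_definition: 'up_genes' must be non-empty", call. = FALSE)
  }
  if (length(intersect(up_genes, down_genes)) > 0) {
    stop("signature_definition: up and down gene sets must be disjoint",
         call. = FALSE)
  }
  structure(list(name = name, up_genes = up_genes, down_genes = down_genes,
                 scoring_scale = scoring_scale, provenance = provenance),
            class = "signature_definition")
}

#' @export
print.signature_definition <- function(x, ...) {
  cat(sprintf("signature '%s': %d up / %d down genes (%s scale)\n",
              x$name, length(x$up_genes), length(x$down_genes),
              x$scoring_scale))
  invisible(x)
}

#' Gene-clustering configuration
#'
#' Hierarchical clustering of gene expression profiles on correlation
#' distance (1 - Pearson r) with complete linkage; the tree is cut at the
#' number of clusters maximizing mean silhouette width over `k_range`, and
#' the cluster containing `anchor_gene` is selected.
#'
#' @param k_range Integer candidate cluster counts (clipped to
#'   `[2, n_genes - 1]` at run time).
#' @param anchor_gene Identifier of the anchor gene (default "AXIN2").
#' @return A list of class `clustering_config`.
#' @export
clustering_config <- function(k_range = 2:15, anchor_gene = "AXIN2") {
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2)) stop("clustering_config: k_range must be >= 2", call. = FALSE)
  structure(list(distance = "correlation", linkage = "complete",
                 k_range = k_range, anchor_gene = anchor_gene),
            class = "clustering_config")
}

#' Cluster genes by correlation distance with complete linkage
#'
#' Computes pairwise distances d(g, h) = 1 - Pearson correlation of the two
#' genes' expression profiles across samples, builds a complete-linkage
#' agglomerative tree, and cuts it at the k in `k_range` that maximizes the
#' mean silhouette width (smallest such k on ties). Genes are ordered
#' lexicographically before clustering so ties in the merge sequence break
#' deterministically.
#'
#' @param x Gene x sample numeric matrix (>= 3 genes, >= 3 samples, no
#'   zero-variance gene).
#' @param cfg A [clustering_config()].
#' @return A list with `labels` (named integer cluster ids), `k`, `tree`
#'   (the hclust object), `silhouette` (mean width per candidate k) and
#'   `dist` (the distance matrix).
#' @export
cluster_genes <- function(x, cfg = clustering_config()) {
  if (nrow(x) < 3) stop("cluster_genes: need >= 3 genes", call. = FALSE)
  if (ncol(x) < 3) stop("cluster_genes: need >= 3 samples", call. = FALSE)
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    stop(sprintf("cluster_genes: zero-variance gene(s): %s",
                 paste(utils::head(rownames(x)[v == 0], 10), collapse = ", ")),
         call. = FALSE)
  }
  x <- x[order(rownames(x)), , drop = FALSE]
  d <- 1 - stats::cor(t(x))
  d[d < 0] <- 0  # guard tiny negative rounding
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  if (max(d) < 1e-8) {
    # all profiles perfectly correlated: a single cluster is the only
    # meaningful answer, silhouettes are undefined
    labels <- stats::setNames(rep(1L, nrow(x)), rownames(x))
    return(list(labels = labels, k = 1L, tree = hc,
                silhouette = stats::setNames(numeric(0), integer(0)),
                dist = d))
  }
  ks <- cfg$k_range[cfg$k_range <= nrow(x) - 1]
  if (length(ks) == 0) {
    stop("cluster_genes: k_range has no feasible value for this input",
         call. = FALSE)
  }
  sil <- vapply(ks, function(k) {
    cl <- stats::cutree(hc, k = k)
    mean(cluster::silhouette(cl, dmatrix = d)[, "sil_width"])
  }, numeric(1))
  k_best <- ks[which.max(sil)]
  labels <- stats::cutree(hc, k = k_best)
  list(labels = labels, k = k_best, tree = hc,
       silhouette = stats::setNames(sil, ks), dist = d)
}

#' Build the BA signature from DE gene sets and epithelial calls
#'
#' Retains the epithelial members of the ortholog-mapped up- and
#' down-regulated sets; the signature value of a sample is later computed
#' as mean(up) - mean(down) on the z-score scale.
#'
#' @param up,down Human gene sets (ortholog-mapped) from the DE stage.
#' @param epithelial Set of epithelial-specific human genes.
#' @return A [signature_definition()] named "BA".
#' @export
build_ba_signature <- function(up, down, epithelial) {
  up_e <- intersect(up, epithelial)
  down_e <- intersect(down, epithelial)
  if (length(up_e) == 0) {
    stop(paste("build_ba_signature: no up-regulated gene is epithelial-specific;",
               "review the DE and specificity thresholds"), call. = FALSE)
  }
  signature_definition(
    "BA", up_e, down_e, scoring_scale = "zscore",
    provenance = sprintf("epithelial intersection of DE sets (%d/%d up, %d/%d down retained)",
                         length(up_e), length(up), length(down_e), length(down))
  )
}

#' Build the WA signature as the anchor-containing expression cluster
#'
#' Restricts a human cohort expression matrix to the epithelial up-genes,
#' clusters them with [cluster_genes()], and returns the cluster containing
#' the anchor gene (default "AXIN2") as an up-only signature.
#'
#' @param up_epithelial Candidate gene set (epithelial up-genes); must
#'   contain the anchor.
#' @param expr Gene x sample expression matrix of the derivation cohort (or
#'   a [cohort_table()]).
#' @param cfg A [clustering_config()].
#' @return A [signature_definition()] named "WA".
#' @export
build_wa_signature <- function(up_epithelial, expr, cfg = clustering_config()) {
  if (inherits(expr, "cohort_table")) expr <- expr$expr
  if (!cfg$anchor_gene %in% up_epithelial) {
    stop(sprintf("build_wa_signature: anchor gene '%s' is not among the candidate genes",
                 cfg$anchor_gene), call. = FALSE)
  }
  keep <- intersect(up_epithelial, rownames(expr))
  if (!cfg$anchor_gene %in% keep) {
    stop(sprintf("build_wa_signature: anchor gene '%s' is absent from the cohort matrix",
                 cfg$anchor_gene), call. = FALSE)
  }
  cl <- cluster_genes(expr[keep, , drop = FALSE], cfg)
  anchor_cluster <- cl$labels[[cfg$anchor_gene]]
  up <- names(cl$labels)[cl$labels == anchor_cluster]
  signature_definition(
    "WA", up, character(), scoring_scale = "zscore",
    provenance = sprintf("anchor-containing cluster (k = %d of %d candidate genes)",
                         cl$k, length(keep))
  )
}

#' The packaged default WA signature
#'
#' The 8-gene Wnt-activation module (MACC1, KRT23, FGFR4, RPS6KA6, PROX1,
#' ASCL2, AXIN2, RASSF10), shipped as a GMT resource and used whenever no
#' derivation cohort is supplied.
#'
#' @return A [signature_definition()] named "WA".
#' @export
wa_default_signature <- function() {
  path <- system.file("extdata", "wa_default.gmt", package = "crcsig",
                      mustWork = TRUE)
  sets <- read_gmt(path)
  signature_definition("WA", sets[[1]], character(), scoring_scale = "zscore",
                       provenance = "packaged default 8-gene Wnt-activation module")
}

#' Score samples against a signature
#'
#' On the default z-score scale each gene is standardized across samples
#' (mean 0, SD 1; a zero-variance gene contributes 0) before averaging; the
#' score is mean over up genes present minus mean over down genes present.
#' On the "log-expression" scale the matrix is used as-is. Genes absent
#' from the matrix are skipped; a warning is issued when less than 80% of
#' the signature is covered.
#'
#' @param expr Gene x sample numeric matrix or a [cohort_table()].
#' @param sig A [signature_definition()].
#' @return A data frame of class `sig_scores` with columns `sample_id` and
#'   `score`, and attributes `n_up_used`, `n_down_used`, `signature`.
#' @export
score_signature <- function(expr, sig) {
  stopifnot(inherits(sig, "signature_definition"))
  if (inherits(expr, "cohort_table")) expr <- expr$expr
  up <- intersect(sig$up_genes, rownames(expr))
  down <- intersect(sig$down_genes, rownames(expr))
  if (length(up) == 0) {
    stop(sprintf("score_signature: no up gene of '%s' present in the matrix",
                 sig$name), call. = FALSE)
  }
  coverage <- (length(up) + length(down)) /
    (length(sig$up_genes) + length(sig$down_genes))
  if (coverage < 0.8) {
    warning(sprintf("score_signature: only %.0f%% of signature '%s' found in the matrix",
                    100 * coverage, sig$name))
  }
  m <- expr
  if (sig$scoring_scale == "zscore") {
    mu <- rowMeans(m)
    sdv <- apply(m, 1, stats::sd)
    sdv[sdv == 0] <- Inf  # constant gene -> all-zero z profile
    m <- (m - mu) / sdv
  }
  score <- colMeans(m[up, , drop = FALSE])
  if (length(down) > 0) score <- score - colMeans(m[down, , drop = FALSE])
  out <- data.frame(sample_id = colnames(expr), score = as.numeric(score),
                    stringsAsFactors = FALSE)
  attr(out, "n_up_used") <- length(up)
  attr(out, "n_down_used") <- length(down)
  attr(out, "signature") <- sig$name
  class(out) <- c("sig_scores", "data.frame")
  out
}
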