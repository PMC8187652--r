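#' Construct an annotated expression cohort
#'
#' @param expr Gene x sample numeric matrix (continuous expression).
#' @param annotations Data frame with a `sample_id` column and any of the
#'   clinical columns braf_status, side, cms, t_stage, lesion_type,
#'   surv_time, surv_event. Annotation sample ids must be a subset of the
#'   expression columns.
#' @return A list of class `cohort_table`.
#' @export
cohort_table <- function(expr, annotations) {
  stopifnot(is.matrix(expr), is.data.frame(annotations),
            "sample_id" %in% names(annotations))
  if (!all(annotations$sample_id %in% colnames(expr))) {
    stop("cohort_table: annotation sample ids not found in the expression matrix",
         call. = FALSE)
  }
  if ("surv_time" %in% names(annotations) &&
      any(annotations$surv_time < 0, na.rm = TRUE)) {
    stop("cohort_table: negative survival time", call. = FALSE)
  }
  structure(list(expr = expr, annotations = annotations),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d genes x %d samples; annotations: %s\n",
              nrow(x$expr), ncol(x$expr),
              paste(setdiff(names(x$annotations), "sample_id"), collapse = ", ")))
  invisible(x)
}

#' Read / write a count matrix with sample annotations
#'
#' The matrix file is tab-delimited with the gene id in the first column;
#' the annotation file is a CSV with columns sample_id, condition, batch.
#'
#' @param counts_path,samples_path File paths.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  ann <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "condition", "batch") %in% names(ann)))
  ann <- ann[match(colnames(counts), ann$sample_id), ]
  count_matrix(counts, ann$condition, ann$batch)
}

#' @rdname read_count_matrix
#' @param m A [count_matrix()].
#' @export
write_count_matrix <- function(m, counts_path, samples_path) {
  stopifnot(inherits(m, "count_matrix"))
  out <- data.frame(gene_id = rownames(m$counts), m$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(m$samples, samples_path, row.names = FALSE, quote = FALSE)
  invisible(c(counts_path, samples_path))
}

#' Read / write cell-level count data in long format
#'
#' Tab-delimited long format with columns cell_id, sample_id, cell_type,
#' gene, count; zero counts are omitted on write and filled on read.
#'
#' @param path File path.
#' @return A list with `counts` (gene x cell matrix) and `cells` (cell_id,
#'   sample_id, cell_type).
#' @export
read_cell_data <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cell_id", "sample_id", "cell_type", "gene", "count") %in%
                  names(long)))
  cells <- unique(long[, c("cell_id", "sample_id", "cell_type")])
  genes <- sort(unique(long$gene))
  counts <- matrix(0L, length(genes), nrow(cells),
                   dimnames = list(genes, cells$cell_id))
  counts[cbind(match(long$gene, genes), match(long$cell_id, cells$cell_id))] <-
    long$count
  rownames(cells) <- NULL
  list(counts = counts, cells = cells)
}

#' @rdname read_cell_data
#' @param cell_data List with `counts` and `cells` as produced by
#'   [simulate_cell_counts()].
#' @export
write_cell_data <- function(cell_data, path) {
  counts <- cell_data$counts
  nz <- which(counts != 0, arr.ind = TRUE)
  cells <- cell_data$cells
  idx <- match(colnames(counts)[nz[, "col"]], cells$cell_id)
  long <- data.frame(
    cell_id = cells$cell_id[idx],
    sample_id = cells$sample_id[idx],
    cell_type = cells$cell_type[idx],
    gene = rownames(counts)[nz[, "row"]],
    count = counts[nz],
    stringsAsFactors = FALSE
  )
  long <- long[order(long$cell_id, long$gene), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an annotated cohort
#'
#' Expression as a tab-delimited gene x sample matrix (gene id first
#' column); annotations as CSV with a sample_id column.
#'
#' @param expr_path,ann_path File paths.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(expr_path, ann_path) {
  tab <- utils::read.delim(expr_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  expr <- as.matrix(tab[, -1, drop = FALSE])
  rownames(expr) <- tab[[1]]
  ann <- utils::read.csv(ann_path, stringsAsFactors = FALSE)
  cohort_table(expr, ann)
}

#' @rdname read_cohort
#' @param cohort A [cohort_table()].
#' @export
write_cohort <- function(cohort, expr_path, ann_path) {
  stopifnot(inherits(cohort, "cohort_table"))
  out <- data.frame(gene_id = rownames(cohort$expr), cohort$expr,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(cohort$annotations, ann_path, row.names = FALSE,
                   quote = FALSE)
  invisible(c(expr_path, ann_path))
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then the member genes,
#' tab-separated.
#'
#' @param path File path.
#' @return A named list of character vectors with a "descriptions"
#'   attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1)
  attr(sets, "descriptions") <- stats::setNames(vapply(parts, `[`, "", 2),
                                                names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a signature as GMT lines
#'
#' The up component is written as `NAME_UP`; a non-empty down component adds
#' a `NAME_DOWN` line.
#'
#' @param sig A [signature_definition()].
#' @param path File path.
#' @export
write_signature_gmt <- function(sig, path) {
  stopifnot(inherits(sig, "signature_definition"))
  sets <- stats::setNames(list(sig$up_genes), paste0(sig$name, "_UP"))
  desc <- sig$provenance
  if (length(sig$down_genes) > 0) {
    sets[[paste0(sig$name, "_DOWN")]] <- sig$down_genes
    desc <- c(desc, sig$provenance)
  }
  write_gmt(sets, path, descriptions = desc)
}

#' Write / read a truth table as JSON
#'
#' @param truth A truth table from a generator.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  x$specificity_labels <- as.list(x$specificity_labels)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$specificity_labels <- unlist(x$specificity_labels)
  if (!is.null(x$latent) && length(x$latent) > 0) {
    x$latent <- as.data.frame(x$latent, stringsAsFactors = FALSE)
  }
  class(x) <- "truth_table"
  x
}

#' Pipeline configuration
#'
#' One serializable object holding every input path, stage configuration
#' and the seed; round-trips unchanged through YAML.
#'
#' @param paths Named list of input/output paths (counts_a, samples_a,
#'   counts_b, samples_b, ortholog_map, cell_table, cohort_expr,
#'   cohort_ann, out_dir).
#' @param de A [de_config()].
#' @param specificity A [specificity_config()].
#' @param clustering A [clustering_config()].
#' @param combine_policy "union-consistent" or "intersection".
#' @param scoring_scale "zscore" or "log-expression".
#' @param seed Integer seed for any stochastic step.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(paths = list(), de = de_config(),
                            specificity = specificity_config(),
                            clustering = clustering_config(),
                            combine_policy = "union-consistent",
                            scoring_scale = "zscore", seed = 1L) {
  structure(list(paths = paths, de = unclass(de),
                 specificity = unclass(specificity),
                 clustering = unclass(clustering),
                 combine_policy = combine_policy,
                 scoring_scale = scoring_scale, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(
    paths = x$paths %||% list(),
    de = do.call(de_config, x$de %||% list()),
    specificity = do.call(specificity_config, x$specificity %||% list()),
    clustering = do.call(clustering_config,
                         Filter(Negate(is.null),
                                list(k_range = x$clustering$k_range,
                                     anchor_gene = x$clustering$anchor_gene))),
    combine_policy = x$combine_policy %||% "union-consistent",
    scoring_scale = x$scoring_scale %||% "zscore",
    seed = x$seed %||% 1L
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a derivation audit record
#'
#' Checks the audit list against the packaged schema (required keys and
#' their types); errors on the first violation.
#'
#' @param audit Audit list as produced by [derive_signatures()].
#' @return TRUE invisibly.
#' @export
validate_audit <- function(audit) {
  schema <- jsonlite::read_json(
    system.file("extdata", "audit_schema.json", package = "crcsig",
                mustWork = TRUE), simplifyVector = TRUE)
  for (key in schema$required) {
    if (is.null(audit[[key]])) {
      stop(sprintf("validate_audit: missing required field '%s'", key),
           call. = FALSE)
    }
  }
  for (key in names(schema$numeric_fields)) {
    val <- audit[[schema$numeric_fields[[key]]]]
    if (!is.null(val) && !is.numeric(unlist(val))) {
      stop(sprintf("validate_audit: field '%s' must be numeric",
                   schema$numeric_fields[[key]]), call. = FALSE)
    }
  }
  invisible(TRUE)
}
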