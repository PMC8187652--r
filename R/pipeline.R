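.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Derive the BA and WA signatures from study inputs
#'
#' Runs the full derivation chain: per-contrast differential expression and
#' strict filtering, merging of the contrasts, ortholog mapping to
#' unambiguous high-confidence human genes, pseudobulk specificity
#' classification, and construction of the BA (epithelial up/down) and WA
#' (anchor-containing cluster) signatures. Any stage failure is re-raised
#' with the stage name prefixed. When no derivation cohort is supplied the
#' packaged default 8-gene WA module is returned instead of a derived one.
#'
#' @param contrasts List of [count_matrix()] objects (one or more
#'   contrasts, each case vs control).
#' @param ortholog_map Ortholog table (see [map_orthologs()]).
#' @param cell_data List with `counts` and `cells` (cell-level data), or
#'   NULL if `specificity_calls` is given.
#' @param cohort Optional derivation [cohort_table()] for the WA clustering.
#' @param specificity_calls Optional precomputed calls from
#'   [classify_specificity()] (used when `cell_data` is NULL).
#' @param de_cfg,spec_cfg,clust_cfg Stage configurations.
#' @param combine_policy Contrast-merging policy, see [combine_contrasts()].
#' @return A list with `ba`, `wa` (signature definitions) and `audit`
#'   (stage-by-stage gene counts and dropped-gene reasons).
#' @export
derive_signatures <- function(contrasts, ortholog_map, cell_data = NULL,
                              cohort = NULL, specificity_calls = NULL,
                              de_cfg = de_config(),
                              spec_cfg = specificity_config(),
                              clust_cfg = clustering_config(),
                              combine_policy = "union-consistent") {
  if (inherits(contrasts, "count_matrix")) contrasts <- list(contrasts)
  if (is.null(cell_data) && is.null(specificity_calls)) {
    stop(paste("derive_signatures: missing input - provide either 'cell_data'",
               "(cell-level counts with labels) or precomputed",
               "'specificity_calls'"), call. = FALSE)
  }

  sets <- .stage("differential_expression", {
    per_contrast <- lapply(contrasts, function(m) filter_de(fit_de(m, de_cfg), de_cfg))
    Reduce(function(a, b) combine_contrasts(a, b, policy = combine_policy),
           per_contrast)
  })

  mapped_up <- .stage("ortholog_mapping", map_orthologs(sets$up, ortholog_map))
  mapped_down <- .stage("ortholog_mapping", map_orthologs(sets$down, ortholog_map))

  calls <- .stage("specificity", {
    if (is.null(specificity_calls)) {
      pb <- aggregate_pseudobulk(cell_data$counts, cell_data$cells$cell_type,
                                 cell_data$cells$sample_id)
      classify_specificity(pb, spec_cfg)
    } else {
      specificity_calls
    }
  })
  parts <- partition_epithelial(calls)

  ba <- .stage("ba_signature",
               build_ba_signature(mapped_up$human_genes,
                                  mapped_down$human_genes, parts$epithelial))

  wa <- .stage("wa_signature", {
    if (is.null(cohort)) {
      wa_default_signature()
    } else {
      build_wa_signature(ba$up_genes, cohort, clust_cfg)
    }
  })

  audit <- list(
    combine_policy = combine_policy,
    stages = list(
      de_up = length(sets$up), de_down = length(sets$down),
      mapped_up = length(mapped_up$human_genes),
      mapped_down = length(mapped_down$human_genes),
      epithelial = length(parts$epithelial),
      non_epithelial = length(parts$non_epithelial),
      non_specific = length(parts$non_specific),
      ba_up = length(ba$up_genes), ba_down = length(ba$down_genes),
      wa = length(wa$up_genes)
    ),
    dropped_genes = list(
      up = mapped_up$dropped, down = mapped_down$dropped
    ),
    ba = list(up = ba$up_genes, down = ba$down_genes),
    wa = list(up = wa$up_genes,
              derived = !is.null(cohort))
  )
  list(ba = ba, wa = wa, audit = audit)
}

#' Run the derivation pipeline from files
#'
#' Reads every input named in the configuration's `paths`, runs
#' [derive_signatures()], and writes the BA and WA signatures as GMT files
#' plus a JSON audit record into `paths$out_dir`.
#'
#' @param config A [pipeline_config()]. Recognized paths: `counts_a` /
#'   `samples_a` (and optionally `counts_b` / `samples_b` for a second
#'   contrast), `ortholog_map` (TSV), `cell_table` (long TSV) or
#'   `specificity_calls` (TSV), optionally `cohort_expr` / `cohort_ann`,
#'   and `out_dir`.
#' @return The [derive_signatures()] result, invisibly; side effect: files
#'   `ba_signature.gmt`, `wa_signature.gmt`, `audit.json` in `out_dir`.
#' @export
run_derive <- function(config) {
  p <- config$paths
  if (is.null(p$counts_a) || is.null(p$samples_a)) {
    stop("run_derive: missing input 'counts_a'/'samples_a' (mouse count matrix)",
         call. = FALSE)
  }
  if (is.null(p$ortholog_map)) {
    stop("run_derive: missing input 'ortholog_map'", call. = FALSE)
  }
  if (is.null(p$cell_table) && is.null(p$specificity_calls)) {
    stop(paste("run_derive: missing input - provide 'cell_table' (cell-level",
               "counts) or 'specificity_calls' (precomputed classification)"),
         call. = FALSE)
  }
  contrasts <- list(read_count_matrix(p$counts_a, p$samples_a))
  if (!is.null(p$counts_b)) {
    contrasts <- c(contrasts, list(read_count_matrix(p$counts_b, p$samples_b)))
  }
  omap <- utils::read.delim(p$ortholog_map, stringsAsFactors = FALSE)
  cell_data <- if (!is.null(p$cell_table)) read_cell_data(p$cell_table)
  calls <- if (!is.null(p$specificity_calls)) {
    utils::read.delim(p$specificity_calls, stringsAsFactors = FALSE)
  }
  cohort <- if (!is.null(p$cohort_expr)) read_cohort(p$cohort_expr, p$cohort_ann)

  res <- derive_signatures(
    contrasts, omap, cell_data = cell_data, cohort = cohort,
    specificity_calls = calls,
    de_cfg = do.call(de_config, config$de),
    spec_cfg = do.call(specificity_config, config$specificity),
    clust_cfg = clustering_config(k_range = config$clustering$k_range,
                                  anchor_gene = config$clustering$anchor_gene),
    combine_policy = config$combine_policy
  )

  out_dir <- p$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_signature_gmt(res$ba, file.path(out_dir, "ba_signature.gmt"))
  write_signature_gmt(res$wa, file.path(out_dir, "wa_signature.gmt"))
  validate_audit(res$audit)
  jsonlite::write_json(res$audit, file.path(out_dir, "audit.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(res)
}

#' Score signatures on a cohort and run the association battery
#'
#' Scores each signature on the cohort, then runs every association the
#' annotations support: BA score by BRAF status, tumour side, CMS subtype
#' (CMS1 vs rest plus overall ANOVA), T stage (T1-2 vs T3-4), lesion type
#' (SSA vs TVA), the BA-WA Pearson correlation, and median-split survival
#' of the BA score. Analyses whose annotation columns are absent are
#' skipped with a warning.
#'
#' @param cohort A [cohort_table()].
#' @param signatures Named list of [signature_definition()] objects;
#'   elements named "BA" and "WA" receive the full battery.
#' @param out_dir Optional directory for `scores.csv` and
#'   `associations.json`.
#' @return A list with `scores` (long data frame) and `associations`.
#' @export
run_score <- function(cohort, signatures, out_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_table"), length(signatures) > 0)
  if (is.null(names(signatures))) {
    names(signatures) <- vapply(signatures, `[[`, "", "name")
  }
  scores <- lapply(signatures, function(s) score_signature(cohort, s))
  ann <- cohort$annotations
  ids <- ann$sample_id

  aligned <- lapply(scores, function(sc) {
    stats::setNames(sc$score, sc$sample_id)[ids]
  })
  assoc <- list()
  ba <- aligned[["BA"]]
  has <- function(col) col %in% names(ann) && sum(!is.na(ann[[col]])) > 0

  try_assoc <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      warning(sprintf("run_score: skipping '%s': %s", name,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
  }
  if (!is.null(ba)) {
    if (has("braf_status")) {
      assoc$braf <- try_assoc("braf", compare_groups(ba, ann$braf_status))
    }
    if (has("side")) {
      assoc$side <- try_assoc("side", compare_groups(ba, ann$side))
    }
    if (has("cms")) {
      assoc$cms <- try_assoc("cms", compare_multi(ba, ann$cms, focus = "CMS1"))
    }
    if (has("t_stage")) {
      stage_bin <- ifelse(ann$t_stage %in% c("T1", "T2"), "T1-2",
                          ifelse(ann$t_stage %in% c("T3", "T4"), "T3-4", NA))
      assoc$t_stage <- try_assoc("t_stage", compare_groups(ba, stage_bin))
    }
    if (has("surv_time") && has("surv_event")) {
      assoc$survival <- try_assoc(
        "survival", survival_stratify(ba, ann$surv_time, ann$surv_event))
    } else {
      warning("run_score: survival columns absent, skipping survival analysis",
              call. = FALSE)
    }
  }
  wa <- aligned[["WA"]]
  if (!is.null(wa) && has("lesion_type")) {
    assoc$lesion <- try_assoc("lesion", compare_groups(wa, ann$lesion_type))
  }
  if (!is.null(ba) && !is.null(wa)) {
    assoc$ba_wa_correlation <- try_assoc(
      "ba_wa_correlation",
      correlate_signatures(scores[["BA"]], scores[["WA"]]))
  }

  score_long <- do.call(rbind, lapply(names(scores), function(nm) {
    data.frame(signature = nm, sample_id = scores[[nm]]$sample_id,
               score = scores[[nm]]$score, stringsAsFactors = FALSE)
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(score_long, file.path(out_dir, "scores.csv"),
                     row.names = FALSE, quote = FALSE)
    serializable <- lapply(assoc, function(a) {
      if (inherits(a, "survival_result")) unclass(a) else a
    })
    jsonlite::write_json(serializable, file.path(out_dir, "associations.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  list(scores = score_long, associations = assoc)
}
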