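#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators into one validated
#' object. The defaults describe the study conditions the rest of the package
#' is tested under: negative-binomial bulk counts with a moderate batch
#' effect and strongly planted differential expression, a five-cell-type
#' single-cell experiment with eight-fold type-specific genes, and a
#' 500-sample cohort carrying an AXIN2-anchored co-expression block that is
#' negatively correlated with a BA-like program driving group labels and
#' relapse hazard.
#'
#' @param seed Integer seed; identical configurations produce byte-identical
#'   output from every generator.
#' @param n_genes Number of genes in the simulated universe.
#' @param n_samples_per_group Bulk samples per condition (control/case).
#' @param nb_dispersion Negative-binomial dispersion (1/size), shared across
#'   genes; must be positive.
#' @param baseline_log_mean_range Range (log2 counts) from which per-gene
#'   baseline means are drawn uniformly.
#' @param frac_de Fraction of genes with a planted condition effect.
#' @param planted_lfc Planted absolute log2 fold change for DE genes.
#' @param batch_effect_sd SD (log2 units) of the per-gene batch offset.
#' @param n_cell_types Number of cell types in the single-cell generator
#'   (at least 2; the first is always "epithelial").
#' @param cells_per_sample_per_type Cells per (sample, cell type) unit.
#' @param n_samples_sc Number of single-cell samples (biological replicates).
#' @param frac_type_specific Fraction of genes planted as cell-type specific.
#' @param specificity_fold Expected expression fold of a planted specific
#'   gene in its own type over every other type; values <= 1 plant nothing.
#' @param cohort_n Number of cohort samples.
#' @param wa_block_size Size of the planted AXIN2-anchored gene block (>= 2).
#' @param wa_within_cor Expected pairwise correlation within the WA block
#'   (also used as the loading of BA-program genes), in (0, 1).
#' @param ba_wa_cor Correlation of the latent BA and WA programs, in (-1, 1).
#' @param hazard_log_hr_per_sd Log hazard ratio per SD of the latent BA
#'   program in the planted survival model.
#' @param censor_rate Expected fraction of censored survival times, in [0, 1).
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_samples_per_group = 5L,
                       nb_dispersion = 0.1,
                       baseline_log_mean_range = c(3, 9),
                       frac_de = 0.1,
                       planted_lfc = 4,
                       batch_effect_sd = 0.5,
                       n_cell_types = 5L,
                       cells_per_sample_per_type = 200L,
                       n_samples_sc = 4L,
                       frac_type_specific = 0.1,
                       specificity_fold = 8,
                       cohort_n = 500L,
                       wa_block_size = 8L,
                       wa_within_cor = 0.9,
                       ba_wa_cor = -0.6,
                       hazard_log_hr_per_sd = 0.7,
                       censor_rate = 0.3) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    n_samples_per_group = as.integer(n_samples_per_group),
    nb_dispersion = nb_dispersion,
    baseline_log_mean_range = baseline_log_mean_range,
    frac_de = frac_de,
    planted_lfc = planted_lfc,
    batch_effect_sd = batch_effect_sd,
    n_cell_types = as.integer(n_cell_types),
    cells_per_sample_per_type = as.integer(cells_per_sample_per_type),
    n_samples_sc = as.integer(n_samples_sc),
    frac_type_specific = frac_type_specific,
    specificity_fold = specificity_fold,
    cohort_n = as.integer(cohort_n),
    wa_block_size = as.integer(wa_block_size),
    wa_within_cor = wa_within_cor,
    ba_wa_cor = ba_wa_cor,
    hazard_log_hr_per_sd = hazard_log_hr_per_sd,
    censor_rate = censor_rate
  )
  if (!is.finite(cfg$nb_dispersion) || cfg$nb_dispersion <= 0) {
    stop("sim_config: 'nb_dispersion' must be positive", call. = FALSE)
  }
  if (cfg$frac_de < 0 || cfg$frac_de > 1) {
    stop("sim_config: 'frac_de' must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$planted_lfc < 0) {
    stop("sim_config: 'planted_lfc' must be >= 0", call. = FALSE)
  }
  if (cfg$batch_effect_sd < 0) {
    stop("sim_config: 'batch_effect_sd' must be >= 0", call. = FALSE)
  }
  if (cfg$n_cell_types < 2) {
    stop("sim_config: 'n_cell_types' must be >= 2", call. = FALSE)
  }
  if (cfg$cells_per_sample_per_type < 1) {
    stop("sim_config: 'cells_per_sample_per_type' must be >= 1", call. = FALSE)
  }
  if (cfg$wa_block_size < 2) {
    stop("sim_config: 'wa_block_size' must be >= 2 (cluster undefined below that)",
         call. = FALSE)
  }
  if (abs(cfg$ba_wa_cor) >= 1) {
    stop("sim_config: 'ba_wa_cor' must lie strictly inside (-1, 1)", call. = FALSE)
  }
  if (cfg$wa_within_cor <= 0 || cfg$wa_within_cor >= 1) {
    stop("sim_config: 'wa_within_cor' must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1) {
    stop("sim_config: 'censor_rate' must lie in [0, 1)", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# Cell-type vocabulary used throughout: the first name is reserved.
.cell_type_names <- function(n) {
  pool <- c("epithelial", "stroma", "myeloid", "lymphocytes", "endothelial",
            "other")
  if (n <= length(pool)) pool[seq_len(n)] else c(pool, paste0("type", seq_len(n - length(pool))))
}

.empty_truth <- function() {
  structure(list(
    de_up_genes = character(), de_down_genes = character(),
    specificity_labels = character(), wa_block_genes = character(),
    ba_up_genes = character(), ba_down_genes = character(),
    latent = NULL, true_hazard_ratio = NA_real_
  ), class = "truth_table")
}

#' Simulate a mouse bulk RNA-seq count matrix with planted DE genes
#'
#' Draws gene-wise negative-binomial counts for two conditions (control,
#' case) in two batches balanced across conditions. A fraction `frac_de` of
#' genes carries a planted log2 fold change of `+planted_lfc` (up genes) or
#' `-planted_lfc` (down genes) in the case condition; every gene carries a
#' batch offset drawn with SD `batch_effect_sd` so the downstream model's
#' batch covariate has something to absorb.
#'
#' @param config A [sim_config()].
#' @param gene_ids Optional character vector of gene identifiers (length
#'   `n_genes`); defaults to `Gene00001 ...`.
#' @param de_up,de_down Optional explicit sets of planted up/down genes
#'   (subsets of `gene_ids`); when `NULL` they are sampled according to
#'   `frac_de`, split evenly between directions.
#'
#' @return A list with elements `matrix` (a [count_matrix()]) and `truth`
#'   (a truth table recording the planted sets).
#' @export
simulate_mouse_counts <- function(config, gene_ids = NULL,
                                  de_up = NULL, de_down = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_samples_per_group < 2) {
    stop("simulate_mouse_counts: need >= 2 samples per group", call. = FALSE)
  }
  set.seed(config$seed)
  ng <- config$n_genes
  if (is.null(gene_ids)) gene_ids <- sprintf("Gene%05d", seq_len(ng))
  stopifnot(length(gene_ids) == ng, !anyDuplicated(gene_ids))

  n <- config$n_samples_per_group
  condition <- rep(c("control", "case"), each = n)
  # batches alternate within condition so the design is balanced, never confounded
  batch <- rep(rep(c("b1", "b2"), length.out = n), times = 2)
  sample_ids <- sprintf("%s_%02d", condition, c(seq_len(n), seq_len(n)))

  if (is.null(de_up) || is.null(de_down)) {
    n_de <- round(config$frac_de * ng)
    de_idx <- if (n_de > 0) sample.int(ng, n_de) else integer()
    n_up <- ceiling(n_de / 2)
    de_up <- gene_ids[de_idx[seq_len(n_up)]]
    de_down <- gene_ids[de_idx[setdiff(seq_len(n_de), seq_len(n_up))]]
  }
  lfc <- numeric(ng)
  names(lfc) <- gene_ids
  lfc[de_up] <- config$planted_lfc
  lfc[de_down] <- -config$planted_lfc

  baseline <- stats::runif(ng, config$baseline_log_mean_range[1],
                           config$baseline_log_mean_range[2])
  batch_off <- stats::rnorm(ng, 0, config$batch_effect_sd)

  log2mu <- matrix(baseline, ng, 2 * n) +
    outer(lfc, as.numeric(condition == "case")) +
    outer(batch_off, as.numeric(batch == "b2"))
  mu <- 2^log2mu
  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
    nrow = ng, dimnames = list(gene_ids, sample_ids)
  )

  truth <- .empty_truth()
  truth$de_up_genes <- de_up
  truth$de_down_genes <- de_down
  list(matrix = count_matrix(counts, condition, batch), truth = truth)
}

#' Simulate cell-level single-cell counts with planted type-specific genes
#'
#' Generates negative-binomial cell-level counts for `n_cell_types` cell
#' types observed in `n_samples_sc` samples, with
#' `cells_per_sample_per_type` cells per (sample, type) unit. A fraction
#' `frac_type_specific` of genes is planted as specific to one type: their
#' expected expression in that type exceeds every other type by factor
#' `specificity_fold`. With `specificity_fold <= 1` nothing is planted and
#' all genes are labelled non-specific.
#'
#' @param config A [sim_config()].
#' @param gene_ids Optional gene identifiers (length `n_genes`).
#' @param specific_genes Optional named list (cell type -> gene ids) fixing
#'   which genes are planted specific to which type; overrides
#'   `frac_type_specific`.
#'
#' @return A list with `counts` (gene x cell integer matrix), `cells`
#'   (data frame: cell_id, sample_id, cell_type) and `truth` (specificity
#'   labels, "non-specific" for unplanted genes).
#' @export
simulate_cell_counts <- function(config, gene_ids = NULL,
                                 specific_genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$cells_per_sample_per_type < 1) {
    stop("simulate_cell_counts: 'cells_per_sample_per_type' must be >= 1",
         call. = FALSE)
  }
  if (config$n_samples_sc < 2) {
    stop("simulate_cell_counts: need >= 2 samples", call. = FALSE)
  }
  set.seed(config$seed)
  ng <- config$n_genes
  if (is.null(gene_ids)) gene_ids <- sprintf("GENE%05d", seq_len(ng))
  stopifnot(length(gene_ids) == ng, !anyDuplicated(gene_ids))

  types <- .cell_type_names(config$n_cell_types)
  samples <- sprintf("scs%02d", seq_len(config$n_samples_sc))

  labels <- stats::setNames(rep("non-specific", ng), gene_ids)
  if (is.null(specific_genes)) {
    if (config$specificity_fold > 1 && config$frac_type_specific > 0) {
      n_spec <- round(config$frac_type_specific * ng)
      idx <- if (n_spec > 0) sample.int(ng, n_spec) else integer()
      labels[idx] <- sample(types, length(idx), replace = TRUE)
    }
  } else {
    stopifnot(all(names(specific_genes) %in% types))
    for (ty in names(specific_genes)) {
      g <- intersect(specific_genes[[ty]], gene_ids)
      labels[g] <- ty
    }
    if (config$specificity_fold <= 1) labels[] <- "non-specific"
  }

  cells <- expand.grid(
    cell = seq_len(config$cells_per_sample_per_type),
    sample_id = samples, cell_type = types,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  cells$cell_id <- sprintf("c%06d", seq_len(nrow(cells)))
  cells <- cells[, c("cell_id", "sample_id", "cell_type")]

  base_mu <- 2^stats::runif(ng, -2, 2)          # cell-level means ~0.25-4
  samp_fac <- stats::setNames(exp(stats::rnorm(length(samples), 0, 0.1)), samples)

  # per-type expected expression: fold bump for the planted type only
  mu_type <- matrix(base_mu, ng, length(types), dimnames = list(gene_ids, types))
  for (ty in types) {
    sel <- labels == ty
    if (any(sel)) mu_type[sel, ty] <- mu_type[sel, ty] * config$specificity_fold
  }

  mu_cell <- mu_type[, cells$cell_type, drop = FALSE] *
    rep(samp_fac[cells$sample_id], each = ng)
  counts <- matrix(
    stats::rnbinom(length(mu_cell), mu = mu_cell, size = 1 / config$nb_dispersion),
    nrow = ng, dimnames = list(gene_ids, cells$cell_id)
  )

  truth <- .empty_truth()
  truth$specificity_labels <- labels
  list(counts = counts, cells = cells, truth = truth)
}

#' Simulate an annotated human expression cohort with planted structure
#'
#' Draws two latent per-sample programs — a BA-like program and a WA-like
#' (Wnt-activation) program — from a standard bivariate normal with
#' correlation `ba_wa_cor`. A block of `wa_block_size` genes (anchored by
#' "AXIN2") loads on the WA program with pairwise expected correlation
#' `wa_within_cor`; disjoint up/down gene sets load positively/negatively on
#' the BA program with the same loading. Remaining genes are independent
#' noise. Clinical annotations are linked to the programs: BRAF mutation,
#' right-sidedness, CMS1 membership and advanced T stage become more likely
#' with higher BA program; tubulovillous (vs sessile serrated) lesion
#' morphology becomes more likely with higher WA program. Relapse survival
#' times are exponential with log hazard `hazard_log_hr_per_sd` per SD of
#' the BA program, independently censored so that each sample is censored
#' with probability `censor_rate`.
#'
#' @param config A [sim_config()].
#' @param gene_sets Optional list with elements `wa_block`, `ba_up`,
#'   `ba_down`, `background` overriding the default synthetic gene names.
#'   `wa_block` must contain the anchor gene "AXIN2".
#'
#' @return A list with `cohort` (a [cohort_table()]) and `truth` (planted
#'   block membership, latent programs, true hazard ratio).
#' @export
simulate_cohort <- function(config, gene_sets = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$cohort_n < 20) {
    stop("simulate_cohort: 'cohort_n' must be >= 20", call. = FALSE)
  }
  set.seed(config$seed)
  n <- config$cohort_n

  if (is.null(gene_sets)) {
    k <- config$wa_block_size
    wa_block <- c("AXIN2", sprintf("WAG%02d", seq_len(k - 1)))
    ba_up <- sprintf("BAUP%02d", seq_len(20))
    ba_down <- sprintf("BADN%02d", seq_len(20))
    n_bg <- max(config$n_genes - length(wa_block) - 40, 0)
    background <- sprintf("GENE%05d", seq_len(n_bg))
  } else {
    wa_block <- gene_sets$wa_block
    ba_up <- gene_sets$ba_up
    ba_down <- gene_sets$ba_down
    background <- gene_sets$background
  }
  if (!"AXIN2" %in% wa_block) {
    stop("simulate_cohort: the WA block must contain the anchor gene 'AXIN2'",
         call. = FALSE)
  }
  genes <- c(wa_block, ba_up, ba_down, background)
  stopifnot(!anyDuplicated(genes))

  ba <- stats::rnorm(n)
  wa <- config$ba_wa_cor * ba + sqrt(1 - config$ba_wa_cor^2) * stats::rnorm(n)

  r <- config$wa_within_cor
  load <- sqrt(r)
  noise_sd <- sqrt(1 - r)
  draw_block <- function(latent, sign, k) {
    if (k == 0) return(NULL)
    t(vapply(seq_len(k),
             function(i) sign * load * latent + noise_sd * stats::rnorm(n),
             numeric(n)))
  }
  expr <- rbind(
    draw_block(wa, +1, length(wa_block)),
    draw_block(ba, +1, length(ba_up)),
    draw_block(ba, -1, length(ba_down)),
    if (length(background) > 0) {
      matrix(stats::rnorm(length(background) * n), length(background), n)
    }
  )
  rownames(expr) <- genes
  # gene-specific location/scale so the matrix looks like log-intensity data
  g_mean <- stats::rnorm(length(genes), 8, 2)
  g_sd <- stats::runif(length(genes), 0.5, 2)
  expr <- expr * g_sd + g_mean
  sample_ids <- sprintf("pt%04d", seq_len(n))
  colnames(expr) <- sample_ids

  link <- function(intercept, slope, latent) {
    stats::runif(n) < stats::plogis(intercept + slope * latent)
  }
  braf <- ifelse(link(stats::qlogis(0.35), 1.2, ba), "MUT", "WT")
  side <- ifelse(link(0, 1.0, ba), "right", "left")
  cms1 <- link(stats::qlogis(0.25), 1.2, ba)
  cms <- ifelse(cms1, "CMS1", sample(c("CMS2", "CMS3", "CMS4"), n, replace = TRUE))
  late <- link(stats::qlogis(0.6), 0.8, ba)
  t_stage <- ifelse(late,
                    ifelse(stats::runif(n) < 0.8, "T3", "T4"),
                    ifelse(stats::runif(n) < 0.3, "T1", "T2"))
  lesion <- ifelse(link(0, 1.2, wa), "TVA", "SSA")

  z_ba <- as.numeric(scale(ba))
  lambda <- log(2) / 365 * exp(config$hazard_log_hr_per_sd * z_ba)
  t_event <- stats::rexp(n, rate = lambda)
  if (config$censor_rate > 0) {
    lam_c <- lambda * config$censor_rate / (1 - config$censor_rate)
    t_cens <- stats::rexp(n, rate = lam_c)
  } else {
    t_cens <- rep(Inf, n)
  }
  surv_time <- pmin(t_event, t_cens)
  surv_event <- as.integer(t_event <= t_cens)

  ann <- data.frame(
    sample_id = sample_ids, braf_status = braf, side = side, cms = cms,
    t_stage = t_stage, lesion_type = lesion,
    surv_time = surv_time, surv_event = surv_event,
    stringsAsFactors = FALSE
  )

  truth <- .empty_truth()
  truth$wa_block_genes <- wa_block
  truth$ba_up_genes <- ba_up
  truth$ba_down_genes <- ba_down
  truth$latent <- data.frame(sample_id = sample_ids, ba = ba, wa = wa)
  truth$true_hazard_ratio <- exp(config$hazard_log_hr_per_sd)
  list(cohort = cohort_table(expr, ann), truth = truth)
}

#' Simulate a mouse-to-human ortholog table
#'
#' Identity-style map (human id = upper-cased mouse id) with configurable
#' fractions of genes that are dropped to low confidence, mapped ambiguously
#' to two human genes, or collide on one human gene, to exercise the
#' one-to-one high-confidence filter.
#'
#' @param mouse_genes Character vector of mouse gene ids.
#' @param low_conf_frac Fraction demoted to confidence "low".
#' @param ambiguous_frac Fraction given a second high-confidence human hit.
#' @param collision_frac Fraction whose human id collides with another
#'   mouse gene's mapping.
#' @param protect Gene ids whose identity mapping is never perturbed
#'   (used by [simulate_study()] to keep the anchor gene mappable).
#' @param seed Integer seed.
#'
#' @return A data frame with columns `mouse_gene`, `human_gene`,
#'   `confidence` ("high"/"low").
#' @export
simulate_ortholog_map <- function(mouse_genes, low_conf_frac = 0.03,
                                  ambiguous_frac = 0.02,
                                  collision_frac = 0.02,
                                  protect = character(), seed = 1L) {
  set.seed(seed)
  n <- length(mouse_genes)
  map <- data.frame(
    mouse_gene = mouse_genes,
    human_gene = toupper(mouse_genes),
    confidence = "high",
    stringsAsFactors = FALSE
  )
  pool <- setdiff(sample.int(n), which(mouse_genes %in% protect))
  n_low <- round(low_conf_frac * n)
  n_amb <- round(ambiguous_frac * n)
  n_col <- round(collision_frac * n)
  i_low <- pool[seq_len(n_low)]
  i_amb <- pool[n_low + seq_len(n_amb)]
  i_col <- pool[n_low + n_amb + seq_len(n_col)]
  map$confidence[i_low] <- "low"
  extra <- data.frame(
    mouse_gene = mouse_genes[i_amb],
    human_gene = paste0(toupper(mouse_genes[i_amb]), "B"),
    confidence = "high", stringsAsFactors = FALSE
  )
  # collision targets must themselves be unprotected genes
  free <- setdiff(seq_len(n), c(which(mouse_genes %in% protect), i_col))
  targets <- free[seq_len(min(length(i_col), length(free)))]
  i_col <- i_col[seq_along(targets)]
  # the collision rows replace the identity rows for those mouse genes
  map$human_gene[i_col] <- toupper(mouse_genes[targets])
  out <- rbind(map, extra)
  out <- out[!duplicated(out[, c("mouse_gene", "human_gene")]), ]
  rownames(out) <- NULL
  out
}

#' Simulate a coordinated multi-dataset study
#'
#' Wires the individual generators into one coherent synthetic study so the
#' whole derivation pipeline can run end to end: two mouse bulk contrasts
#' sharing the same planted DE genes, an ortholog map over the mouse genes,
#' single-cell data in which most planted DE genes (mapped to human) are
#' epithelial-specific and a few are stromal, and a human cohort in which an
#' AXIN2-anchored subset of the planted epithelial up-genes forms the WA
#' block while the remaining planted genes load on the BA program.
#'
#' @param config A [sim_config()].
#' @param frac_epithelial Fraction of planted DE genes made
#'   epithelial-specific in the single-cell data (the rest become stromal).
#'
#' @return A list with `contrasts` (two count matrices + truths),
#'   `ortholog_map`, `cell_data`, `cohort`, and `truth` (the study-level
#'   planted sets on the human gene namespace).
#' @export
simulate_study <- function(config, frac_epithelial = 0.9) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  gene_ids <- sprintf("Gene%05d", seq_len(ng))

  n_de <- round(config$frac_de * ng)
  de_idx <- sample.int(ng, n_de)
  n_up <- ceiling(n_de / 2)
  up_idx <- de_idx[seq_len(n_up)]
  down_idx <- de_idx[setdiff(seq_len(n_de), seq_len(n_up))]

  k <- config$wa_block_size
  if (length(up_idx) < k) {
    stop("simulate_study: fewer planted up-genes than 'wa_block_size'",
         call. = FALSE)
  }
  # rename the WA-block genes so the human anchor is literally AXIN2
  gene_ids[up_idx[1]] <- "Axin2"
  gene_ids[up_idx[seq(2, k)]] <- sprintf("Wamod%02d", seq_len(k - 1))
  de_up <- gene_ids[up_idx]
  de_down <- gene_ids[down_idx]

  sub_cfg <- function(s) {
    cfg <- config
    cfg$seed <- as.integer((config$seed + s) %% .Machine$integer.max)
    cfg
  }
  contrast_a <- simulate_mouse_counts(sub_cfg(101L), gene_ids, de_up, de_down)
  contrast_b <- simulate_mouse_counts(sub_cfg(202L), gene_ids, de_up, de_down)

  omap <- simulate_ortholog_map(gene_ids, protect = de_up[seq_len(k)],
                                seed = sub_cfg(303L)$seed)
  human_ids <- toupper(gene_ids)

  set.seed(sub_cfg(404L)$seed)
  de_human <- toupper(c(de_up, de_down))
  n_epi <- round(frac_epithelial * length(de_human))
  epi_pick <- sample(de_human, n_epi)
  epi_pick <- union(epi_pick, toupper(de_up[seq_len(k)]))  # WA block stays epithelial
  stroma_pick <- setdiff(de_human, epi_pick)
  # some background genes are specific to other types too
  bg <- setdiff(human_ids, de_human)
  bg_spec <- sample(bg, round(0.05 * length(bg)))
  types <- .cell_type_names(config$n_cell_types)
  bg_assign <- split(bg_spec, sample(types, length(bg_spec), replace = TRUE))
  specific <- bg_assign
  specific$epithelial <- union(specific$epithelial, epi_pick)
  specific$stroma <- union(specific$stroma, stroma_pick)
  cell_data <- simulate_cell_counts(sub_cfg(505L), human_ids, specific)

  wa_block_h <- toupper(de_up[seq_len(k)])
  ba_up_h <- setdiff(intersect(toupper(de_up), epi_pick), wa_block_h)
  ba_down_h <- intersect(toupper(de_down), epi_pick)
  background_h <- setdiff(human_ids, c(wa_block_h, ba_up_h, ba_down_h))
  cohort <- simulate_cohort(sub_cfg(606L), gene_sets = list(
    wa_block = wa_block_h, ba_up = ba_up_h, ba_down = ba_down_h,
    background = background_h
  ))

  truth <- .empty_truth()
  truth$de_up_genes <- de_up
  truth$de_down_genes <- de_down
  truth$specificity_labels <- cell_data$truth$specificity_labels
  truth$wa_block_genes <- wa_block_h
  truth$ba_up_genes <- ba_up_h
  truth$ba_down_genes <- ba_down_h
  truth$latent <- cohort$truth$latent
  truth$true_hazard_ratio <- cohort$truth$true_hazard_ratio

  list(
    contrasts = list(a = contrast_a, b = contrast_b),
    ortholog_map = omap,
    cell_data = cell_data,
    cohort = cohort$cohort,
    truth = truth
  )
}
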