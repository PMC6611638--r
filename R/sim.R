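#' Configuration for the multi-study expression simulator
#'
#' Builds a validated configuration for [generate_multistudy()]. The generator
#' follows an additive model on the natural-log scale: each gene has a
#' baseline, each study-level factor (including the study itself) contributes
#' a per-gene, per-level random shift, a minority of "core" genes carry a
#' condition effect of fixed sign, and i.i.d. Gaussian noise is added before
#' exponentiating to TPM-like positive abundances.
#'
#' The defaults emulate the design of published aposymbiotic-vs-symbiotic
#' *Aiptasia* RNA-seq experiments: four studies contributing 4, 5, 4 and 4
#' replicates per condition (17 samples per symbiotic state in total),
#' strong study-specific batch effects that dominate the condition signal,
#' and five study-level husbandry factors (feeding frequency, days after
#' feeding, water source, light intensity, temperature).
#'
#' @param n_genes number of genes to simulate.
#' @param n_studies number of independent studies.
#' @param replicates_per_condition integer vector, one entry per study:
#'   replicates per condition in that study.
#' @param core_fraction fraction of genes carrying a true condition effect.
#' @param core_effect_mean,core_effect_sd mean and sd of the condition
#'   log-fold-change magnitude (natural-log scale). The sign of each core
#'   gene's effect is drawn once, so both directions occur.
#' @param factor_design named list: factor name -> character vector of level
#'   assignments, one per study. Must contain a `study` factor. See
#'   [default_factor_design()].
#' @param factor_sd named numeric: factor name -> between-level standard
#'   deviation of the per-gene level effects (natural-log scale).
#' @param noise_sd within-group standard deviation (natural-log scale).
#' @param baseline_log_mean,baseline_log_sd distribution of per-gene baseline
#'   log-expression.
#' @param seed integer master seed; all random draws derive from it.
#' @return a list of class `sim_config`.
#' @seealso [generate_multistudy()]
#' @export
sim_config <- function(n_genes = 2000L,
                       n_studies = 4L,
                       replicates_per_condition = c(4L, 5L, 4L, 4L),
                       core_fraction = 0.05,
                       core_effect_mean = 1.5,
                       core_effect_sd = 0.3,
                       factor_design = default_factor_design(n_studies),
                       factor_sd = default_factor_sd(factor_design),
                       noise_sd = 0.4,
                       baseline_log_mean = 3,
                       baseline_log_sd = 1.5,
                       seed = 1L) {
  n_genes <- as.integer(n_genes)
  n_studies <- as.integer(n_studies)
  replicates_per_condition <- as.integer(replicates_per_condition)
  if (n_genes < 1L || n_studies < 1L)
    stop("n_genes and n_studies must be >= 1", call. = FALSE)
  if (length(replicates_per_condition) != n_studies)
    stop("replicates_per_condition must have one entry per study", call. = FALSE)
  if (any(replicates_per_condition < 1L))
    stop("all replicate counts must be >= 1", call. = FALSE)
  if (core_fraction < 0 || core_fraction > 1)
    stop("core_fraction must lie in [0, 1]", call. = FALSE)
  if (core_effect_sd < 0 || noise_sd < 0 || baseline_log_sd < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  if (!is.list(factor_design) || is.null(names(factor_design)) ||
      !"study" %in% names(factor_design))
    stop("factor_design must be a named list containing a 'study' factor",
         call. = FALSE)
  bad_len <- vapply(factor_design, function(x) length(x) != n_studies, logical(1))
  if (any(bad_len))
    stop("factor_design entries inconsistent with n_studies: ",
         paste(names(factor_design)[bad_len], collapse = ", "), call. = FALSE)
  factor_sd <- factor_sd[names(factor_design)]
  if (anyNA(factor_sd) || any(factor_sd < 0))
    stop("factor_sd must supply a non-negative sd for every design factor",
         call. = FALSE)
  structure(list(
    n_genes = n_genes, n_studies = n_studies,
    replicates_per_condition = replicates_per_condition,
    core_fraction = core_fraction,
    core_effect_mean = core_effect_mean, core_effect_sd = core_effect_sd,
    factor_design = lapply(factor_design, as.character),
    factor_sd = factor_sd,
    noise_sd = noise_sd,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default study-level factor design
#'
#' For four studies, returns a curated design in the style of published
#' multi-study *Aiptasia* experiments (each factor takes one level per study,
#' so factors are nested in study, as in real cross-study data). For other
#' study counts only the mandatory `study` factor is returned.
#'
#' @param n_studies number of studies.
#' @return named list of per-study level assignments.
#' @export
default_factor_design <- function(n_studies = 4L) {
  study <- paste0("S", seq_len(n_studies))
  if (n_studies != 4L) return(list(study = study))
  list(
    study             = study,
    feeding_frequency = c("2x_week", "3x_week", "3x_week", "3x_week"),
    days_after_feeding = c("2", "5", "2", "4"),
    water             = c("ASW", "RSW", "ASW", "ASW"),
    light             = c("20umol", "30umol", "40umol", "40umol"),
    temperature       = c("25C", "25C", "26C", "26C")
  )
}

#' Default between-level standard deviations for the simulator factors
#'
#' The study factor dominates (sd 1.5 on the natural-log scale) so that,
#' as in real cross-study expression data, samples group by study rather
#' than by condition; husbandry factors contribute smaller shifts.
#'
#' @param factor_design a design as returned by [default_factor_design()].
#' @return named numeric vector of standard deviations.
#' @export
default_factor_sd <- function(factor_design) {
  sds <- c(study = 1.5, feeding_frequency = 0.4, days_after_feeding = 0.4,
           water = 0.3, light = 0.3, temperature = 0.3)
  out <- sds[names(factor_design)]
  out[is.na(out)] <- 0.5
  names(out) <- names(factor_design)
  out
}

#' Simulate a multi-study expression experiment with known ground truth
#'
#' Draws gene-level baselines, per-factor level effects, signed condition
#' effects for a core subset of genes, and i.i.d. noise, all on the
#' natural-log scale, then exponentiates. For a core gene with effect
#' `delta`, aposymbiotic samples receive `+delta/2` and symbiotic samples
#' `-delta/2`, so the natural-log ratio of geometric means (apo over sym)
#' equals `delta` and the condition factor contributes a per-sample variance
#' of `delta^2/4`.
#'
#' All draws derive from the single master seed in `config`; identical
#' configurations produce bit-identical output.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `multistudy_sim` with elements
#'   \describe{
#'     \item{expr}{numeric matrix, genes x samples, strictly positive
#'       TPM-scale abundances.}
#'     \item{meta}{data.frame with columns `sample`, `study`, `condition`
#'       (`"aposymbiotic"`/`"symbiotic"`) and one column per design factor.}
#'     \item{truth}{ground truth: `core_gene_ids`, `per_gene_effect` (named,
#'       exactly 0 for non-core genes), `variance_components` (per-sample
#'       log-scale variances for each factor, the condition and the noise),
#'       and `seed`.}
#'   }
#' @examples
#' sim <- generate_multistudy(sim_config(n_genes = 50, seed = 7))
#' dim(sim$expr)
#' head(sim$truth$core_gene_ids)
#' @export
generate_multistudy <- function(config) {
  if (!inherits(config, "sim_config"))
    config <- do.call(sim_config, config)
  set.seed(config$seed)
  G <- config$n_genes
  genes <- sprintf("g%05d", seq_len(G))

  # sample layout
  studies <- config$factor_design$study
  reps <- config$replicates_per_condition
  meta <- do.call(rbind, lapply(seq_len(config$n_studies), function(s) {
    data.frame(
      sample = c(sprintf("%s_apo_%d", studies[s], seq_len(reps[s])),
                 sprintf("%s_sym_%d", studies[s], seq_len(reps[s]))),
      study = studies[s],
      condition = rep(c("aposymbiotic", "symbiotic"), each = reps[s]),
      stringsAsFactors = FALSE
    )
  }))
  for (f in setdiff(names(config$factor_design), "study"))
    meta[[f]] <- config$factor_design[[f]][match(meta$study, studies)]
  n <- nrow(meta)

  baseline <- stats::rnorm(G, config$baseline_log_mean, config$baseline_log_sd)

  # Per-factor, per-level gene effects (levels shared across studies that
  # reuse them, as for a real husbandry variable). Each gene's level
  # effects are weighted-centered and rescaled so the realized per-sample
  # variance equals factor_sd^2 exactly: the generator controls log-scale
  # moments exactly so variance-component recovery has a sharp truth.
  log_expr <- matrix(baseline, nrow = G, ncol = n)
  for (f in names(config$factor_design)) {
    lv <- unique(config$factor_design[[f]])
    if (length(lv) < 2L || config$factor_sd[[f]] == 0) next
    wl <- as.vector(table(factor(meta[[f]], levels = lv))) / n
    eff <- matrix(stats::rnorm(G * length(lv)), nrow = G,
                  dimnames = list(NULL, lv))
    eff <- eff - as.vector(eff %*% wl)
    realized_sd <- sqrt(as.vector(eff^2 %*% wl))
    eff <- eff * (config$factor_sd[[f]] / realized_sd)
    log_expr <- log_expr + eff[, match(meta[[f]], lv), drop = FALSE]
  }

  # condition effect for core genes, sign fixed per gene
  n_core <- round(config$core_fraction * G)
  core_idx <- if (n_core > 0) sort(sample.int(G, n_core)) else integer(0)
  delta <- numeric(G)
  if (n_core > 0) {
    magnitude <- stats::rnorm(n_core, config$core_effect_mean,
                              config$core_effect_sd)
    sign_g <- sample(c(-1, 1), n_core, replace = TRUE)
    delta[core_idx] <- sign_g * magnitude
  }
  half <- ifelse(meta$condition == "aposymbiotic", 0.5, -0.5)
  log_expr <- log_expr + outer(delta, half)

  log_expr <- log_expr + matrix(stats::rnorm(G * n, 0, config$noise_sd),
                                nrow = G)
  expr <- exp(log_expr)
  dimnames(expr) <- list(genes, meta$sample)

  vc <- c(vapply(names(config$factor_design), function(f) {
            if (length(unique(config$factor_design[[f]])) < 2L) 0
            else config$factor_sd[[f]]^2
          }, numeric(1)),
          condition = if (n_core > 0) mean(delta[core_idx]^2) / 4 *
                        (n_core / G) else 0,
          noise = config$noise_sd^2)

  truth <- list(
    core_gene_ids = genes[core_idx],
    per_gene_effect = stats::setNames(delta, genes),
    variance_components = vc,
    seed = config$seed
  )
  structure(list(expr = expr, meta = meta, truth = truth, config = config),
            class = "multistudy_sim")
}

#' @export
print.multistudy_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated multi-study expression data: %d genes x %d samples (%d studies)\n",
    nrow(x$expr), ncol(x$expr), x$config$n_studies))
  cat(sprintf("  core genes: %d (true condition effect), seed %d\n",
              length(x$truth$core_gene_ids), x$truth$seed))
  invisible(x)
}

#' Write / read simulator outputs as plain text
#'
#' The expression matrix and sample metadata are written as tab-separated
#' files (first expression column `gene`, header = sample ids); the ground
#' truth is written as JSON.
#'
#' @param sim a `multistudy_sim` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expr = file.path(dir, "expression.tsv"),
             meta = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression(sim$expr, paths[["expr"]])
  utils::write.table(sim$meta, paths[["meta"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_out <- sim$truth
  # a named list serialises as a JSON object, keeping the gene ids
  truth_out$per_gene_effect <- as.list(truth_out$per_gene_effect)
  truth_out$variance_components <- as.list(truth_out$variance_components)
  jsonlite::write_json(truth_out, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' @rdname write_sim
#' @param expr genes x samples matrix.
#' @param path file path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sim
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in ", path,
                                       call. = FALSE)
  if (any(m < 0)) stop("negative abundances in ", path, call. = FALSE)
  m
}
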