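#' Default pipeline configuration
#'
#' Every tunable of [run_pipeline()] with its default, so that a run's
#' manifest can record the complete effective configuration (no hidden
#' defaults). Values supplied by the user (an R list or a JSON file)
#' override these.
#'
#' @return nested list of defaults.
#' @export
pipeline_defaults <- function() {
  list(
    stages = list(simulate = TRUE, de = TRUE, meta = TRUE, overlap = TRUE,
                  qc = TRUE, pvca = TRUE, mc = FALSE, enrich = FALSE),
    sim = list(n_genes = 2000L, seed = 1L),
    expr_path = NULL, meta_path = NULL,        # used when simulate = FALSE
    pseudocount = 0.01,
    study_alpha = 0.05,
    alpha = 0.05,
    min_studies = 2L,
    eligibility = "significant",
    correction = "BY",
    pc_var_threshold = 0.6,
    pvca_factors = NULL,                       # default: all metadata factors
    subset_size = NULL,                        # default: number of meta DEGs
    n_trials = 100L,
    gmt_path = NULL,
    seed = 1L,
    out_dir = "degmeta_run",
    qc_max_genes = 500L
  )
}

merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Run the cross-study meta-analysis pipeline
#'
#' Orchestrates simulate -> per-study differential expression -> DL
#' meta-analysis -> overlap/concordance -> QC (normalization, PCA, Kendall
#' correlation) -> PVCA -> Monte-Carlo subset test -> set enrichment, with
#' stage toggles. Every intermediate table is written to `out_dir`, along
#' with a JSON manifest recording the effective configuration, seeds and
#' per-stage row counts, and a plain-text log. Re-running with an
#' identical configuration reproduces identical outputs.
#'
#' @param config an R list, or path to a JSON file, overriding
#'   [pipeline_defaults()].
#' @return the manifest, invisibly.
#' @examples
#' \donttest{
#' man <- run_pipeline(list(sim = list(n_genes = 300, seed = 4),
#'                          out_dir = tempfile("run")))
#' names(man$stages)
#' }
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- merge_config(pipeline_defaults(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  manifest <- list(package = "degmeta",
                   version = as.character(utils::packageVersion("degmeta")),
                   config = cfg, stages = list())
  outputs <- character(0)
  add_output <- function(path) outputs <<- c(outputs, path)

  run_stage <- function(name, fun) {
    if (!isTRUE(cfg$stages[[name]])) return(invisible(NULL))
    say("stage %s: start", name)
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    say("stage %s: done", name)
    res
  }

  state <- new.env(parent = emptyenv())

  run_stage("simulate", function() {
    sim <- generate_multistudy(do.call(sim_config, cfg$sim))
    paths <- write_sim(sim, cfg$out_dir)
    for (p in paths) add_output(p)
    state$expr <- sim$expr; state$meta <- sim$meta; state$truth <- sim$truth
    manifest$stages$simulate <<- list(
      n_genes = nrow(sim$expr), n_samples = ncol(sim$expr),
      n_core = length(sim$truth$core_gene_ids), seed = sim$truth$seed)
  })
  if (!isTRUE(cfg$stages$simulate)) {
    if (is.null(cfg$expr_path) || is.null(cfg$meta_path))
      stop("expr_path and meta_path are required when simulate is off",
           call. = FALSE)
    state$expr <- read_expression(cfg$expr_path)
    state$meta <- utils::read.delim(cfg$meta_path, stringsAsFactors = FALSE)
  }

  run_stage("de", function() {
    studies <- unique(state$meta$study)
    tabs <- lapply(studies, function(s) {
      tb <- call_degs(
        study_effect_sizes(state$expr, state$meta, s,
                           pseudocount = cfg$pseudocount),
        alpha = cfg$study_alpha)
      path <- file.path(cfg$out_dir, paste0("effects_", s, ".tsv"))
      write_summary_table(tb, path)
      add_output(path)
      tb
    })
    names(tabs) <- studies
    state$tables <- tabs
    manifest$stages$de <<- list(
      studies = studies,
      deg_counts = vapply(tabs, function(tb) sum(tb$deg), integer(1)))
  })

  run_stage("meta", function() {
    res <- run_meta(state$tables, min_studies = cfg$min_studies,
                    alpha = cfg$alpha, eligibility = cfg$eligibility,
                    study_alpha = cfg$study_alpha,
                    correction = cfg$correction)
    path <- file.path(cfg$out_dir, "meta_results.tsv")
    utils::write.table(res, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add_output(path)
    state$meta_res <- res
    manifest$stages$meta <<- list(
      n_eligible = attr(res, "n_eligible"), n_tested = nrow(res),
      n_deg = sum(res$deg))
  })

  run_stage("overlap", function() {
    cs <- overlap_classify(state$tables)
    write_concordance(cs,
                      path_tsv = file.path(cfg$out_dir, "concordance.tsv"),
                      path_json = file.path(cfg$out_dir, "concordance.json"))
    add_output(file.path(cfg$out_dir, "concordance.tsv"))
    add_output(file.path(cfg$out_dir, "concordance.json"))
    state$concordance <- cs
    manifest$stages$overlap <<- list(
      overlap = cs$overlap, concordant_up = cs$concordant_up,
      concordant_down = cs$concordant_down, discordant = cs$discordant,
      discordant_fraction = cs$discordant_fraction)
  })

  run_stage("qc", function() {
    nrm <- normalize_intersample(state$expr)
    state$norm <- nrm$expr
    pc <- pca_samples(nrm$expr)
    pc_path <- file.path(cfg$out_dir, "pca_scores.tsv")
    utils::write.table(data.frame(sample = rownames(pc$scores), pc$scores),
                       pc_path, sep = "\t", quote = FALSE, row.names = FALSE)
    add_output(pc_path)
    # Kendall is quadratic in genes; use the most variable genes
    L <- log2(nrm$expr + 0.5)
    ord <- order(apply(L, 1L, stats::var), decreasing = TRUE)
    top <- ord[seq_len(min(cfg$qc_max_genes, nrow(L)))]
    km <- kendall_matrix(nrm$expr[top, , drop = FALSE])
    km_path <- file.path(cfg$out_dir, "kendall_correlation.tsv")
    utils::write.table(data.frame(sample = rownames(km), km), km_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add_output(km_path)
    manifest$stages$qc <<- list(
      size_factor_range = range(nrm$size_factors),
      pc1_share = pc$explained_variance[1],
      kendall_genes = length(top))
  })

  run_stage("pvca", function() {
    expr <- if (!is.null(state$norm)) state$norm else state$expr
    facs <- cfg$pvca_factors
    if (is.null(facs)) facs <- setdiff(names(state$meta), "sample")
    design <- state$meta[, c("sample", facs), drop = FALSE]
    subset <- if (!is.null(state$meta_res)) {
      degs <- state$meta_res$gene[state$meta_res$deg]
      if (length(degs) >= 2L) degs else NULL
    } else NULL
    pv_all <- pvca_partition(expr, design,
                             pc_var_threshold = cfg$pc_var_threshold)
    pv <- list(all_genes = pv_all$fractions)
    if (!is.null(subset)) {
      pv_deg <- pvca_partition(expr, design, subset,
                               pc_var_threshold = cfg$pc_var_threshold)
      pv$meta_degs <- pv_deg$fractions
    }
    path <- file.path(cfg$out_dir, "pvca_fractions.json")
    jsonlite::write_json(pv, path, auto_unbox = TRUE, digits = NA)
    add_output(path)
    state$pvca <- pv
    state$pvca_design <- design
    manifest$stages$pvca <<- pv
  })

  run_stage("mc", function() {
    if (is.null(state$tables) || is.null(state$meta_res))
      stop("mc stage requires de and meta stages", call. = FALSE)
    expr <- if (!is.null(state$norm)) state$norm else state$expr
    deg_lists <- lapply(state$tables, function(tb) tb$gene[tb$deg])
    observed <- state$meta_res$gene[state$meta_res$deg]
    subset_size <- if (is.null(cfg$subset_size))
      min(length(observed), vapply(deg_lists, length, integer(1)))
    else cfg$subset_size
    mc <- mc_gene_subset_test(expr, state$pvca_design, deg_lists,
                              subset_size = subset_size,
                              n_trials = cfg$n_trials,
                              observed_genes = observed,
                              seed = cfg$seed,
                              pc_var_threshold = cfg$pc_var_threshold)
    path <- file.path(cfg$out_dir, "mc_null.json")
    jsonlite::write_json(
      mc[c("observed_statistic", "n_trials", "n_draws", "subset_size",
           "count_ge", "p_empirical", "seed", "null_draws")],
      path, auto_unbox = TRUE, digits = NA)
    add_output(path)
    manifest$stages$mc <<- list(
      observed_statistic = mc$observed_statistic, n_draws = mc$n_draws,
      count_ge = mc$count_ge, p_empirical = mc$p_empirical)
  })

  run_stage("enrich", function() {
    if (is.null(cfg$gmt_path)) stop("enrich stage requires gmt_path",
                                    call. = FALSE)
    if (is.null(state$meta_res)) stop("enrich stage requires meta stage",
                                      call. = FALSE)
    sets <- read_gmt(cfg$gmt_path)
    degs <- state$meta_res$gene[state$meta_res$deg]
    universe <- state$meta_res$gene
    enr <- fisher_set_enrichment(degs, sets, universe, alpha = cfg$alpha)
    path <- file.path(cfg$out_dir, "enrichment.tsv")
    utils::write.table(enr, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add_output(path)
    manifest$stages$enrich <<- list(
      n_sets = nrow(enr), n_flagged = sum(enr$status != "ns"))
  })

  manifest$outputs <- outputs
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  writeLines(log_lines, log_path)
  invisible(manifest)
}
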