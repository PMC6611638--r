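#' Cross-study overlap and direction concordance of DEG calls
#'
#' Identifies the genes flagged as differentially expressed in *every*
#' study and classifies them by direction agreement: concordant-up (up in
#' symbiotic animals in all studies, i.e. `T < 0` everywhere),
#' concordant-down (`T > 0` everywhere), or discordant (significant in all
#' studies but in differing directions). A zero effect on a flagged gene
#' breaks concordance and is counted as discordant (with a message), so no
#' gene is silently misclassified.
#'
#' @param deg_tables list of study effect tables carrying `deg` and `T`
#'   columns (see [call_degs()]).
#' @return an object of class `concordance_summary`: list with
#'   `per_study_degs` (named counts), `overlap`, `concordant_up`,
#'   `concordant_down`, `discordant`, `discordant_fraction` (percentage of
#'   the overlap, one decimal; `NA` when the overlap is empty), and
#'   `overlap_genes`.
#' @examples
#' sim <- generate_multistudy(sim_config(n_genes = 300, seed = 5))
#' tabs <- lapply(unique(sim$meta$study), function(s)
#'   call_degs(study_effect_sizes(sim$expr, sim$meta, s)))
#' overlap_classify(tabs)
#' @export
overlap_classify <- function(deg_tables) {
  if (length(deg_tables) < 2L)
    stop("at least two study tables are required", call. = FALSE)
  if (any(vapply(deg_tables, function(tb) is.null(tb$deg), logical(1))))
    stop("every table must carry a 'deg' flag (run call_degs first)",
         call. = FALSE)
  per_study <- vapply(deg_tables, function(tb) sum(tb$deg), integer(1))
  studies <- vapply(deg_tables, function(tb) as.character(tb$study[1]),
                    character(1))
  names(per_study) <- studies
  deg_sets <- lapply(deg_tables, function(tb) tb$gene[tb$deg])
  overlap_genes <- Reduce(intersect, deg_sets)

  signs <- vapply(deg_tables, function(tb)
    sign(tb$T)[match(overlap_genes, tb$gene)],
    numeric(length(overlap_genes)))
  if (length(overlap_genes) == 1L) signs <- matrix(signs, nrow = 1L)
  if (length(overlap_genes) > 0L) {
    has_zero <- apply(signs == 0, 1L, any)
    if (any(has_zero))
      message(sum(has_zero), " overlapping gene(s) with a zero effect ",
              "counted as discordant")
    all_pos <- apply(signs > 0, 1L, all)   # higher in apo = down in symbiotic
    all_neg <- apply(signs < 0, 1L, all)
    concordant_down <- sum(all_pos)
    concordant_up <- sum(all_neg)
  } else {
    concordant_down <- concordant_up <- 0L
  }
  concordance_summary(concordant_up = concordant_up,
                      concordant_down = concordant_down,
                      discordant = length(overlap_genes) -
                        concordant_up - concordant_down,
                      per_study_degs = per_study,
                      overlap_genes = overlap_genes)
}

#' Build a concordance summary from class counts
#'
#' Useful when only the published class counts of an overlap analysis are
#' available: the overlap is the sum of the three classes and the
#' discordant fraction is `100 * discordant / overlap`, reported to one
#' decimal place.
#'
#' @param concordant_up,concordant_down,discordant class counts.
#' @param per_study_degs optional named per-study DEG counts.
#' @param overlap_genes optional character vector of overlap gene ids.
#' @return a `concordance_summary` object (see [overlap_classify()]).
#' @examples
#' concordance_summary(166, 134, 93) # discordant fraction 23.7%
#' @export
concordance_summary <- function(concordant_up, concordant_down, discordant,
                                per_study_degs = NULL,
                                overlap_genes = NULL) {
  if (min(concordant_up, concordant_down, discordant) < 0)
    stop("class counts must be non-negative", call. = FALSE)
  overlap <- concordant_up + concordant_down + discordant
  frac <- if (overlap > 0) round(100 * discordant / overlap, 1) else NA_real_
  structure(list(
    per_study_degs = per_study_degs,
    overlap = overlap,
    concordant_up = concordant_up,
    concordant_down = concordant_down,
    discordant = discordant,
    discordant_fraction = frac,
    overlap_genes = overlap_genes
  ), class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  if (!is.null(x$per_study_degs)) {
    cat("Per-study DEG counts:\n")
    print(x$per_study_degs)
  }
  cat(sprintf("Overlap (significant in all studies): %d\n", x$overlap))
  cat(sprintf("  concordant up in symbiotic:   %d\n", x$concordant_up))
  cat(sprintf("  concordant down in symbiotic: %d\n", x$concordant_down))
  cat(sprintf("  discordant:                   %d (%.1f%%)\n",
              x$discordant, x$discordant_fraction))
  invisible(x)
}

#' Write a concordance summary as TSV and JSON
#'
#' @param x a `concordance_summary`.
#' @param path_tsv,path_json output paths (either may be `NULL` to skip).
#' @export
write_concordance <- function(x, path_tsv = NULL, path_json = NULL) {
  row <- data.frame(overlap = x$overlap, concordant_up = x$concordant_up,
                    concordant_down = x$concordant_down,
                    discordant = x$discordant,
                    discordant_fraction = x$discordant_fraction)
  if (!is.null(path_tsv))
    utils::write.table(row, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(x[c("per_study_degs", "overlap", "concordant_up",
                             "concordant_down", "discordant",
                             "discordant_fraction")],
                         path_json, auto_unbox = TRUE, digits = NA)
  invisible(x)
}
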