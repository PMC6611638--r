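#' Read gene sets from a GMT file
#'
#' Thin wrapper around [fgsea::gmtPathways()]; returns a named list of
#' member gene-id vectors, the collection format the enrichment functions
#' consume.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets)))
    stop("duplicate set ids in ", path, call. = FALSE)
  sets
}

#' Fisher's exact gene-set over-representation test
#'
#' For each gene set, tests the 2x2 table (in list / not in list) x (in set
#' / not in set) over the gene universe with a two-sided Fisher's exact
#' test, then controls the false discovery rate across sets with
#' Benjamini-Hochberg. A set is flagged enriched when its odds ratio
#' exceeds 1 and depleted otherwise, at `fdr < alpha`.
#'
#' @param gene_list character vector of genes of interest. Genes outside
#'   the universe are dropped with a warning.
#' @param sets named list of member gene-id vectors (e.g. [read_gmt()]).
#'   Members are intersected with the universe.
#' @param universe character vector of all considered genes (typically the
#'   genes entering the analysis that produced `gene_list`).
#' @param alpha FDR threshold for flagging.
#' @return data.frame with one row per set: `set_id`, `overlap`,
#'   `list_size`, `set_size`, `universe_size`, `odds_ratio` (sample
#'   estimate `ad/bc`, `Inf` when `bc = 0`), `p`, `fdr`, `status`
#'   (`"enriched"`, `"depleted"` or `"ns"`).
#' @examples
#' universe <- sprintf("g%03d", 1:100)
#' sets <- list(A = universe[1:20], B = universe[51:70])
#' fisher_set_enrichment(universe[c(1:8, 90, 95)], sets, universe)
#' @export
fisher_set_enrichment <- function(gene_list, sets, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  gene_list <- unique(gene_list)
  outside <- setdiff(gene_list, universe)
  if (length(outside)) {
    warning(length(outside), " gene(s) outside the universe dropped from ",
            "the list", call. = FALSE)
    gene_list <- intersect(gene_list, universe)
  }
  if (length(gene_list) == 0L) stop("empty gene list", call. = FALSE)
  N <- length(universe)
  K <- length(gene_list)

  rows <- lapply(names(sets), function(id) {
    members <- intersect(unique(sets[[id]]), universe)
    n <- length(members)
    a <- length(intersect(gene_list, members))
    b <- K - a
    cc <- n - a
    d <- N - a - b - cc
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2L))$p.value
    or <- if (b * cc == 0) {
      if (a * d == 0) NaN else Inf
    } else (a * d) / (b * cc)
    data.frame(set_id = id, overlap = a, list_size = K, set_size = n,
               universe_size = N, odds_ratio = or, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, "BH")
  out$status <- ifelse(out$fdr < alpha,
                       ifelse(is.finite(out$odds_ratio) & out$odds_ratio < 1,
                              "depleted", "enriched"),
                       "ns")
  out[order(out$p), ]
}
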