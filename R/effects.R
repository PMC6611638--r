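#' Per-study effect sizes for the aposymbiotic vs symbiotic contrast
#'
#' For one study, computes for every gene the natural-log ratio of
#' geometric-mean expression, aposymbiotic over symbiotic:
#' `T = ln(geomean(apo) / geomean(sym))`, i.e. the difference of the two
#' group means of `log(TPM + pseudocount)`. The standard error is the
#' Welch-style standard error of that difference,
#' `SE = sqrt(s2_apo/n_apo + s2_sym/n_sym)`, and the p-value comes from the
#' normal approximation `z = T/SE`. The sign convention is pipeline-wide:
#' `T > 0` means higher expression in aposymbiotic animals, i.e. the gene is
#' downregulated in symbiotic animals.
#'
#' The per-study variance fed to the meta-analysis is `v = SE^2 * n` with
#' `n` the total number of replicates in the study (both conditions). This
#' is the convention the downstream random-effects model expects; the more
#' conventional `v = SE^2` is available via `variance = "se_sq"` (in which
#' case `v = SE^2` is stored and the `v = SE^2 * n` invariant is relaxed).
#'
#' Genes whose log-values have zero variance in both groups are flagged in
#' the `zero_var` column rather than dropped; they get `p = 1` when `T = 0`
#' and `p = NA` otherwise.
#'
#' @param expr genes x samples matrix of non-negative TPM-scale abundances.
#' @param meta sample metadata data.frame with columns `sample`, `study`,
#'   `condition` (values `"aposymbiotic"`/`"symbiotic"`).
#' @param study study id to analyse.
#' @param pseudocount positive value added before taking logs (geometric
#'   means are undefined at zero). Default 0.01 TPM.
#' @param n_definition `"total"` (default): `n` = replicates in the study
#'   across both conditions; `"per_condition"`: `n` = min of the two group
#'   sizes.
#' @param variance `"se_sq_times_n"` (default) or `"se_sq"`, see Details.
#' @return data.frame of class `study_effect_table` with columns
#'   `gene`, `study`, `T`, `SE`, `n`, `v`, `p`, `zero_var`.
#' @examples
#' sim <- generate_multistudy(sim_config(n_genes = 100, seed = 3))
#' eff <- study_effect_sizes(sim$expr, sim$meta, "S1")
#' head(eff)
#' @export
study_effect_sizes <- function(expr, meta, study, pseudocount = 0.01,
                               n_definition = c("total", "per_condition"),
                               variance = c("se_sq_times_n", "se_sq")) {
  n_definition <- match.arg(n_definition)
  variance <- match.arg(variance)
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  if (!study %in% meta$study)
    stop("study '", study, "' not present in metadata", call. = FALSE)
  sm <- meta[meta$study == study, , drop = FALSE]
  apo <- sm$sample[sm$condition == "aposymbiotic"]
  sym <- sm$sample[sm$condition == "symbiotic"]
  if (length(apo) < 2L || length(sym) < 2L)
    stop("study '", study, "' needs >= 2 samples in each condition",
         call. = FALSE)
  missing_cols <- setdiff(c(apo, sym), colnames(expr))
  if (length(missing_cols))
    stop("samples absent from expression matrix: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  La <- log(expr[, apo, drop = FALSE] + pseudocount)
  Ls <- log(expr[, sym, drop = FALSE] + pseudocount)
  na <- length(apo); ns <- length(sym)
  ma <- rowMeans(La); ms <- rowMeans(Ls)
  va <- rowSums((La - ma)^2) / (na - 1)
  vs <- rowSums((Ls - ms)^2) / (ns - 1)

  T_ <- ma - ms
  SE <- sqrt(va / na + vs / ns)
  zero_var <- SE == 0
  z <- ifelse(zero_var, NA_real_, T_ / SE)
  p <- 2 * stats::pnorm(-abs(z))
  p[zero_var & T_ == 0] <- 1
  if (any(zero_var))
    message(sum(zero_var), " gene(s) with zero variance in both groups ",
            "flagged for study ", study)

  n <- switch(n_definition, total = na + ns, per_condition = min(na, ns))
  v <- switch(variance, se_sq_times_n = SE^2 * n, se_sq = SE^2)

  out <- data.frame(gene = rownames(expr), study = study, T = T_, SE = SE,
                    n = n, v = v, p = p, zero_var = zero_var,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("study_effect_table", "data.frame")
  attr(out, "pseudocount") <- pseudocount
  attr(out, "variance") <- variance
  out
}

#' Flag differentially expressed genes within one study
#'
#' Applies a within-study multiple-testing correction (Benjamini-Hochberg
#' by default, matching the q-values a per-study differential-expression
#' fit would report) and flags genes with `q < alpha`. The reported
#' direction is relative to the symbiotic state: `T > 0` (higher in
#' aposymbiotic) is `"down"` in symbiotic animals, `T < 0` is `"up"`.
#'
#' @param effects a `study_effect_table` (or compatible data.frame with
#'   `gene`, `T`, `p`).
#' @param alpha significance threshold on the corrected p-value, in (0,1).
#' @param method correction method passed to [stats::p.adjust()].
#' @return the input with added columns `q`, `deg` (logical) and
#'   `direction` (`"up"`/`"down"`/`"none"`, regulation in symbiotic).
#' @export
call_degs <- function(effects, alpha = 0.05, method = "BH") {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (anyNA(effects$p) && !all(effects$zero_var[is.na(effects$p)]))
    stop("p-values missing for non-degenerate genes", call. = FALSE)
  effects$q <- stats::p.adjust(effects$p, method = method)
  effects$deg <- !is.na(effects$q) & effects$q < alpha
  effects$direction <- ifelse(effects$T > 0, "down",
                              ifelse(effects$T < 0, "up", "none"))
  effects
}

#' Read a per-study differential-expression summary table
#'
#' Reads an external summary table (tab-separated, columns `gene`, `b`,
#' `se_b`, `n`, optionally `p` and `q`) as produced by a per-study
#' differential-expression fit, and converts it to the internal
#' `study_effect_table` schema: `T <- b`, `SE <- se_b`, `v <- se_b^2 * n`.
#' Malformed rows (non-numeric fields) are reported with their line numbers
#' and dropped.
#'
#' @param path path to the TSV file.
#' @param study optional study id to stamp on the rows (default: basename
#'   of the file without extension).
#' @return a `study_effect_table` data.frame.
#' @export
read_summary_table <- function(path, study = NULL) {
  if (is.null(study)) study <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) {
    warning("empty summary table: ", path, call. = FALSE)
    out <- data.frame(gene = character(0), study = character(0),
                      T = numeric(0), SE = numeric(0), n = integer(0),
                      v = numeric(0), p = numeric(0), zero_var = logical(0))
    class(out) <- c("study_effect_table", "data.frame")
    return(out)
  }
  need <- c("gene", "b", "se_b", "n")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing mandatory column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  num <- lapply(c(b = "b", se_b = "se_b", n = "n"),
                function(cl) suppressWarnings(as.numeric(df[[cl]])))
  bad <- Reduce(`|`, lapply(num, is.na))
  if (any(bad)) {
    # +1 for the header line
    warning("dropping ", sum(bad), " malformed row(s) in ", path,
            " (line ", paste(which(bad) + 1L, collapse = ", "), ")",
            call. = FALSE)
  }
  keep <- !bad
  out <- data.frame(
    gene = df$gene[keep], study = study,
    T = num$b[keep], SE = num$se_b[keep], n = num$n[keep],
    v = num$se_b[keep]^2 * num$n[keep],
    p = if ("p" %in% names(df))
          suppressWarnings(as.numeric(df$p[keep])) else NA_real_,
    zero_var = num$se_b[keep] == 0,
    stringsAsFactors = FALSE
  )
  if ("q" %in% names(df))
    out$q <- suppressWarnings(as.numeric(df$q[keep]))
  class(out) <- c("study_effect_table", "data.frame")
  out
}

#' Write a study effect table to TSV
#'
#' Writes the external schema (`gene`, `b`, `se_b`, `n`, plus `p`/`q` when
#' present) so that [read_summary_table()] round-trips all values.
#'
#' @param effects a `study_effect_table`.
#' @param path output path.
#' @export
write_summary_table <- function(effects, path) {
  out <- data.frame(gene = effects$gene, b = effects$T, se_b = effects$SE,
                    n = effects$n)
  if (!is.null(effects$p)) out$p <- effects$p
  if (!is.null(effects$q)) out$q <- effects$q
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
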