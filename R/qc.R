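#' Median-ratio inter-sample normalization
#'
#' Puts samples from different studies on a common scale so expression
#' values can be compared directly across experiments. For each sample the
#' scaling factor is the median of its ratios to a reference sample (the
#' per-gene geometric mean over all samples), computed over genes expressed
#' (> 0) in every sample; factors are rescaled to geometric mean 1 and the
#' matrix is divided by them. Genes not shared by all input matrices are
#' dropped (and counted in a message).
#'
#' With factors normalised to geometric mean 1 the operation is idempotent:
#' applying it to its own output yields factors of exactly 1.
#'
#' @param matrices a genes x samples matrix, or a list of such matrices
#'   (one per study) sharing a gene universe; the intersection of gene ids
#'   is used.
#' @return list of class `intersample_norm` with `expr` (normalized
#'   matrix), `size_factors` (named, geometric mean 1) and `dropped_genes`.
#' @examples
#' sim <- generate_multistudy(sim_config(n_genes = 100, seed = 2))
#' nrm <- normalize_intersample(sim$expr)
#' summary(nrm$size_factors)
#' @export
normalize_intersample <- function(matrices) {
  if (is.list(matrices) && !is.matrix(matrices)) {
    genes <- Reduce(intersect, lapply(matrices, rownames))
    if (length(genes) == 0L) stop("no genes shared by all matrices",
                                  call. = FALSE)
    dropped <- unique(unlist(lapply(matrices, function(m)
      setdiff(rownames(m), genes))))
    if (length(dropped))
      message(length(dropped), " gene(s) absent from some study dropped")
    x <- do.call(cbind, lapply(matrices, function(m) m[genes, , drop = FALSE]))
  } else {
    x <- matrices
    dropped <- character(0)
  }
  if (ncol(x) < 2L) stop("at least two samples are required", call. = FALSE)
  pos <- rowSums(x > 0) == ncol(x)
  if (!any(pos))
    stop("no gene is expressed in all samples; cannot compute size factors",
         call. = FALSE)
  logref <- rowMeans(log(x[pos, , drop = FALSE]))
  sf <- apply(x[pos, , drop = FALSE], 2L,
              function(col) exp(stats::median(log(col) - logref)))
  sf <- sf / exp(mean(log(sf)))
  structure(list(expr = sweep(x, 2L, sf, "/"),
                 size_factors = sf,
                 dropped_genes = dropped),
            class = "intersample_norm")
}

#' @export
print.intersample_norm <- function(x, ...) {
  cat(sprintf("Inter-sample normalized matrix: %d genes x %d samples\n",
              nrow(x$expr), ncol(x$expr)))
  cat("Size factors:\n")
  print(round(x$size_factors, 4))
  invisible(x)
}

#' Principal component analysis of samples
#'
#' Sample-relationship diagnostic: log2(x + offset) transform, removal of
#' zero-variance genes, gene-wise centering (optionally unit scaling) and
#' singular value decomposition. In multi-study data with strong batch
#' effects the leading components typically separate studies rather than
#' conditions.
#'
#' @param expr genes x samples matrix (normalized TPM scale).
#' @param n_components number of components to return.
#' @param scale_genes also divide each gene by its standard deviation.
#' @param offset pseudo-value added before the log2 transform.
#' @return list of class `sample_pca` with `scores` (samples x components),
#'   `explained_variance` (share per returned component) and `sdev`.
#' @export
pca_samples <- function(expr, n_components = 10L, scale_genes = FALSE,
                        offset = 0.5) {
  if (ncol(expr) < 2L) stop("at least two samples are required", call. = FALSE)
  L <- log2(expr + offset)
  keep <- apply(L, 1L, stats::sd) > 0
  if (!any(keep)) stop("expression matrix is constant", call. = FALSE)
  if (any(!keep))
    message(sum(!keep), " zero-variance gene(s) dropped before PCA")
  pc <- stats::prcomp(t(L[keep, , drop = FALSE]), center = TRUE,
                      scale. = scale_genes)
  k <- min(n_components, ncol(pc$x))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 explained_variance = ev[seq_len(k)],
                 sdev = pc$sdev),
            class = "sample_pca")
}

#' Pairwise Kendall rank correlation of samples
#'
#' Computes the tie-corrected Kendall tau-b between every pair of samples
#' over genes (ties at zero TPM are common, so the tie-corrected variant is
#' used). Tau-b is invariant under any strictly monotone per-sample
#' transform of the values. A constant sample yields `NA` against every
#' other sample, with a warning.
#'
#' @param expr genes x samples matrix.
#' @return symmetric samples x samples correlation matrix with unit
#'   diagonal.
#' @export
kendall_matrix <- function(expr) {
  if (ncol(expr) < 2L) stop("at least two samples are required", call. = FALSE)
  const <- apply(expr, 2L, function(x) stats::sd(x) == 0)
  if (any(const))
    warning("constant sample(s): ",
            paste(colnames(expr)[const], collapse = ", "),
            "; their correlations are NA", call. = FALSE)
  suppressWarnings(km <- stats::cor(expr, method = "kendall"))
  diag(km) <- ifelse(const, NA_real_, 1)
  km
}
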