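#' One-way random-effects variance components by REML
#'
#' Restricted maximum likelihood estimation for the model
#' `y = mu + a_group + e`, with `a ~ N(0, sigma_a^2)` and
#' `e ~ N(0, sigma_e^2)`. The grouped structure gives the REML criterion in
#' closed form as a function of the ratio `theta = sigma_a^2 / sigma_e^2`
#' (block determinants and quadratic forms need only group sums), so a
#' one-dimensional search suffices; `theta = 0` is always evaluated so the
#' boundary solution is exact. This routine is the per-component workhorse
#' of [pvca_partition()] and is cheap enough to be called tens of thousands
#' of times in [mc_gene_subset_test()].
#'
#' @param y numeric response vector.
#' @param g grouping factor (coerced).
#' @return named numeric vector `c(group = sigma_a^2, resid = sigma_e^2)`.
#' @export
reml_oneway <- function(y, g) {
  g <- droplevels(as.factor(g))
  n <- length(y)
  if (n != length(g)) stop("y and g lengths differ", call. = FALSE)
  if (nlevels(g) < 2L)
    return(c(group = 0, resid = stats::var(y)))
  ng <- tabulate(g)
  Sg <- rowsum(y, g)[, 1L]
  y2g <- rowsum(y^2, g)[, 1L]

  crit <- function(theta) {
    d <- 1 + theta * ng
    mu <- sum(Sg / d) / sum(ng / d)
    rS <- Sg - ng * mu                      # group sums of residuals
    r2 <- sum(y2g) - 2 * mu * sum(Sg) + n * mu^2
    qf <- r2 - theta * sum(rS^2 / d)        # r' V0^-1 r
    s2 <- qf / (n - 1)
    if (s2 <= 0) return(Inf)
    (n - 1) * log(s2) + sum(log(d)) + log(sum(ng / d))
  }
  opt <- stats::optimize(function(u) crit(exp(u)), interval = c(-30, 30),
                         tol = 1e-10)
  theta <- if (crit(0) <= opt$objective) 0 else exp(opt$minimum)
  d <- 1 + theta * ng
  mu <- sum(Sg / d) / sum(ng / d)
  rS <- Sg - ng * mu
  r2 <- sum(y2g) - 2 * mu * sum(Sg) + n * mu^2
  s2 <- (r2 - theta * sum(rS^2 / d)) / (n - 1)
  c(group = theta * s2, resid = s2)
}

#' Principal variance component analysis
#'
#' Partitions the total expression variance among experimental factors.
#' The matrix is restricted to `gene_subset`, log2(x + offset) transformed
#' and gene-centered (set `scale_genes = TRUE` to also divide each gene by
#' its standard deviation; centering alone is the convention of the
#' original PVCA method, and unit scaling distorts the partition when
#' realized per-gene factor variances differ); the sample-sample covariance is
#' eigen-decomposed; the minimal set of leading principal components whose
#' cumulative eigenvalue share reaches `pc_var_threshold` is retained; on
#' each retained PC's score vector a one-way random-effects variance
#' component is estimated by REML for every factor independently, with the
#' per-PC residual taken as the part of the score variance the factors do
#' not absorb. Per-PC fractions are averaged with weights equal to each
#' PC's eigenvalue share of the *total* variance, and the unretained share
#' is attributed to the residual, so the reported fractions are a true
#' decomposition of total variance and sum to one.
#'
#' Factors confounded down to a single level in the data are dropped with a
#' warning; factors nested in (or identical to) the study labels are
#' retained, as such study-specific variables are the norm in cross-study
#' designs.
#'
#' @param expr genes x samples matrix (normalized TPM scale).
#' @param design data.frame of factor columns, one row per sample, in the
#'   column order of `expr` (a `sample` column, if present, is matched to
#'   `colnames(expr)` instead).
#' @param gene_subset character vector of gene ids (default: all genes).
#' @param pc_var_threshold cumulative eigenvalue share that decides how
#'   many PCs are modelled, in (0, 1]. Default 0.6.
#' @param offset pseudo-value for the log2 transform.
#' @param scale_genes divide each gene by its standard deviation after
#'   centering (default `FALSE`).
#' @return list of class `pvca_result` with `fractions` (named, factors
#'   plus `resid`, summing to 1), `n_pcs`, `pc_shares` (eigenvalue share of
#'   each retained PC), `per_pc` (per-PC fraction matrix) and `n_genes`.
#' @examples
#' sim <- generate_multistudy(sim_config(n_genes = 300, seed = 9))
#' pv <- pvca_partition(sim$expr, sim$meta[, c("study", "condition")])
#' pv$fractions
#' @export
pvca_partition <- function(expr, design, gene_subset = NULL,
                           pc_var_threshold = 0.6, offset = 0.5,
                           scale_genes = FALSE) {
  if (pc_var_threshold <= 0 || pc_var_threshold > 1)
    stop("pc_var_threshold must lie in (0, 1]", call. = FALSE)
  if (ncol(expr) < 2L) stop("at least two samples are required", call. = FALSE)
  if ("sample" %in% names(design)) {
    design <- design[match(colnames(expr), design$sample), , drop = FALSE]
    design$sample <- NULL
  }
  if (nrow(design) != ncol(expr))
    stop("design must have one row per sample", call. = FALSE)
  if (!is.null(gene_subset)) {
    gene_subset <- intersect(gene_subset, rownames(expr))
    if (length(gene_subset) == 0L)
      stop("gene_subset shares no genes with the expression matrix",
           call. = FALSE)
    expr <- expr[gene_subset, , drop = FALSE]
  }

  L <- log2(expr + offset)
  mu <- rowMeans(L)
  s <- sqrt(rowSums((L - mu)^2) / (ncol(L) - 1))
  keep <- s > 0
  if (!any(keep)) stop("no gene with non-zero variance in subset",
                       call. = FALSE)
  X <- L[keep, , drop = FALSE] - mu[keep]
  if (scale_genes) X <- X / s[keep]
  G <- nrow(X)

  S <- crossprod(X) / (G - 1)              # samples x samples covariance
  eg <- eigen(S, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  shares <- ev / sum(ev)
  n_pcs <- which(cumsum(shares) >= pc_var_threshold - 1e-12)[1L]
  if (is.na(n_pcs)) n_pcs <- length(shares)

  usable <- vapply(design, function(f) length(unique(f)) >= 2L, logical(1))
  if (any(!usable))
    warning("factor(s) with a single level dropped: ",
            paste(names(design)[!usable], collapse = ", "), call. = FALSE)
  design <- design[, usable, drop = FALSE]
  if (ncol(design) == 0L) stop("no usable factor in design", call. = FALSE)
  fac_names <- names(design)

  per_pc <- matrix(0, nrow = n_pcs, ncol = length(fac_names) + 1L,
                   dimnames = list(paste0("PC", seq_len(n_pcs)),
                                   c(fac_names, "resid")))
  for (j in seq_len(n_pcs)) {
    score <- eg$vectors[, j]
    comps <- vapply(fac_names, function(f)
      reml_oneway(score, design[[f]])[["group"]], numeric(1))
    tot <- stats::var(score)
    resid <- max(tot - sum(comps), 0)
    per_pc[j, ] <- c(comps, resid) / (sum(comps) + resid)
  }

  fractions <- colSums(per_pc * shares[seq_len(n_pcs)])
  fractions[["resid"]] <- fractions[["resid"]] +
    (1 - sum(shares[seq_len(n_pcs)]))
  structure(list(fractions = fractions, n_pcs = n_pcs,
                 pc_shares = shares[seq_len(n_pcs)], per_pc = per_pc,
                 n_genes = G),
            class = "pvca_result")
}

#' @export
print.pvca_result <- function(x, ...) {
  cat(sprintf("PVCA on %d genes, %d retained PC(s) (%.1f%% of variance)\n",
              x$n_genes, x$n_pcs, 100 * sum(x$pc_shares)))
  cat("Variance fractions:\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Monte-Carlo random-gene-subset test of a PVCA condition fraction
#'
#' Tests whether the condition-associated variance fraction of an observed
#' gene set (e.g. the meta-analysis DEGs) could have arisen by picking an
#' equally sized random subset from per-study DEG lists. For every trial
#' and every DEG list, `subset_size` genes are sampled without replacement
#' and [pvca_partition()] is run on them; the empirical p-value uses
#' add-one smoothing, `p = (count_ge + 1) / (n_draws + 1)`, while the raw
#' count of null draws at or above the observed statistic is also reported
#' so statements like "0 of 40,000 trials" can be reconstructed.
#'
#' @param expr genes x samples matrix.
#' @param design factor design, see [pvca_partition()].
#' @param deg_lists list of character vectors of gene ids (one per study).
#' @param subset_size genes to sample per draw; must not exceed any list.
#' @param n_trials number of trials (each trial draws once per list).
#' @param observed_genes gene ids whose condition fraction is the observed
#'   statistic.
#' @param seed optional integer seed for reproducible draws.
#' @param condition name of the condition factor in `design`.
#' @param pc_var_threshold passed to [pvca_partition()].
#' @return list of class `mc_null_result` with `observed_statistic`,
#'   `null_draws`, `n_trials`, `n_draws`, `subset_size`, `count_ge`,
#'   `p_empirical` and `seed`.
#' @export
mc_gene_subset_test <- function(expr, design, deg_lists, subset_size,
                                n_trials, observed_genes, seed = NULL,
                                condition = "condition",
                                pc_var_threshold = 0.6) {
  if (n_trials < 1L) stop("n_trials must be >= 1", call. = FALSE)
  sizes <- vapply(deg_lists, length, integer(1))
  if (any(sizes < subset_size))
    stop("subset_size (", subset_size, ") exceeds a DEG list (min size ",
         min(sizes), ")", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  observed <- pvca_partition(expr, design, observed_genes,
                             pc_var_threshold)$fractions[[condition]]
  null_draws <- numeric(n_trials * length(deg_lists))
  i <- 0L
  for (trial in seq_len(n_trials)) {
    for (lst in deg_lists) {
      i <- i + 1L
      pick <- sample(lst, subset_size)
      null_draws[i] <- pvca_partition(expr, design, pick,
                                      pc_var_threshold)$fractions[[condition]]
    }
  }
  count_ge <- sum(null_draws >= observed)
  structure(list(observed_statistic = observed,
                 null_draws = null_draws,
                 n_trials = n_trials,
                 n_draws = length(null_draws),
                 subset_size = subset_size,
                 count_ge = count_ge,
                 p_empirical = (count_ge + 1) / (length(null_draws) + 1),
                 seed = seed),
            class = "mc_null_result")
}

#' @export
print.mc_null_result <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo gene-subset test: %d of %d null draws >= observed %.4f\n",
    x$count_ge, x$n_draws, x$observed_statistic))
  cat(sprintf("  empirical p (add-one) = %.6g\n", x$p_empirical))
  invisible(x)
}
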