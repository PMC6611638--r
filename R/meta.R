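#' DerSimonian-Laird between-study variance
#'
#' Method-of-moments estimate of the between-study variance tau^2 from k
#' study effects `T` with within-study variances `v`. Fixed-effect weights
#' `w = 1/v` give the weighted mean `Tbar = sum(w T)/sum(w)`, the
#' heterogeneity statistic `Q = sum(w (T - Tbar)^2)`, the scaling constant
#' `C = sum(w) - sum(w^2)/sum(w)`, and
#' `tau2 = max((Q - (k - 1)) / C, 0)`.
#'
#' @param T numeric vector of per-study effect sizes (natural-log ratios).
#' @param v numeric vector of within-study variances, all > 0.
#' @return list with elements `Q`, `C`, `tau2`, `df`, `k`.
#' @examples
#' dl_tau2(c(0, 1), c(0.25, 0.25)) # Q = 2, C = 4, tau2 = 0.25
#' @export
dl_tau2 <- function(T, v) {
  k <- length(T)
  if (k < 2L) stop("at least two studies are required", call. = FALSE)
  if (length(v) != k) stop("T and v must have the same length", call. = FALSE)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all within-study variances must be positive and finite",
         call. = FALSE)
  w <- 1 / v
  Tbar <- sum(w * T) / sum(w)
  Q <- sum(w * (T - Tbar)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max((Q - (k - 1)) / C, 0)
  list(Q = Q, C = C, tau2 = tau2, df = k - 1L, k = k)
}

#' Combine study effects under the random-effects model
#'
#' Given study effects `T`, within-study variances `v` and a between-study
#' variance `tau2` (typically from [dl_tau2()]), computes random-effects
#' weights `w* = 1/(v + tau2)`, the combined effect
#' `m* = sum(w* T)/sum(w*)`, its standard error `SE(m*) = 1/sqrt(sum(w*))`,
#' and the two-tailed normal p-value `p = 2 [1 - Phi(|m*/SE|)]`. With
#' `tau2 = 0` this is exactly the fixed-effect inverse-variance estimate.
#'
#' @inheritParams dl_tau2
#' @param tau2 non-negative between-study variance.
#' @return list with elements `m_star`, `se_m`, `z`, `p`.
#' @examples
#' dl_combine(c(0.7, 0.7, 0.7), c(0.3, 0.3, 0.3), 0) # m* = 0.7, p ~ 0.027
#' @export
dl_combine <- function(T, v, tau2) {
  k <- length(T)
  if (k < 2L) stop("at least two studies are required", call. = FALSE)
  if (length(v) != k) stop("T and v must have the same length", call. = FALSE)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all within-study variances must be positive and finite",
         call. = FALSE)
  if (!is.finite(tau2) || tau2 < 0)
    stop("tau2 must be >= 0", call. = FALSE)
  ws <- 1 / (v + tau2)
  m_star <- sum(ws * T) / sum(ws)
  se_m <- 1 / sqrt(sum(ws))
  z <- m_star / se_m
  p <- 2 * stats::pnorm(-abs(z))
  list(m_star = m_star, se_m = se_m, z = z, p = p)
}

#' Benjamini-Yekutieli correction for arbitrary dependence
#'
#' Adjusts p-values with the Benjamini-Hochberg-Yekutieli procedure:
#' `q_(i) = min over j >= i of min(1, p_(j) * m * c(m) / j)` where
#' `c(m) = sum_{h=1..m} 1/h` is the harmonic number that makes the
#' false-discovery-rate bound valid under arbitrary dependence between
#' tests. Output order matches input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of adjusted q-values, same order as `p`.
#' @examples
#' bhy_adjust(c(0.01, 0.02, 0.04, 0.8))
#' @export
bhy_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p, na.last = TRUE)
  q_sorted <- p[o] * m * cm / seq_len(m)
  # enforce monotonicity from the largest p downwards
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q[is.na(p)] <- NA_real_
  q
}

#' Random-effects meta-analysis across study effect tables
#'
#' Runs the per-gene DerSimonian-Laird combination across studies and
#' corrects across genes. A gene enters the meta-analysis when it is
#' significant (per-study `q < study_alpha`) in at least `min_studies`
#' studies (`eligibility = "significant"`, the default) or merely has a
#' valid effect estimate in at least `min_studies` studies
#' (`eligibility = "estimable"`). Eligible genes are then combined over
#' *all* studies in which they have a valid estimate; rows with `SE = 0`
#' are excluded from the combination (their fixed-effect weight would be
#' infinite) and counted in a message.
#'
#' Genes that are significant in different directions in different studies
#' are still combined; discordance is a property the concordance module
#' reports, not an exclusion rule.
#'
#' @param tables list of `study_effect_table` objects (one per study). If a
#'   table has no `q` column it is passed through [call_degs()] with
#'   `study_alpha` first.
#' @param min_studies minimum number of qualifying studies per gene (>= 2).
#' @param alpha significance threshold on the corrected meta p-value.
#' @param eligibility `"significant"` or `"estimable"`, see Details.
#' @param study_alpha per-study significance threshold used for eligibility.
#' @param correction across-gene correction: `"BY"` (default,
#'   [bhy_adjust()]) or `"BH"`.
#' @return data.frame of class `meta_result` with one row per tested gene:
#'   `gene`, `k`, `Q`, `tau2`, `m_star`, `se_m`, `z`, `p`, `q`, `deg`,
#'   `direction` (`"up"`/`"down"` in symbiotic animals; `m_star > 0`, i.e.
#'   higher in aposymbiotic, is `"down"`). The number of eligible genes is
#'   attached as attribute `n_eligible`.
#' @examples
#' sim <- generate_multistudy(sim_config(n_genes = 200, seed = 11))
#' tabs <- lapply(unique(sim$meta$study), function(s)
#'   call_degs(study_effect_sizes(sim$expr, sim$meta, s)))
#' res <- run_meta(tabs)
#' head(res[res$deg, ])
#' @export
run_meta <- function(tables, min_studies = 2L, alpha = 0.05,
                     eligibility = c("significant", "estimable"),
                     study_alpha = 0.05, correction = c("BY", "BH")) {
  eligibility <- match.arg(eligibility)
  correction <- match.arg(correction)
  if (length(tables) < 2L)
    stop("at least two study tables are required", call. = FALSE)
  if (min_studies < 2L) stop("min_studies must be >= 2", call. = FALSE)
  tables <- lapply(tables, function(tb) {
    if (is.null(tb$q)) tb <- call_degs(tb, alpha = study_alpha)
    tb
  })
  long <- do.call(rbind, lapply(tables, function(tb)
    tb[, c("gene", "study", "T", "SE", "n", "v", "q")]))
  n_zero_se <- sum(long$SE == 0, na.rm = TRUE)
  if (n_zero_se > 0)
    message(n_zero_se, " study-gene row(s) with SE = 0 excluded from the ",
            "meta-analysis")
  valid <- long[!is.na(long$SE) & long$SE > 0 & is.finite(long$T), ,
                drop = FALSE]

  sig_counts <- tapply(long$q < study_alpha, long$gene,
                       function(x) sum(x, na.rm = TRUE))
  est_counts <- table(valid$gene)
  eligible <- switch(eligibility,
    significant = names(sig_counts)[sig_counts >= min_studies],
    estimable = names(est_counts)[est_counts >= min_studies])
  # combination always needs >= 2 usable rows
  eligible <- intersect(eligible, names(est_counts)[est_counts >= 2L])
  message(length(eligible), " gene(s) eligible for meta-analysis (",
          eligibility, ", min_studies = ", min_studies, ")")
  if (length(eligible) == 0L) {
    out <- data.frame(gene = character(0), k = integer(0), Q = numeric(0),
                      tau2 = numeric(0), m_star = numeric(0),
                      se_m = numeric(0), z = numeric(0), p = numeric(0),
                      q = numeric(0), deg = logical(0),
                      direction = character(0))
    class(out) <- c("meta_result", "data.frame")
    attr(out, "n_eligible") <- 0L
    return(out)
  }

  valid <- valid[valid$gene %in% eligible, , drop = FALSE]
  by_gene <- split(valid, valid$gene)
  rows <- lapply(by_gene, function(d) {
    ht <- dl_tau2(d$T, d$v)
    cb <- dl_combine(d$T, d$v, ht$tau2)
    data.frame(gene = d$gene[1], k = nrow(d), Q = ht$Q, tau2 = ht$tau2,
               m_star = cb$m_star, se_m = cb$se_m, z = cb$z, p = cb$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- switch(correction, BY = bhy_adjust(out$p),
                  BH = stats::p.adjust(out$p, "BH"))
  out$deg <- out$q < alpha
  out$direction <- ifelse(out$m_star > 0, "down", "up")
  class(out) <- c("meta_result", "data.frame")
  attr(out, "n_eligible") <- length(eligible)
  out
}
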