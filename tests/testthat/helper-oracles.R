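# Independent oracles, kept deliberately naive: literal loop transcriptions
# of the defining formulas, used to validate the package implementations.

# DerSimonian-Laird pipeline written as explicit loops over studies.
dl_brute <- function(T, v) {
  k <- length(T)
  w <- numeric(k)
  for (i in seq_len(k)) w[i] <- 1 / v[i]
  sw <- 0; swT <- 0
  for (i in seq_len(k)) { sw <- sw + w[i]; swT <- swT + w[i] * T[i] }
  Tbar <- swT / sw
  Q <- 0
  for (i in seq_len(k)) Q <- Q + w[i] * (T[i] - Tbar)^2
  sw2 <- 0
  for (i in seq_len(k)) sw2 <- sw2 + w[i]^2
  C <- sw - sw2 / sw
  tau2 <- max((Q - (k - 1)) / C, 0)
  ws <- numeric(k)
  for (i in seq_len(k)) ws[i] <- 1 / (v[i] + tau2)
  m <- 0; sws <- 0
  for (i in seq_len(k)) { m <- m + ws[i] * T[i]; sws <- sws + ws[i] }
  m <- m / sws
  se <- 1 / sqrt(sws)
  z <- m / se
  # two-tailed normal p evaluated through the complementary error function,
  # which keeps full precision in the far tail: 2[1 - Phi(|z|)] = erfc(|z|/sqrt(2))
  p <- pracma::erfc(abs(z) / sqrt(2))
  list(Q = Q, C = C, tau2 = tau2, m_star = m, se_m = se, z = z, p = p)
}

# Benjamini-Yekutieli by direct evaluation of the defining minimum.
by_brute <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  s <- p[o]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, s[j] * m * cm / j)
    q_sorted[i] <- min(1, best)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Two-sided Fisher p by exhaustive hypergeometric summation with choose().
hyper_two_sided <- function(a, K, n, N) {
  lo <- max(0L, K + n - N)
  hi <- min(K, n)
  kk <- lo:hi
  probs <- choose(n, kk) * choose(N - n, K - kk) / choose(N, K)
  sum(probs[probs <= probs[a - lo + 1L] * (1 + 1e-7)])
}

# Kendall tau-b by O(n^2) concordant/discordant pair counting.
kendall_brute <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx_total(x)) * (n0 - tx_total(y)))
}

tx_total <- function(x) {
  tt <- table(x)
  sum(tt * (tt - 1) / 2)
}

# Mean silhouette width of a labelling, via cluster::silhouette.
mean_silhouette <- function(coords, labels) {
  d <- dist(coords)
  mean(cluster::silhouette(as.integer(factor(labels)), d)[, "sil_width"])
}

# A small 4-study simulation used across tests.
small_sim <- function(seed = 1, n_genes = 300, ...) {
  generate_multistudy(sim_config(n_genes = n_genes, seed = seed, ...))
}

# Generator settings with exact log-scale variance components
# (study 4, condition 1, noise 1) used by the PVCA recovery checks.
vc_sim_config <- function(seed, n_genes = 1000) {
  sim_config(n_genes = n_genes, core_fraction = 1, core_effect_mean = 2,
             core_effect_sd = 0, noise_sd = 1,
             factor_design = list(study = paste0("S", 1:4)),
             factor_sd = c(study = 2),
             baseline_log_mean = 6, baseline_log_sd = 0.5, seed = seed)
}

# Per-study effect tables with DEG calls for a simulation.
sim_tables <- function(sim, ...) {
  suppressMessages(lapply(unique(sim$meta$study), function(s)
    call_degs(study_effect_sizes(sim$expr, sim$meta, s), ...)))
}
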