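test_that("tau2 estimation reproduces hand-evaluated heterogeneity", {
  # homogeneous studies: no heterogeneity
  h <- dl_tau2(c(1, 1, 1), c(0.5, 0.5, 0.5))
  expect_equal(h$Q, 0)
  expect_equal(h$tau2, 0)

  # w = (4, 4), Tbar = 0.5, Q = 2, C = 4, tau2 = 0.25
  h2 <- dl_tau2(c(0, 1), c(0.25, 0.25))
  expect_equal(h2$Q, 2)
  expect_equal(h2$C, 4)
  expect_equal(h2$tau2, 0.25)

  # Q below df: truncation at zero
  h3 <- dl_tau2(c(0.10, 0.12), c(1, 1))
  expect_equal(h3$Q, 2e-04)
  expect_equal(h3$tau2, 0)

  expect_error(dl_tau2(1, 1), "two studies")
  expect_error(dl_tau2(c(0, 1), c(0, 1)), "positive")
})

test_that("random-effects combination matches normal-CDF oracles", {
  cb <- dl_combine(c(0.7, 0.7, 0.7), c(0.3, 0.3, 0.3), 0)
  expect_equal(cb$m_star, 0.7)
  expect_equal(cb$se_m, sqrt(0.1))
  expect_equal(cb$p, 2 * (1 - pnorm(0.7 / sqrt(0.1))))
  expect_equal(cb$p, 0.0268567, tolerance = 1e-6)

  # perfect cancellation
  h <- dl_tau2(c(1, -1), c(0.5, 0.5))
  cb2 <- dl_combine(c(1, -1), c(0.5, 0.5), h$tau2)
  expect_equal(cb2$m_star, 0)
  expect_equal(cb2$p, 1)

  # continuation of the tau2 worked example: w* = (2, 2), z = 1
  cb3 <- dl_combine(c(0, 1), c(0.25, 0.25), 0.25)
  expect_equal(cb3$m_star, 0.5)
  expect_equal(cb3$se_m, 0.5)
  expect_equal(cb3$z, 1)
  expect_equal(cb3$p, 2 * (1 - pnorm(1)))
})

test_that("DL estimator agrees with brute-force and metafor on random draws", {
  set.seed(101)
  for (i in 1:300) {
    k <- sample(2:8, 1)
    T <- rnorm(k, 0, 2)
    v <- runif(k, 0.01, 2)
    h <- dl_tau2(T, v)
    cb <- dl_combine(T, v, h$tau2)
    o <- dl_brute(T, v)
    expect_equal(h$Q, o$Q, tolerance = 1e-12)
    expect_equal(h$tau2, o$tau2, tolerance = 1e-12)
    expect_equal(cb$m_star, o$m_star, tolerance = 1e-12)
    expect_equal(cb$se_m, o$se_m, tolerance = 1e-12)
    expect_equal(cb$p, o$p, tolerance = 1e-12)
  }

  skip_if_not_installed("metafor")
  set.seed(7)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    T <- rnorm(k); v <- runif(k, 0.05, 1)
    h <- dl_tau2(T, v)
    cb <- dl_combine(T, v, h$tau2)
    fit <- metafor::rma(yi = T, vi = v, method = "DL")
    expect_equal(h$tau2, fit$tau2, tolerance = 1e-8)
    expect_equal(cb$m_star, as.numeric(fit$beta), tolerance = 1e-8)
    expect_equal(cb$se_m, fit$se, tolerance = 1e-8)
  }
})

test_that("tau2 = 0 reduces to the fixed-effect inverse-variance estimate", {
  set.seed(11)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    T <- rnorm(k); v <- runif(k, 0.01, 1)
    cb <- dl_combine(T, v, 0)
    w <- 1 / v
    expect_equal(cb$m_star, sum(w * T) / sum(w))
    expect_equal(cb$se_m, 1 / sqrt(sum(w)))
  }
})

test_that("the combined effect is convex and SE grows with tau2", {
  set.seed(13)
  for (i in 1:50) {
    k <- sample(2:7, 1)
    T <- rnorm(k, 0, 3); v <- runif(k, 0.01, 2)
    tau2 <- runif(1, 0, 2)
    cb <- dl_combine(T, v, tau2)
    expect_gte(cb$m_star, min(T) - 1e-12)
    expect_lte(cb$m_star, max(T) + 1e-12)
    cb_hi <- dl_combine(T, v, tau2 + 0.5)
    expect_gte(cb_hi$se_m, cb$se_m)
  }
})

test_that("BY adjustment matches hand evaluation, reference and invariants", {
  expect_equal(bhy_adjust(0.03), 0.03)   # c(1) = 1
  q <- bhy_adjust(c(0.01, 0.02, 0.04, 0.8))
  expect_equal(q, c(1 / 12, 1 / 12, 1 / 9, 1))
  expect_equal(round(q, 4), c(0.0833, 0.0833, 0.1111, 1))

  set.seed(21)
  for (i in 1:50) {
    p <- runif(sample(2:200, 1))
    expect_equal(bhy_adjust(p), p.adjust(p, "BY"))
    # order equivariance
    perm <- sample(seq_along(p))
    expect_equal(bhy_adjust(p[perm]), bhy_adjust(p)[perm])
    # BY >= BH >= raw p elementwise
    expect_true(all(bhy_adjust(p) >= p.adjust(p, "BH") - 1e-12))
    expect_true(all(p.adjust(p, "BH") >= p - 1e-12))
  }
  expect_error(bhy_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("run_meta combines identical strong signals exactly", {
  tb <- data.frame(gene = c("g1", "g2"), study = "S1",
                   T = c(2, 0.1), SE = c(0.1, 0.5), n = 8,
                   v = c(0.08, 2), p = c(1e-10, 0.8), zero_var = FALSE)
  tb2 <- transform(tb, study = "S2")
  res <- suppressMessages(run_meta(list(tb, tb2)))
  expect_equal(res$gene, "g1")            # g2 not significant anywhere
  expect_equal(res$m_star, 2)             # identical effects combine to 2
  expect_equal(res$tau2, 0)
  expect_true(res$deg)
  expect_equal(res$direction, "down")     # positive = higher in aposymbiotic
})

test_that("eligibility rules control which genes enter the meta-analysis", {
  # g1 significant in both studies; g2 significant in one; g3 in neither;
  # g4 present (significant) in only one study
  mk <- function(study, genes, p) data.frame(
    gene = genes, study = study, T = 1, SE = 0.2, n = 8, v = 0.32,
    p = p, zero_var = FALSE)
  t1 <- mk("S1", c("g1", "g2", "g3", "g4"), c(1e-9, 1e-9, 0.9, 1e-9))
  t2 <- mk("S2", c("g1", "g2", "g3"), c(1e-9, 0.9, 0.9))
  res <- suppressMessages(run_meta(list(t1, t2)))
  expect_equal(res$gene, "g1")
  res_loose <- suppressMessages(run_meta(list(t1, t2),
                                         eligibility = "estimable"))
  expect_setequal(res_loose$gene, c("g1", "g2", "g3"))
  expect_false("g4" %in% res_loose$gene)  # single-study gene excluded
})

test_that("zero-SE rows are excluded from the combination", {
  t1 <- data.frame(gene = "g1", study = "S1", T = 1, SE = 0.2, n = 8,
                   v = 0.32, p = 1e-9, zero_var = FALSE)
  t2 <- transform(t1, study = "S2")
  t3 <- data.frame(gene = "g1", study = "S3", T = 5, SE = 0, n = 8,
                   v = 0, p = 1e-9, zero_var = TRUE)
  msgs <- capture_messages(res <- run_meta(list(t1, t2, t3)))
  expect_match(paste(msgs, collapse = " "), "SE = 0")
  expect_equal(res$k, 2)                  # only the two valid rows combined
  expect_equal(res$m_star, 1)
})

test_that("meta-analysis recovers core genes with controlled FDR", {
  stats <- t(vapply(1:8, function(s) {
    sim <- generate_multistudy(sim_config(n_genes = 1000, seed = s))
    res <- suppressMessages(run_meta(sim_tables(sim)))
    called <- res$gene[res$deg]
    core <- sim$truth$core_gene_ids
    c(recall = mean(core %in% called),
      fdr = if (length(called) > 0) mean(!(called %in% core)) else 0)
  }, numeric(2)))
  expect_gt(mean(stats[, "recall"]), 0.8)
  expect_lt(mean(stats[, "fdr"]), 0.05)
})
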