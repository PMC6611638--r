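test_that("one-way REML matches lme4 on balanced and unbalanced data", {
  skip_if_not_installed("lme4")
  set.seed(41)
  for (i in 1:10) {
    k <- sample(3:6, 1)
    ng <- sample(3:10, k, replace = TRUE)
    g <- rep(seq_len(k), times = ng)
    y <- rnorm(length(g)) + rnorm(k, 0, runif(1, 0, 2))[g]
    mine <- reml_oneway(y, g)
    fit <- lme4::lmer(y ~ 1 + (1 | g),
                      control = lme4::lmerControl(calc.derivs = FALSE))
    vc <- as.data.frame(lme4::VarCorr(fit))$vcov
    expect_equal(mine[["group"]], vc[1], tolerance = 1e-4)
    expect_equal(mine[["resid"]], vc[2], tolerance = 1e-4)
  }
})

test_that("REML returns the boundary solution when groups are homogeneous", {
  set.seed(43)
  g <- rep(1:4, each = 8)
  y <- rnorm(32)                        # no group structure
  est <- replicate(20, reml_oneway(sample(y), g)["group"])
  expect_lt(mean(est), 0.1)             # mostly at or near zero
  expect_true(any(est == 0))
})

test_that("pure i.i.d. noise attributes ~everything to the residual", {
  fracs <- sapply(1:5, function(s) {
    sim <- generate_multistudy(sim_config(
      n_genes = 400, core_fraction = 0, noise_sd = 1,
      factor_design = list(study = paste0("S", 1:4)),
      factor_sd = c(study = 0), baseline_log_mean = 6,
      baseline_log_sd = 0.5, seed = s))
    pvca_partition(sim$expr,
                   sim$meta[, c("sample", "study", "condition")])$fractions
  })
  m <- rowMeans(fracs)
  expect_gt(m[["resid"]], 0.9)
  expect_lt(m[["study"]], 0.05)
  expect_lt(m[["condition"]], 0.05)
})

test_that("a saturated two-level factor absorbs ~all the variance", {
  # one strong condition shift on every gene, nothing else
  sim <- generate_multistudy(sim_config(
    n_genes = 400, core_fraction = 1, core_effect_mean = 4,
    core_effect_sd = 0, noise_sd = 0.05,
    factor_design = list(study = paste0("S", 1:4)),
    factor_sd = c(study = 0), baseline_log_mean = 6, baseline_log_sd = 0.3,
    seed = 17))
  pv <- pvca_partition(sim$expr,
                       sim$meta[, c("sample", "study", "condition")])
  expect_gt(pv$fractions[["condition"]], 0.95)
})

test_that("variance fractions sum to one and respect invariances", {
  sim <- small_sim(seed = 19, n_genes = 300)
  design <- sim$meta[, c("sample", "study", "condition")]
  pv <- pvca_partition(sim$expr, design)
  expect_equal(sum(pv$fractions), 1, tolerance = 1e-9)
  expect_true(all(pv$fractions >= 0))

  # gene relabeling leaves fractions unchanged
  relab <- sim$expr
  rownames(relab) <- rev(rownames(relab))
  pv2 <- pvca_partition(relab, design)
  expect_equal(pv2$fractions, pv$fractions)

  # sample order permutation leaves fractions unchanged
  perm <- sample(ncol(sim$expr))
  pv3 <- pvca_partition(sim$expr[, perm], design[perm, ])
  expect_equal(pv3$fractions, pv$fractions, tolerance = 1e-9)
})

test_that("the partition is stable under random 95% gene subsets", {
  sim <- generate_multistudy(vc_sim_config(seed = 23))
  design <- sim$meta[, c("sample", "study", "condition")]
  full <- pvca_partition(sim$expr, design, pc_var_threshold = 0.8)$fractions
  set.seed(23)
  sub_genes <- sample(rownames(sim$expr), round(0.95 * nrow(sim$expr)))
  sub <- pvca_partition(sim$expr, design, sub_genes,
                        pc_var_threshold = 0.8)$fractions
  expect_true(all(abs(full - sub) < 0.05))
})

test_that("degenerate designs are caught", {
  sim <- small_sim(seed = 25, n_genes = 60)
  design <- sim$meta[, c("sample", "study", "condition")]
  design$onelevel <- "same"
  expect_warning(pv <- pvca_partition(sim$expr, design), "single level")
  expect_false("onelevel" %in% names(pv$fractions))
  expect_error(pvca_partition(sim$expr, design, pc_var_threshold = 0),
               "pc_var_threshold")
  expect_error(pvca_partition(sim$expr, design, gene_subset = "nope"),
               "no genes")
})

test_that("Monte-Carlo subset test honours its edge contracts", {
  sim <- generate_multistudy(vc_sim_config(seed = 29, n_genes = 600))
  design <- sim$meta[, c("sample", "study", "condition")]
  core <- sim$truth$core_gene_ids
  noise_pool <- rownames(sim$expr)

  # condition-free null lists: observed core statistic beats every draw
  null_lists <- lapply(1:4, function(i) {
    sim0 <- generate_multistudy(sim_config(
      n_genes = 600, core_fraction = 0, noise_sd = 1,
      factor_design = list(study = paste0("S", 1:4)),
      factor_sd = c(study = 2), baseline_log_mean = 6,
      baseline_log_sd = 0.5, seed = 100 + i))
    sim0$expr
  })
  # replace condition-associated genes with pure-batch genes in the matrix
  expr_mix <- rbind(sim$expr[core[1:100], ],
                    null_lists[[1]][1:500, ])
  rownames(expr_mix) <- c(paste0("core", 1:100), paste0("null", 1:500))
  lists <- lapply(1:4, function(i) paste0("null", 1:500))
  mc <- mc_gene_subset_test(expr_mix, design, lists, subset_size = 50,
                            n_trials = 25, observed_genes = paste0("core", 1:100),
                            seed = 5, pc_var_threshold = 0.8)
  expect_equal(mc$count_ge, 0)
  expect_equal(mc$p_empirical, 1 / (mc$n_draws + 1))
  expect_equal(mc$n_draws, 100)

  # observed below every draw: p ~ 1
  lists_core <- lapply(1:4, function(i) paste0("core", 1:100))
  mc2 <- mc_gene_subset_test(expr_mix, design, lists_core, subset_size = 50,
                             n_trials = 25,
                             observed_genes = paste0("null", 1:500),
                             seed = 5, pc_var_threshold = 0.8)
  expect_equal(mc2$count_ge, mc2$n_draws)
  expect_gt(mc2$p_empirical, 0.99)

  # bit-identical under a fixed seed
  mc3 <- mc_gene_subset_test(expr_mix, design, lists, subset_size = 50,
                             n_trials = 25,
                             observed_genes = paste0("core", 1:100),
                             seed = 5, pc_var_threshold = 0.8)
  expect_identical(mc, mc3)

  expect_error(
    mc_gene_subset_test(expr_mix, design, lists, subset_size = 501,
                        n_trials = 2, observed_genes = paste0("core", 1:100)),
    "exceeds")
})
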