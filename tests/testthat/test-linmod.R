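test_that("design matrices encode the three parameterizations", {
  groups <- c("control", "control", "I", "II", "III", "IV")
  Xb <- build_design(groups, "baseline")
  Xc <- build_design(groups, "cellmeans")
  Xn <- build_design(groups, "numeric")
  expect_equal(colnames(Xb), c("intercept", "stageI", "stageII", "stageIII",
                               "stageIV"))
  expect_equal(unname(Xn[, "stage_num"]), c(0, 0, 1, 2, 3, 4))
  expect_equal(colnames(Xn), c("intercept", "stage_num"))
  # all-control baseline design: stage columns all zero
  X0 <- build_design(rep("control", 4), "baseline")
  expect_true(all(X0[, -1] == 0))
  expect_error(build_design(c("control", "V")), "unknown group")
  # same column space: projections agree
  expect_equal(qr(cbind(Xb, Xc))$rank, qr(Xb)$rank)
})

test_that("per-gene least squares matches the normal-equations oracle", {
  ds <- tiny_dataset(n_genes = 12, per_group = 4, seed = 31)
  X <- build_design(ds$samples$group, "cellmeans")
  fit <- fit_gene_models(ds, X)
  for (g in c(1, 5, 12)) {
    expect_equal(unname(fit$coefficients[g, ]),
                 ols_oracle(X, ds$exprs[g, ]), tolerance = 1e-10)
  }
  # unweighted cell-means coefficients are exactly the group sample means
  for (s in stage_levels()) {
    expect_equal(unname(fit$coefficients[, s]),
                 unname(rowMeans(ds$exprs[, ds$samples$group == s])),
                 tolerance = 1e-12)
  }
  # baseline and cell-means give identical fitted values
  fitb <- fit_gene_models(ds, build_design(ds$samples$group, "baseline"))
  expect_equal(fitted(fitb), fitted(fit), tolerance = 1e-10)
  # baseline stage coefficient equals (stage - control) mean difference
  expect_equal(unname(fitb$coefficients[, "stageIII"]),
               unname(fit$coefficients[, "III"] -
                        fit$coefficients[, "control"]),
               tolerance = 1e-10)
})

test_that("degenerate fits behave as closed forms dictate", {
  # constant gene: zero residual variance, zero non-intercept coefficients
  exprs <- matrix(7, 2, 10, dimnames = list(c("a", "b"), NULL))
  exprs[2, ] <- rnorm(10)
  ds <- stage_dataset(exprs, tibble::tibble(
    barcode = paste0("s", 1:10), group = rep(stage_levels(), each = 2)))
  fit <- fit_gene_models(ds, build_design(ds$samples$group, "baseline"))
  expect_equal(unname(fit$coefficients["a", ]), c(7, 0, 0, 0, 0),
               tolerance = 1e-12)
  expect_equal(fit$sigma2[["a"]], 0, tolerance = 1e-20)

  # saturated model: one sample per group, values 1..5
  ds1 <- stage_dataset(
    matrix(1:5, 1, 5, dimnames = list("g", NULL)),
    tibble::tibble(barcode = paste0("s", 1:5), group = stage_levels()))
  fit1 <- fit_gene_models(ds1, build_design(stage_levels(), "cellmeans"))
  expect_equal(unname(fit1$coefficients[1, ]), c(1, 2, 3, 4, 5))
  expect_equal(fit1$df_residual, 0)
  expect_error(ebayes_moderate(fit1), "residual")

  # rank-deficient design errors and names the collinear column
  Xbad <- cbind(build_design(ds$samples$group, "cellmeans"), dup = 1)
  expect_error(fit_gene_models(ds, Xbad), "rank deficient")
})

test_that("mean-variance weights are positive and flat under homoskedasticity", {
  sim <- simulate_stage_expression(sim_config(
    n_genes = 600, class_fractions = c(null = 1), prior_df = 1e6,
    prior_var = 0.1, seed = 17,
    group_sizes = c(control = 20, I = 20, II = 20, III = 20, IV = 20)))
  X <- build_design(sim$dataset$samples$group, "baseline")
  w <- estimate_meanvar_weights(sim$dataset, X)
  expect_true(all(w > 0))
  # flat true trend: weights within 20% of their median
  expect_lt(max(w) / median(w), 1.2)
  expect_gt(min(w) / median(w), 0.8)
  # weights disabled gives fits identical to unweighted fits
  f0 <- fit_gene_models(sim$dataset, X)
  f1 <- fit_gene_models(sim$dataset, X, weights = NULL)
  expect_identical(f0$coefficients, f1$coefficients)
  # too few genes: unit weights with a warning
  small <- subset_dataset(sim$dataset, genes = 1:5)
  expect_warning(w5 <- estimate_meanvar_weights(small, X), "unit weights")
  expect_true(all(w5 == 1))
})

test_that("moderation obeys its closed-form limits", {
  ds <- tiny_dataset(n_genes = 30, per_group = 5, seed = 41)
  X <- build_design(ds$samples$group, "baseline")
  fit <- fit_gene_models(ds, X)

  # prior df 0: moderated t equals ordinary t exactly
  m0 <- ebayes_moderate(fit, prior_df = 0)
  t_ord <- fit$coefficients / (fit$stdev_unscaled * sqrt(fit$sigma2))
  expect_equal(m0$t, t_ord, tolerance = 1e-12)
  expect_equal(unname(m0$var_post), unname(fit$sigma2), tolerance = 1e-12)

  # prior df Inf: posterior variance is the prior variance for every gene
  mInf <- ebayes_moderate(fit, prior_df = Inf, prior_var = 0.25)
  expect_true(all(mInf$var_post == 0.25))

  # posterior variance always lies between s2 and s0^2
  m <- ebayes_moderate(fit)
  lo <- pmin(fit$sigma2, m$var_prior)
  hi <- pmax(fit$sigma2, m$var_prior)
  expect_true(all(m$var_post >= lo - 1e-12 & m$var_post <= hi + 1e-12))

  # moderated F at prior df 0 equals the classical F of the joint test
  q <- 4
  rss1 <- fit$sigma2 * fit$df_residual
  mu0 <- rowMeans(ds$exprs)
  rss0 <- rowSums((ds$exprs - mu0)^2)
  F_classic <- ((rss0 - rss1) / q) / fit$sigma2
  expect_equal(unname(m0$F), unname(F_classic), tolerance = 1e-10)

  # adjusted p >= raw p, in [0, 1]
  expect_true(all(m$adj_p >= m$p - 1e-15))
  expect_true(all(m$adj_p >= 0 & m$adj_p <= 1))
})

test_that("variance-prior hyperparameters are recovered from simulation", {
  d0 <- 4; s0 <- 0.05
  sim <- simulate_stage_expression(sim_config(
    n_genes = 10000, class_fractions = c(null = 1),
    prior_df = d0, prior_var = s0, seed = 23))
  X <- build_design(sim$dataset$samples$group, "baseline")
  m <- ebayes_moderate(fit_gene_models(sim$dataset, X))
  expect_lt(abs(m$df_prior - d0) / d0, 0.2)
  expect_lt(abs(m$var_prior - s0) / s0, 0.2)
})

test_that("moderation agrees with an independent reference implementation", {
  skip_if_not_installed("limma")
  ds <- tiny_dataset(n_genes = 60, per_group = 5, seed = 53,
                     offsets = matrix(rnorm(60 * 4, sd = 0.5), 60, 4))
  X <- build_design(ds$samples$group, "baseline")
  fit <- fit_gene_models(ds, X)
  m <- ebayes_moderate(fit)
  lf <- limma::eBayes(limma::lmFit(ds$exprs, X))
  expect_equal(m$df_prior, lf$df.prior, tolerance = 1e-6)
  expect_equal(unname(m$var_prior), unname(lf$s2.prior), tolerance = 1e-6)
  expect_equal(unname(m$t), unname(lf$t), tolerance = 1e-8)
  expect_equal(unname(m$p), unname(lf$p.value), tolerance = 1e-8)
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(c(0.005, 0.1, 0.9)), c(0.015, 0.15, 0.9))
  expect_equal(adjust_bh(0.73), 0.73)
  expect_error(adjust_bh(c(0.1, 1.2)), "\\[0, 1\\]")

  # all permutations of a p-vector of length <= 6
  base_p <- c(0.001, 0.02, 0.04, 0.3, 0.31, 0.9)
  perms <- rbind(1:6, 6:1)
  set.seed(77)
  for (i in 1:40) perms <- rbind(perms, sample(6))
  for (i in seq_len(nrow(perms))) {
    p <- base_p[perms[i, ]]
    expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
  # random vectors of every length up to 6
  for (len in 1:6) {
    for (r in 1:20) {
      p <- round(runif(len), 3)
      expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
    }
  }
})

test_that("regulation status reflects lfc signs", {
  expect_equal(regulation_status(c(1.2, 2.0, 1.1, 0.5)), "UP")
  expect_equal(regulation_status(c(-1, -2, -1, -3)), "DOWN")
  expect_equal(regulation_status(c(1, -1, 1, 1)), "MIXED")
  m <- rbind(c(1, 1, 1, 1), c(-1, -1, -1, -1), c(0, 1, 1, 1))
  expect_equal(regulation_status(m), c("UP", "DOWN", "MIXED"))
})
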