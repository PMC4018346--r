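# Penalized multi-SNP engine: optimality (KKT), limiting cases, the
# independent-optimizer oracle, penalty tuning, bootstrap stability and
# post-selection inference.

make_instance <- function(seed, n = 150L, p = 12L, n_cov = 3L, beta = NULL) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 2L, runif(p, 0.1, 0.45)[rep(1:p, each = n)]),
              n, p)
  colnames(X) <- paste0("s", seq_len(p))
  Xc <- if (n_cov > 0) matrix(rnorm(n * n_cov), n) else NULL
  eta <- -0.2 + if (is.null(beta)) 0 else drop(X %*% beta)
  y <- rbinom(n, 1L, plogis(eta))
  list(X = X, Xc = Xc, y = y)
}

pen_objective <- function(X, Xc, y, intercept, beta_cov, beta_snps, lambda) {
  eta <- intercept + drop(X %*% beta_snps) +
    if (is.null(Xc)) 0 else drop(Xc %*% beta_cov)
  sum(y * eta - log1p(exp(eta))) - lambda * sum(abs(beta_snps))
}

test_that("lambda = 0 recovers the unpenalized maximum likelihood fit", {
  inst <- make_instance(1, beta = c(0.6, rep(0, 11)))
  f <- fit_penalized(inst$X, inst$Xc, inst$y, 0)
  g <- glm(inst$y ~ inst$Xc + inst$X, family = binomial)
  expect_lt(max(abs(c(f$intercept, f$beta_covariates, f$beta_snps) -
                      coef(g))), 1e-6)
})

test_that("penalties at or above lambda_max zero out every SNP", {
  inst <- make_instance(2)
  lmax <- snplasso:::lambda_max_null(inst$X, inst$Xc, inst$y, lasso_config())
  f <- fit_penalized(inst$X, inst$Xc, inst$y, lmax * 1.0001)
  expect_true(all(f$beta_snps == 0))
  expect_length(f$selected, 0)
  # covariates and intercept sit at the covariate-only MLE
  g <- glm(inst$y ~ inst$Xc, family = binomial)
  expect_lt(max(abs(c(f$intercept, f$beta_covariates) - coef(g))), 1e-6)
})

test_that("returned fits satisfy the KKT optimality conditions", {
  for (seed in 1:10) {
    inst <- make_instance(seed + 10, n = 120L, p = 15L,
                          beta = c(0.5, -0.4, rep(0, 13)))
    lmax <- snplasso:::lambda_max_null(inst$X, inst$Xc, inst$y,
                                       lasso_config())
    lambda <- runif(1, 0.02, 0.8) * lmax
    f <- fit_penalized(inst$X, inst$Xc, inst$y, lambda)
    expect_lt(f$kkt_violation, 1e-5)
    expect_setequal(f$selected, names(f$beta_snps)[f$beta_snps != 0])
    # objective never below the all-zero-SNP solution at the same penalty
    g0 <- glm(inst$y ~ inst$Xc, family = binomial)
    obj_fit <- pen_objective(inst$X, inst$Xc, inst$y, f$intercept,
                             f$beta_covariates, f$beta_snps, lambda)
    obj_null <- pen_objective(inst$X, inst$Xc, inst$y, coef(g0)[1],
                              coef(g0)[-1], rep(0, ncol(inst$X)), lambda)
    expect_gte(obj_fit, obj_null - 1e-8)
    # AIC bookkeeping
    k <- length(f$selected) + length(f$beta_covariates) + 1L
    expect_equal(f$aic, -2 * f$log_likelihood + 2 * k)
  }
})

test_that("objective values match an independent optimizer", {
  skip_if_not_installed("glmnet")
  for (seed in 1:5) {
    inst <- make_instance(seed + 30, n = 50L, p = 10L, n_cov = 0L,
                          beta = c(0.8, rep(0, 9)))
    lmax <- snplasso:::lambda_max_null(inst$X, NULL, inst$y, lasso_config())
    lambda <- 0.3 * lmax
    mine <- fit_penalized(inst$X, NULL, inst$y, lambda)
    gn <- glmnet::glmnet(inst$X, inst$y, family = "binomial",
                         lambda = lambda / length(inst$y),
                         standardize = FALSE, thresh = 1e-14)
    obj_mine <- pen_objective(inst$X, NULL, inst$y, mine$intercept,
                              numeric(0), mine$beta_snps, lambda)
    obj_gn <- pen_objective(inst$X, NULL, inst$y, gn$a0,
                            numeric(0), as.numeric(gn$beta), lambda)
    expect_gte(obj_mine, obj_gn - 1e-6)
    expect_lt(abs(obj_mine - obj_gn), 1e-4)
  }
})

test_that("invalid penalized-fit inputs are rejected", {
  inst <- make_instance(3)
  expect_error(fit_penalized(inst$X, inst$Xc, inst$y, -1), "nonnegative")
  Xna <- inst$X
  Xna[1, 1] <- NA
  expect_error(fit_penalized(Xna, inst$Xc, inst$y, 1), "impute")
  expect_error(fit_penalized(inst$X, inst$Xc, inst$y + 1, 1), "binary")
  expect_error(lasso_config(lambda_grid = c(1, 2, 3)), "decreasing")
  expect_error(lasso_config(n_folds = 1), "n_folds")
})

test_that("support size is monotone along the penalty path", {
  inst <- make_instance(4, n = 250L, p = 20L,
                        beta = c(0.5, 0.4, -0.5, rep(0, 17)))
  lc <- lasso_config(dfmax = 1000L)
  grid <- snplasso:::default_lambda_grid(inst$X, inst$Xc, inst$y, lc)
  d <- snplasso:::lasso_design(inst$X, inst$Xc, lc)
  pf <- snplasso:::cpp_lasso_path(d$X, as.numeric(inst$y), d$penalty, grid,
                                  numeric(ncol(d$X)), lc$convergence_tol,
                                  lc$max_iter, lc$dfmax)
  # grid is decreasing, so support size must not shrink along it
  # (occasional single-coordinate swaps are allowed)
  expect_true(all(diff(pf$nnz) >= -1))
  expect_gt(pf$nnz[length(grid)], pf$nnz[1])
})

test_that("penalty tuning honours the grid and selects sensibly", {
  inst <- make_instance(5, n = 300L, p = 15L)
  one <- lasso_config(lambda_grid = 2.5)
  set.seed(1)
  tuned <- choose_lambda_cv_aic(inst$X, inst$Xc, inst$y, one)
  expect_equal(tuned$lambda_opt, 2.5)
  # pure noise: the empty model should usually win (scaled to 15 datasets)
  empties <- vapply(1:15, function(i) {
    inst <- make_instance(100 + i, n = 300L, p = 20L)
    set.seed(i)
    length(choose_lambda_cv_aic(inst$X, inst$Xc, inst$y,
                                lasso_config())$fit$selected) == 0L
  }, NA)
  expect_gte(mean(empties), 0.6)
})

test_that("a strong SNP is selected at the tuned penalty", {
  # per-allele log-OR 0.5 at the study scale; scaled to 10 datasets
  hits <- vapply(1:10, function(i) {
    sim <- small_cohort(seed = 700L + i, n_cases = 1058L, n_controls = 1138L,
                        n_snps = 20L, effects = c(rs6567355 = 0.5))
    cd <- covariate_design(sim$cohort)
    set.seed(i)
    sel <- choose_lambda_cv_aic(sim$genotypes$dosage[cd$keep, ], cd$X,
                                cd$y, lasso_config())$fit$selected
    "rs6567355" %in% sel
  }, NA)
  expect_gte(mean(hits), 0.9)
})

test_that("an overwhelming effect is always reproducible in bootstrap", {
  inst <- make_instance(6, n = 250L, p = 5L, beta = c(2.5, rep(0, 4)))
  lc <- lasso_config(seed = 3L)
  rep <- bootstrap_stability(inst$X, inst$Xc, inst$y, lc, n_bootstrap = 10L)
  expect_equal(unname(rep["s1"]), 100)
  expect_true(all(rep >= 0 & rep <= 100))
})

test_that("null-data reproducibility stays below 50%", {
  inst <- make_instance(7, n = 400L, p = 15L)
  lc <- lasso_config(seed = 5L)
  rep <- bootstrap_stability(inst$X, inst$Xc, inst$y, lc, n_bootstrap = 30L)
  expect_lt(mean(rep), 50)
})

test_that("strongly correlated SNPs split their selection credit", {
  # two near-duplicate markers (r ~ 0.9) carrying one real effect: the
  # signal is found reliably, but the individual reproducibilities divide
  # it between the twins - the collinearity caveat of stability selection
  set.seed(71)
  n <- 500L
  g <- rbinom(n, 2L, 0.3)
  g2 <- g
  swap <- runif(n) < 0.10
  g2[swap] <- rbinom(sum(swap), 2L, 0.3)
  X <- cbind(dup1 = g, dup2 = g2, other = rbinom(n, 2L, 0.3))
  y <- rbinom(n, 1L, plogis(-0.3 + 0.9 * g))
  lc <- lasso_config(seed = 9L)
  run_boot <- function(cols) {
    set.seed(11)
    vapply(1:20, function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      list(choose_lambda_cv_aic(X[idx, cols], NULL, y[idx], lc)$fit$selected)
    }, list(1))
  }
  sets <- run_boot(1:3)
  either <- mean(vapply(sets, function(s)
    any(c("dup1", "dup2") %in% s), NA))
  each <- vapply(c("dup1", "dup2"), function(v)
    mean(vapply(sets, function(s) v %in% s, NA)), 0)
  single <- mean(vapply(run_boot(c(1L, 3L)), function(s)
    "dup1" %in% s, NA))
  expect_gte(either, max(each))
  expect_lt(min(each), either)  # credit is split between the twins
  expect_lte(abs(either - single), 0.2)  # combined ~ single-marker case
})

test_that("post-selection conventions and bounds hold", {
  inst <- make_instance(8, n = 200L, p = 10L)
  empty <- post_selection_test(inst$X, inst$Xc, inst$y, character(0), 1,
                               lasso_config(), n_perm = 1999L)
  expect_equal(empty$p_corrected, 1)
  expect_equal(empty$p_raw, 1)
  inst2 <- make_instance(9, n = 400L, p = 10L, beta = c(1.2, rep(0, 9)))
  lc <- lasso_config(seed = 13L)
  set.seed(13)
  tuned <- choose_lambda_cv_aic(inst2$X, inst2$Xc, inst2$y, lc)
  expect_true("s1" %in% tuned$fit$selected)
  expect_warning(
    post <- post_selection_test(inst2$X, inst2$Xc, inst2$y,
                                tuned$fit$selected, tuned$lambda_opt, lc,
                                n_perm = 199L),
    "resolution")
  expect_gte(post$p_corrected, 1 / 200)
  expect_equal(post$df, length(tuned$fit$selected))
  expect_lte(post$p_raw, 0.05)  # genuinely strong signal
})

test_that("stability selection is deterministic given config and data", {
  inst <- make_instance(10, n = 200L, p = 8L, beta = c(0.9, rep(0, 7)))
  lc <- lasso_config(seed = 21L, n_bootstrap = 8L, n_perm_post = 1500L)
  a <- suppressWarnings(stability_selection(inst$X, inst$Xc, inst$y, lc))
  b <- suppressWarnings(stability_selection(inst$X, inst$Xc, inst$y, lc))
  expect_identical(a$reproducibility, b$reproducibility)
  expect_identical(a$final_selected, b$final_selected)
  expect_identical(a$post$p_corrected, b$post$p_corrected)
  expect_identical(a$lambda_opt, b$lambda_opt)
})
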