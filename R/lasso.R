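# Multi-SNP engine: L1-penalized logistic likelihood with unpenalized
# covariates, cross-validated AIC penalty tuning, bootstrap stability
# selection and permutation-corrected post-selection inference. The
# optimizer is an iteratively reweighted (proximal Newton) coordinate
# descent implemented in C++ (src/cd_lasso.cpp); SNP dosages are kept on
# the 0/1/2 scale so penalized coefficients are per-allele log odds ratios.

#' Configuration for the penalized multi-SNP analysis
#'
#' @param lambda_grid optional decreasing positive penalty grid; by default
#'   `n_lambda` log-spaced values from the data-driven lambda_max (the
#'   smallest penalty zeroing every SNP) down to
#'   `lambda_max * lambda_min_ratio`.
#' @param n_lambda grid length (default 50).
#' @param lambda_min_ratio ratio of smallest to largest grid value
#'   (default 1e-3).
#' @param n_folds cross-validation folds (default 5).
#' @param n_bootstrap bootstrap resamples for stability selection
#'   (default 1000).
#' @param n_perm_post permutations for post-selection correction
#'   (default 10000).
#' @param seed integer seed.
#' @param penalize_covariates penalize the covariate block too (default
#'   `FALSE`: covariates are adjusted for, not selected over).
#' @param convergence_tol coordinate-descent convergence tolerance on the
#'   maximum coefficient change (default 1e-7).
#' @param max_iter maximum outer (IRLS) iterations (default 100).
#' @param cv_aic_method `"cv_loglik"` scores each penalty by the
#'   cross-validated log-likelihood with the mean across-fold support size
#'   as degrees of freedom; `"full_data"` computes a plain AIC on the
#'   full-data path fit.
#' @param bootstrap_mode `"resample"` (size-n with replacement, default) or
#'   `"subsample"` (m-out-of-n without replacement).
#' @param subsample_fraction m/n for `"subsample"` mode.
#' @param retune_per_perm re-run penalty tuning inside each post-selection
#'   permutation (expensive; default `FALSE` keeps the observed optimum).
#' @param dfmax support-size cap for path fits during penalty tuning: once a
#'   path solution selects more than `dfmax` SNPs the remaining smaller
#'   penalties are skipped (they cannot minimize a sparsity-seeking AIC but
#'   dominate compute time). Single [fit_penalized()] calls are never
#'   capped.
#' @return an object of class `lasso_config`.
#' @export
lasso_config <- function(lambda_grid = NULL, n_lambda = 50L,
                         lambda_min_ratio = 1e-3, n_folds = 5L,
                         n_bootstrap = 1000L, n_perm_post = 10000L,
                         seed = 1L, penalize_covariates = FALSE,
                         convergence_tol = 1e-7, max_iter = 100L,
                         cv_aic_method = c("cv_loglik", "full_data"),
                         bootstrap_mode = c("resample", "subsample"),
                         subsample_fraction = 0.632,
                         retune_per_perm = FALSE, dfmax = 50L) {
  if (!is.null(lambda_grid)) {
    if (any(lambda_grid <= 0)) stop_input("lambda_grid must be positive")
    if (is.unsorted(rev(lambda_grid), strictly = TRUE))
      stop_input("lambda_grid must be strictly decreasing")
  }
  if (n_folds < 2L) stop_input("n_folds must be at least 2")
  structure(list(lambda_grid = lambda_grid, n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 n_folds = as.integer(n_folds),
                 n_bootstrap = as.integer(n_bootstrap),
                 n_perm_post = as.integer(n_perm_post),
                 seed = as.integer(seed),
                 penalize_covariates = isTRUE(penalize_covariates),
                 convergence_tol = convergence_tol,
                 max_iter = as.integer(max_iter),
                 cv_aic_method = match.arg(cv_aic_method),
                 bootstrap_mode = match.arg(bootstrap_mode),
                 subsample_fraction = subsample_fraction,
                 retune_per_perm = isTRUE(retune_per_perm),
                 dfmax = as.integer(dfmax)),
            class = "lasso_config")
}

# Assemble the full design: intercept, covariate block, SNP block; the
# penalty vector is 0 for intercept/covariates, 1 for SNPs (unless
# covariates are penalized too).
lasso_design <- function(X_snps, X_cov, config) {
  X_snps <- as.matrix(X_snps)
  if (is.null(colnames(X_snps)))
    colnames(X_snps) <- paste0("snp", seq_len(ncol(X_snps)))
  if (is.null(X_cov)) X_cov <- matrix(numeric(0), nrow(X_snps), 0L)
  X_cov <- as.matrix(X_cov)
  X <- cbind(`(Intercept)` = 1, X_cov, X_snps)
  # center every non-intercept column: with an unpenalized intercept the
  # slope solutions are unchanged, and decorrelating the columns from the
  # intercept conditions the coordinate descent far better. The intercept
  # on the original scale is recovered as b0 - sum(centers * slopes).
  centers <- c(0, colMeans(X[, -1L, drop = FALSE]))
  X <- X - rep(centers, each = nrow(X))
  penalty <- c(0, rep(if (config$penalize_covariates) 1 else 0, ncol(X_cov)),
               rep(1, ncol(X_snps)))
  list(X = X, penalty = penalty, n_cov = ncol(X_cov),
       snp_names = colnames(X_snps), centers = centers,
       snp_idx = (2L + ncol(X_cov)):(1L + ncol(X_cov) + ncol(X_snps)))
}

uncenter_intercept <- function(beta, d) {
  beta[1L] - sum(d$centers[-1L] * beta[-1L])
}

# Smallest penalty at which every SNP coefficient is zero: the maximum
# absolute score (likelihood gradient) over the SNP block at the
# covariate-only maximum-likelihood fit.
lambda_max_null <- function(X_snps, X_cov, y, config) {
  d <- lasso_design(X_snps, X_cov, config)
  Xnull <- d$X[, seq_len(1L + d$n_cov), drop = FALSE]
  fit0 <- quiet_glm_fit(Xnull, y)
  score <- drop(crossprod(d$X[, d$snp_idx, drop = FALSE],
                          y - fit0$fitted.values))
  max(abs(score))
}

default_lambda_grid <- function(X_snps, X_cov, y, config) {
  lmax <- lambda_max_null(X_snps, X_cov, y, config)
  if (lmax <= 0) lmax <- 1
  exp(seq(log(lmax), log(lmax * config$lambda_min_ratio),
          length.out = config$n_lambda))
}

#' Fit the L1-penalized logistic model at one penalty value
#'
#' Maximizes `loglik(beta) - lambda * sum_j |beta_j|` over the SNP block,
#' with the intercept and covariates unpenalized, by proximal-Newton
#' coordinate descent. Coordinate descent produces exact zeros, so the
#' selected set is the exact support of the SNP coefficients. The returned
#' fit records the Karush-Kuhn-Tucker residual certifying optimality.
#'
#' @param X_snps numeric matrix of additive SNP dosages (samples x SNPs).
#' @param X_cov covariate matrix (no intercept column), or `NULL`.
#' @param y 0/1 outcome vector.
#' @param lambda nonnegative penalty.
#' @param config a [lasso_config()].
#' @return an object of class `lasso_fit`: list with `lambda`, `beta_snps`,
#'   `beta_covariates`, `intercept`, `log_likelihood`, `aic`, `selected`,
#'   `n_obs`, `kkt_violation`, `converged`, `iterations`.
#' @export
fit_penalized <- function(X_snps, X_cov, y, lambda, config = lasso_config()) {
  if (length(lambda) != 1L || is.na(lambda) || lambda < 0)
    stop_input("lambda must be a single nonnegative number")
  if (anyNA(X_snps)) stop_input("X_snps contains missing values: impute first")
  if (!all(y %in% c(0, 1))) stop_input("y must be binary 0/1")
  d <- lasso_design(X_snps, X_cov, config)
  res <- cpp_lasso_logistic(d$X, as.numeric(y), d$penalty, lambda,
                            numeric(ncol(d$X)), config$convergence_tol,
                            config$max_iter)
  if (!res$converged)
    stop("penalized fit did not converge in ", config$max_iter,
         " outer iterations (lambda = ", signif(lambda, 4),
         ", max coefficient change above tolerance ", config$convergence_tol,
         ")", call. = FALSE)
  beta <- res$beta
  beta_snps <- setNames(beta[d$snp_idx], d$snp_names)
  new_lasso_fit(lambda, beta_snps,
                beta_cov = beta[seq_len(d$n_cov) + 1L],
                intercept = uncenter_intercept(beta, d), loglik = res$loglik,
                n_obs = length(y), n_cov = d$n_cov,
                kkt = res$kkt_violation, converged = res$converged,
                iterations = res$iterations)
}

new_lasso_fit <- function(lambda, beta_snps, beta_cov, intercept, loglik,
                          n_obs, n_cov, kkt, converged, iterations) {
  selected <- names(beta_snps)[beta_snps != 0]
  k <- length(selected) + n_cov + 1L
  structure(list(lambda = lambda, beta_snps = beta_snps,
                 beta_covariates = beta_cov, intercept = intercept,
                 log_likelihood = loglik, aic = -2 * loglik + 2 * k,
                 selected = selected, n_obs = n_obs,
                 kkt_violation = kkt, converged = converged,
                 iterations = iterations),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("lasso_fit: lambda = %.4g, %d/%d SNPs selected, AIC = %.2f\n",
              x$lambda, length(x$selected), length(x$beta_snps), x$aic))
  invisible(x)
}

# Stratified fold assignment: shuffles within each outcome class so every
# fold sees both classes.
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

heldout_loglik <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

#' Choose the penalty by cross-validated AIC
#'
#' For each penalty on the grid, the model is fitted on each of `n_folds`
#' stratified training splits (warm-started along the path) and scored on
#' the held-out fold. The AIC profile is
#' `-2 * cv_loglik(lambda) + 2 * df(lambda)` with `df` the mean selected
#' support size across folds plus the unpenalized parameters; the optimum
#' is the minimizer, ties going to the larger (sparser) penalty. With
#' `cv_aic_method = "full_data"` the profile is instead the plain AIC of
#' the full-data path fit.
#'
#' @inheritParams fit_penalized
#' @return list with `lambda_opt`, `path` (data.frame: lambda, df,
#'   cv_loglik, aic, nnz_full), and `fit` (the full-data [fit_penalized()]
#'   fit at the optimum).
#' @export
choose_lambda_cv_aic <- function(X_snps, X_cov, y, config = lasso_config()) {
  grid <- config$lambda_grid %||% default_lambda_grid(X_snps, X_cov, y, config)
  if (!length(grid)) stop_input("empty lambda grid")
  d <- lasso_design(X_snps, X_cov, config)
  n_unpen <- sum(d$penalty == 0)

  full <- cpp_lasso_path(d$X, as.numeric(y), d$penalty, grid,
                         numeric(ncol(d$X)), config$convergence_tol,
                         config$max_iter, config$dfmax)
  usable <- full$computed

  if (config$cv_aic_method == "full_data") {
    df <- full$nnz + n_unpen
    aic <- -2 * full$loglik + 2 * df
    cv_ll <- rep(NA_real_, length(grid))
  } else {
    fold <- stratified_folds(y, config$n_folds)
    cv_ll <- numeric(length(grid))
    nnz_cv <- matrix(0L, config$n_folds, length(grid))
    for (f in seq_len(config$n_folds)) {
      tr <- fold != f
      pf <- cpp_lasso_path(d$X[tr, , drop = FALSE], as.numeric(y[tr]),
                           d$penalty, grid, numeric(ncol(d$X)),
                           config$convergence_tol, config$max_iter,
                           config$dfmax)
      usable <- usable & pf$computed
      for (k in seq_along(grid))
        cv_ll[k] <- cv_ll[k] + heldout_loglik(d$X[!tr, , drop = FALSE],
                                              y[!tr], pf$beta[, k])
      nnz_cv[f, ] <- pf$nnz
    }
    df <- colMeans(nnz_cv) + n_unpen
    aic <- -2 * cv_ll + 2 * df
  }
  aic[!usable] <- Inf
  opt <- which.min(aic)  # grid is decreasing: first minimum = largest lambda
  beta <- full$beta[, opt]
  fit <- new_lasso_fit(grid[opt], setNames(beta[d$snp_idx], d$snp_names),
                       beta_cov = beta[seq_len(d$n_cov) + 1L],
                       intercept = uncenter_intercept(beta, d),
                       loglik = full$loglik[opt],
                       n_obs = length(y), n_cov = d$n_cov,
                       kkt = full$kkt_violation[opt],
                       converged = full$converged[opt],
                       iterations = full$iterations[opt])
  list(lambda_opt = grid[opt],
       path = data.frame(lambda = grid, df = df, cv_loglik = cv_ll,
                         aic = aic, nnz_full = full$nnz),
       fit = fit)
}

#' Bootstrap stability (reproducibility) of SNP selection
#'
#' Draws `n_bootstrap` resamples (size n with replacement by default, or
#' m-out-of-n subsamples), re-tunes the penalty by [choose_lambda_cv_aic()]
#' on each resample, and records which SNPs enter the selected model. A
#' SNP's reproducibility is the percentage of resamples in which it was
#' selected; SNPs monomorphic within a resample are unselectable there and
#' count as not selected.
#'
#' @inheritParams fit_penalized
#' @param n_bootstrap overrides `config$n_bootstrap` when given.
#' @return named numeric vector of reproducibility percentages.
#' @export
bootstrap_stability <- function(X_snps, X_cov, y, config = lasso_config(),
                                n_bootstrap = NULL) {
  B <- n_bootstrap %||% config$n_bootstrap
  n <- length(y)
  m <- if (config$bootstrap_mode == "subsample")
    max(2L, round(config$subsample_fraction * n)) else n
  snp_names <- colnames(as.matrix(X_snps)) %||%
    paste0("snp", seq_len(ncol(X_snps)))
  count <- setNames(numeric(length(snp_names)), snp_names)
  with_seed(substream_seed(config$seed, "bootstrap"), {
    for (b in seq_len(B)) {
      idx <- sample.int(n, m, replace = config$bootstrap_mode == "resample")
      if (length(unique(y[idx])) < 2L) next  # degenerate resample
      Xb <- as.matrix(X_snps)[idx, , drop = FALSE]
      Cb <- if (is.null(X_cov)) NULL else as.matrix(X_cov)[idx, , drop = FALSE]
      sel <- tryCatch(
        choose_lambda_cv_aic(Xb, Cb, y[idx], config)$fit$selected,
        error = function(e) character(0))
      count[sel] <- count[sel] + 1
    }
  })
  100 * count / B
}

#' Post-selection likelihood-ratio test with permutation correction
#'
#' Tests the LASSO-selected SNP set by an unpenalized multivariate LRT of
#' covariates plus selected SNPs against covariates alone (df = number of
#' selected SNPs). Because the set was chosen by the data, the naive
#' chi-squared p-value overstates significance; the corrected p-value
#' re-runs the selection on label-permuted data (at the observed optimal
#' penalty, or with full re-tuning when `config$retune_per_perm`) and
#' compares each permutation's own post-selection LRT statistic with the
#' observed one.
#'
#' @inheritParams fit_penalized
#' @param selected character vector of selected SNP column names; an empty
#'   selection returns corrected p = 1 by convention.
#' @param lambda_opt penalty at which selection was made.
#' @param n_perm overrides `config$n_perm_post` when given.
#' @return list with `lrt_stat`, `df`, `p_raw`, `p_corrected`, `n_perm`.
#' @export
post_selection_test <- function(X_snps, X_cov, y, selected, lambda_opt,
                                config = lasso_config(), n_perm = NULL) {
  n_perm <- n_perm %||% config$n_perm_post
  if (n_perm < 1000L)
    warning("fewer than 1000 permutations: corrected p has coarse resolution")
  if (!length(selected))
    return(list(lrt_stat = 0, df = 0L, p_raw = 1, p_corrected = 1,
                n_perm = as.integer(n_perm)))
  X_snps <- as.matrix(X_snps)
  Xc <- if (is.null(X_cov)) matrix(numeric(0), nrow(X_snps), 0L)
        else as.matrix(X_cov)

  post_stat <- function(yy, Xc_perm, sel) {
    if (!length(sel)) return(0)
    base <- cbind(1, Xc_perm)
    f0 <- quiet_glm_fit(base, yy)
    f1 <- quiet_glm_fit(cbind(base, X_snps[, sel, drop = FALSE]), yy)
    max(0, 2 * (glmfit_loglik(f1) - glmfit_loglik(f0)))
  }
  obs <- post_stat(y, Xc, selected)
  df <- length(selected)
  p_raw <- pchisq(obs, df, lower.tail = FALSE)

  n <- length(y)
  exceed <- with_seed(substream_seed(config$seed, "post_perm"), {
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      yy <- y[idx]
      Xc_perm <- Xc[idx, , drop = FALSE]
      sel <- if (config$retune_per_perm) {
        tryCatch(choose_lambda_cv_aic(X_snps, Xc_perm, yy, config)$fit$selected,
                 error = function(e) character(0))
      } else {
        f <- tryCatch(fit_penalized(X_snps, Xc_perm, yy, lambda_opt, config),
                      error = function(e) NULL)
        if (is.null(f)) character(0) else f$selected
      }
      if (post_stat(yy, Xc_perm, sel) >= obs) cnt <- cnt + 1L
    }
    cnt
  })
  list(lrt_stat = obs, df = df, p_raw = p_raw,
       p_corrected = (1 + exceed) / (n_perm + 1),
       n_perm = as.integer(n_perm))
}

#' Full stability-selection analysis of a SNP panel
#'
#' Orchestrates the multi-SNP engine: penalty tuning by cross-validated
#' AIC, the final penalized fit, bootstrap reproducibility of each SNP's
#' selection, and the permutation-corrected post-selection LRT.
#'
#' @inheritParams fit_penalized
#' @return an object of class `stability_report`: list with `fit` (the
#'   optimal [fit_penalized()] fit), `lambda_opt`, `path`, `reproducibility`
#'   (percent per SNP), `final_selected`, `post` (the
#'   [post_selection_test()] result) and `config`.
#' @export
stability_selection <- function(X_snps, X_cov, y, config = lasso_config()) {
  tuned <- with_seed(substream_seed(config$seed, "cv"),
                     choose_lambda_cv_aic(X_snps, X_cov, y, config))
  repro <- bootstrap_stability(X_snps, X_cov, y, config)
  post <- post_selection_test(X_snps, X_cov, y, tuned$fit$selected,
                              tuned$lambda_opt, config)
  structure(list(fit = tuned$fit, lambda_opt = tuned$lambda_opt,
                 path = tuned$path, reproducibility = repro,
                 final_selected = tuned$fit$selected, post = post,
                 config = config),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability_report: lambda_opt = %.4g, selected = {%s}\n",
              x$lambda_opt, paste(x$final_selected, collapse = ", ")))
  if (length(x$final_selected)) {
    cat(sprintf("  post-selection LRT = %.2f (df = %d), raw p = %.3g, corrected p = %.3g\n",
                x$post$lrt_stat, x$post$df, x$post$p_raw, x$post$p_corrected))
    for (s in x$final_selected)
      cat(sprintf("  %s: reproducibility %.0f%%\n", s, x$reproducibility[s]))
  }
  invisible(x)
}
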