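# Classical per-SNP inference: covariate-adjusted logistic likelihood-ratio
# tests under four modes of inheritance, polytomous subphenotype
# heterogeneity, interaction scans, min-p permutation correction for
# multiple testing, and study power for the per-allele trend test.

## ---- covariate design ------------------------------------------------------

#' Covariate design matrix for adjusted models
#'
#' Builds treatment-coded dummies for age group, gender, region and smoking
#' status. Samples with missing smoking are dropped (complete-case), the
#' convention of the emulated study.
#'
#' @param cohort validated cohort table.
#' @return list with `X` (matrix, no intercept column), `keep` (logical rows
#'   retained) and `y` (0/1 case indicator for retained rows).
#' @export
covariate_design <- function(cohort) {
  cohort <- validate_cohort(cohort)
  keep <- cohort$smoking != "missing"
  cc <- droplevels(cohort[keep, , drop = FALSE])
  blocks <- lapply(c("age_group", "gender", "region", "smoking"), function(v) {
    f <- cc[[v]]
    if (nlevels(f) < 2L) return(NULL)  # constant covariates carry no dummies
    m <- model.matrix(~f)[, -1L, drop = FALSE]
    colnames(m) <- paste0(v, levels(f)[-1L])
    m
  })
  blocks <- Filter(Negate(is.null), blocks)
  X <- if (length(blocks)) do.call(cbind, blocks)
       else matrix(numeric(0), nrow(cc), 0L)
  list(X = X, keep = keep, y = as.integer(cc$status == "case"))
}

# Binomial log-likelihood of a fitted glm.fit object
glmfit_loglik <- function(fit) {
  mu <- pmin(pmax(fit$fitted.values, 1e-12), 1 - 1e-12)
  y <- fit$y
  sum(y * log(mu) + (1 - y) * log(1 - mu))
}

quiet_glm_fit <- function(x, y, ...) {
  suppressWarnings(glm.fit(x, y, family = binomial(), ...))
}

## ---- per-SNP logistic fits -------------------------------------------------

#' Covariate-adjusted logistic fit of one SNP under a mode of inheritance
#'
#' Fits `status ~ genotype(moi) + age + gender + region + smoking` by
#' maximum likelihood, with significance from the likelihood-ratio test
#' against the covariate-only null and Wald 95% confidence intervals on the
#' genotype log-odds. Degenerate fits (constant genotype coding, separation,
#' non-convergence) are returned flagged rather than failing. An empty
#' heterozygote or rare-homozygote cell under the codominant coding is
#' collapsed to the dominant coding with a warning.
#'
#' @param g integer dosage vector (0/1/2, no missing), aligned with `cohort`.
#' @param cohort validated cohort table.
#' @param moi mode of inheritance (see [encode_moi()]).
#' @param adjust adjust for covariates (default `TRUE`); `FALSE` fits
#'   genotype-only models.
#' @param snp_id identifier carried into the result.
#' @return an object of class `association_result`: list with `snp_id`,
#'   `moi`, `beta`, `or_point`, `ci95` (2-column matrix), `lrt_stat`,
#'   `lrt_df`, `p_value`, `flagged`, `flag_reason`, `n_obs`.
#' @export
fit_snp_logistic <- function(g, cohort, moi = "additive", adjust = TRUE,
                             snp_id = NA_character_) {
  cohort <- validate_cohort(cohort)
  if (length(g) != nrow(cohort)) stop_input("genotype/cohort length mismatch")
  if (anyNA(g)) stop_input("missing genotypes present: impute first")
  cd <- covariate_design(cohort)
  g <- g[cd$keep]
  y <- cd$y
  Xcov <- if (adjust) cd$X else matrix(numeric(0), length(y), 0L)

  flagged_result <- function(reason) {
    structure(list(snp_id = snp_id, moi = moi, beta = NA_real_,
                   or_point = NA_real_,
                   ci95 = matrix(NA_real_, 1L, 2L,
                                 dimnames = list(NULL, c("lo", "hi"))),
                   lrt_stat = NA_real_, lrt_df = NA_integer_,
                   p_value = NA_real_, flagged = TRUE, flag_reason = reason,
                   n_obs = length(y)),
              class = "association_result")
  }
  if (length(unique(g)) == 1L) return(flagged_result("constant genotype"))

  if (moi == "codominant" && (sum(g == 1L) == 0L || sum(g == 2L) == 0L)) {
    warning("empty genotype class under codominant coding; collapsing to dominant")
    moi <- "dominant"
  }
  G <- encode_moi(g, moi)
  if (any(apply(G, 2L, function(col) length(unique(col)) == 1L)))
    return(flagged_result("constant genotype coding"))

  Xalt <- cbind(`(Intercept)` = 1, Xcov, G)
  Xnull <- cbind(`(Intercept)` = 1, Xcov)
  fit1 <- quiet_glm_fit(Xalt, y)
  fit0 <- quiet_glm_fit(Xnull, y)
  k <- ncol(G)
  idx <- (ncol(Xalt) - k + 1L):ncol(Xalt)
  beta <- fit1$coefficients[idx]

  # Wald SEs from the unscaled covariance of the IRLS fit
  R <- fit1$qr
  se <- rep(NA_real_, ncol(Xalt))
  ok <- fit1$qr$rank == ncol(Xalt)
  if (ok) {
    cov_un <- chol2inv(R$qr[seq_len(R$rank), seq_len(R$rank), drop = FALSE])
    se <- sqrt(diag(cov_un))
  }
  se_g <- se[idx]
  lrt <- 2 * (glmfit_loglik(fit1) - glmfit_loglik(fit0))
  flag <- !fit1$converged || !ok || any(abs(beta) > 10) ||
    any(!is.finite(se_g)) || any(se_g > 10)
  z <- qnorm(0.975)
  structure(list(snp_id = snp_id, moi = moi, beta = beta,
                 or_point = exp(beta),
                 ci95 = cbind(lo = exp(beta - z * se_g),
                              hi = exp(beta + z * se_g)),
                 lrt_stat = max(lrt, 0), lrt_df = k,
                 p_value = pchisq(max(lrt, 0), df = k, lower.tail = FALSE),
                 flagged = flag,
                 flag_reason = if (flag) "non-convergence or separation" else NA_character_,
                 n_obs = length(y)),
            class = "association_result")
}

#' Fit one SNP under all four modes of inheritance
#'
#' @inheritParams fit_snp_logistic
#' @return named list of [fit_snp_logistic()] results
#'   (additive, dominant, recessive, codominant).
#' @export
fit_all_moi <- function(g, cohort, adjust = TRUE, snp_id = NA_character_) {
  mois <- c("additive", "dominant", "recessive", "codominant")
  setNames(lapply(mois, function(m)
    suppressWarnings(fit_snp_logistic(g, cohort, m, adjust, snp_id))), mois)
}

#' Best mode of inheritance by minimum p-value
#'
#' Given the four per-MOI fits of one SNP, returns the mode with the lowest
#' LRT p-value. Flagged fits are excluded; ties break in the fixed order
#' additive, dominant, recessive, codominant.
#'
#' @param results named list of four `association_result`s as from
#'   [fit_all_moi()].
#' @return list with `moi`, `p_value`, and `excluded` (names of flagged
#'   fits).
#' @export
best_moi <- function(results) {
  order_moi <- c("additive", "dominant", "recessive", "codominant")
  results <- results[order_moi]
  excl <- names(results)[vapply(results, function(r)
    isTRUE(r$flagged) || is.na(r$p_value), logical(1L))]
  usable <- setdiff(order_moi, excl)
  if (!length(usable))
    return(list(moi = NA_character_, p_value = NA_real_, excluded = excl))
  p <- vapply(results[usable], `[[`, 0, "p_value")
  i <- which.min(p)  # first minimum = tie order
  list(moi = usable[i], p_value = unname(p[i]), excluded = excl)
}

#' Per-SNP association scan across modes of inheritance
#'
#' @param gm imputed [genotype_matrix()].
#' @param cohort validated cohort table.
#' @param mois modes to fit.
#' @param adjust adjust for covariates.
#' @return data.frame, one row per SNP x MOI (codominant contributes two
#'   coefficient rows sharing one LRT p), plus `p_trend` (the additive-model
#'   p) and the best-MOI summary columns.
#' @export
snp_scan <- function(gm, cohort,
                     mois = c("additive", "dominant", "recessive",
                              "codominant"),
                     adjust = TRUE) {
  rows <- list()
  for (s in gm$snp_ids) {
    g <- gm$dosage[, s]
    fits <- fit_all_moi(g, cohort, adjust = adjust, snp_id = s)
    p_trend <- fits$additive$p_value
    best <- best_moi(fits)
    for (m in mois) {
      r <- fits[[m]]
      for (k in seq_along(r$beta)) {
        rows[[length(rows) + 1L]] <- data.frame(
          snp_id = s, gene = unname(gm$gene_of[s]), moi = r$moi,
          term = if (length(r$beta) > 1L) c("het", "hom")[k] else r$moi,
          or_point = r$or_point[k], ci_lo = r$ci95[k, 1L],
          ci_hi = r$ci95[k, 2L], lrt_stat = r$lrt_stat, lrt_df = r$lrt_df,
          p_value = r$p_value, p_trend = p_trend, flagged = r$flagged,
          best_moi = best$moi, best_p = best$p_value,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

## ---- polytomous subphenotype heterogeneity ---------------------------------

# Multinomial logistic log-likelihood and analytic gradient, with the
# genotype coefficient either free per outcome class or shared across
# classes. X includes the intercept; class 1 is the baseline (controls).
multinom_negll <- function(theta, X, gdose, yk, K, shared) {
  p <- ncol(X)
  n <- nrow(X)
  eta <- matrix(0, n, K)
  gb <- if (shared) theta[(K - 1) * p + 1L] else NA
  for (k in 2:K) {
    gam <- theta[((k - 2) * p + 1L):((k - 1) * p)]
    b <- if (shared) gb else theta[(K - 1) * p + (k - 1L)]
    eta[, k] <- X %*% gam + gdose * b
  }
  m <- apply(eta, 1L, max)
  lse <- m + log(rowSums(exp(eta - m)))
  -sum(eta[cbind(seq_len(n), yk)] - lse)
}

multinom_grad <- function(theta, X, gdose, yk, K, shared) {
  p <- ncol(X)
  n <- nrow(X)
  eta <- matrix(0, n, K)
  gb <- if (shared) theta[(K - 1) * p + 1L] else NA
  for (k in 2:K) {
    gam <- theta[((k - 2) * p + 1L):((k - 1) * p)]
    b <- if (shared) gb else theta[(K - 1) * p + (k - 1L)]
    eta[, k] <- X %*% gam + gdose * b
  }
  m <- apply(eta, 1L, max)
  P <- exp(eta - m)
  P <- P / rowSums(P)
  grad <- numeric(length(theta))
  gshared <- 0
  for (k in 2:K) {
    resid <- (yk == k) - P[, k]
    grad[((k - 2) * p + 1L):((k - 1) * p)] <- -crossprod(X, resid)
    if (shared) gshared <- gshared - sum(gdose * resid)
    else grad[(K - 1) * p + (k - 1L)] <- -sum(gdose * resid)
  }
  if (shared) grad[(K - 1) * p + 1L] <- gshared
  grad
}

fit_multinom <- function(X, g, yk, K, shared) {
  p <- ncol(X)
  npar <- (K - 1) * p + if (shared) 1L else (K - 1L)
  opt <- optim(numeric(npar), multinom_negll, gr = multinom_grad, X = X,
               gdose = g, yk = yk, K = K, shared = shared, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  list(loglik = -opt$value, par = opt$par, converged = opt$convergence == 0)
}

#' Heterogeneity of a SNP's effect across disease subphenotypes
#'
#' Fits a polytomous (multinomial) logistic model of outcome class
#' (control plus each subphenotype with at least one case) on the additive
#' genotype and covariates. Heterogeneity is the likelihood-ratio test of
#' the model with a free per-subtype genotype log-odds against the model
#' with a single shared genotype log-odds, on (number of subtypes - 1)
#' degrees of freedom. Subtypes without cases are dropped with a warning.
#' With `subtype_col = "p53_class"` the same machinery tests heterogeneity
#' between p53-low and p53-high expressing tumors.
#'
#' @param g integer dosage vector (0/1/2, no missing), aligned with `cohort`.
#' @param cohort validated cohort table.
#' @param subtype_col `"subphenotype"` or `"p53_class"`.
#' @param snp_id identifier carried into the result.
#' @return an object of class `heterogeneity_result`: list with `snp_id`,
#'   `per_subtype_betas`, `shared_beta`, `het_lrt_stat`, `het_df`, `het_p`,
#'   `subtypes`.
#' @export
polytomous_heterogeneity <- function(g, cohort,
                                     subtype_col = c("subphenotype",
                                                     "p53_class"),
                                     snp_id = NA_character_) {
  subtype_col <- match.arg(subtype_col)
  cohort <- validate_cohort(cohort)
  if (anyNA(g)) stop_input("missing genotypes present: impute first")
  cd <- covariate_design(cohort)
  g <- as.numeric(g[cd$keep])
  cc <- cohort[cd$keep, , drop = FALSE]

  is_case <- cc$status == "case"
  lab <- ifelse(is_case, as.character(cc[[subtype_col]]), "control")
  keep2 <- !is_case | !(lab %in% c("unknown"))
  if (any(!keep2)) warning(sum(!keep2), " cases with unknown subtype dropped")
  lab <- lab[keep2]
  g <- g[keep2]
  X <- cbind(1, cd$X[keep2, , drop = FALSE])
  is_case <- is_case[keep2]

  all_sub <- setdiff(unique(lab[is_case]), "control")
  order_sub <- if (subtype_col == "subphenotype")
    c("lowNMIT", "highNMIT", "MIT") else c("low", "high")
  subtypes <- intersect(order_sub, all_sub)
  dropped <- setdiff(order_sub, subtypes)
  if (length(dropped))
    warning("subtype(s) with zero cases dropped: ",
            paste(dropped, collapse = ", "))
  if (length(subtypes) < 2L)
    stop_input("need at least 2 subtypes with cases for a heterogeneity test")
  yk <- match(lab, c("control", subtypes))
  stopifnot(!anyNA(yk))
  K <- length(subtypes) + 1L

  free <- fit_multinom(X, g, yk, K, shared = FALSE)
  shared <- fit_multinom(X, g, yk, K, shared = TRUE)
  stat <- max(0, 2 * (free$loglik - shared$loglik))
  df <- length(subtypes) - 1L
  p <- ncol(X)
  betas <- setNames(free$par[(K - 1) * p + seq_len(K - 1L)], subtypes)
  structure(list(snp_id = snp_id, per_subtype_betas = betas,
                 shared_beta = shared$par[(K - 1) * p + 1L],
                 het_lrt_stat = stat, het_df = df,
                 het_p = pchisq(stat, df, lower.tail = FALSE),
                 subtypes = subtypes,
                 converged = free$converged && shared$converged),
            class = "heterogeneity_result")
}

## ---- interaction scans -----------------------------------------------------

#' Pairwise SNP-SNP and SNP-smoking interaction scan
#'
#' For `snp_snp`, every unordered SNP pair is tested by a 1-df LRT comparing
#' the adjusted logistic model with both additive genotype terms plus their
#' product against the model without the product (a single multiplicative
#' per-allele interaction). For `snp_smoking`, each SNP's additive term is
#' crossed with ever-smoking (never vs. ever).
#'
#' @param gm imputed [genotype_matrix()].
#' @param cohort validated cohort table.
#' @param kind `"snp_snp"` or `"snp_smoking"`.
#' @return data.frame of tests with LRT statistics and p-values;
#'   non-converging fits are flagged.
#' @export
interaction_scan <- function(gm, cohort, kind = c("snp_snp", "snp_smoking")) {
  kind <- match.arg(kind)
  cohort <- validate_cohort(cohort)
  if (anyNA(gm$dosage)) stop_input("missing genotypes present: impute first")
  cd <- covariate_design(cohort)
  y <- cd$y
  D <- gm$dosage[cd$keep, , drop = FALSE]
  base <- cbind(`(Intercept)` = 1, cd$X)
  p <- ncol(D)

  if (kind == "snp_snp") {
    pairs <- utils::combn(p, 2L)
    res <- vector("list", ncol(pairs))
    for (i in seq_len(ncol(pairs))) {
      j <- pairs[1L, i]; k <- pairs[2L, i]
      gj <- D[, j]; gk <- D[, k]
      X0 <- cbind(base, gj, gk)
      X1 <- cbind(X0, gj * gk)
      f0 <- quiet_glm_fit(X0, y)
      f1 <- quiet_glm_fit(X1, y)
      stat <- max(0, 2 * (glmfit_loglik(f1) - glmfit_loglik(f0)))
      res[[i]] <- data.frame(
        snp1 = gm$snp_ids[j], snp2 = gm$snp_ids[k], lrt_stat = stat,
        p_value = pchisq(stat, 1L, lower.tail = FALSE),
        flagged = !f1$converged || !f0$converged, stringsAsFactors = FALSE)
    }
    return(do.call(rbind, res))
  }

  ever <- as.numeric(cohort$smoking[cd$keep] != "never")
  res <- vector("list", p)
  for (j in seq_len(p)) {
    gj <- D[, j]
    X0 <- cbind(base, gj)
    X1 <- cbind(X0, gj * ever)
    f0 <- quiet_glm_fit(X0, y)
    f1 <- quiet_glm_fit(X1, y)
    stat <- max(0, 2 * (glmfit_loglik(f1) - glmfit_loglik(f0)))
    res[[j]] <- data.frame(
      snp = gm$snp_ids[j], lrt_stat = stat,
      p_value = pchisq(stat, 1L, lower.tail = FALSE),
      flagged = !f1$converged || !f0$converged, stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

## ---- fast vectorized additive trend test -----------------------------------

# 1-df additive logistic LRT from aggregated genotype-by-status counts,
# Newton iteration vectorized across SNPs. `case_counts` and `ctrl_counts`
# are 3 x p matrices of genotype counts (rows g = 0, 1, 2).
additive_lrt_counts <- function(case_counts, ctrl_counts) {
  Ng <- case_counts + ctrl_counts
  cg <- case_counts
  p <- ncol(Ng)
  gvals <- c(0, 1, 2)
  C <- colSums(cg)
  N <- colSums(Ng)
  # degenerate: genotype has no variation among observed classes
  nclass <- colSums(Ng > 0)
  mu0 <- C / N
  ll0 <- ifelse(C > 0 & C < N, C * log(mu0) + (N - C) * log(1 - mu0), 0)

  a <- log(pmin(pmax(mu0, 1e-8), 1 - 1e-8) / (1 - pmin(pmax(mu0, 1e-8),
                                                       1 - 1e-8)))
  b <- numeric(p)
  for (it in 1:100) {
    eta <- outer(gvals, b) + matrix(a, 3L, p, byrow = TRUE)
    mu <- 1 / (1 + exp(-eta))
    w <- Ng * mu * (1 - mu)
    ga <- colSums(cg - Ng * mu)
    gb <- colSums(gvals * (cg - Ng * mu))
    haa <- colSums(w)
    hab <- colSums(gvals * w)
    hbb <- colSums(gvals^2 * w)
    det <- haa * hbb - hab^2
    det[det < 1e-300] <- 1e-300
    da <- (hbb * ga - hab * gb) / det
    db <- (haa * gb - hab * ga) / det
    da <- pmin(pmax(da, -5), 5)
    db <- pmin(pmax(db, -5), 5)
    a <- a + da
    b <- b + db
    b <- pmin(pmax(b, -15), 15)
    if (max(abs(da), abs(db)) < 1e-10) break
  }
  eta <- outer(gvals, b) + matrix(a, 3L, p, byrow = TRUE)
  ll1 <- colSums(cg * eta - Ng * log1p(exp(eta)))
  stat <- pmax(0, 2 * (ll1 - ll0))
  pv <- pchisq(stat, 1L, lower.tail = FALSE)
  pv[nclass < 2L] <- NA_real_
  pv
}

# Additive LRT p-values for every SNP, unadjusted, via aggregated counts.
# G1/G2 are precomputed indicator matrices (dosage == 1 / == 2); colN_g the
# fixed per-SNP genotype totals.
additive_pvec_counts <- function(G1, G2, colN0, colN1, colN2, y) {
  c1 <- drop(crossprod(G1, y))
  c2 <- drop(crossprod(G2, y))
  c0 <- sum(y) - c1 - c2
  case <- rbind(c0, c1, c2)
  ctrl <- rbind(colN0 - c0, colN1 - c1, colN2 - c2)
  additive_lrt_counts(case, ctrl)
}

# Adjusted additive LRT p-values for every SNP via glm.fit; the null
# (covariate-only) log-likelihood is supplied since it is permutation
# invariant under joint (y, covariates) permutation.
additive_pvec_adjusted <- function(D, y, base, ll0) {
  p <- ncol(D)
  pv <- numeric(p)
  for (j in seq_len(p)) {
    f1 <- quiet_glm_fit(cbind(base, D[, j]), y)
    stat <- max(0, 2 * (glmfit_loglik(f1) - ll0))
    pv[j] <- pchisq(stat, 1L, lower.tail = FALSE)
  }
  pv
}

## ---- min-p permutation correction ------------------------------------------

#' Min-p permutation correction for a family of per-SNP tests
#'
#' Corrects the per-SNP additive-model LRT p-values for multiple testing by
#' the min-p permutation method: case/control labels (together with their
#' covariates) are permuted against the genotype matrix, the whole test
#' family is recomputed on each permutation, and each SNP's corrected
#' p-value is the proportion of permutations whose family-wise minimum p is
#' at or below the SNP's observed p (with the +1 finite-sample correction).
#' Permuting the (label, covariate) block jointly preserves
#' covariate-outcome and genotype-genotype dependence while breaking the
#' genotype-outcome association.
#'
#' @param gm imputed [genotype_matrix()].
#' @param cohort validated cohort table.
#' @param family `"additive_adjusted"` (covariate-adjusted LRTs) or
#'   `"additive_unadjusted"` (fast count-based LRTs).
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed.
#' @return an object of class `permutation_correction`: list with `n_perm`,
#'   `observed_p`, `corrected_p`, `min_p_perm` (the permutation null of the
#'   family minimum), `family`, `seed`.
#' @export
minp_permutation <- function(gm, cohort,
                             family = c("additive_adjusted",
                                        "additive_unadjusted"),
                             n_perm = 1000L, seed = 1L) {
  family <- match.arg(family)
  if (n_perm < 100L) stop_input("n_perm must be at least 100")
  cohort <- validate_cohort(cohort)
  if (anyNA(gm$dosage)) stop_input("missing genotypes present: impute first")
  cd <- covariate_design(cohort)
  y <- cd$y
  D <- gm$dosage[cd$keep, , drop = FALSE]
  n <- length(y)

  if (family == "additive_unadjusted") {
    G1 <- (D == 1L) * 1
    G2 <- (D == 2L) * 1
    colN1 <- colSums(G1)
    colN2 <- colSums(G2)
    colN0 <- n - colN1 - colN2
    pfun <- function(yy, base = NULL, ll0 = NULL)
      additive_pvec_counts(G1, G2, colN0, colN1, colN2, yy)
    obs <- pfun(y)
    minp <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      min(pfun(y[sample.int(n)]), na.rm = TRUE), 0))
  } else {
    base <- cbind(`(Intercept)` = 1, cd$X)
    ll0 <- glmfit_loglik(quiet_glm_fit(base, y))
    obs <- additive_pvec_adjusted(D, y, base, ll0)
    minp <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      min(additive_pvec_adjusted(D, y[idx], base[idx, , drop = FALSE], ll0),
          na.rm = TRUE)
    }, 0))
  }
  corrected <- vapply(obs, function(p0) {
    if (is.na(p0)) return(NA_real_)
    (1 + sum(minp <= p0)) / (n_perm + 1)
  }, 0)
  corrected <- pmax(corrected, obs)  # corrected can never undercut raw
  names(obs) <- names(corrected) <- gm$snp_ids
  structure(list(n_perm = as.integer(n_perm), observed_p = obs,
                 corrected_p = corrected, min_p_perm = minp,
                 family = family, seed = as.integer(seed)),
            class = "permutation_correction")
}

## ---- study power -----------------------------------------------------------

#' Analytic power of the per-allele (additive trend) test
#'
#' Normal-approximation power of the 1-df allele-based test: the case
#' genotype distribution is the exponentially tilted control HWE
#' distribution at the design odds ratio; the test statistic is the log
#' allelic odds ratio with its allele-count variance.
#'
#' @param n_cases,n_controls arm sizes.
#' @param maf control minor-allele frequency in (0, 0.5].
#' @param or_per_allele design per-allele odds ratio (> 0).
#' @param alpha two-sided significance level.
#' @return power in \[0, 1\].
#' @export
power_per_allele <- function(n_cases, n_controls, maf, or_per_allele,
                             alpha = 0.05) {
  if (maf <= 0 || maf > 0.5) stop_input("maf must lie in (0, 0.5]")
  if (or_per_allele <= 0) stop_input("odds ratio must be positive")
  if (alpha <= 0 || alpha >= 1) stop_input("alpha must lie in (0, 1)")
  p0 <- maf
  probs1 <- tilt_probs(hwe_probs(maf), log(or_per_allele))
  p1 <- (probs1[2L] + 2 * probs1[3L]) / 2
  delta <- log(p1 / (1 - p1)) - log(p0 / (1 - p0))
  v <- 1 / (2 * n_cases * p1 * (1 - p1)) +
    1 / (2 * n_controls * p0 * (1 - p0))
  za <- qnorm(1 - alpha / 2)
  z <- abs(delta) / sqrt(v)
  pnorm(z - za) + pnorm(-z - za)
}

#' Empirical power of the additive trend test by simulation
#'
#' Simulates case/control genotype counts under the tilted HWE model and
#' applies the 1-df additive logistic LRT to each replicate cohort.
#'
#' @inheritParams power_per_allele
#' @param n_rep number of replicate cohorts.
#' @param seed integer seed.
#' @return list with `power` (fraction of replicates with p <= alpha),
#'   `n_rep`, and `se` (binomial Monte-Carlo standard error).
#' @export
power_simulate <- function(n_cases, n_controls, maf, or_per_allele,
                           alpha = 0.05, n_rep = 1000L, seed = 1L) {
  probs0 <- hwe_probs(maf)
  probs1 <- tilt_probs(probs0, log(or_per_allele))
  pv <- with_seed(seed, {
    case <- rmultinom(n_rep, n_cases, probs1)
    ctrl <- rmultinom(n_rep, n_controls, probs0)
    additive_lrt_counts(case, ctrl)
  })
  pow <- mean(pv <= alpha, na.rm = TRUE)
  list(power = pow, n_rep = as.integer(n_rep),
       se = sqrt(pow * (1 - pow) / n_rep))
}
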