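# Single-SNP inference: adjusted logistic LRTs, best mode of inheritance,
# polytomous heterogeneity, interaction scans, min-p permutation, power.

test_that("unadjusted dominant odds ratio equals the 2x2 cross-product", {
  # genotype counts: 968/56/2 in cases, 998/90/0 in controls; dominant
  # exposure = minor-allele carriage (58 cases, 90 controls)
  g <- c(rep(0L, 968), rep(1L, 56), rep(2L, 2),
         rep(0L, 998), rep(1L, 90), rep(0L, 0))
  status <- rep(c(1L, 0L), c(1026L, 1088L))
  cohort <- bare_cohort(status)
  r <- fit_snp_logistic(g, cohort, "dominant", adjust = FALSE)
  expect_equal(unname(r$or_point), (58 * 998) / (90 * 968), tolerance = 1e-6)
  expect_equal(r$lrt_df, 1L)
  expect_true(r$ci95[1, "lo"] <= r$or_point && r$or_point <= r$ci95[1, "hi"])
})

test_that("null-SNP LRT p-values are uniform and reject at the nominal rate", {
  # scaled from the stated 500 replicates to 300 at n = 150+150
  pvals <- vapply(1:300, function(i) {
    sim <- small_cohort(seed = 3000L + i, n_cases = 150L, n_controls = 150L,
                        n_snps = 1L)
    fit_snp_logistic(sim$genotypes$dosage[, 1], sim$cohort,
                     "additive")$p_value
  }, 0)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  band <- 2.576 * sqrt(0.05 * 0.95 / 300)
  expect_lt(abs(mean(pvals <= 0.05) - 0.05), band)
})

test_that("degenerate genotype columns are flagged, not fatal", {
  sim <- small_cohort(seed = 14L, n_cases = 60L, n_controls = 60L,
                      n_snps = 16L)
  r <- fit_snp_logistic(rep(1L, 120), sim$cohort, "additive")
  expect_true(r$flagged)
  expect_true(is.na(r$p_value))
  # empty rare-homozygote cell collapses codominant to dominant
  g <- pmin(sim$genotypes$dosage[, 2], 1L)
  expect_warning(r2 <- fit_snp_logistic(g, sim$cohort, "codominant"),
                 "collapsing to dominant")
  expect_equal(r2$moi, "dominant")
})

test_that("best_moi picks the minimum p with fixed tie order", {
  mk <- function(p, moi, flagged = FALSE)
    structure(list(moi = moi, p_value = p, flagged = flagged),
              class = "association_result")
  res <- list(additive = mk(0.04, "additive"), dominant = mk(0.2, "dominant"),
              recessive = mk(0.3, "recessive"),
              codominant = mk(0.5, "codominant"))
  expect_equal(best_moi(res)$moi, "additive")
  ties <- lapply(res, function(r) { r$p_value <- 0.2; r })
  expect_equal(best_moi(ties)$moi, "additive")
  res$additive$flagged <- TRUE
  res$dominant$p_value <- 0.01
  b <- best_moi(res)
  expect_equal(b$moi, "dominant")
  expect_equal(b$excluded, "additive")
})

test_that("a recessive-only effect is usually assigned the recessive mode", {
  # oracle simulation: case genotypes tilted on the rare-homozygote
  # indicator only
  picks <- vapply(1:60, function(i) {
    set.seed(800L + i)
    q <- 0.35
    p0 <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    p1 <- p0 * exp(1.0 * c(0, 0, 1))
    p1 <- p1 / sum(p1)
    g <- c(sample(0:2, 400, TRUE, p0), sample(0:2, 400, TRUE, p1))
    status <- rep(c(0L, 1L), c(400L, 400L))
    fits <- fit_all_moi(g, bare_cohort(status), adjust = FALSE)
    best_moi(fits)$moi
  }, "")
  expect_gt(mean(picks == "recessive"), 0.5)
})

test_that("subtype heterogeneity LRT is nonnegative and calibrated", {
  # equal effects across subtypes: rejection at 5% should stay nominal
  # (scaled to 60 replicates)
  rej <- vapply(1:60, function(i) {
    sim <- small_cohort(seed = 400L + i, n_cases = 120L, n_controls = 120L,
                        n_snps = 1L, effects = c(rs11757379 = 0.3))
    h <- polytomous_heterogeneity(sim$genotypes$dosage[, 1], sim$cohort)
    expect_gte(h$het_lrt_stat, 0)
    expect_equal(h$het_df, 2L)
    h$het_p <= 0.05
  }, NA)
  expect_lt(mean(rej), 0.05 + 2.576 * sqrt(0.05 * 0.95 / 60))
})

test_that("a subtype-specific effect raises heterogeneity rejections", {
  # cases of one subtype carry the effect, the others none: build cohorts
  # by mixing tilted and untilted case genotypes
  rej <- vapply(1:40, function(i) {
    set.seed(600L + i)
    q <- 0.3
    p0 <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    p1 <- p0 * exp(0.8 * (0:2))
    p1 <- p1 / sum(p1)
    n0 <- 300L; n1 <- 300L
    sub <- sample(c("lowNMIT", "highNMIT", "MIT"), n1, TRUE)
    g <- c(sample(0:2, n0, TRUE, p0),
           ifelse(sub == "MIT", sample(0:2, n1, TRUE, p1),
                  sample(0:2, n1, TRUE, p0)))
    cohort <- bare_cohort(rep(c(0L, 1L), c(n0, n1)))
    cohort$subphenotype[cohort$status == "case"] <- sub
    h <- polytomous_heterogeneity(g, cohort)
    h$het_p <= 0.05
  }, NA)
  expect_gt(mean(rej), 0.05 + 2.576 * sqrt(0.05 * 0.95 / 40))
})

test_that("p53 expression subtypes reuse the heterogeneity machinery", {
  sim <- small_cohort(seed = 19L, n_cases = 200L, n_controls = 200L,
                      n_snps = 2L)
  h <- polytomous_heterogeneity(sim$genotypes$dosage[, 1], sim$cohort,
                                subtype_col = "p53_class")
  expect_equal(h$het_df, 1L)
  expect_equal(sort(h$subtypes), c("high", "low"))
  expect_true(h$het_p >= 0 && h$het_p <= 1)
})

test_that("interaction scans emit one test per pair and stay calibrated", {
  sim <- small_cohort(seed = 23L, n_cases = 250L, n_controls = 250L,
                      n_snps = 20L)
  ix <- interaction_scan(sim$genotypes, sim$cohort, "snp_snp")
  expect_equal(nrow(ix), choose(20, 2))
  expect_gt(ks.test(ix$p_value[!ix$flagged], "punif")$p.value, 0.01)
  sm <- interaction_scan(sim$genotypes, sim$cohort, "snp_smoking")
  expect_equal(nrow(sm), 20L)
  expect_true(all(sm$lrt_stat >= 0))
})

test_that("a multiplicative product-term effect is detected above nominal", {
  hits <- vapply(1:30, function(i) {
    set.seed(1200L + i)
    n <- 1200L
    g1 <- draw_hwe(n, 0.3)
    g2 <- draw_hwe(n, 0.3)
    y <- rbinom(n, 1, plogis(-0.6 + 0.2 * g1 + 0.2 * g2 +
                               log(1.5) * g1 * g2))
    cohort <- random_cohort(n, seed = i)
    cohort$status <- ifelse(y == 1, "case", "control")
    cohort$subphenotype <- ifelse(y == 1, "lowNMIT", "control")
    gm <- genotype_matrix(cbind(a = g1, b = g2),
                          sample_ids = cohort$sample_id)
    ix <- interaction_scan(gm, cohort, "snp_snp")
    ix$p_value[1] <= 0.05
  }, NA)
  expect_gt(mean(hits), 0.05 + 2.576 * sqrt(0.05 * 0.95 / 30))
})

test_that("single-test families give corrected p close to raw p", {
  sim <- small_cohort(seed = 29L, n_cases = 200L, n_controls = 200L,
                      n_snps = 1L)
  pc <- minp_permutation(sim$genotypes, sim$cohort, "additive_unadjusted",
                         n_perm = 400L, seed = 5L)
  expect_lt(abs(pc$corrected_p[1] - pc$observed_p[1]), 0.08)
  expect_gte(pc$corrected_p[1], pc$observed_p[1])
})

test_that("corrected p-values respect their bounds and monotonicity", {
  sim <- small_cohort(seed = 31L, n_cases = 300L, n_controls = 300L,
                      n_snps = 15L, effects = c(rs6567355 = 1.2))
  pc <- minp_permutation(sim$genotypes, sim$cohort, "additive_unadjusted",
                         n_perm = 200L, seed = 6L)
  expect_true(all(pc$corrected_p >= 1 / 201 & pc$corrected_p <= 1))
  expect_true(all(pc$corrected_p >= pc$observed_p))
  # the planted strong effect beats every permutation minimum
  expect_equal(unname(pc$corrected_p["rs6567355"]), 1 / 201)
  # monotone in raw p within one run
  ord <- order(pc$observed_p)
  expect_true(!is.unsorted(pc$corrected_p[ord]))
  expect_error(minp_permutation(sim$genotypes, sim$cohort, n_perm = 50L),
               "at least 100")
})

test_that("adjusted and unadjusted permutation families agree on nulls", {
  sim <- small_cohort(seed = 37L, n_cases = 150L, n_controls = 150L,
                      n_snps = 8L)
  pa <- minp_permutation(sim$genotypes, sim$cohort, "additive_adjusted",
                         n_perm = 100L, seed = 8L)
  expect_true(all(pa$corrected_p >= pa$observed_p))
  expect_equal(length(pa$min_p_perm), 100L)
})

test_that("per-allele power is exact at the null and matches simulation", {
  expect_equal(power_per_allele(500, 500, 0.3, 1.0, 0.05), 0.05)
  # analytic vs Monte-Carlo, scaled to 400 replicates
  an <- power_per_allele(1058, 1138, 0.25, 1.3, 0.05)
  sim <- power_simulate(1058, 1138, 0.25, 1.3, 0.05, n_rep = 400L, seed = 2L)
  expect_lt(abs(an - sim$power), 2 * sim$se + 0.01)
  # monotone in effect size
  ors <- c(1.1, 1.2, 1.3, 1.5)
  pw <- vapply(ors, function(o) power_per_allele(1058, 1138, 0.25, o), 0)
  expect_true(!is.unsorted(pw))
  expect_error(power_per_allele(100, 100, 0.7, 1.3), "maf")
})

test_that("additive and collapsed codings coincide on two-class genotypes", {
  sim <- small_cohort(seed = 41L, n_cases = 120L, n_controls = 120L,
                      n_snps = 16L)
  # only {0,1} observed: additive equals the dominant/collapsed-codominant fit
  g01 <- pmin(sim$genotypes$dosage[, 3], 1L)
  a <- fit_snp_logistic(g01, sim$cohort, "additive")
  cod <- suppressWarnings(fit_snp_logistic(g01, sim$cohort, "codominant"))
  expect_equal(a$p_value, cod$p_value, tolerance = 1e-8)
  # only {0,2} observed: additive is a rescaled recessive indicator
  g02 <- sim$genotypes$dosage[, 3]
  g02[g02 == 1L] <- 0L
  a2 <- fit_snp_logistic(g02, sim$cohort, "additive")
  r2 <- fit_snp_logistic(g02, sim$cohort, "recessive")
  expect_equal(a2$p_value, r2$p_value, tolerance = 1e-8)
})
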