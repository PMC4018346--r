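# Shared fixture builders: everything is generated in code at test time.

# Small simulated cohort; effects is a named vector of per-allele log-ORs.
small_cohort <- function(seed = 1L, n_cases = 150L, n_controls = 150L,
                         n_snps = 20L, effects = NULL, missing_rate = 0) {
  specs <- if (n_snps < 16L) default_snp_specs(16L)[seq_len(n_snps), ]
           else default_snp_specs(n_snps)
  if (!is.null(effects))
    specs$per_allele_log_or[match(names(effects), specs$snp_id)] <- effects
  cfg <- sim_config(n_cases = n_cases, n_controls = n_controls,
                    snp_specs = specs, missing_rate = missing_rate,
                    seed = seed)
  simulate_cohort(cfg)
}

# Minimal hand-built cohort around given genotype and status vectors, with
# constant covariates (they drop out of the design).
bare_cohort <- function(status) {
  n <- length(status)
  data.frame(sample_id = sprintf("B%04d", seq_len(n)),
             status = ifelse(status == 1, "case", "control"),
             subphenotype = ifelse(status == 1, "lowNMIT", "control"),
             p53_class = "unknown",
             age_group = "<55", gender = "male", region = "Barcelona",
             smoking = "never", stringsAsFactors = FALSE)
}

# Random cohort table with varied covariates (no genotype model), used for
# tests that need a realistic covariate design.
random_cohort <- function(n, p_case = 0.5, seed = 1L) {
  set.seed(seed)
  status <- rbinom(n, 1, p_case)
  data.frame(sample_id = sprintf("R%04d", seq_len(n)),
             status = ifelse(status == 1, "case", "control"),
             subphenotype = ifelse(status == 1, "lowNMIT", "control"),
             p53_class = "unknown",
             age_group = sample(c("<55", "55-64", "65-69", "70-74", "75+"),
                                n, TRUE),
             gender = sample(c("male", "female"), n, TRUE, c(0.87, 0.13)),
             region = sample(c("Barcelona", "Valles", "Elche", "Tenerife",
                               "Asturias"), n, TRUE),
             smoking = sample(c("never", "occasional", "former", "current"),
                              n, TRUE),
             stringsAsFactors = FALSE)
}

# Hardy-Weinberg genotype draw at minor allele frequency q.
draw_hwe <- function(n, q) {
  sample(0:2, n, TRUE, prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
}
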