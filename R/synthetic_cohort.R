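# Synthetic case-control cohort generator. Emulates the structure of a
# hospital-based bladder-cancer candidate-gene study: a 184-tagSNP / 18-gene
# panel under Hardy-Weinberg equilibrium in controls, a 1,058-case /
# 1,138-control design, categorical covariates (age group, gender, region,
# smoking) with configurable log-odds on disease, stage/grade subphenotypes
# among cases, and p53 staining-intensity percentage vectors.

# Reference tagSNP panel: the published control genotype counts of the 16
# individually significant SNPs, used as traceable default allele
# frequencies. MAFs are derived from the counts at construction time.
TABLE_SNPS <- data.frame(
  gene = c("BAK1", "IGF1R", "IGF1R", "IGF1R", "IGF1R", "IGF1R", "P53AIP1",
           "PMAIP1", "PMAIP1", "SERPINB5", "SERPINB5", "SERPINB5", "TP63",
           "TP63", "TP63", "TP73"),
  snp_id = c("rs11757379", "rs1058696", "rs12591122", "rs4966015", "rs702497",
             "rs7166348", "rs2604235", "rs1942919", "rs7240884", "rs1509476",
             "rs1509478", "rs6567355", "rs12489753", "rs13321831", "rs6779677",
             "rs3765731"),
  n_AA = c(642, 998, 824, 771, 645, 670, 463, 353, 477, 614, 450, 552, 934,
           927, 347, 544),
  n_Aa = c(390, 90, 250, 276, 366, 355, 473, 509, 471, 405, 493, 435, 146,
           155, 547, 446),
  n_aa = c(54, 0, 14, 41, 73, 62, 149, 224, 138, 69, 139, 93, 7, 6, 194, 96),
  stringsAsFactors = FALSE
)

PANEL_GENES <- c("TP53", "TP63", "TP73", "BAK1", "BAX", "BBC3", "BIRC5",
                 "CDKN1A", "FAS", "GADD45A", "IGF1R", "MDM2", "PCNA",
                 "PMAIP1", "SERPINB5", "SFN", "TP53AIP1", "MYC")

#' Reference SNP specifications from the published control genotype counts
#'
#' Sixteen tagSNPs with control genotype counts and the minor-allele
#' frequencies they imply, used as traceable anchors for the default
#' synthetic panel.
#'
#' @return data.frame with columns `gene`, `snp_id`, `n_AA`, `n_Aa`, `n_aa`,
#'   `control_maf`.
#' @export
table_snp_specs <- function() {
  df <- TABLE_SNPS
  df$control_maf <- apply(df[, c("n_AA", "n_Aa", "n_aa")], 1L,
                          minor_allele_freq)
  df
}

#' Default synthetic tagSNP panel
#'
#' The 16 reference SNPs of [table_snp_specs()] plus deterministic null
#' filler SNPs up to `n_snps`, with filler minor-allele frequencies spread
#' evenly over \[0.05, 0.5\] and gene labels cycling through the 18 panel
#' genes. All per-allele log odds ratios default to 0 (a null panel);
#' effects are injected by editing `per_allele_log_or` for chosen SNPs.
#'
#' @param n_snps total panel size (default 184).
#' @return data.frame with columns `snp_id`, `gene`, `control_maf`,
#'   `per_allele_log_or`.
#' @export
default_snp_specs <- function(n_snps = 184L) {
  anchors <- table_snp_specs()
  base <- data.frame(snp_id = anchors$snp_id, gene = anchors$gene,
                     control_maf = anchors$control_maf,
                     per_allele_log_or = 0, stringsAsFactors = FALSE)
  n_fill <- n_snps - nrow(base)
  if (n_fill < 0) stop_input("n_snps smaller than the 16 reference SNPs")
  if (n_fill > 0) {
    fill <- data.frame(
      snp_id = sprintf("snpF%03d", seq_len(n_fill)),
      gene = rep(PANEL_GENES, length.out = n_fill),
      control_maf = seq(0.05, 0.5, length.out = n_fill),
      per_allele_log_or = 0, stringsAsFactors = FALSE)
    base <- rbind(base, fill)
  }
  base
}

# Cohort margins of the emulated study (cases n = 1058, controls n = 1138):
# counts per covariate category. Control counts define the control sampling
# distribution; the case/control count ratios define the default per-category
# log-odds, so that tilted case sampling reproduces the case margins.
COVARIATE_COUNTS <- list(
  age_group = list(levels = COHORT_LEVELS$age_group,
                   cases = c(149, 222, 241, 225, 221),
                   controls = c(181, 278, 263, 222, 194)),
  gender = list(levels = COHORT_LEVELS$gender,
                cases = c(920, 138), controls = c(991, 147)),
  region = list(levels = COHORT_LEVELS$region,
                cases = c(214, 173, 83, 195, 393),
                controls = c(233, 181, 80, 207, 437)),
  smoking = list(levels = COHORT_LEVELS$smoking,
                 cases = c(147, 43, 409, 454, 5),
                 controls = c(334, 81, 429, 283, 11))
)

#' Default covariate model for the synthetic cohort
#'
#' For each covariate: control category probabilities (from the emulated
#' study's control margins) and per-category log-odds on disease relative to
#' the first level, chosen so that exponential tilting of the control
#' distribution reproduces the study's case margins (e.g. 43% current
#' smokers among cases vs 25% among controls).
#'
#' @return named list, one element per covariate, each with `levels`,
#'   `control_probs`, `log_odds`.
#' @export
default_covariate_model <- function() {
  lapply(COVARIATE_COUNTS, function(cc) {
    p0 <- cc$controls / sum(cc$controls)
    lo <- log((cc$cases / cc$cases[1L]) / (cc$controls / cc$controls[1L]))
    list(levels = cc$levels, control_probs = p0, log_odds = lo)
  })
}

#' Simulation configuration for synthetic cohorts
#'
#' The stated world of the generator: sample sizes of the emulated study,
#' the 184-SNP panel with control minor-allele frequencies and per-allele
#' log odds ratios, covariate category probabilities with their disease
#' log-odds, subphenotype mix among cases (60-65% of bladder tumors are
#' low-risk non-muscle-invasive, 15-20% high-risk non-muscle-invasive,
#' 20-30% muscle-invasive; defaults 0.625/0.175/0.200), a Dirichlet model
#' for p53 staining-intensity percentages, and a missing-genotype rate.
#'
#' @param n_cases,n_controls arm sizes (defaults 1058 / 1138).
#' @param snp_specs data.frame as from [default_snp_specs()].
#' @param covariate_model list as from [default_covariate_model()].
#' @param subphenotype_probs probabilities of (lowNMIT, highNMIT, MIT) among
#'   cases; must sum to 1.
#' @param p53_alpha Dirichlet concentration for the 4 intensity percentages.
#' @param missing_rate MCAR genotype missingness in \[0, 1).
#' @param seed integer seed.
#' @param sampling `"retrospective"` draws each arm from its exact
#'   (tilted) distribution; `"prospective"` rejection-samples from the
#'   population model until both arms are filled.
#' @param max_reject_iter iteration cap for prospective sampling.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 1058L, n_controls = 1138L,
                       snp_specs = default_snp_specs(),
                       covariate_model = default_covariate_model(),
                       subphenotype_probs = c(0.625, 0.175, 0.200),
                       p53_alpha = c(4, 2, 1.5, 1),
                       missing_rate = 0, seed = 1L,
                       sampling = c("retrospective", "prospective"),
                       max_reject_iter = 500L) {
  sampling <- match.arg(sampling)
  cfg <- structure(list(n_cases = as.integer(n_cases),
                        n_controls = as.integer(n_controls),
                        snp_specs = snp_specs,
                        covariate_model = covariate_model,
                        subphenotype_probs = subphenotype_probs,
                        p53_alpha = p53_alpha,
                        missing_rate = missing_rate, seed = as.integer(seed),
                        sampling = sampling,
                        max_reject_iter = as.integer(max_reject_iter)),
                   class = "sim_config")
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config an object to validate.
#' @export
validate_sim_config <- function(config) {
  if (!inherits(config, "sim_config")) stop_input("not a sim_config")
  if (config$n_cases < 1L || config$n_controls < 1L)
    stop_input("arm sizes must be positive")
  s <- config$snp_specs
  need <- c("snp_id", "gene", "control_maf", "per_allele_log_or")
  if (!all(need %in% names(s))) stop_input("snp_specs missing columns")
  if (anyDuplicated(s$snp_id)) stop_input("duplicated SNP ids in snp_specs")
  if (any(s$control_maf <= 0 | s$control_maf > 0.5))
    stop_input("control_maf must lie in (0, 0.5]")
  for (nm in names(config$covariate_model)) {
    cm <- config$covariate_model[[nm]]
    if (abs(sum(cm$control_probs) - 1) > 1e-12)
      stop_input("category probabilities for ", nm, " must sum to 1")
    if (any(cm$control_probs < 0 | cm$control_probs > 1))
      stop_input("probabilities must lie in [0,1]")
  }
  if (abs(sum(config$subphenotype_probs) - 1) > 1e-12 ||
      any(config$subphenotype_probs < 0))
    stop_input("subphenotype_probs must be nonnegative and sum to 1")
  if (config$missing_rate < 0 || config$missing_rate >= 1)
    stop_input("missing_rate must lie in [0, 1)")
  invisible(config)
}

# Hardy-Weinberg genotype probabilities at minor allele frequency q.
hwe_probs <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

# Exponential tilting of a genotype distribution by a per-allele log-OR:
# P_case(g) proportional to P_ctrl(g) * exp(beta * g). Under the additive
# logistic model this is the exact case genotype distribution.
tilt_probs <- function(p, beta) {
  w <- p * exp(beta * (seq_along(p) - 1))
  w / sum(w)
}

# Draw n genotypes for all SNPs from per-SNP categorical distributions
# given by a 3 x p matrix of probabilities.
draw_genotypes <- function(n, prob3) {
  p <- ncol(prob3)
  out <- matrix(0L, n, p)
  u <- matrix(runif(n * p), n, p)
  c1 <- matrix(prob3[1L, ], n, p, byrow = TRUE)
  c2 <- matrix(prob3[1L, ] + prob3[2L, ], n, p, byrow = TRUE)
  out[u >= c1] <- 1L
  out[u >= c2] <- 2L
  out
}

#' Simulate genotypes for a case-control cohort
#'
#' Control genotypes are drawn under Hardy-Weinberg equilibrium at each
#' SNP's control minor-allele frequency. Case genotypes are drawn from the
#' exponentially tilted distribution, which makes the per-allele odds ratio
#' between arms exactly `exp(per_allele_log_or)` under the additive logistic
#' model. SNPs are simulated independently (the emulated panel consists of
#' low-LD tagSNPs). Missingness is applied completely at random.
#'
#' @param config a [sim_config()].
#' @param status optional 0/1 vector (1 = case) fixing the arm of each row;
#'   by default `n_controls` controls followed by `n_cases` cases.
#' @return a [genotype_matrix()] with rows aligned to `status`.
#' @export
simulate_genotypes <- function(config, status = NULL) {
  validate_sim_config(config)
  s <- config$snp_specs
  if (is.null(status))
    status <- rep(c(0L, 1L), c(config$n_controls, config$n_cases))
  p0 <- vapply(s$control_maf, hwe_probs, numeric(3L))
  p1 <- vapply(seq_len(nrow(s)), function(j)
    tilt_probs(p0[, j], s$per_allele_log_or[j]), numeric(3L))
  with_seed(substream_seed(config$seed, "genotypes"), {
    d <- matrix(0L, length(status), nrow(s))
    ctrl <- status == 0L
    if (any(ctrl)) d[ctrl, ] <- draw_genotypes(sum(ctrl), p0)
    if (any(!ctrl)) d[!ctrl, ] <- draw_genotypes(sum(!ctrl), p1)
    if (config$missing_rate > 0) {
      mask <- matrix(runif(length(d)) < config$missing_rate, nrow(d))
      d[mask] <- NA_integer_
    }
  })
  ids <- sprintf("S%05d", seq_along(status))
  genotype_matrix(d, ids, s$snp_id,
                  gene_of = setNames(s$gene, s$snp_id),
                  allele_labels = setNames(rep(list(c("G", "A")), nrow(s)),
                                           s$snp_id))
}

# Sample categorical covariates for one arm. `tilted` switches between the
# control distribution and its exponentially tilted case counterpart.
draw_covariates <- function(n, covariate_model, tilted) {
  out <- lapply(names(covariate_model), function(nm) {
    cm <- covariate_model[[nm]]
    pr <- if (tilted) tilt_categorical(cm) else cm$control_probs
    factor(sample(cm$levels, n, replace = TRUE, prob = pr), levels = cm$levels)
  })
  names(out) <- names(covariate_model)
  as.data.frame(out, stringsAsFactors = FALSE)
}

tilt_categorical <- function(cm) {
  w <- cm$control_probs * exp(cm$log_odds)
  w / sum(w)
}

# Stage/grade pairs consistent with each subphenotype, sampled uniformly
# within class so that assign_subphenotype() recovers the class exactly.
SUBPHENO_SG <- list(
  lowNMIT = list(c("Ta", "G1"), c("Ta", "G2")),
  highNMIT = list(c("Ta", "G3"), c("T1", "G2"), c("T1", "G3"),
                  c("Tis", "unknown")),
  MIT = list(c("T2", "G2"), c("T2", "G3"), c("T3", "G3"), c("T4", "G3"))
)

#' Simulate a full case-control cohort
#'
#' Draws exactly `n_cases` cases and `n_controls` controls. Under the
#' default retrospective sampling, each arm's covariates and genotypes come
#' from the arm-specific distributions implied by the joint logistic model
#' (controls from the stated control distributions, cases from their
#' exponentially tilted counterparts), which is the sampling design of a
#' case-control study. Cases receive a stage/grade pair (hence a
#' subphenotype) and a p53 intensity-percentage vector; p53 class is the
#' median histoscore split among cases.
#'
#' @param config a [sim_config()].
#' @return list with elements `genotypes` (a [genotype_matrix()]) and
#'   `cohort` (a validated cohort data.frame, controls first).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  n0 <- config$n_controls
  n1 <- config$n_cases
  status <- rep(c(0L, 1L), c(n0, n1))
  if (config$sampling == "prospective")
    return(simulate_cohort_prospective(config))

  cov_seed <- substream_seed(config$seed, "covariates")
  cohort <- with_seed(cov_seed, {
    ctrl_cov <- draw_covariates(n0, config$covariate_model, tilted = FALSE)
    case_cov <- draw_covariates(n1, config$covariate_model, tilted = TRUE)
    cov <- rbind(ctrl_cov, case_cov)

    sub <- rep("control", n0 + n1)
    stage <- rep(NA_character_, n0 + n1)
    grade <- rep(NA_character_, n0 + n1)
    cls <- sample(c("lowNMIT", "highNMIT", "MIT"), n1, replace = TRUE,
                  prob = config$subphenotype_probs)
    for (i in seq_len(n1)) {
      sg <- SUBPHENO_SG[[cls[i]]]
      pick <- sg[[sample.int(length(sg), 1L)]]
      stage[n0 + i] <- pick[1L]
      grade[n0 + i] <- pick[2L]
    }
    sub[(n0 + 1):(n0 + n1)] <-
      as.character(assign_subphenotype(stage[(n0 + 1):(n0 + n1)],
                                       grade[(n0 + 1):(n0 + n1)]))

    # p53 intensity percentages (Dirichlet) and median-split class for cases
    a <- config$p53_alpha
    gmat <- matrix(rgamma(n1 * 4L, shape = rep(a, each = n1)), n1, 4L)
    pct <- 100 * gmat / rowSums(gmat)
    scores <- histoscore(pct)
    p53 <- rep("unknown", n0 + n1)
    p53[(n0 + 1):(n0 + n1)] <- as.character(classify_p53(scores))
    p53pct <- matrix(NA_real_, n0 + n1, 4L)
    p53pct[(n0 + 1):(n0 + n1), ] <- pct

    data.frame(sample_id = sprintf("S%05d", seq_len(n0 + n1)),
               status = ifelse(status == 1L, "case", "control"),
               subphenotype = sub,
               stage = stage, grade = grade,
               p53_class = p53,
               p53_pct0 = p53pct[, 1L], p53_pct1 = p53pct[, 2L],
               p53_pct2 = p53pct[, 3L], p53_pct3 = p53pct[, 4L],
               cov, stringsAsFactors = FALSE)
  })
  cohort <- validate_cohort(cohort)
  gm <- simulate_genotypes(config, status = status)
  list(genotypes = gm, cohort = cohort)
}

# Prospective sampling: draw population individuals (control covariate and
# HWE genotype distributions), assign disease from the joint logistic model,
# and keep drawing until both arms are filled or the iteration cap is hit.
simulate_cohort_prospective <- function(config) {
  s <- config$snp_specs
  p0 <- vapply(s$control_maf, hwe_probs, numeric(3L))
  # baseline intercept for a hospital-based design: ~30% case prevalence
  intercept <- log(0.3 / 0.7) - sum(s$per_allele_log_or *
                                      (2 * s$control_maf))
  need0 <- config$n_controls
  need1 <- config$n_cases
  batch <- need0 + need1
  got <- list()
  with_seed(substream_seed(config$seed, "prospective"), {
    for (iter in seq_len(config$max_reject_iter)) {
      cov <- draw_covariates(batch, config$covariate_model, tilted = FALSE)
      g <- draw_genotypes(batch, p0)
      lo <- rep(intercept, batch)
      for (nm in names(config$covariate_model)) {
        cm <- config$covariate_model[[nm]]
        lo <- lo + cm$log_odds[as.integer(cov[[nm]])]
      }
      lo <- lo + g %*% s$per_allele_log_or
      y <- rbinom(batch, 1L, 1 / (1 + exp(-lo)))
      got[[iter]] <- list(cov = cov, g = g, y = y)
      n1 <- sum(vapply(got, function(b) sum(b$y == 1L), 0L))
      n0 <- sum(vapply(got, function(b) sum(b$y == 0L), 0L))
      if (n1 >= need1 && n0 >= need0) break
    }
  })
  y <- unlist(lapply(got, `[[`, "y"))
  if (sum(y == 1L) < need1 || sum(y == 0L) < need0)
    stop_input("prospective sampling did not reach target arm sizes within ",
               config$max_reject_iter, " iterations")
  cov <- do.call(rbind, lapply(got, `[[`, "cov"))
  g <- do.call(rbind, lapply(got, `[[`, "g"))
  keep <- c(which(y == 0L)[seq_len(need0)], which(y == 1L)[seq_len(need1)])
  sub_cfg <- config
  sub_cfg$sampling <- "retrospective"
  out <- simulate_cohort(sub_cfg)  # reuse case-only annotations & layout
  out$cohort[names(cov)] <- cov[keep, ]
  out$genotypes$dosage[] <- g[keep, ]
  storage.mode(out$genotypes$dosage) <- "integer"
  if (config$missing_rate > 0) {
    d <- out$genotypes$dosage
    with_seed(substream_seed(config$seed, "missing"), {
      mask <- matrix(runif(length(d)) < config$missing_rate, nrow(d))
      d[mask] <- NA_integer_
    })
    out$genotypes$dosage <- d
  }
  out
}
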