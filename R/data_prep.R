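# Containers and data-preparation operations: genotype matrix I/O, MAF and
# Hardy-Weinberg screening, mode-of-inheritance encodings, genotype
# imputation, p53 histoscore classification and stage/grade subphenotypes.

COHORT_LEVELS <- list(
  status       = c("control", "case"),
  subphenotype = c("control", "lowNMIT", "highNMIT", "MIT", "unknown"),
  p53_class    = c("low", "high", "unknown"),
  age_group    = c("<55", "55-64", "65-69", "70-74", "75+"),
  gender       = c("male", "female"),
  region       = c("Barcelona", "Valles", "Elche", "Tenerife", "Asturias"),
  smoking      = c("never", "occasional", "former", "current", "missing")
)

#' Construct a genotype matrix
#'
#' A genotype matrix stores minor-allele dosages (0, 1, 2 or `NA` for
#' missing) for samples by SNPs, together with per-SNP metadata: the gene
#' each tagSNP belongs to and its major/minor allele labels.
#'
#' @param dosage integer matrix, samples x SNPs, values in 0/1/2/NA.
#' @param sample_ids character vector of unique sample identifiers.
#' @param snp_ids character vector of unique SNP identifiers.
#' @param gene_of named character vector mapping SNP id to gene label.
#' @param allele_labels named list mapping SNP id to `c(major, minor)`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, sample_ids = rownames(dosage),
                            snp_ids = colnames(dosage),
                            gene_of = NULL, allele_labels = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosage)))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(dosage)))
  if (anyDuplicated(sample_ids)) stop_input("duplicated sample ids")
  if (anyDuplicated(snp_ids)) stop_input("duplicated SNP ids")
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) stop_input("dosage values must be 0, 1, 2 or NA")
  storage.mode(dosage) <- "integer"
  dimnames(dosage) <- list(sample_ids, snp_ids)
  if (is.null(gene_of)) gene_of <- setNames(rep(NA_character_, length(snp_ids)), snp_ids)
  if (is.null(allele_labels))
    allele_labels <- setNames(rep(list(c("N", "N")), length(snp_ids)), snp_ids)
  structure(list(dosage = dosage, sample_ids = sample_ids, snp_ids = snp_ids,
                 gene_of = gene_of[snp_ids], allele_labels = allele_labels[snp_ids]),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%d genes), %.2f%% missing\n",
              length(x$sample_ids), length(x$snp_ids),
              length(unique(stats::na.omit(x$gene_of))),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Validate a cohort phenotype/covariate table
#'
#' Checks the enumerated category tokens, uniqueness of sample ids, and the
#' control-row constraints (controls carry subphenotype `control` and p53
#' class `unknown`).
#'
#' @param cohort data.frame with columns `sample_id`, `status`,
#'   `subphenotype`, `p53_class`, `age_group`, `gender`, `region`, `smoking`.
#' @return the cohort, invisibly, with the categorical columns as factors.
#' @export
validate_cohort <- function(cohort) {
  need <- c("sample_id", "status", "subphenotype", "p53_class", "age_group",
            "gender", "region", "smoking")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop_input("cohort table missing columns: ",
                               paste(miss, collapse = ", "))
  if (anyDuplicated(cohort$sample_id)) stop_input("duplicated sample ids")
  for (col in names(COHORT_LEVELS)) {
    vals <- as.character(cohort[[col]])
    bad <- setdiff(unique(vals), COHORT_LEVELS[[col]])
    if (length(bad)) stop_input("invalid ", col, " tokens: ",
                                paste(bad, collapse = ", "))
    cohort[[col]] <- factor(vals, levels = COHORT_LEVELS[[col]])
  }
  ctrl <- cohort$status == "control"
  if (any(cohort$subphenotype[ctrl] != "control"))
    stop_input("controls must have subphenotype 'control'")
  if (any(cohort$p53_class[ctrl] != "unknown"))
    stop_input("controls must have p53_class 'unknown'")
  invisible(cohort)
}

## ---- genotype file I/O -----------------------------------------------------

#' Write a genotype matrix to disk
#'
#' Two plain-text dialects are supported. `plink_raw` mimics a PLINK
#' `--recode A` additive dosage export: a tab-delimited header
#' `FID IID <snp>_<minor> ...` followed by one row per sample with missing
#' genotypes written as `NA`. `csv` is a comma-separated table with a
#' `sample_id` column followed by one column per SNP.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @param dialect `"plink_raw"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, dialect = c("plink_raw", "csv")) {
  dialect <- match.arg(dialect)
  d <- gm$dosage
  if (dialect == "plink_raw") {
    minor <- vapply(gm$allele_labels, `[`, "", 2L)
    header <- c("FID", "IID", paste0(gm$snp_ids, "_", minor))
    body <- cbind(gm$sample_ids, gm$sample_ids,
                  matrix(ifelse(is.na(d), "NA", as.character(d)), nrow = nrow(d)))
    lines <- c(paste(header, collapse = "\t"),
               apply(body, 1L, paste, collapse = "\t"))
    writeLines(lines, path)
  } else {
    df <- data.frame(sample_id = gm$sample_ids, d, check.names = FALSE)
    write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE, na = "NA")
  }
  invisible(path)
}

#' Read a genotype matrix from disk
#'
#' Counterpart of [write_genotypes()]; see there for the dialects. Any token
#' other than `0`, `1`, `2` or `NA` is a parse error reporting the offending
#' line and column. Gene labels and major alleles are not carried by either
#' dialect; supply them through `snp_info`, a data.frame with columns
#' `snp_id`, `gene`, `major`, `minor` (as written by [write_snp_info()]).
#'
#' @param path input file path.
#' @param dialect `"plink_raw"` or `"csv"`.
#' @param snp_info optional SNP metadata data.frame or path to a TSV.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("plink_raw", "csv"),
                           snp_info = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_input("file not found: ", path)
  sep <- if (dialect == "plink_raw") "\t" else ","
  lines <- readLines(path)
  if (length(lines) < 1L) stop_input("empty genotype file: ", path)
  header <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]]
  if (dialect == "plink_raw") {
    if (length(header) < 3L || header[1L] != "FID" || header[2L] != "IID")
      stop_input("malformed plink_raw header (expected FID\tIID\t<snp>_<allele>...)")
    raw_ids <- header[-(1:2)]
    snp_ids <- sub("_[^_]*$", "", raw_ids)
    minor <- sub("^.*_", "", raw_ids)
    first_geno_col <- 3L
  } else {
    if (header[1L] != "sample_id")
      stop_input("malformed csv header (expected leading sample_id column)")
    snp_ids <- header[-1L]
    minor <- rep("N", length(snp_ids))
    first_geno_col <- 2L
  }
  if (anyDuplicated(snp_ids)) stop_input("duplicated SNP ids in header")
  n <- length(lines) - 1L
  d <- matrix(NA_integer_, n, length(snp_ids))
  sample_ids <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], sep, fixed = TRUE)[[1L]]
    if (length(f) != length(header))
      stop_input(sprintf("line %d: %d fields, expected %d", i + 1L,
                         length(f), length(header)))
    sample_ids[i] <- f[1L]
    g <- f[first_geno_col:length(f)]
    ok <- g %in% c("0", "1", "2", "NA")
    if (!all(ok)) {
      j <- which(!ok)[1L]
      stop_input(sprintf("line %d, column %d: invalid genotype token '%s'",
                         i + 1L, j + first_geno_col - 1L, g[j]))
    }
    d[i, ] <- suppressWarnings(as.integer(g))
  }
  if (anyDuplicated(sample_ids)) stop_input("duplicated sample ids")
  alleles <- setNames(lapply(minor, function(m) c("N", m)), snp_ids)
  gene_of <- NULL
  if (!is.null(snp_info)) {
    if (is.character(snp_info))
      snp_info <- read.table(snp_info, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    gene_of <- setNames(snp_info$gene, snp_info$snp_id)[snp_ids]
    alleles <- setNames(Map(c, snp_info$major, snp_info$minor),
                        snp_info$snp_id)[snp_ids]
  }
  genotype_matrix(d, sample_ids, snp_ids, gene_of = gene_of,
                  allele_labels = alleles)
}

#' Write per-SNP metadata (gene and allele labels) as TSV
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_snp_info <- function(gm, path) {
  df <- data.frame(snp_id = gm$snp_ids,
                   gene = unname(gm$gene_of[gm$snp_ids]),
                   major = vapply(gm$allele_labels, `[`, "", 1L),
                   minor = vapply(gm$allele_labels, `[`, "", 2L))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a cohort table as CSV
#' @param cohort a validated cohort data.frame.
#' @param path file path.
#' @return `path` (write) or the validated cohort data.frame (read).
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  write.table(cohort, path, sep = ",", row.names = FALSE, quote = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  validate_cohort(df)
}

## ---- allele frequency and Hardy-Weinberg -----------------------------------

#' Minor allele frequency from genotype counts
#'
#' @param counts numeric length-3 vector `(n_AA, n_Aa, n_aa)` of
#'   common-homozygote, heterozygote and rare-homozygote counts.
#' @return the minor allele frequency `(n_Aa + 2 n_aa) / (2 N)`.
#' @export
minor_allele_freq <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L || any(counts < 0) || anyNA(counts))
    stop_input("counts must be 3 nonnegative numbers (n_AA, n_Aa, n_aa)")
  n <- sum(counts)
  if (n == 0) stop_input("all genotype counts are zero")
  (counts[2L] + 2 * counts[3L]) / (2 * n)
}

#' Pearson chi-squared test for Hardy-Weinberg equilibrium
#'
#' Compares observed genotype counts with the proportions expected at the
#' sample allele frequency (p^2, 2pq, q^2) using a 1-df Pearson chi-squared
#' statistic. Intended to be run on control genotypes. Departures are flagged
#' at p <= 1e-4, a screening threshold for genotyping artefacts; flagged
#' SNPs are reported, not removed.
#'
#' @param counts numeric length-3 vector `(n_AA, n_Aa, n_aa)`.
#' @param snp_id optional SNP identifier carried into the result.
#' @return an object of class `hwe_result`: list with `snp_id`, `chi2`,
#'   `df`, `p_value`, `control_counts`, `flagged`.
#' @export
hwe_test <- function(counts, snp_id = NA_character_) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L || any(counts < 0) || anyNA(counts))
    stop_input("counts must be 3 nonnegative numbers")
  n <- sum(counts)
  if (n < 1) stop_input("at least one genotyped sample required")
  q <- minor_allele_freq(counts)
  if (q == 0 || q == 1) {
    warning("monomorphic SNP: HWE test undefined, returning p = 1")
    chi2 <- 0
    p <- 1
  } else {
    expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
    chi2 <- sum((counts - expected)^2 / expected)
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(list(snp_id = snp_id, chi2 = chi2, df = 1L, p_value = p,
                 control_counts = counts, flagged = p <= 1e-4),
            class = "hwe_result")
}

#' Hardy-Weinberg screen of all SNPs in controls
#'
#' @param gm a [genotype_matrix()].
#' @param cohort a validated cohort table aligned with `gm` rows.
#' @return data.frame with one row per SNP: counts, chi2, p-value, flag.
#' @export
hwe_screen <- function(gm, cohort) {
  cohort <- validate_cohort(cohort)
  ctrl <- cohort$status == "control"
  res <- lapply(gm$snp_ids, function(s) {
    g <- gm$dosage[ctrl, s]
    cnt <- c(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
             sum(g == 2L, na.rm = TRUE))
    h <- suppressWarnings(hwe_test(cnt, s))
    data.frame(snp_id = s, n_AA = cnt[1L], n_Aa = cnt[2L], n_aa = cnt[3L],
               maf = minor_allele_freq(cnt), chi2 = h$chi2,
               p_value = h$p_value, flagged = h$flagged)
  })
  do.call(rbind, res)
}

## ---- mode-of-inheritance encodings ----------------------------------------

#' Encode a dosage column under a mode of inheritance
#'
#' Additive keeps the allele count 0/1/2; dominant indicates carriage of at
#' least one minor allele; recessive indicates the rare homozygote;
#' codominant returns two free indicator columns for the heterozygote and
#' rare homozygote (common homozygote as reference).
#'
#' @param g integer dosage vector in 0/1/2, no missing values.
#' @param moi one of `"additive"`, `"dominant"`, `"recessive"`,
#'   `"codominant"`.
#' @return a numeric matrix with 1 column (2 for codominant).
#' @export
encode_moi <- function(g, moi = c("additive", "dominant", "recessive",
                                  "codominant")) {
  moi <- match.arg(moi)
  if (anyNA(g)) stop_input("missing genotypes present: impute before encoding")
  if (!all(g %in% 0:2)) stop_input("dosages must be 0, 1 or 2")
  switch(moi,
    additive  = matrix(as.numeric(g), dimnames = list(NULL, "additive")),
    dominant  = matrix(as.numeric(g >= 1), dimnames = list(NULL, "dominant")),
    recessive = matrix(as.numeric(g == 2), dimnames = list(NULL, "recessive")),
    codominant = cbind(het = as.numeric(g == 1), hom = as.numeric(g == 2))
  )
}

## ---- imputation ------------------------------------------------------------

#' Impute missing genotypes by sampling the observed genotype distribution
#'
#' Each missing dosage is drawn from the empirical genotype distribution of
#' that SNP (cases and controls pooled). This is a deliberately simple
#' frequency-based replacement for phasing-based imputation, adequate for a
#' low-LD tagSNP panel where neighbouring markers carry little information
#' about each other. Deterministic given `seed`.
#'
#' @param gm a [genotype_matrix()].
#' @param seed integer seed.
#' @return a [genotype_matrix()] without missing values.
#' @export
impute_missing <- function(gm, seed = 1L) {
  d <- gm$dosage
  all_miss <- colSums(!is.na(d)) == 0L
  if (any(all_miss))
    stop_input("SNPs with 100% missingness: ",
               paste(gm$snp_ids[all_miss], collapse = ", "))
  with_seed(seed, {
    for (j in seq_len(ncol(d))) {
      miss <- which(is.na(d[, j]))
      if (!length(miss)) next
      obs <- d[-miss, j]
      tab <- tabulate(obs + 1L, nbins = 3L)
      d[miss, j] <- sample(0:2, length(miss), replace = TRUE,
                           prob = tab / sum(tab))
    }
  })
  out <- gm
  out$dosage <- d
  out
}

## ---- p53 histoscore and subphenotypes -------------------------------------

#' Immunohistochemistry histoscore
#'
#' The histoscore summarises p53 staining as `sum_i p_i * i` over intensity
#' categories i = 0..3 weighted by the percentage of cells `p_i` at each
#' intensity; the score ranges from 0 to 300.
#'
#' @param p numeric length-4 vector (or n x 4 matrix) of cell percentages at
#'   intensities 0, 1, 2, 3; each row must sum to 100.
#' @return numeric score(s) in \[0, 300\].
#' @export
histoscore <- function(p) {
  p <- if (is.matrix(p)) p else matrix(p, nrow = 1L)
  if (ncol(p) != 4L) stop_input("need 4 intensity percentages (i = 0..3)")
  if (any(p < 0)) stop_input("percentages must be nonnegative")
  if (any(abs(rowSums(p) - 100) > 1e-6))
    stop_input("intensity percentages must sum to 100")
  drop(p %*% c(0, 1, 2, 3))
}

#' Classify p53 expression relative to the median histoscore
#'
#' Cases at or below the median of the case histoscores are `low`, the rest
#' `high`; ties at the median go to `low`.
#'
#' @param scores numeric histoscores of the cases.
#' @return factor with levels `low`, `high`.
#' @export
classify_p53 <- function(scores) {
  if (!length(scores) || anyNA(scores)) stop_input("need non-missing scores")
  m <- median(scores)
  factor(ifelse(scores <= m, "low", "high"), levels = c("low", "high"))
}

#' Tumor subphenotype from stage and grade
#'
#' Maps bladder-tumor stage (T category) and grade to the three established
#' subphenotypes: low-risk non-muscle-invasive (TaG1, TaG2), high-risk
#' non-muscle-invasive (TaG3, T1G2, T1G3, Tis) and muscle-invasive
#' (T2, T3, T4, any grade). Combinations outside the mapping (e.g. T1G1)
#' return `unknown`.
#'
#' @param stage character vector in `Ta, T1, Tis, T2, T3, T4`.
#' @param grade character vector in `G1, G2, G3, unknown`.
#' @return factor with levels `lowNMIT`, `highNMIT`, `MIT`, `unknown`.
#' @export
assign_subphenotype <- function(stage, grade) {
  ok_stage <- c("Ta", "T1", "Tis", "T2", "T3", "T4")
  ok_grade <- c("G1", "G2", "G3", "unknown")
  if (!all(stage %in% ok_stage))
    stop_input("invalid stage token(s): ",
               paste(setdiff(stage, ok_stage), collapse = ", "))
  if (!all(grade %in% ok_grade))
    stop_input("invalid grade token(s): ",
               paste(setdiff(grade, ok_grade), collapse = ", "))
  out <- rep("unknown", length(stage))
  out[stage == "Ta" & grade %in% c("G1", "G2")] <- "lowNMIT"
  out[(stage == "Ta" & grade == "G3") |
      (stage == "T1" & grade %in% c("G2", "G3")) |
      stage == "Tis"] <- "highNMIT"
  out[stage %in% c("T2", "T3", "T4")] <- "MIT"
  factor(out, levels = c("lowNMIT", "highNMIT", "MIT", "unknown"))
}
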