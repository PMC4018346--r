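# Pipeline orchestration: simulate -> prep -> assoc -> lasso -> report,
# driven by a YAML/JSON config, with a structured run log and deterministic
# per-stage seed substreams.

PIPELINE_STAGES <- c("simulate", "prep", "assoc", "lasso", "report")

#' Build and validate a pipeline run configuration
#'
#' @param config named list, or path to a YAML/JSON config file. Recognised
#'   keys: `seed` (global seed), `stages` (contiguous prefix of
#'   simulate/prep/assoc/lasso/report; later stages imply earlier ones),
#'   `simulate` (logical), `sim` (arguments to [sim_config()], e.g.
#'   `n_cases`, `n_controls`, `n_snps`, `missing_rate`), `inputs`
#'   (`genotypes`, `dialect`, `snp_info`, `cohort` paths when not
#'   simulating), `assoc` (`n_perm`, `family`, `adjust`), and `lasso`
#'   (arguments to [lasso_config()]).
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  defaults <- list(seed = 1L, stages = PIPELINE_STAGES, simulate = TRUE,
                   sim = list(), inputs = list(),
                   assoc = list(n_perm = 1000L, family = "additive_adjusted",
                                adjust = TRUE, interactions = FALSE),
                   lasso = list())
  cfg <- modifyList(defaults, config)
  if (!isTRUE(cfg$simulate) && is.null(config$stages))
    cfg$stages <- setdiff(PIPELINE_STAGES, "simulate")
  bad <- setdiff(cfg$stages, PIPELINE_STAGES)
  if (length(bad)) stop_input("unknown stage(s): ", paste(bad, collapse = ", "))
  # stages must form a contiguous prefix of the pipeline DAG (simulate is
  # optional when inputs are supplied)
  want <- PIPELINE_STAGES %in% cfg$stages
  first <- which(want)[1L]
  last <- max(which(want))
  if (!all(want[first:last]))
    stop_input("stages must be contiguous in the pipeline DAG")
  if (first > 2L)
    stop_input("stages must start at 'simulate' or 'prep'")
  if (!cfg$simulate && "simulate" %in% cfg$stages)
    stop_input("stage 'simulate' requested but simulate = FALSE")
  if (!cfg$simulate &&
      (is.null(cfg$inputs$genotypes) || is.null(cfg$inputs$cohort)))
    stop_input("simulate = FALSE requires inputs$genotypes and inputs$cohort")
  class(cfg) <- "run_config"
  cfg
}

log_line <- function(con, stage, msg) {
  line <- sprintf("%s\t%s\t%s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  writeLines(line, con)
  flush(con)  # partial logs must survive a failing stage
  invisible(line)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages, writing per-stage artifacts and a run log
#' (`run_log.txt`) to `out_dir`. The single global seed is fanned out to
#' every stage by a named substream, so results are reproducible
#' end-to-end and independent of stage order. On a stage failure partial
#' outputs are preserved and the log records the failing stage.
#'
#' @param config a [run_config()] (or list / file path coerced through it).
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out_dir, "run_log.txt"), open = "wt")
  on.exit(close(logf), add = TRUE)
  log_line(logf, "init", sprintf("snplasso %s | seed %d | stages %s",
                                 as.character(utils::packageVersion("snplasso")),
                                 cfg$seed, paste(cfg$stages, collapse = ",")))
  log_line(logf, "init", paste("decisions: imputer=frequency-sampling",
                               "permutation=label+covariate-block",
                               "cv_aic=", cfg$lasso$cv_aic_method %||% "cv_loglik",
                               "bootstrap=", cfg$lasso$bootstrap_mode %||% "resample"))

  run_stage <- function(stage, expr) {
    log_line(logf, stage, "start")
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      log_line(logf, stage, paste("FAILED:", conditionMessage(e)))
      stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
           call. = FALSE)
    })
    log_line(logf, stage, sprintf("done (%.1fs)",
                                  as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs"))))
    res
  }

  ## -- load or simulate ------------------------------------------------------
  if (cfg$simulate) {
    sc <- do.call(sim_config, modifyList(
      list(seed = substream_seed(cfg$seed, "simulate")),
      cfg$sim[setdiff(names(cfg$sim), "n_snps")]))
    if (!is.null(cfg$sim$n_snps))
      sc$snp_specs <- default_snp_specs(cfg$sim$n_snps)
    sim <- run_stage("simulate", {
      out <- simulate_cohort(sc)
      write_genotypes(out$genotypes, file.path(out_dir, "genotypes.raw"))
      write_snp_info(out$genotypes, file.path(out_dir, "snp_info.tsv"))
      write_cohort(out$cohort, file.path(out_dir, "cohort.csv"))
      log_line(logf, "simulate",
               sprintf("n=%d samples, %d SNPs", nrow(out$cohort),
                       length(out$genotypes$snp_ids)))
      out
    })
    gm <- sim$genotypes
    cohort <- sim$cohort
  } else {
    gm <- read_genotypes(cfg$inputs$genotypes,
                         dialect = cfg$inputs$dialect %||% "plink_raw",
                         snp_info = cfg$inputs$snp_info)
    cohort <- read_cohort(cfg$inputs$cohort)
  }
  if (!any(c("prep", "assoc", "lasso", "report") %in% cfg$stages))
    return(invisible(out_dir))

  # downstream stages need complete genotypes: fail fast before any compute
  if (!("prep" %in% cfg$stages) && anyNA(gm$dosage) &&
      any(c("assoc", "lasso") %in% cfg$stages))
    stop_input("genotypes contain missing values but stage 'prep' ",
               "(imputation) was not requested")

  ## -- prep ------------------------------------------------------------------
  if ("prep" %in% cfg$stages) {
    prep <- run_stage("prep", {
      hw <- hwe_screen(gm, cohort)
      write.table(hw, file.path(out_dir, "hwe_screen.csv"), sep = ",",
                  row.names = FALSE, quote = FALSE)
      gi <- impute_missing(gm, seed = substream_seed(cfg$seed, "impute"))
      write_genotypes(gi, file.path(out_dir, "genotypes_imputed.raw"))
      log_line(logf, "prep", sprintf("%d SNPs HWE-flagged", sum(hw$flagged)))
      gi
    })
    gm <- prep
  }

  ## -- single-SNP association ------------------------------------------------
  assoc <- NULL
  if ("assoc" %in% cfg$stages) {
    assoc <- run_stage("assoc", {
      scan <- snp_scan(gm, cohort, adjust = isTRUE(cfg$assoc$adjust))
      write.table(scan, file.path(out_dir, "assoc_results.csv"), sep = ",",
                  row.names = FALSE, quote = FALSE)
      pc <- minp_permutation(gm, cohort, family = cfg$assoc$family,
                             n_perm = cfg$assoc$n_perm,
                             seed = substream_seed(cfg$seed, "perm"))
      write.table(data.frame(snp_id = names(pc$observed_p),
                             p_raw = pc$observed_p,
                             p_corrected = pc$corrected_p),
                  file.path(out_dir, "perm_corrected.csv"), sep = ",",
                  row.names = FALSE, quote = FALSE)
      if (isTRUE(cfg$assoc$interactions)) {
        ix <- interaction_scan(gm, cohort, "snp_smoking")
        write.table(ix, file.path(out_dir, "interaction_smoking.csv"),
                    sep = ",", row.names = FALSE, quote = FALSE)
      }
      list(scan = scan, perm = pc)
    })
  }

  ## -- lasso -----------------------------------------------------------------
  stab <- NULL
  if ("lasso" %in% cfg$stages) {
    stab <- run_stage("lasso", {
      lc <- do.call(lasso_config, modifyList(
        list(seed = substream_seed(cfg$seed, "lasso")), cfg$lasso))
      cd <- covariate_design(cohort)
      X <- gm$dosage[cd$keep, , drop = FALSE]
      rep <- stability_selection(X, cd$X, cd$y, lc)
      jsonlite::write_json(
        list(lambda_opt = rep$lambda_opt, selected = rep$final_selected,
             aic_profile = rep$path,
             reproducibility = as.list(rep$reproducibility),
             post = rep$post, seed = lc$seed),
        file.path(out_dir, "lasso_report.json"), auto_unbox = TRUE,
        digits = NA)
      write.table(data.frame(snp_id = names(rep$reproducibility),
                             reproducibility = rep$reproducibility,
                             selected = names(rep$reproducibility) %in%
                               rep$final_selected),
                  file.path(out_dir, "stability.csv"), sep = ",",
                  row.names = FALSE, quote = FALSE)
      rep
    })
  }

  ## -- report ----------------------------------------------------------------
  if ("report" %in% cfg$stages && !is.null(assoc)) {
    run_stage("report", {
      hw <- hwe_screen(gm, cohort)
      best <- unique(assoc$scan[, c("snp_id", "gene", "best_moi", "best_p")])
      add <- assoc$scan[assoc$scan$moi == "additive",
                        c("snp_id", "or_point", "ci_lo", "ci_hi", "p_value")]
      summary <- merge(merge(best, add, by = "snp_id"),
                       hw[, c("snp_id", "n_AA", "n_Aa", "n_aa", "maf",
                              "p_value")],
                       by = "snp_id", suffixes = c("", "_hwe"))
      summary$p_corrected <- assoc$perm$corrected_p[summary$snp_id]
      summary$reproducibility <- if (is.null(stab)) NA_real_ else
        stab$reproducibility[summary$snp_id]
      write.table(summary[order(summary$best_p), ],
                  file.path(out_dir, "summary.csv"), sep = ",",
                  row.names = FALSE, quote = FALSE)
      NULL
    })
  }
  invisible(out_dir)
}

#' Write small fixture files for tests and examples
#'
#' Generates a cohort of at most 500 samples over the 16 reference SNPs
#' plus four null fillers and writes the genotype matrix (PLINK-raw
#' dialect), SNP metadata and cohort CSV.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @param n_cases,n_controls arm sizes (total capped at 500).
#' @param effects optional named vector of per-allele log odds ratios to
#'   inject, named by SNP id.
#' @return named list of file paths.
#' @export
make_fixtures <- function(seed = 1L, dir = tempfile("fixtures"),
                          n_cases = 250L, n_controls = 250L, effects = NULL) {
  if (n_cases + n_controls > 500L) stop_input("fixtures capped at 500 samples")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  specs <- default_snp_specs(20L)
  if (!is.null(effects))
    specs$per_allele_log_or[match(names(effects), specs$snp_id)] <- effects
  cfg <- sim_config(n_cases = n_cases, n_controls = n_controls,
                    snp_specs = specs, seed = seed)
  sim <- simulate_cohort(cfg)
  paths <- list(genotypes = file.path(dir, "genotypes.raw"),
                snp_info = file.path(dir, "snp_info.tsv"),
                cohort = file.path(dir, "cohort.csv"))
  write_genotypes(sim$genotypes, paths$genotypes)
  write_snp_info(sim$genotypes, paths$snp_info)
  write_cohort(sim$cohort, paths$cohort)
  paths
}

#' Command-line entry point
#'
#' Verbs: `simulate`, `prep`, `assoc`, `lasso`, `all` (each verb runs the
#' pipeline through that stage) and `fixtures`. Typical use:
#' `Rscript -e 'snplasso::pipeline_main()' all --out runs/r1 --seed 7`.
#'
#' @param args character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status 0 invisibly; calls `stop()` on failure.
#' @export
pipeline_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  spec <- list(
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "YAML/JSON config file"),
    optparse::make_option("--out", type = "character", default = "snplasso_run",
                          help = "output directory"),
    optparse::make_option("--seed", type = "integer", default = 1L,
                          help = "global seed"))
  parser <- optparse::OptionParser(
    usage = "%prog [simulate|prep|assoc|lasso|all|fixtures] [options]",
    option_list = spec)
  parsed <- optparse::parse_args(parser, args = args, positional_arguments = 1L)
  verb <- parsed$args
  opt <- parsed$options
  if (verb == "fixtures") {
    paths <- make_fixtures(seed = opt$seed, dir = opt$out)
    message("fixtures written to ", opt$out)
    return(invisible(0L))
  }
  upto <- switch(verb, simulate = "simulate", prep = "prep", assoc = "assoc",
                 lasso = "lasso", all = "report",
                 stop_input("unknown verb: ", verb))
  cfg <- if (is.null(opt$config)) list() else run_config(opt$config)
  cfg <- modifyList(list(seed = opt$seed), unclass(cfg))
  cfg$stages <- PIPELINE_STAGES[seq_len(match(upto, PIPELINE_STAGES))]
  run_pipeline(run_config(cfg), opt$out)
  invisible(0L)
}
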