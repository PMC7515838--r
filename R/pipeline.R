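# End-to-end orchestration of the synthetic study: simulate genotypes and
# summary statistics, build polygenic scores, simulate the cohort with
# dropout, validate the scores, fit the growth models, and run the genetic
# association analyses -- all from one config with deterministic seeding.

#' Build a pipeline configuration
#'
#' @param out_dir output directory (created if absent).
#' @param seed root seed; all stage seeds are derived from it
#'   deterministically (a seed stream drawn once at startup), so runs are
#'   byte-reproducible and stages individually re-runnable.
#' @param n cohort size at wave 1.
#' @param m number of SNPs.
#' @param gwas_n discovery GWAS size for the simulated summary statistics.
#' @param causal_frac fraction of SNPs with nonzero true effect per trait.
#' @param r2_max,window_kb,p_threshold clumping/threshold parameters.
#' @param spec optional `generative_spec` (default built from `n`).
#' @param n_starts optimizer starts for the factors-of-curves fits.
#' @param association_method "sem" or "factor_score".
#' @param apoe_adjusted,simultaneous,lifetime,mediation,validation,parallel
#'   stage toggles.
#' @param alzheimer_strict_threshold second threshold for the Alzheimer
#'   score (NULL to skip).
#' @param genotypes_file optional path to a dosage TSV or VCF to use instead
#'   of simulating genotypes.
#' @param input_files additional input paths checked at pre-flight.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, n = 1091, m = 5000,
                            gwas_n = 1e5, causal_frac = 0.05,
                            r2_max = 0.25, window_kb = 250, p_threshold = 1.0,
                            spec = NULL, n_starts = 2,
                            association_method = c("sem", "factor_score"),
                            apoe_adjusted = TRUE, simultaneous = TRUE,
                            lifetime = TRUE, mediation = TRUE,
                            validation = TRUE, parallel = TRUE,
                            alzheimer_strict_threshold = 0.01,
                            genotypes_file = NULL,
                            input_files = character()) {
  association_method <- match.arg(association_method)
  if (is.null(spec)) spec <- generative_spec(n = n)
  structure(list(out_dir = out_dir, seed = as.integer(seed), n = n, m = m,
                 gwas_n = gwas_n, causal_frac = causal_frac,
                 r2_max = r2_max, window_kb = window_kb,
                 p_threshold = p_threshold, spec = spec, n_starts = n_starts,
                 association_method = association_method,
                 apoe_adjusted = apoe_adjusted, simultaneous = simultaneous,
                 lifetime = lifetime, mediation = mediation,
                 validation = validation, parallel = parallel,
                 alzheimer_strict_threshold = alzheimer_strict_threshold,
                 genotypes_file = genotypes_file,
                 input_files = c(genotypes_file, input_files)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

write_table_prov <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cogslope provenance: config_hash=%s seed=%d", hash,
                     seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic-study pipeline
#'
#' Stages, in the preregistered-analysis order the package emulates:
#' polygenic score construction and own-phenotype validation, the score
#' correlation matrix and parallel analysis, per-test growth curves, the
#' factors-of-curves model with fit indices and variance decomposition,
#' single-predictor associations with per-column FDR, APOE-adjusted and
#' simultaneous models, lifetime-change associations, and the education
#' mediation model. All tabular outputs are CSVs with a provenance header;
#' identical config + seed yields byte-identical outputs.
#'
#' @param config a `pipeline_config`.
#' @return (invisibly) list of in-memory results; files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[3]
  # pre-flight: every referenced input must resolve before anything is written
  missing_in <- config$input_files[!file.exists(config$input_files)]
  if (length(missing_in))
    stop("pre-flight: missing input file(s): ",
         paste(missing_in, collapse = ", "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  set.seed(config$seed)
  seeds <- sample.int(1e8, 64)
  log <- list(config_hash = hash, seed = config$seed, stages = list())
  stage <- function(name, rec) log$stages[[name]] <<- rec
  emit <- function(df, fname) write_table_prov(df, file.path(config$out_dir,
                                                             fname),
                                               hash, config$seed)
  gspec <- config$spec
  pe <- gspec$predictor_effects
  traits <- pe$predictor[pe$type == "continuous"]

  # --- stage 1: genotypes ---------------------------------------------------
  geno <- if (!is.null(config$genotypes_file)) {
    if (grepl("\\.vcf$", config$genotypes_file))
      read_vcf_dosage(config$genotypes_file) else
        read_dosage_tsv(config$genotypes_file)
  } else simulate_genotypes(config$n, config$m, seed = seeds[1])
  if (nrow(geno$dosage) != config$n)
    stop("pre-flight: genotype rows do not match cohort n")
  config$m <- ncol(geno$dosage)
  stage("genotypes", list(n = config$n, m = config$m, seed = seeds[1]))

  # --- stage 2: summary statistics and polygenic scores ----------------------
  set.seed(seeds[2])
  n_causal <- max(1L, round(config$m * config$causal_frac))
  pgs_truth <- matrix(NA_real_, config$n, length(traits),
                      dimnames = list(NULL, traits))
  pgs_std <- matrix(NA_real_, config$n, length(traits),
                    dimnames = list(NULL, traits))
  snp_counts <- setNames(integer(length(traits)), traits)
  alz_strict <- NULL
  for (k in seq_along(traits)) {
    tr <- traits[k]
    tb <- numeric(config$m)
    idx <- sample.int(config$m, n_causal)
    tb[idx] <- rnorm(n_causal, 0, 0.05)
    if (tr == "alzheimer" && config$m > 0)
      tb[idx[1]] <- 0.4        # one large-effect locus (APOE-like region)
    ss <- simulate_summary_stats(geno, tb, config$gwas_n,
                                 seed = seeds[2 + k])
    h <- harmonize_sumstats(ss, geno)
    cl <- ld_clump(h, geno, config$r2_max, config$window_kb)
    sc <- pgs_score(geno, h, cl, config$p_threshold)
    pgs_std[, k] <- sc$score_std
    pgs_truth[, k] <- drop(geno$dosage %*% tb)
    snp_counts[k] <- sc$n_snps_used
    if (tr == "alzheimer" && !is.null(config$alzheimer_strict_threshold))
      alz_strict <- pgs_score(geno, h, cl, config$alzheimer_strict_threshold)
  }
  stage("pgs", list(n_snps_used = as.list(snp_counts),
                    r2_max = config$r2_max, window_kb = config$window_kb,
                    p_threshold = config$p_threshold))

  # --- stage 3: cohort -------------------------------------------------------
  cohort <- simulate_cohort(gspec, pgs_truth = pgs_truth, seed = seeds[20])
  cohort <- apply_dropout(cohort, seed = seeds[21])
  bat <- gspec$battery
  stage("cohort", list(n = nrow(cohort),
                       retained = as.list(setNames(gspec$retention,
                                                   paste0("w", seq_along(gspec$retention))))))

  # analysis table: cohort + computed (standardized) scores
  adat <- cohort
  # score columns get a pgs_ prefix so they never shadow the phenotype
  # columns of the same trait (height, bmi, ...)
  score_cols <- paste0("pgs_", traits)
  for (k in seq_along(traits)) adat[[score_cols[k]]] <- pgs_std[, traits[k]]
  if (!is.null(alz_strict)) adat$pgs_alzheimer_p01 <- alz_strict$score_std
  predictors <- c(score_cols, "apoe")

  results <- list()

  # --- stage 4: preliminary validation / correlations / parallel ------------
  if (config$validation) {
    vs <- gspec$validation
    covs <- data.frame(age = cohort$age_days_w1, sex = cohort$sex,
                       cohort[, paste0("mds", 1:4)])
    tab1 <- do.call(rbind, lapply(seq_len(nrow(vs)), function(v) {
      validate_own_phenotype(adat[[paste0("pgs_", vs$predictor[v])]],
                             adat[[vs$phenotype[v]]],
                             vs$type[v], covs, score_name = vs$predictor[v],
                             outcome_name = vs$phenotype[v])
    }))
    tab1$q <- fdr_adjust(tab1$p)
    emit(tab1, "table1_validation.csv")
    results$validation <- tab1
    cm <- pgs_correlation_matrix(adat[, score_cols])
    emit(cbind(score = rownames(cm$r), as.data.frame(round(cm$r, 6))),
         "pgs_correlations.csv")
    results$correlations <- cm
  }
  if (config$parallel) {
    pa <- parallel_analysis(adat[, score_cols], n_simulations = 100,
                            seed = seeds[22])
    results$parallel <- pa
    emit(data.frame(rank = seq_along(pa$eigenvalues),
                    observed = pa$eigenvalues, reference = pa$reference,
                    retained = seq_along(pa$eigenvalues) <= pa$n_factors),
         "parallel_analysis.csv")
    stage("parallel", list(n_factors = pa$n_factors))
  }

  # --- stage 5: growth curves (raw scores) ----------------------------------
  fspec <- foc_model_spec(bat, gspec$time_basis)
  tab2 <- do.call(rbind, lapply(bat$test, function(tst) {
    sc <- as.matrix(cohort[, score_col(tst, seq_along(gspec$time_basis))])
    g <- fit_univariate_lgc(sc, gspec$time_basis, n_starts = 1)
    data.frame(test = tst, domain = bat$domain[match(tst, bat$test)],
               mean_baseline = g$mean_intercept,
               raw_change_per_year = g$mean_slope, se = g$slope_se,
               p = 2 * pnorm(-abs(g$mean_slope / g$slope_se)),
               sd_change_per_year = g$sd_scaled_slope,
               stringsAsFactors = FALSE)
  }))
  emit(tab2, "table2_growth.csv")
  results$growth <- tab2
  stage("growth", list(tests = nrow(tab2)))

  # --- stage 6: factors-of-curves model on residualized scores --------------
  rdat <- residualize_scores(adat, bat$test, length(gspec$time_basis))
  base_fit <- fit_foc(fspec, rdat, n_starts = config$n_starts)
  if (!isTRUE(base_fit$converged))
    stop("pipeline stage foc_fit: base model did not converge")
  fi <- fit_indices(base_fit, rdat)
  dec <- variance_decomposition(base_fit)
  emit(dec$table, "decomposition.csv")
  jsonlite::write_json(
    list(estimates = as.list(round(base_fit$par, 8)),
         se = as.list(round(base_fit$se, 8)),
         loglik = base_fit$loglik, n = base_fit$n,
         converged = base_fit$converged,
         fit_indices = fi[c("chisq", "df", "pvalue", "rmsea", "cfi", "tli",
                            "srmr")],
         mean_variance_shares = dec$means,
         provenance = list(config_hash = hash, seed = config$seed)),
    file.path(config$out_dir, "foc_model.json"),
    auto_unbox = TRUE, digits = 10, pretty = TRUE)
  results$foc <- list(fit = base_fit, indices = fi, decomposition = dec)
  stage("foc_fit", list(loglik = base_fit$loglik, cfi = fi$cfi,
                        rmsea = fi$rmsea))

  # --- stage 7: associations -------------------------------------------------
  assoc_args <- list(n_starts = config$n_starts)
  tab3 <- do.call(rbind, lapply(predictors, function(p)
    do.call(single_predictor_association,
            c(list(fspec, rdat, p, method = config$association_method,
                   base_fit = base_fit), assoc_args))))
  for (oc in unique(tab3$outcome))
    tab3$q[tab3$outcome == oc] <- fdr_adjust(tab3$p[tab3$outcome == oc])
  emit(tab3, "table3_associations.csv")
  results$associations <- tab3
  stage("associations", list(rows = nrow(tab3),
                             method = config$association_method))

  if (config$apoe_adjusted) {
    sig <- unique(tab3$predictor[tab3$q < 0.05 & tab3$predictor != "apoe"])
    if (length(sig)) {
      taba <- do.call(rbind, lapply(sig, function(p)
        do.call(apoe_adjusted_association,
                c(list(fspec, rdat, p, method = config$association_method,
                       base_fit = base_fit), assoc_args))))
      emit(taba, "apoe_adjusted.csv")
      results$apoe_adjusted <- taba
    }
  }
  if (config$simultaneous) {
    tabs <- do.call(simultaneous_association,
                    c(list(fspec, rdat, score_cols, method = "factor_score",
                           base_fit = base_fit), assoc_args))
    for (oc in unique(tabs$outcome))
      tabs$q[tabs$outcome == oc] <- fdr_adjust(tabs$p[tabs$outcome == oc])
    emit(tabs, "simultaneous.csv")
    results$simultaneous <- tabs
  }
  if (config$lifetime) {
    tab4 <- do.call(rbind, lapply(predictors, function(p)
      do.call(lifetime_change_association,
              c(list(fspec, rdat, p, method = config$association_method,
                     base_fit = base_fit), assoc_args))))
    for (oc in unique(tab4$outcome))
      tab4$q[tab4$outcome == oc] <- fdr_adjust(tab4$p[tab4$outcome == oc])
    emit(tab4, "table4_lifetime.csv")
    results$lifetime <- tab4
  }
  if (config$mediation) {
    med <- mediation_education(fspec, rdat, pgs = "pgs_education",
                               base_fit = base_fit)
    jsonlite::write_json(
      c(med[c("a", "b", "c_direct", "indirect", "total",
              "proportion_mediated", "unstable", "n")],
        list(provenance = list(config_hash = hash, seed = config$seed))),
      file.path(config$out_dir, "mediation.json"),
      auto_unbox = TRUE, digits = 10, pretty = TRUE)
    results$mediation <- med
  }

  # run_log content is deterministic (no timings) so reruns are byte-identical
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$elapsed_seconds <- round(proc.time()[3] - t0, 1)
  invisible(results)
}
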