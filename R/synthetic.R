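# Synthetic cohort generator: genotypes with block LD, GWAS summary
# statistics, and a four-wave longitudinal cohort with the hierarchical
# factors-of-curves structure, small polygenic effects on the general level,
# a binary risk allele affecting the general slope, an age-11 score linked to
# the adult level factor, own-phenotype validation outcomes, and monotone
# score-dependent (MAR) dropout.

#' Default genetic predictor effects
#'
#' Standardized effects of each predictor on the general cognitive level,
#' general slope, and the age-11 score. Continuous polygenic predictors are
#' standardized before their effect applies; the binary APOE e4 indicator
#' enters 0/1 (its effect is standardized with respect to the outcome only).
#'
#' @return data.frame: `predictor`, `beta_level`, `beta_slope`, `beta_age11`,
#'   `type`.
#' @export
default_predictor_effects <- function() {
  data.frame(
    predictor = c("education", "neuroticism", "conscientiousness", "alzheimer",
                  "schizophrenia", "mdd", "cad", "stroke", "t2d", "smoking",
                  "height", "bmi", "fev1", "grip", "apoe"),
    beta_level = c(0.302, -0.077, -0.017, -0.017, -0.148, -0.037, -0.108,
                   -0.056, -0.089, -0.178, 0.093, -0.135, 0.074, -0.041,
                   -0.153),
    beta_slope = c(0.006, -0.004, 0.015, -0.073, -0.110, -0.008, -0.011,
                   -0.016, -0.010, -0.035, 0.009, 0.028, 0.051, 0.035,
                   -0.319),
    beta_age11 = c(0.321, -0.032, 0.010, 0.012, -0.136, 0.028, -0.098,
                   -0.075, -0.079, -0.187, 0.063, -0.164, 0.055, -0.030,
                   0.024),
    type = c(rep("continuous", 14), "binary"),
    stringsAsFactors = FALSE)
}

#' Default own-phenotype validation outcomes
#'
#' One outcome per polygenic predictor, with the generating standardized
#' coefficient (continuous/ordinal) or log-odds coefficient and prevalence
#' (binary). Smoking status is a 3-level ordinal (never/ex/current).
#'
#' @return data.frame describing the validation phenotypes.
#' @export
default_validation_spec <- function() {
  data.frame(
    phenotype = c("educ_years", "neuroticism_score", "conscientiousness_score",
                  "mmse", "hads_depression", "cvd", "stroke_dx", "diabetes",
                  "smoking_status", "height", "bmi", "fev1", "grip"),
    predictor = c("education", "neuroticism", "conscientiousness", "alzheimer",
                  "mdd", "cad", "stroke", "t2d", "smoking", "height", "bmi",
                  "fev1", "grip"),
    type = c("continuous", "continuous", "continuous", "continuous",
             "continuous", "binary", "binary", "binary", "ordinal",
             "continuous", "continuous", "continuous", "continuous"),
    coef = c(0.276, 0.176, 0.083, -0.061, 0.002, 0.267, 0.169, 0.608,
             0.147, 0.365, 0.359, 0.191, 0.065),
    prevalence = c(NA, NA, NA, NA, NA, 0.245, 0.050, 0.086, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}

#' Generative specification for the synthetic cohort
#'
#' Encodes the stated world the generator draws from: a 13-test battery in 4
#' domains measured at 4 waves, a hierarchical factor structure over latent
#' levels and slopes (general level factor indexing ~41% and general slope
#' factor ~70% of test-level variance under the defaults), genetic predictor
#' effects, an age-11 score whose standardized regression on the general
#' level is `age11_beta`, wave retention targets with score-dependent
#' monotone dropout, and own-phenotype validation outcomes.
#'
#' All latent construction happens on standardized scales and is then mapped
#' to each test's raw units via its baseline SD. Derived residual variances
#' and cross-equation covariances are calibrated here once, and an error is
#' raised if the requested moments are not jointly attainable.
#'
#' @param n number of individuals at wave 1.
#' @param battery test battery (see [default_battery()]).
#' @param time_basis years since wave 1 at each wave.
#' @param level_general_loading standardized domain-on-general loadings for
#'   levels (recycled across domains).
#' @param slope_general_loading same for slopes.
#' @param level_domain_loading standardized test-on-domain loadings for
#'   levels (recycled across tests).
#' @param slope_domain_loading same for slopes.
#' @param level_share share of baseline observed score variance attributable
#'   to the latent level (the rest is occasion residual).
#' @param slope_sd_frac between-person slope SD per year, as a fraction of
#'   the baseline SD.
#' @param cor_level_slope correlation of the general level and slope factors.
#' @param predictor_effects see [default_predictor_effects()].
#' @param apoe_frequency carrier proportion of the binary risk indicator.
#' @param apoe_alzheimer_r latent-scale correlation between the risk-allele
#'   liability and the Alzheimer polygenic truth (yields a small positive
#'   point-biserial correlation).
#' @param age11_beta standardized regression of the general level factor on
#'   the age-11 score.
#' @param education mediation wiring for the education score: `a` (score ->
#'   years of education) plus either `b` (years of education -> level,
#'   conditional) or `proportion_mediated` from which `b` is derived.
#' @param sex_frac_female proportion female.
#' @param sex_effect_frac additive sex effect on each test in baseline-SD
#'   units.
#' @param age_baseline_mean,age_baseline_sd mean/SD of age (years) at wave 1.
#' @param age_jitter_sd SD of per-wave attendance-date jitter (years).
#' @param retention per-wave retained counts (non-increasing; defaults scale
#'   the 1091/866/697/550 pattern to `n`).
#' @param mar_strength dropout selection: log-odds of retention per SD of the
#'   previous wave's observed general composite.
#' @param validation see [default_validation_spec()].
#' @return object of class `generative_spec` with a `derived` element holding
#'   all calibrated quantities.
#' @export
generative_spec <- function(n = 1091,
                            battery = default_battery(),
                            time_basis = c(0, 2.98, 6.71, 9.78),
                            level_general_loading = 0.75,
                            slope_general_loading = 0.92,
                            level_domain_loading = 0.85,
                            slope_domain_loading = 0.91,
                            level_share = 0.70,
                            slope_sd_frac = 0.06,
                            cor_level_slope = 0.30,
                            predictor_effects = default_predictor_effects(),
                            apoe_frequency = 306 / 1028,
                            apoe_alzheimer_r = 0.154,
                            age11_beta = 0.814,
                            education = list(a = 0.276,
                                             proportion_mediated = 0.064,
                                             b = NULL),
                            sex_frac_female = 543 / 1091,
                            sex_effect_frac = 0.10,
                            age_baseline_mean = 69.54,
                            age_baseline_sd = 0.83,
                            age_jitter_sd = 0.15,
                            retention = NULL,
                            mar_strength = 0.8,
                            validation = default_validation_spec()) {
  stopifnot(n >= 0, is.data.frame(battery))
  if (time_basis[1] != 0 || any(diff(time_basis) <= 0))
    stop("time_basis must start at 0 and be strictly increasing")
  nt <- nrow(battery)
  doms <- unique(battery$domain)
  if (anyDuplicated(battery$test)) stop("tests must be unique")
  if (is.null(retention))
    retention <- pmin(n, round(n * c(1091, 866, 697, 550) / 1091))
  if (length(retention) != length(time_basis))
    stop("retention must have one count per wave")
  if (any(diff(retention) > 0)) stop("retention targets must be non-increasing")
  if (retention[1] > n) stop("first retention target exceeds n")
  if (level_share <= 0 || level_share > 1) stop("level_share in (0, 1]")
  stopifnot(all(battery$sd0 > 0))

  gl <- rep_len(level_general_loading, length(doms))
  gs <- rep_len(slope_general_loading, length(doms))
  ll <- rep_len(level_domain_loading, nt)
  ls <- rep_len(slope_domain_loading, nt)
  if (any(abs(c(gl, gs, ll, ls)) >= 1))
    stop("standardized loadings must lie in (-1, 1)")

  pe <- predictor_effects
  stopifnot(all(c("predictor", "beta_level", "beta_slope", "beta_age11",
                  "type") %in% names(pe)))
  vx <- ifelse(pe$type == "binary", apoe_frequency * (1 - apoe_frequency), 1)

  var_uG_raw <- 1 - sum(pe$beta_level^2 * vx)
  var_uS <- 1 - sum(pe$beta_slope^2 * vx)
  var_ea <- 1 - sum(pe$beta_age11^2 * vx)
  if (min(var_uG_raw, var_uS, var_ea) <= 0)
    stop("predictor effects leave no residual variance")

  # education mediation: educ = a * x_edu + e_m; the level factor loads on
  # e_m with weight b so that the conditional (on score and age-11)
  # education -> level path equals b.
  a_med <- education$a %||% 0.276
  i_edu <- match("education", pe$predictor)
  cov_eaG <- age11_beta - sum(pe$beta_age11 * pe$beta_level * vx)
  phi <- cov_eaG / var_ea
  b_med <- education$b
  if (is.null(b_med)) {
    prop <- education$proportion_mediated %||% 0
    total_cond <- if (!is.na(i_edu))
      pe$beta_level[i_edu] - phi * pe$beta_age11[i_edu] else 0
    b_med <- if (a_med != 0 && total_cond != 0) prop * total_cond / a_med else 0
  }
  var_em <- 1 - a_med^2
  if (var_em < 0) stop("education path a must lie in [-1, 1]")
  var_uG <- var_uG_raw - b_med^2 * var_em
  if (var_uG <= 0) stop("education mediation path too large")

  cov_GSres <- cor_level_slope - sum(pe$beta_level * pe$beta_slope * vx)
  # residual trivariate covariance (e_a, u_G, u_S); e_a relates to u_S only
  # through u_G
  cov_eaS <- cov_eaG * cov_GSres / var_uG
  Sres <- matrix(c(var_ea, cov_eaG, cov_eaS,
                   cov_eaG, var_uG, cov_GSres,
                   cov_eaS, cov_GSres, var_uS), 3, 3)
  ev <- eigen(Sres, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("requested age-11 linkage / level-slope correlation not jointly ",
         "attainable with these predictor effects")

  d_idx <- match(battery$domain, doms)
  derived <- list(
    doms = doms, d_idx = d_idx,
    gl = gl, gs = gs, ll = ll, ls = ls,
    sdI = sqrt(level_share) * battery$sd0,
    sdS = slope_sd_frac * battery$sd0,
    theta = (1 - level_share) * battery$sd0^2,
    sex_delta = sex_effect_frac * battery$sd0,
    vx = vx, var_uG = var_uG, var_uS = var_uS, var_ea = var_ea,
    var_em = var_em, a_med = a_med, b_med = b_med, phi = phi,
    Sres = Sres, cov_GSres = cov_GSres, cov_eaG = cov_eaG, cov_eaS = cov_eaS)

  structure(list(
    n = n, battery = battery, time_basis = time_basis,
    level_general_loading = gl, slope_general_loading = gs,
    level_domain_loading = ll, slope_domain_loading = ls,
    level_share = level_share, slope_sd_frac = slope_sd_frac,
    cor_level_slope = cor_level_slope,
    predictor_effects = pe, apoe_frequency = apoe_frequency,
    apoe_alzheimer_r = apoe_alzheimer_r, age11_beta = age11_beta,
    education = list(a = a_med, b = b_med),
    sex_frac_female = sex_frac_female, sex_effect_frac = sex_effect_frac,
    age_baseline_mean = age_baseline_mean, age_baseline_sd = age_baseline_sd,
    age_jitter_sd = age_jitter_sd,
    retention = retention, mar_strength = mar_strength,
    validation = validation, derived = derived),
    class = "generative_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.generative_spec <- function(x, ...) {
  cat("Generative spec: n =", x$n, ",", nrow(x$battery), "tests in",
      length(unique(x$battery$domain)), "domains,",
      length(x$time_basis), "waves\n  retention:",
      paste(x$retention, collapse = "/"), "\n")
  invisible(x)
}

#' Population moments implied by a generative specification
#'
#' Exact mean vector and covariance matrix of the complete-data observed
#' scores (including the additive sex effect and the baseline-age
#' contribution), computed from the generating parameters by linear moment
#' algebra -- independent of the simulation path.
#'
#' @param spec a `generative_spec`.
#' @return list `mu`, `Sigma` over the `<test>_w<wave>` columns.
#' @export
truth_moments <- function(spec) {
  d <- spec$derived; bat <- spec$battery; tb <- spec$time_basis
  nt <- nrow(bat); W <- length(tb)
  # standardized latent level/slope covariance across tests
  covL <- matrix(0, nt, nt); covS <- matrix(0, nt, nt)
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    same <- d$d_idx[i] == d$d_idx[j]
    gg_l <- d$gl[d$d_idx[i]] * d$gl[d$d_idx[j]]
    gg_s <- d$gs[d$d_idx[i]] * d$gs[d$d_idx[j]]
    covL[i, j] <- d$ll[i] * d$ll[j] *
      (gg_l + if (same) 1 - d$gl[d$d_idx[i]]^2 else 0) +
      (if (i == j) 1 - d$ll[i]^2 else 0)
    covS[i, j] <- d$ls[i] * d$ls[j] *
      (gg_s + if (same) 1 - d$gs[d$d_idx[i]]^2 else 0) +
      (if (i == j) 1 - d$ls[i]^2 else 0)
  }
  # cross level-slope: only through the general factors
  covX <- outer(d$ll * d$gl[d$d_idx], d$ls * d$gs[d$d_idx]) *
    spec$cor_level_slope
  CIS <- rbind(cbind(covL * tcrossprod(d$sdI), covX * outer(d$sdI, d$sdS)),
               cbind(t(covX * outer(d$sdI, d$sdS)), covS * tcrossprod(d$sdS)))
  muIS <- c(bat$mean0, bat$slope_per_year)
  # design: score(test t, wave w) = I_t + tb_w * S_t + extras
  Tm <- matrix(0, nt * W, 2 * nt)
  for (t in seq_len(nt)) for (w in seq_len(W)) {
    r <- (t - 1) * W + w
    Tm[r, t] <- 1
    Tm[r, nt + t] <- tb[w]
  }
  Sigma <- Tm %*% CIS %*% t(Tm)
  mu <- drop(Tm %*% muIS)
  # occasion residuals
  diag(Sigma) <- diag(Sigma) + rep(d$theta, each = W)
  # additive sex effect and shared baseline-age contribution
  pf <- spec$sex_frac_female
  delta <- rep(d$sex_delta, each = W)
  agev <- rep(bat$slope_per_year, each = W)
  Sigma <- Sigma + tcrossprod(delta) * pf * (1 - pf) +
    tcrossprod(agev) * spec$age_baseline_sd^2
  mu <- mu + delta * pf
  nms <- as.vector(vapply(bat$test, function(t) score_col(t, seq_len(W)),
                          character(W)))
  list(mu = setNames(mu, nms),
       Sigma = structure(Sigma, dimnames = list(nms, nms)))
}

#' Population mediation decomposition implied by the generator
#'
#' The education score's effect on the age-11-adjusted level factor splits
#' into an indirect path via years of education (`a * b`) and a direct path
#' `c' = total - a * b`, evaluated exactly from the generating parameters.
#'
#' @param spec a `generative_spec`.
#' @return list `a`, `b`, `c_direct`, `indirect`, `total`,
#'   `proportion_mediated`.
#' @export
implied_mediation <- function(spec) {
  d <- spec$derived; pe <- spec$predictor_effects
  i <- match("education", pe$predictor)
  if (is.na(i)) stop("no education predictor in spec")
  total <- pe$beta_level[i] - d$phi * pe$beta_age11[i]
  ind <- d$a_med * d$b_med
  list(a = d$a_med, b = d$b_med, c_direct = total - ind,
       indirect = ind, total = total,
       proportion_mediated = if (total != 0) ind / total else NA_real_)
}

#' Simulate genotype dosages with block linkage disequilibrium
#'
#' Gaussian-copula latent liabilities, exchangeably correlated within blocks
#' of consecutive SNPs, thresholded per haplotype at the SNP's allele
#' frequency; the two haplotype alleles add to a Hardy-Weinberg binomial
#' dosage in 0..2. Block positions are laid out so a block spans well under
#' the clumping window while distinct blocks are separated by large gaps.
#'
#' @param n individuals.
#' @param m SNPs.
#' @param block_size SNPs per LD block.
#' @param within_block_r latent liability correlation within a block, in
#'   `[0, 1)`.
#' @param maf_range minor-allele-frequency sampling interval within
#'   `(0, 0.5]`.
#' @param spacing_bp distance between adjacent SNPs in a block.
#' @param block_gap_bp gap between blocks.
#' @param prop_ambiguous fraction of SNPs given strand-ambiguous (A/T or
#'   C/G) allele pairs, to exercise harmonization.
#' @param seed optional RNG seed.
#' @return object of class `genotype_matrix`: `dosage` (n x m) and `snps`
#'   metadata (id, chr, bp, a1, a2, maf, block).
#' @export
simulate_genotypes <- function(n, m, block_size = 20, within_block_r = 0.8,
                               maf_range = c(0.05, 0.5), spacing_bp = 5000L,
                               block_gap_bp = 1000000L, prop_ambiguous = 0.1,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n < 0 || m < 0) stop("n and m must be non-negative")
  if (within_block_r < 0 || within_block_r >= 1)
    stop("within_block_r must lie in [0, 1)")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  block <- if (m > 0) rep(seq_len(ceiling(m / block_size)),
                          each = block_size)[seq_len(m)] else integer(0)
  maf <- runif(m, maf_range[1], maf_range[2])
  chr <- if (m > 0) ((block - 1) %% 22) + 1 else integer(0)
  within <- if (m > 0) stats::ave(seq_len(m), block, FUN = seq_along) else integer(0)
  block_on_chr <- if (m > 0) (block - 1) %/% 22 else integer(0)
  bp <- as.integer(1e6 + block_on_chr * (block_gap_bp + block_size * spacing_bp) +
                     (within - 1) * spacing_bp)
  pairs_ok <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"),
                    c("C", "A"), c("G", "A"), c("T", "C"), c("T", "G"))
  pairs_amb <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  amb <- runif(m) < prop_ambiguous
  pick <- function(tab, k) tab[sample.int(nrow(tab), k, replace = TRUE), ,
                               drop = FALSE]
  al <- matrix("", m, 2)
  if (any(amb)) al[amb, ] <- pick(pairs_amb, sum(amb))
  if (any(!amb)) al[!amb, ] <- pick(pairs_ok, sum(!amb))

  D <- matrix(0L, n, m)
  if (n > 0 && m > 0) {
    r <- within_block_r
    for (b in unique(block)) {
      js <- which(block == b); k <- length(js)
      hap <- function() {
        zc <- rnorm(n)
        z <- sqrt(r) * matrix(zc, n, k) + sqrt(1 - r) * matrix(rnorm(n * k), n, k)
        sweep(z, 2, qnorm(maf[js]), `<`) + 0L
      }
      D[, js] <- hap() + hap()
    }
  }
  snps <- data.frame(id = sprintf("snp%06d", seq_len(m)), chr = chr, bp = bp,
                     a1 = al[, 1], a2 = al[, 2], maf = maf, block = block,
                     stringsAsFactors = FALSE)
  colnames(D) <- snps$id
  structure(list(dosage = D, snps = snps), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$dosage), "individuals x", ncol(x$dosage),
      "SNPs\n")
  invisible(x)
}

#' Simulate GWAS summary statistics
#'
#' Per-SNP marginal effect estimates for a standardized phenotype:
#' `beta = true_beta + N(0, SE)` with the analytic standard error
#' `SE = 1 / sqrt(gwas_n * 2 maf (1 - maf))`, and two-sided normal p-values.
#'
#' @param genotypes a `genotype_matrix` (supplies SNP metadata and MAF).
#' @param true_betas per-SNP true effects, aligned to the genotype columns.
#' @param gwas_n discovery GWAS sample size.
#' @param seed optional RNG seed.
#' @return data.frame of class `summary_stats`: SNP, CHR, BP, A1, A2, BETA,
#'   SE, P.
#' @export
simulate_summary_stats <- function(genotypes, true_betas, gwas_n,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- genotypes$snps
  if (length(true_betas) != nrow(s))
    stop("true_betas must align with the genotype SNPs")
  if (gwas_n <= 0) stop("gwas_n must be positive")
  se <- 1 / sqrt(gwas_n * 2 * s$maf * (1 - s$maf))
  beta <- true_betas + rnorm(nrow(s), 0, se)
  z <- beta / se
  p <- pmin(pmax(2 * pnorm(-abs(z)), .Machine$double.xmin), 1)
  structure(data.frame(SNP = s$id, CHR = s$chr, BP = s$bp, A1 = s$a1,
                       A2 = s$a2, BETA = beta, SE = se, P = p,
                       stringsAsFactors = FALSE),
            class = c("summary_stats", "data.frame"))
}

#' Simulate the longitudinal cohort
#'
#' Draws per-person general level and slope factors (with genetic predictor
#' effects added as linear regressions), domain and test factors, and
#' observed wave scores; generates the age-11 score so its standardized
#' regression on the general level equals the specified default; attaches
#' sex, ages in days, the binary risk-allele indicator, ancestry components,
#' and own-phenotype validation outcomes. All waves are complete; apply
#' dropout with [apply_dropout()].
#'
#' @param spec a `generative_spec`.
#' @param pgs_truth optional n x k matrix/data.frame of per-person true
#'   genetic scores, columns named after continuous predictors in the spec;
#'   any continuous predictor without a supplied column is drawn iid N(0,1).
#'   Columns are standardized internally.
#' @param seed optional RNG seed.
#' @return data.frame of class `cohort_table` with attributes `battery`,
#'   `spec`, and `truth` (per-person true latent values).
#' @export
simulate_cohort <- function(spec, pgs_truth = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(spec, "generative_spec"))
  n <- spec$n; d <- spec$derived; bat <- spec$battery
  tb <- spec$time_basis; W <- length(tb); nt <- nrow(bat)
  pe <- spec$predictor_effects

  if (!is.null(pgs_truth)) {
    pgs_truth <- as.data.frame(pgs_truth)
    bad <- setdiff(colnames(pgs_truth),
                   pe$predictor[pe$type == "continuous"])
    if (length(bad))
      stop("pgs_truth columns not in predictor_effects: ",
           paste(bad, collapse = ", "))
    if (nrow(pgs_truth) != n) stop("pgs_truth must have n rows")
  }
  X <- matrix(0, n, nrow(pe), dimnames = list(NULL, pe$predictor))
  for (j in seq_len(nrow(pe))) {
    p <- pe$predictor[j]
    if (pe$type[j] == "binary") next
    x <- if (!is.null(pgs_truth) && p %in% colnames(pgs_truth))
      pgs_truth[[p]] else rnorm(n)
    if (sd(x) == 0) stop("constant pgs_truth column: ", p)
    X[, j] <- as.numeric(scale(x))
  }
  # binary risk indicator, weakly correlated with the Alzheimer score truth
  i_apoe <- which(pe$type == "binary")
  apoe <- integer(n)
  if (length(i_apoe)) {
    rho <- spec$apoe_alzheimer_r
    base <- if ("alzheimer" %in% pe$predictor) X[, "alzheimer"] else rnorm(n)
    liab <- rho * base + sqrt(1 - rho^2) * rnorm(n)
    apoe <- as.integer(liab > qnorm(1 - spec$apoe_frequency))
    for (j in i_apoe) X[, j] <- apoe - mean(apoe)   # centered for effects
  }

  # residual block (e_a, u_G, u_S) with calibrated covariance
  L <- chol(d$Sres + diag(1e-12, 3))
  res <- matrix(rnorm(n * 3), n, 3) %*% L
  e_a <- res[, 1]; u_G <- res[, 2]; u_S <- res[, 3]
  e_m <- rnorm(n, 0, sqrt(d$var_em))

  age11 <- drop(X %*% pe$beta_age11) + e_a
  G <- drop(X %*% pe$beta_level) + d$b_med * e_m + u_G
  GS <- drop(X %*% pe$beta_slope) + u_S
  educ_years <- if ("education" %in% colnames(X))
    d$a_med * X[, "education"] + e_m else e_m

  # hierarchy: domains then tests, standardized, then scaled to raw units
  nd <- length(d$doms)
  Dlev <- matrix(G, n, nd) * matrix(d$gl, n, nd, byrow = TRUE) +
    matrix(rnorm(n * nd), n, nd) %*% diag(sqrt(1 - d$gl^2), nd)
  Dslo <- matrix(GS, n, nd) * matrix(d$gs, n, nd, byrow = TRUE) +
    matrix(rnorm(n * nd), n, nd) %*% diag(sqrt(1 - d$gs^2), nd)
  Ilat <- matrix(0, n, nt); Slat <- matrix(0, n, nt)
  for (t in seq_len(nt)) {
    dd <- d$d_idx[t]
    Ilat[, t] <- bat$mean0[t] + d$sdI[t] *
      (d$ll[t] * Dlev[, dd] + rnorm(n, 0, sqrt(1 - d$ll[t]^2)))
    Slat[, t] <- bat$slope_per_year[t] + d$sdS[t] *
      (d$ls[t] * Dslo[, dd] + rnorm(n, 0, sqrt(1 - d$ls[t]^2)))
  }

  sex <- rbinom(n, 1, spec$sex_frac_female)
  age_base <- rnorm(n, 0, spec$age_baseline_sd)   # deviation from cohort mean

  out <- data.frame(id = sprintf("p%05d", seq_len(n)), sex = sex)
  for (w in seq_len(W)) {
    age_w <- spec$age_baseline_mean + tb[w] + age_base +
      rnorm(n, 0, spec$age_jitter_sd)
    out[[paste0("age_days_w", w)]] <- round(age_w * 365.25)
  }
  for (t in seq_len(nt)) {
    for (w in seq_len(W)) {
      y <- Ilat[, t] + Slat[, t] * tb[w] +
        bat$slope_per_year[t] * age_base +
        d$sex_delta[t] * sex +
        rnorm(n, 0, sqrt(d$theta[t]))
      out[[score_col(bat$test[t], w)]] <- y
    }
  }
  out$age11 <- 100 + 15 * age11
  out$apoe <- apoe
  for (k in 1:4) out[[paste0("mds", k)]] <- rnorm(n)

  # validation phenotypes
  vs <- spec$validation
  for (v in seq_len(nrow(vs))) {
    p <- vs$predictor[v]; ph <- vs$phenotype[v]
    if (!p %in% colnames(X)) next
    x <- X[, p]
    if (ph == "educ_years") { out[[ph]] <- educ_years; next }
    if (vs$type[v] == "continuous") {
      cf <- vs$coef[v]
      out[[ph]] <- cf * x + sqrt(max(1 - cf^2, 0)) * rnorm(n)
    } else if (vs$type[v] == "binary") {
      eta <- qlogis(vs$prevalence[v]) + vs$coef[v] * x
      out[[ph]] <- rbinom(n, 1, plogis(eta))
    } else {   # ordinal: latent cut into never / ex / current
      lat <- vs$coef[v] * x + sqrt(max(1 - vs$coef[v]^2, 0)) * rnorm(n)
      cuts <- quantile(lat, c(0.45, 0.85))
      out[[ph]] <- as.integer(cut(lat, c(-Inf, cuts, Inf))) - 1L
    }
  }

  truth <- data.frame(id = out$id, g = G, gs = GS, age11_std = age11,
                      e_m = e_m)
  for (j in seq_len(ncol(X)))
    truth[[paste0("x_", colnames(X)[j])]] <- X[, j]
  colnames(Ilat) <- paste0("I_", bat$test)
  colnames(Slat) <- paste0("S_", bat$test)
  truth <- cbind(truth, Ilat, Slat)

  attr(out, "battery") <- bat
  attr(out, "spec") <- spec
  attr(out, "truth") <- truth
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Apply monotone score-dependent (MAR) dropout
#'
#' At each wave after the first, the retained subset of the target size is
#' drawn from the previous wave's attendees with inclusion weights
#' `exp(mar_strength * composite)`, where the composite is the mean of the
#' person's standardized observed test scores at the previous wave. Scores
#' and ages at unattended waves are set to missing; attendance is monotone
#' and the retained counts match the targets exactly. Selection depends only
#' on observed values, so the missing-at-random assumption behind FIML holds
#' by construction.
#'
#' @param cohort a `cohort_table` from [simulate_cohort()].
#' @param retention per-wave retained counts (default from the cohort's
#'   spec).
#' @param mar_strength log-odds scale selection strength (default from
#'   spec).
#' @param seed optional RNG seed.
#' @return the cohort with post-dropout missingness.
#' @export
apply_dropout <- function(cohort, retention = NULL, mar_strength = NULL,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- attr(cohort, "spec")
  bat <- attr(cohort, "battery")
  if (is.null(retention)) retention <- spec$retention
  if (is.null(mar_strength)) mar_strength <- spec$mar_strength
  W <- length(retention)
  n <- nrow(cohort)
  if (any(diff(retention) > 0)) stop("retention targets must be non-increasing")
  if (retention[1] > n) stop("first retention target exceeds cohort size")

  retained <- sample.int(n, retention[1])
  attend <- matrix(FALSE, n, W)
  attend[retained, 1] <- TRUE
  for (w in 2:W) {
    prev <- which(attend[, w - 1])
    comp <- composite_score(cohort, bat$test, w - 1, rows = prev)
    wgt <- exp(mar_strength * comp)
    keep <- prev[sample.int(length(prev), retention[w], prob = wgt)]
    attend[keep, w] <- TRUE
  }
  out <- cohort
  for (w in seq_len(W)) {
    off <- which(!attend[, w])
    for (tst in bat$test) out[[score_col(tst, w)]][off] <- NA
    out[[paste0("age_days_w", w)]][off] <- NA
  }
  attr(out, "attendance") <- attend
  out
}

# mean of standardized observed scores at one wave (standardized over the
# given rows)
composite_score <- function(cohort, tests, wave, rows = seq_len(nrow(cohort))) {
  Z <- vapply(tests, function(tst) {
    x <- cohort[[score_col(tst, wave)]][rows]
    (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)
  }, numeric(length(rows)))
  rowMeans(Z, na.rm = TRUE)
}
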