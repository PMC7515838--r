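# Preliminary score validation: does each polygenic score predict its own
# phenotype (partial R-squared for continuous outcomes, a Nagelkerke
# R-squared difference for binary ones), what do the scores' mutual
# correlations look like, and does Horn's parallel analysis support a
# general factor of the score battery?

#' Validate a polygenic score against its own phenotype
#'
#' Continuous (and 0/1/2-coded ordinal) outcomes: linear model of the
#' phenotype on the standardized score plus covariates; variance explained
#' is the partial R-squared beyond the covariate-only model. Binary
#' outcomes: logistic model; variance explained is the Nagelkerke
#' R-squared of the score beyond the covariates,
#' `(1 - exp(2 (ll0 - ll1) / n)) / (1 - exp(2 ll0 / n))`
#' with `ll0` the covariate-only and `ll1` the full log-likelihood.
#'
#' @param score per-person score (numeric) or a `pgs_vector`.
#' @param phenotype outcome vector, aligned to the score.
#' @param type "continuous", "binary" or "ordinal" (ordinal is analysed as
#'   its 0/1/2 coding in a linear model).
#' @param covariates optional data.frame of covariates (e.g. age, sex,
#'   ancestry components).
#' @param score_name,outcome_name labels for the result row.
#' @return one-row data.frame: score, outcome, type, beta (standardized for
#'   linear, per-SD log-odds for logistic), se, p, variance_explained.
#' @export
validate_own_phenotype <- function(score, phenotype,
                                   type = c("continuous", "binary", "ordinal"),
                                   covariates = NULL, score_name = "score",
                                   outcome_name = "phenotype") {
  type <- match.arg(type)
  if (inherits(score, "pgs_vector")) score <- score$score
  df <- data.frame(y = phenotype, s = as.numeric(scale(score)))
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[complete.cases(df), , drop = FALSE]
  cv <- setdiff(names(df), c("y", "s"))
  rhs0 <- if (length(cv)) paste(cv, collapse = "+") else "1"
  if (type == "binary") {
    if (length(unique(df$y)) > 2) stop("binary phenotype with > 2 levels")
    f1 <- glm(stats::as.formula(paste("y ~ s +", rhs0)), binomial(), df)
    f0 <- glm(stats::as.formula(paste("y ~", rhs0)), binomial(), df)
    sm <- summary(f1)$coefficients
    n <- nrow(df)
    ll1 <- as.numeric(logLik(f1)); ll0 <- as.numeric(logLik(f0))
    r2 <- (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
    beta <- sm["s", 1]; se <- sm["s", 2]; p <- sm["s", 4]
  } else {
    df$y <- as.numeric(scale(as.numeric(df$y)))
    f1 <- lm(stats::as.formula(paste("y ~ s +", rhs0)), df)
    f0 <- lm(stats::as.formula(paste("y ~", rhs0)), df)
    rss1 <- sum(resid(f1)^2); rss0 <- sum(resid(f0)^2)
    r2 <- (rss0 - rss1) / rss0              # partial R^2 beyond covariates
    sm <- summary(f1)$coefficients
    beta <- sm["s", 1]; se <- sm["s", 2]; p <- sm["s", 4]
  }
  data.frame(score = score_name, outcome = outcome_name, type = type,
             beta = beta, se = se, p = p,
             variance_explained = max(0, min(1, r2)),
             n = nrow(df), stringsAsFactors = FALSE)
}

#' Correlation matrix of polygenic scores
#'
#' Pairwise-complete Pearson correlations with p-values from the t
#' transform, `p = 2 P(T_{n-2} > |r| sqrt((n-2)/(1-r^2)))`, using each
#' pair's complete-case n.
#'
#' @param score_table data.frame/matrix of scores (columns = scores).
#' @return list: `r` (correlations), `p` (p-values), `n` (pairwise n).
#'   Constant columns yield NA entries.
#' @export
pgs_correlation_matrix <- function(score_table) {
  X <- as.matrix(score_table)
  k <- ncol(X)
  if (k < 2) stop("need at least two scores")
  r <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))
  nmat <- crossprod(!is.na(X))
  p <- matrix(NA_real_, k, k, dimnames = dimnames(r))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { p[i, j] <- 0; next }
    n <- nmat[i, j]; rv <- r[i, j]
    if (is.na(rv) || n < 3) next
    tt <- abs(rv) * sqrt((n - 2) / (1 - rv^2))
    p[i, j] <- 2 * pt(tt, n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n = nmat)
}

#' Horn's parallel analysis for factor retention
#'
#' Compares the observed correlation-matrix eigenvalues, rank by rank,
#' against eigenvalues of simulated uncorrelated normal data of identical
#' dimensions; the retained count is the number of ranks at which the
#' observed eigenvalue exceeds the reference (mean or chosen quantile of
#' the simulated eigenvalues).
#'
#' @param score_table data.frame/matrix of scores.
#' @param n_simulations number of null simulations (>= 1).
#' @param criterion "mean" or "quantile".
#' @param q quantile used when `criterion = "quantile"`.
#' @param seed optional RNG seed.
#' @return list of class `parallel_analysis`: `eigenvalues`, `reference`,
#'   `n_factors`, `n_simulations`, `criterion`.
#' @export
parallel_analysis <- function(score_table, n_simulations = 100,
                              criterion = c("mean", "quantile"), q = 0.95,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  criterion <- match.arg(criterion)
  if (n_simulations < 1) stop("n_simulations must be >= 1")
  X <- as.matrix(score_table)
  X <- X[complete.cases(X), , drop = FALSE]
  n <- nrow(X); k <- ncol(X)
  ev <- eigen(cor(X), symmetric = TRUE, only.values = TRUE)$values
  sims <- matrix(0, n_simulations, k)
  for (s in seq_len(n_simulations)) {
    Z <- matrix(rnorm(n * k), n, k)
    sims[s, ] <- eigen(cor(Z), symmetric = TRUE, only.values = TRUE)$values
  }
  ref <- if (criterion == "mean") colMeans(sims) else
    apply(sims, 2, quantile, probs = q)
  structure(list(eigenvalues = ev, reference = ref,
                 n_factors = sum(ev > ref), n_simulations = n_simulations,
                 criterion = criterion), class = "parallel_analysis")
}

#' @export
print.parallel_analysis <- function(x, ...) {
  cat("Parallel analysis (", x$criterion, " of ", x$n_simulations,
      " simulations): ", x$n_factors, " factor(s) retained\n", sep = "")
  invisible(x)
}
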