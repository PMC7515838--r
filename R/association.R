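# Association of genetic predictors with the latent general cognitive level,
# slope, and lifetime change; FDR correction; mediation via years of
# education; Williams's test for comparing dependent correlations.
#
# Two estimation routes are supported, mirroring common practice when
# complex growth SEMs fail to converge with predictors attached:
#   "sem"          -- predictors regressed onto the general factors inside
#                     the factors-of-curves model (FIML for the indicators,
#                     complete cases for the exogenous block);
#   "factor_score" -- regression-method factor scores extracted from a base
#                     model, then ordinary least squares.
# The route actually used is recorded in every result row; the SEM route
# falls back to factor scores automatically if no start converges.

is_binary_col <- function(x) length(unique(na.omit(x))) <= 2

std_cols <- function(data, cols) {
  for (cl in cols) {
    x <- data[[cl]]
    if (!is_binary_col(x)) data[[cl]] <- as.numeric(scale(x))
  }
  data
}

# standardized beta (w.r.t. outcome always; w.r.t. predictor only if
# continuous) from a fitted in-SEM predictor model
sem_assoc_row <- function(fit, predictor, outcome, binary, covariates) {
  pref <- if (outcome == "level") "b_level_" else "b_slope_"
  foc <- attr(fit$model, "foc")
  preds <- if (outcome == "level") foc$level_predictors else
    foc$slope_predictors
  b <- fit$par[paste0(pref, preds)]
  Sx <- matrix(0, length(preds), length(preds),
               dimnames = list(preds, preds))
  for (i in seq_along(preds)) {
    Sx[i, i] <- fit$par[paste0("vx_", preds[i])]
    if (i > 1) for (j in seq_len(i - 1)) {
      cp <- paste0("cx_", preds[j], "_", preds[i])
      if (cp %in% names(fit$par)) Sx[i, j] <- Sx[j, i] <- fit$par[cp]
    }
  }
  sd_out <- sqrt(1 + drop(t(b) %*% Sx %*% b))
  bx <- fit$par[paste0(pref, predictor)]
  se <- fit$se[paste0(pref, predictor)]
  sdx <- if (binary) 1 else sqrt(fit$par[paste0("vx_", predictor)])
  data.frame(predictor = predictor, outcome = outcome,
             beta = unname(bx * sdx / sd_out),
             se = unname(se * sdx / sd_out),
             p = unname(2 * pnorm(-abs(bx / se))),
             q = NA_real_, method = "sem",
             covariates = paste(covariates, collapse = "+"),
             n = fit$n, stringsAsFactors = FALSE)
}

fs_assoc_row <- function(scores, data, predictor, outcome, covariates) {
  y <- as.numeric(scale(scores[, if (outcome == "level") "g" else "gs"]))
  df <- data.frame(y = y, data[, c(predictor, covariates), drop = FALSE])
  df <- df[complete.cases(df), , drop = FALSE]
  df <- std_cols(df, predictor)
  fml <- stats::as.formula(paste("y ~", paste(c(predictor, covariates),
                                              collapse = "+")))
  f <- lm(fml, data = df)
  sm <- summary(f)$coefficients
  data.frame(predictor = predictor, outcome = outcome,
             beta = sm[predictor, 1], se = sm[predictor, 2],
             p = sm[predictor, 4], q = NA_real_,
             method = "factor_score_regression",
             covariates = paste(covariates, collapse = "+"),
             n = nrow(df), stringsAsFactors = FALSE)
}

get_base_scores <- function(spec, data, base_fit, ...) {
  if (is.null(base_fit)) base_fit <- fit_foc(spec, data, ...)
  if (!isTRUE(base_fit$converged)) stop("base model did not converge")
  list(fit = base_fit, scores = factor_scores(base_fit, data))
}

#' Association of one genetic predictor with general level and slope
#'
#' The predictor plus ancestry covariates are regressed onto the general
#' level and general slope factors. Continuous predictors are standardized
#' before entry; binary predictors enter 0/1. Reported betas are
#' standardized with respect to the outcome always, and to the predictor
#' only when continuous.
#'
#' @param spec a `foc_spec`.
#' @param data residualized cohort data (score columns plus predictor and
#'   covariate columns).
#' @param predictor predictor column name.
#' @param covariates covariate column names entered alongside (default: four
#'   ancestry components).
#' @param method "sem" (in-model regression; falls back to factor scores on
#'   non-convergence) or "factor_score".
#' @param base_fit optional prefitted base model (no predictors), reused for
#'   the factor-score route.
#' @param extra additional simultaneous predictor column names (used by the
#'   APOE-adjusted analysis).
#' @param ... passed to [fit_sem()] for the SEM route.
#' @return data.frame with one row per outcome (and per extra predictor):
#'   predictor, outcome, beta, se, p, q (NA until FDR), method, covariates, n.
#' @export
single_predictor_association <- function(spec, data, predictor,
                                         covariates = paste0("mds", 1:4),
                                         method = c("sem", "factor_score"),
                                         base_fit = NULL, extra = character(),
                                         ...) {
  method <- match.arg(method)
  for (cl in c(predictor, extra))
    if (length(unique(na.omit(data[[cl]]))) < 2)
      stop("predictor is constant: ", cl)
  preds <- c(predictor, extra)
  binary <- vapply(preds, function(cl) is_binary_col(data[[cl]]), logical(1))
  exo <- c(preds, covariates)
  dat <- std_cols(data, exo[!exo %in% preds[binary]])
  dat2 <- dat[complete.cases(dat[, exo, drop = FALSE]), , drop = FALSE]

  if (method == "sem") {
    fit <- fit_foc(spec, dat2, level_predictors = exo,
                   slope_predictors = exo, ...)
    if (isTRUE(fit$converged)) {
      rows <- do.call(rbind, lapply(seq_along(preds), function(i)
        rbind(sem_assoc_row(fit, preds[i], "level", binary[i], covariates),
              sem_assoc_row(fit, preds[i], "slope", binary[i], covariates))))
      return(rows)
    }
    method <- "factor_score"   # honest fallback, recorded in the rows
  }
  bs <- get_base_scores(spec, dat, base_fit)
  do.call(rbind, lapply(preds, function(p)
    rbind(fs_assoc_row(bs$scores, dat, p, "level", c(setdiff(preds, p), covariates)),
          fs_assoc_row(bs$scores, dat, p, "slope", c(setdiff(preds, p), covariates)))))
}

#' APOE-adjusted association
#'
#' As [single_predictor_association()] with the binary risk indicator added
#' as a simultaneous predictor; coefficients for both are reported.
#'
#' @inheritParams single_predictor_association
#' @param apoe name of the binary indicator column.
#' @export
apoe_adjusted_association <- function(spec, data, predictor, apoe = "apoe",
                                      covariates = paste0("mds", 1:4),
                                      method = c("sem", "factor_score"),
                                      base_fit = NULL, ...) {
  single_predictor_association(spec, data, predictor, covariates,
                               method = method, base_fit = base_fit,
                               extra = apoe, ...)
}

#' Simultaneous multi-predictor association
#'
#' All predictors entered jointly (plus covariates) onto the general level
#' and slope; per-predictor conditional standardized betas are reported.
#'
#' @inheritParams single_predictor_association
#' @param predictors >= 2 predictor column names; an error names the
#'   collinear set if the predictor matrix is rank deficient.
#' @export
simultaneous_association <- function(spec, data, predictors,
                                     covariates = paste0("mds", 1:4),
                                     method = c("sem", "factor_score"),
                                     base_fit = NULL, ...) {
  method <- match.arg(method)
  if (length(predictors) < 2) stop("need >= 2 predictors")
  X <- as.matrix(data[complete.cases(data[, predictors, drop = FALSE]),
                      predictors, drop = FALSE])
  qr_x <- qr(cbind(1, X))
  if (qr_x$rank < ncol(X) + 1) {
    bad <- colnames(X)[qr_x$pivot[seq(qr_x$rank + 1, ncol(X) + 1)] - 1]
    stop("collinear predictors: ", paste(bad, collapse = ", "))
  }
  binary <- vapply(predictors, function(cl) is_binary_col(data[[cl]]),
                   logical(1))
  exo <- c(predictors, covariates)
  dat <- std_cols(data, exo[!exo %in% predictors[binary]])
  dat2 <- dat[complete.cases(dat[, exo, drop = FALSE]), , drop = FALSE]
  if (method == "sem") {
    fit <- fit_foc(spec, dat2, level_predictors = exo,
                   slope_predictors = exo, ...)
    if (isTRUE(fit$converged))
      return(do.call(rbind, lapply(seq_along(predictors), function(i)
        rbind(sem_assoc_row(fit, predictors[i], "level", binary[i], covariates),
              sem_assoc_row(fit, predictors[i], "slope", binary[i], covariates)))))
  }
  bs <- get_base_scores(spec, dat, base_fit)
  do.call(rbind, lapply(predictors, function(p)
    rbind(fs_assoc_row(bs$scores, dat, p, "level",
                       c(setdiff(predictors, p), covariates)),
          fs_assoc_row(bs$scores, dat, p, "slope",
                       c(setdiff(predictors, p), covariates)))))
}

#' Lifetime cognitive change association
#'
#' The general level factor is regressed simultaneously on the age-11 score
#' and the predictor (plus covariates); the predictor's conditional beta is
#' the lifetime-change association. The predictor's marginal association
#' with the age-11 score itself is reported as a second row
#' (`outcome = "age11"`).
#'
#' @inheritParams single_predictor_association
#' @param age11 age-11 score column name.
#' @export
lifetime_change_association <- function(spec, data, predictor,
                                        age11 = "age11",
                                        covariates = paste0("mds", 1:4),
                                        method = c("sem", "factor_score"),
                                        base_fit = NULL, ...) {
  method <- match.arg(method)
  if (!age11 %in% names(data)) stop("age-11 column missing: ", age11)
  binary <- is_binary_col(data[[predictor]])
  exo <- c(predictor, age11, covariates)
  dat <- std_cols(data, c(if (!binary) predictor, age11, covariates))
  dat2 <- dat[complete.cases(dat[, exo, drop = FALSE]), , drop = FALSE]

  # marginal association with the age-11 score (OLS; age-11 is observed)
  fml <- stats::as.formula(paste(age11, "~", paste(c(predictor, covariates),
                                                   collapse = "+")))
  fa <- lm(fml, data = dat2)
  sm <- summary(fa)$coefficients
  row_a11 <- data.frame(predictor = predictor, outcome = "age11",
                        beta = sm[predictor, 1], se = sm[predictor, 2],
                        p = sm[predictor, 4], q = NA_real_, method = "ols",
                        covariates = paste(covariates, collapse = "+"),
                        n = nrow(dat2), stringsAsFactors = FALSE)

  if (method == "sem") {
    fit <- fit_foc(spec, dat2, level_predictors = exo,
                   slope_predictors = covariates, ...)
    if (isTRUE(fit$converged)) {
      row_l <- sem_assoc_row(fit, predictor, "level", binary, c(age11, covariates))
      row_l$outcome <- "lifetime_change"
      return(rbind(row_l, row_a11))
    }
    method <- "factor_score"
  }
  bs <- get_base_scores(spec, dat, base_fit)
  row_l <- fs_assoc_row(bs$scores, dat, predictor, "level",
                        c(age11, covariates))
  row_l$outcome <- "lifetime_change"
  rbind(row_l, row_a11)
}

#' Mediation of a score-outcome association via years of education
#'
#' Path model on the age-11-adjusted general level: `a` (score -> years of
#' education), `b` (education -> level, conditional on score and age-11) and
#' the direct path `c'`. The indirect effect is `a * b` with a delta-method
#' (Sobel) standard error; `proportion_mediated = indirect / total` with
#' `total = a * b + c'`. Estimated on standardized regression-method factor
#' scores of the general level.
#'
#' @param spec a `foc_spec`.
#' @param data residualized cohort data.
#' @param pgs score column name (mediator's genetic predictor).
#' @param mediator mediator column name (years of education).
#' @param age11 age-11 score column.
#' @param covariates covariate columns.
#' @param base_fit optional prefitted base model.
#' @param ... passed to [fit_sem()] when the base model must be fitted.
#' @return list of class `mediation_result`: a, b, c_direct, indirect,
#'   total, proportion_mediated, SEs, and an `unstable` flag raised when
#'   `|total| < 10 * SE(total)`.
#' @export
mediation_education <- function(spec, data, pgs = "education",
                                mediator = "educ_years", age11 = "age11",
                                covariates = paste0("mds", 1:4),
                                base_fit = NULL, ...) {
  bs <- get_base_scores(spec, data, base_fit, ...)
  df <- data.frame(g = as.numeric(scale(bs$scores[, "g"])),
                   data[, c(pgs, mediator, age11, covariates), drop = FALSE])
  df <- df[complete.cases(df), , drop = FALSE]
  df <- std_cols(df, c(pgs, mediator, age11, covariates))

  fa <- lm(stats::as.formula(paste(mediator, "~", paste(c(pgs, covariates),
                                                        collapse = "+"))), df)
  fb <- lm(stats::as.formula(paste("g ~", paste(c(mediator, pgs, age11,
                                                  covariates),
                                                collapse = "+"))), df)
  sa <- summary(fa)$coefficients; sb <- summary(fb)$coefficients
  a <- sa[pgs, 1]; se_a <- sa[pgs, 2]
  b <- sb[mediator, 1]; se_b <- sb[mediator, 2]
  cdir <- sb[pgs, 1]; se_c <- sb[pgs, 2]
  ind <- a * b
  se_ind <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  total <- ind + cdir
  se_total <- sqrt(se_ind^2 + se_c^2)
  structure(list(a = a, se_a = se_a, b = b, se_b = se_b,
                 c_direct = cdir, se_c_direct = se_c,
                 indirect = ind, se_indirect = se_ind,
                 total = total, se_total = se_total,
                 proportion_mediated = if (total != 0) ind / total else NA_real_,
                 unstable = abs(total) < 10 * se_total,
                 n = nrow(df)), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("a = %.3f (%.3f), b = %.3f (%.3f), c' = %.3f (%.3f)\n",
              x$a, x$se_a, x$b, x$se_b, x$c_direct, x$se_c_direct))
  cat(sprintf("indirect = %.4f (%.4f), total = %.4f, proportion mediated = %.3f%s\n",
              x$indirect, x$se_indirect, x$total, x$proportion_mediated,
              if (x$unstable) "  [unstable: total ~ 0]" else ""))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, capped at 1 and monotone in the p-value ranks.
#' Applied per outcome column across the predictor family in the association
#' tables.
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
fdr_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Williams's test for two dependent correlations sharing one variable
#'
#' Steiger-modified Williams t comparing r12 and r13 given r23, on n - 3
#' degrees of freedom, with `|R| = 1 - r12^2 - r13^2 - r23^2 +
#' 2 r12 r13 r23` and `rbar = (r12 + r13) / 2`:
#' `t = (r12 - r13) * sqrt((n - 1)(1 + r23) /
#'       (2 |R| (n - 1)/(n - 3) + rbar^2 (1 - r23)^3))`.
#'
#' @param r12,r13 the two correlations being compared (shared variable 1).
#' @param r23 correlation of variables 2 and 3.
#' @param n sample size (> 3).
#' @return list: `t`, `df`, `p` (two-sided).
#' @export
williams_test <- function(r12, r13, r23, n) {
  if (n <= 3) stop("n must exceed 3")
  if (any(abs(c(r12, r13, r23)) >= 1)) stop("correlations must lie in (-1, 1)")
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR <= 0) stop("correlation triple is not positive definite")
  rbar <- (r12 + r13) / 2
  tval <- (r12 - r13) *
    sqrt((n - 1) * (1 + r23) /
           (2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r23)^3))
  list(t = tval, df = n - 3, p = 2 * pt(-abs(tval), n - 3))
}
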