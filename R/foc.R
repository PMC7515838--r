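# The factors-of-curves hierarchical latent growth model: a linear latent
# growth curve (intercept + slope) per cognitive test, with the per-test
# intercepts loading on four domain-level factors and those on a general
# level factor, and likewise for the slopes. Estimated by FIML through the
# generic RAM machinery.

#' Default cognitive test battery
#'
#' Thirteen tests in four domains (visuospatial, verbal memory, crystallized,
#' processing speed: 3/3/3/4 tests), with baseline means/SDs and mean annual
#' raw change used as simulation defaults. Choice reaction time is carried on
#' the reversed scale (higher = faster = better), in seconds.
#'
#' @return data.frame with columns `test`, `domain`, `mean0`, `sd0`,
#'   `slope_per_year`.
#' @export
default_battery <- function() {
  data.frame(
    test = c("matrix_reasoning", "block_design", "spatial_span",
             "logical_memory", "verbal_paired_associates", "digit_span_backwards",
             "nart", "wtar", "verbal_fluency",
             "digit_symbol", "symbol_search", "inspection_time",
             "choice_reaction_time"),
    domain = rep(c("visuospatial", "verbal_memory", "crystallized", "speed"),
                 times = c(3, 3, 3, 4)),
    mean0 = c(13.49, 33.79, 7.36, 71.46, 26.44, 7.73,
              34.48, 41.02, 42.42, 56.60, 24.71, 112.14, 0.642),
    sd0 = c(5.13, 10.32, 1.42, 17.96, 9.13, 2.26,
            8.15, 7.17, 12.54, 12.93, 6.39, 11.00, 0.09),
    slope_per_year = c(-0.133, -0.423, -0.038, -0.150, -0.156, -0.038,
                       0.012, -0.034, -0.032, -0.833, -0.258, -0.595, -0.008),
    stringsAsFactors = FALSE)
}

#' Declare a factors-of-curves model structure
#'
#' @param battery data.frame with at least `test` and `domain` columns; each
#'   test belongs to exactly one domain and every domain needs >= 2 tests for
#'   identification (the default battery has 3/3/3/4).
#' @param time_basis fixed slope-factor loadings: years since wave 1 at each
#'   wave. Must start at 0 and be strictly increasing.
#' @param n_waves number of waves (defaults to `length(time_basis)`).
#' @return object of class `foc_spec`.
#' @export
foc_model_spec <- function(battery = default_battery(),
                           time_basis = c(0, 2.98, 6.71, 9.78),
                           n_waves = length(time_basis)) {
  stopifnot(is.data.frame(battery), all(c("test", "domain") %in% names(battery)))
  if (anyDuplicated(battery$test)) stop("duplicate test names")
  if (time_basis[1] != 0 || any(diff(time_basis) <= 0))
    stop("time_basis must start at 0 and be strictly increasing")
  if (length(time_basis) != n_waves) stop("time_basis length != n_waves")
  tab <- table(battery$domain)
  if (any(tab < 2))
    stop("domain(s) with < 2 tests are not identified: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  structure(list(battery = battery, time_basis = time_basis,
                 n_waves = n_waves,
                 domains = unique(battery$domain)), class = "foc_spec")
}

score_col <- function(test, wave) paste0(test, "_w", wave)

#' Build the factors-of-curves RAM model
#'
#' Observed score loadings are fixed (1 on the test's intercept factor, the
#' time basis on its slope factor). Each test's intercept factor loads on its
#' domain level factor, each slope factor on the domain slope factor, and the
#' domain factors load on general level / general slope factors.
#' Identification: general factor variances fixed to 1; each domain factor is
#' scaled by fixing its first test's loading to 1 (marker variable) with the
#' domain residual variance free. Per test the intercept/slope residual
#' covariance is free, occasion residual variance is constant over waves.
#' Exogenous predictors (observed, saturated among themselves) may be
#' regressed onto the general factors.
#'
#' @param spec a `foc_spec`.
#' @param data optional data.frame with the `<test>_w<wave>` score columns
#'   (and any predictor columns); used only to compute starting values.
#' @param level_predictors,slope_predictors names of exogenous observed
#'   columns regressed onto the general level / slope factor. The union forms
#'   a saturated exogenous block.
#' @return a `ram_model` with attribute `foc` describing the structure.
#' @export
build_foc_model <- function(spec, data = NULL,
                            level_predictors = character(),
                            slope_predictors = character()) {
  stopifnot(inherits(spec, "foc_spec"))
  bat <- spec$battery; tb <- spec$time_basis; W <- spec$n_waves
  tests <- bat$test; domains <- spec$domains
  exo <- union(level_predictors, slope_predictors)

  obs <- c(as.vector(t(outer(tests, seq_len(W), score_col))), exo)
  lat <- c(paste0("I_", tests), paste0("S_", tests),
           paste0("L_", domains), paste0("Sl_", domains), "g", "gs")
  m <- ram_model(c(obs, lat), obs)

  # data-driven starting magnitudes (fall back to battery defaults)
  stats_for <- function(test) {
    if (!is.null(data) && score_col(test, 1) %in% colnames(data)) {
      wm <- vapply(seq_len(W), function(w) {
        x <- data[[score_col(test, w)]]; mean(x, na.rm = TRUE)
      }, numeric(1))
      fitc <- stats::coef(lm(wm ~ tb))
      s0 <- sd(data[[score_col(test, 1)]], na.rm = TRUE)
      list(mu = fitc[1], sl = fitc[2], sd = max(s0, 1e-3))
    } else {
      i <- match(test, bat$test)
      list(mu = if ("mean0" %in% names(bat)) bat$mean0[i] else 0,
           sl = if ("slope_per_year" %in% names(bat)) bat$slope_per_year[i] else 0,
           sd = if ("sd0" %in% names(bat)) bat$sd0[i] else 1)
    }
  }
  st <- lapply(setNames(tests, tests), stats_for)
  # analyze each test on its baseline-SD scale: all free parameters end up
  # O(1), which the quasi-Newton fit needs; standardized results are
  # unaffected and the scaling is recorded on the model
  scaling <- numeric(0)
  for (tst in tests) {
    s <- st[[tst]]
    scaling[score_col(tst, seq_len(W))] <- s$sd
    st[[tst]] <- list(mu = s$mu / s$sd, sl = s$sl / s$sd, sd = 1)
  }
  marker <- vapply(domains, function(d) tests[bat$domain == d][1], character(1))

  for (k in seq_along(tests)) {
    tst <- tests[k]; d <- bat$domain[k]; s <- st[[tst]]
    It <- paste0("I_", tst); St <- paste0("S_", tst)
    for (w in seq_len(W)) {
      y <- score_col(tst, w)
      m <- ram_fix(m, "A", y, It, 1)
      m <- ram_fix(m, "A", y, St, tb[w])
    }
    m <- ram_free(m, "S", score_col(tst, 1), score_col(tst, 1),
                  paste0("theta_", tst), 0.3 * s$sd^2, type = "var")
    for (w in 2:W)
      m <- ram_free(m, "S", score_col(tst, w), score_col(tst, w),
                    paste0("theta_", tst), 0.3 * s$sd^2, type = "var")
    m <- ram_free(m, "M", It, param = paste0("muI_", tst), start = s$mu)
    m <- ram_free(m, "M", St, param = paste0("muS_", tst), start = s$sl)
    m <- ram_free(m, "S", It, It, paste0("u_", tst), 0.25 * s$sd^2, type = "var")
    m <- ram_free(m, "S", St, St, paste0("v_", tst), 0.5 * (0.04 * s$sd)^2,
                  type = "var")
    m <- ram_free(m, "S", It, St, paste0("uv_", tst), 0)
    sm <- st[[marker[d]]]
    if (tst == marker[d]) {
      m <- ram_fix(m, "A", It, paste0("L_", d), 1)
      m <- ram_fix(m, "A", St, paste0("Sl_", d), 1)
    } else {
      m <- ram_free(m, "A", It, paste0("L_", d), paste0("lamL_", tst),
                    s$sd / sm$sd)
      m <- ram_free(m, "A", St, paste0("Sl_", d), paste0("lamS_", tst),
                    s$sd / sm$sd)
    }
  }
  for (d in domains) {
    sm <- st[[marker[d]]]
    m <- ram_free(m, "A", paste0("L_", d), "g", paste0("gamL_", d),
                  0.53 * sqrt(0.7) * sm$sd)
    m <- ram_free(m, "A", paste0("Sl_", d), "gs", paste0("gamS_", d),
                  0.8 * 0.04 * sm$sd)
    m <- ram_free(m, "S", paste0("L_", d), paste0("L_", d),
                  paste0("eL_", d), 0.2 * 0.7 * sm$sd^2, type = "var")
    m <- ram_free(m, "S", paste0("Sl_", d), paste0("Sl_", d),
                  paste0("eS_", d), 0.2 * (0.04 * sm$sd)^2, type = "var")
  }
  m <- ram_fix(m, "S", "g", "g", 1)
  m <- ram_fix(m, "S", "gs", "gs", 1)
  m <- ram_free(m, "S", "g", "gs", "cov_g_gs", 0.2)

  # exogenous predictor block: saturated moments + regressions on g / gs
  if (length(exo)) {
    for (i in seq_along(exo)) {
      x <- exo[i]
      xv <- if (!is.null(data) && x %in% colnames(data))
        stats::var(data[[x]], na.rm = TRUE) else 1
      xm <- if (!is.null(data) && x %in% colnames(data))
        mean(data[[x]], na.rm = TRUE) else 0
      m <- ram_free(m, "S", x, x, paste0("vx_", x), max(xv, 1e-6), type = "var")
      m <- ram_free(m, "M", x, param = paste0("mx_", x), start = xm)
      if (i > 1) for (x2 in exo[seq_len(i - 1)])
        m <- ram_free(m, "S", x, x2, paste0("cx_", x2, "_", x), 0)
      if (x %in% level_predictors)
        m <- ram_free(m, "A", "g", x, paste0("b_level_", x), 0)
      if (x %in% slope_predictors)
        m <- ram_free(m, "A", "gs", x, paste0("b_slope_", x), 0)
    }
  }
  attr(m, "scaling") <- scaling
  attr(m, "foc") <- list(spec = spec, marker = marker,
                         level_predictors = level_predictors,
                         slope_predictors = slope_predictors)
  m
}

#' Fit a factors-of-curves model
#'
#' Convenience wrapper: builds the model (with data-driven starts) and fits
#' it by FIML.
#'
#' @inheritParams build_foc_model
#' @param data data.frame with `<test>_w<wave>` columns (NA = missing wave).
#' @param ... passed to [fit_sem()] (`n_starts`, `tol`, `se`, ...).
#' @return a `fitted_sem`.
#' @export
fit_foc <- function(spec, data, level_predictors = character(),
                    slope_predictors = character(), ...) {
  m <- build_foc_model(spec, data, level_predictors, slope_predictors)
  fit_sem(m, data, ...)
}

foc_structure <- function(fitted) {
  f <- attr(fitted$model, "foc")
  if (is.null(f)) stop("not a factors-of-curves fit")
  f
}

#' Standardized variance decomposition of levels and slopes
#'
#' For each test's latent intercept (level) and slope, the proportion of
#' variance attributable to the general factor is the squared product of the
#' standardized test-on-domain loading and domain-on-general loading; the
#' domain-specific and test-specific shares complete the standardized
#' variance. Layer averages across tests are reported.
#'
#' @param fitted a converged factors-of-curves `fitted_sem`.
#' @return list of class `foc_decomposition`: `table` (per test x level/slope
#'   shares) and `means` (per-layer averages).
#' @export
variance_decomposition <- function(fitted) {
  if (!isTRUE(fitted$converged)) stop("model did not converge")
  f <- foc_structure(fitted)
  bat <- f$spec$battery
  par <- fitted$par
  mm <- ram_fill(fitted$model, par)
  vars <- fitted$model$vars
  g <- function(nm) match(nm, vars)

  one <- function(tst, kind) {
    d <- bat$domain[match(tst, bat$test)]
    fac <- if (kind == "level") paste0("I_", tst) else paste0("S_", tst)
    dom <- if (kind == "level") paste0("L_", d) else paste0("Sl_", d)
    gen <- if (kind == "level") "g" else "gs"
    lam <- mm$A[g(fac), g(dom)]
    gam <- mm$A[g(dom), g(gen)]
    res_t <- mm$S[g(fac), g(fac)]
    res_d <- mm$S[g(dom), g(dom)]
    v_d <- gam^2 + res_d              # var(G) fixed at 1
    v_t <- lam^2 * v_d + res_t
    c(share_general = (lam * gam)^2 / v_t,
      share_domain = lam^2 * res_d / v_t,
      share_test = res_t / v_t)
  }
  rows <- do.call(rbind, lapply(bat$test, function(tst)
    data.frame(test = tst, domain = bat$domain[match(tst, bat$test)],
               outcome = c("level", "slope"),
               rbind(one(tst, "level"), one(tst, "slope")))))
  means <- stats::aggregate(cbind(share_general, share_domain, share_test)
                            ~ outcome, rows, mean)
  structure(list(table = rows, means = means), class = "foc_decomposition")
}

#' @export
print.foc_decomposition <- function(x, ...) {
  cat("Mean standardized variance shares:\n")
  print(x$means, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Regression-method factor scores with missing data
#'
#' Per missingness pattern, the conditional expectation of the requested
#' latent variables given the row's observed sub-vector under the fitted
#' joint latent-observed moments. Rows with no observed entries get NA.
#'
#' @param fitted a converged `fitted_sem`.
#' @param data the data (same observed columns as at fit time).
#' @param factors latent variable names to score (default the general level
#'   and slope factors).
#' @return matrix (n x length(factors)), rows aligned to `data`.
#' @export
factor_scores <- function(fitted, data, factors = c("g", "gs")) {
  if (!isTRUE(fitted$converged)) stop("model did not converge")
  model <- fitted$model
  data <- scale_for_model(model, as.data.frame(data))
  X <- as.matrix(data[, model$obs, drop = FALSE])
  pdata <- prepare_fiml_data(X, model$obs)
  mm <- ram_fill(model, fitted$par)
  oi <- ram_idx(model, model$obs)
  li <- ram_idx(model, factors)
  res <- factor_scores_cpp(mm$A, mm$S, mm$M, as.integer(oi - 1L),
                           as.integer(li - 1L),
                           lapply(pdata$patterns, function(p) p[c("cols", "Y")]))
  out <- matrix(NA_real_, nrow(X), length(factors),
                dimnames = list(NULL, factors))
  keep <- which(rowSums(is.finite(X)) > 0L)
  for (k in seq_along(pdata$patterns))
    out[keep[pdata$patterns[[k]]$rows], ] <- res[[k]]
  out
}

#' Univariate latent growth curve for one test
#'
#' Two-latent-variable (intercept, slope) linear growth model on the raw
#' scores of a single test across waves, fitted by FIML. Reports the mean
#' intercept, mean raw slope per year with its SE, and the SD-scaled slope
#' (mean slope divided by the model-implied baseline SD).
#'
#' @param scores n x n_waves matrix (NA = missing); columns in wave order.
#' @param time_basis years since wave 1 per wave.
#' @param ... passed to [fit_sem()].
#' @return list: `mean_intercept`, `mean_slope`, `slope_se`, `sd_scaled_slope`,
#'   `fit` (the `fitted_sem`).
#' @export
fit_univariate_lgc <- function(scores, time_basis = c(0, 2.98, 6.71, 9.78),
                               ...) {
  scores <- as.matrix(scores)
  W <- ncol(scores)
  if (W != length(time_basis)) stop("columns must match time_basis")
  if (sum(colSums(is.finite(scores)) > 0) < 3)
    stop("fewer than 3 waves with data: growth model unidentified")
  ys <- paste0("y_w", seq_len(W))
  colnames(scores) <- ys
  m <- ram_model(c(ys, "I", "S"), ys)
  s0 <- max(sd(scores[, 1], na.rm = TRUE), 1e-8)   # analysis scale
  wm <- colMeans(scores, na.rm = TRUE) / s0
  cf <- stats::coef(lm(wm ~ time_basis))
  for (w in seq_len(W)) {
    m <- ram_fix(m, "A", ys[w], "I", 1)
    m <- ram_fix(m, "A", ys[w], "S", time_basis[w])
    m <- ram_free(m, "S", ys[w], ys[w], "theta", 0.3, type = "var")
  }
  m <- ram_free(m, "M", "I", param = "muI", start = cf[1])
  m <- ram_free(m, "M", "S", param = "muS", start = cf[2])
  m <- ram_free(m, "S", "I", "I", "vI", 0.7, type = "var")
  m <- ram_free(m, "S", "S", "S", "vS", 0.05^2, type = "var")
  m <- ram_free(m, "S", "I", "S", "cIS", 0)
  attr(m, "scaling") <- setNames(rep(s0, W), ys)
  fit <- fit_sem(m, scores, ...)
  if (!isTRUE(fit$converged))
    return(list(mean_intercept = NA_real_, mean_slope = NA_real_,
                slope_se = NA_real_, sd_scaled_slope = NA_real_, fit = fit))
  p <- fit$par
  baseline_sd <- sqrt(p["vI"] + p["theta"])
  # back-transform from the analysis scale to raw units
  list(mean_intercept = unname(p["muI"] * s0),
       mean_slope = unname(p["muS"] * s0),
       slope_se = unname(fit$se["muS"] * s0),
       sd_scaled_slope = unname(p["muS"] / baseline_sd),
       fit = fit)
}

#' Pre-residualize cognitive scores for age and sex
#'
#' Any reversed-scored tests (e.g. reaction time, where a larger raw value
#' means worse performance) are negated first; then, per test and wave, the
#' observed scores are replaced by OLS residuals on age in days at that wave
#' and sex, using available cases. Missing entries stay missing.
#'
#' @param cohort data.frame with `<test>_w<wave>`, `age_days_w<wave>` and
#'   `sex` columns.
#' @param tests character vector of test names.
#' @param n_waves number of waves.
#' @param reverse names of tests to sign-reverse before residualizing.
#' @return the cohort with the score columns replaced by residuals.
#' @export
residualize_scores <- function(cohort, tests, n_waves = 4,
                               reverse = character()) {
  out <- cohort
  for (tst in tests) {
    for (w in seq_len(n_waves)) {
      yc <- score_col(tst, w)
      if (!yc %in% names(out)) stop("missing column ", yc)
      y <- out[[yc]]
      if (tst %in% reverse) y <- -y
      age <- out[[paste0("age_days_w", w)]]
      sex <- out$sex
      ok <- is.finite(y) & is.finite(age) & is.finite(sex)
      if (!any(ok)) stop("test ", tst, " entirely missing at wave ", w)
      fitw <- lm(y[ok] ~ age[ok] + sex[ok])
      r <- rep(NA_real_, length(y))
      r[ok] <- resid(fitw)
      out[[yc]] <- r
    }
  }
  out
}
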