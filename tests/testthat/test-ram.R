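# Core RAM/FIML machinery: implied moments, pattern-grouped likelihood,
# analytic gradients, fitting, saturated EM, fit indices.

# one-factor model over four indicators: 12 free parameters, 14 observed
# moments, df = 2 (identified, with room for misfit)
toy_model <- function() {
  ys <- paste0("y", 1:4)
  m <- ram_model(c(ys, "f"), obs = ys)
  m <- ram_fix(m, "A", "y1", "f", 1)
  for (k in 2:4) m <- ram_free(m, "A", ys[k], "f", paste0("l", k), 0.7)
  m <- ram_free(m, "S", "f", "f", "vf", 1.2, type = "var")
  for (y in ys) {
    m <- ram_free(m, "S", y, y, paste0("e_", y), 0.5, type = "var")
    m <- ram_free(m, "M", y, param = paste0("mu_", y), start = 0.1)
  }
  m
}

toy_data <- function(n = 150, miss = TRUE, seed = 1) {
  set.seed(seed)
  f <- rnorm(n, 0, sqrt(1.2))
  lam <- c(1, 0.8, 0.6, 0.7)
  Y <- sapply(lam, function(l) l * f + rnorm(n, 0, sqrt(.5)))
  colnames(Y) <- paste0("y", 1:4)
  if (miss) {
    Y[sample(n, 30), 2] <- NA
    Y[sample(n, 25), 3] <- NA
  }
  Y
}

test_that("implied moments match hand path-tracing and null structure", {
  # local 3-indicator model with a residual covariance for the path check
  m <- ram_model(c("y1", "y2", "y3", "f"), obs = c("y1", "y2", "y3"))
  m <- ram_fix(m, "A", "y1", "f", 1)
  m <- ram_free(m, "A", "y2", "f", "l2", 0.8)
  m <- ram_free(m, "A", "y3", "f", "l3", 0.6)
  m <- ram_free(m, "S", "f", "f", "vf", 1.2, type = "var")
  for (y in c("y1", "y2", "y3")) {
    m <- ram_free(m, "S", y, y, paste0("e_", y), 0.5, type = "var")
    m <- ram_free(m, "M", y, param = paste0("mu_", y), start = 0.1)
  }
  m <- ram_free(m, "S", "y1", "y2", "c12", 0.05)
  imp <- implied_moments(m, m$start)
  lam <- c(1, 0.8, 0.6)
  Sig <- 1.2 * tcrossprod(lam) + diag(0.5, 3)
  Sig[1, 2] <- Sig[2, 1] <- Sig[1, 2] + 0.05
  expect_lt(max(abs(imp$Sigma - Sig)), 1e-12)
  expect_equal(unname(imp$mu), rep(0.1, 3))

  # all loadings zero -> diagonal of residual variances
  par0 <- m$start
  par0[c("l2", "l3", "c12")] <- 0
  m0 <- ram_fix(m, "A", "y1", "f", 0)
  imp0 <- implied_moments(m0, par0)
  expect_equal(unname(imp0$Sigma), diag(0.5, 3), tolerance = 1e-12)
})

test_that("FIML equals the marginal MVN oracle, complete and missing", {
  m <- toy_model()
  Y <- toy_data(miss = TRUE)
  imp <- implied_moments(m, m$start)
  ll <- fiml_loglik(m$start, m, Y)
  expect_equal(as.numeric(ll), mvn_loglik_oracle(Y, imp$mu, imp$Sigma),
               tolerance = 1e-10)

  Yc <- toy_data(miss = FALSE, seed = 2)
  llc <- fiml_loglik(m$start, m, Yc)
  expect_equal(as.numeric(llc), mvn_loglik_oracle(Yc, imp$mu, imp$Sigma),
               tolerance = 1e-10)

  # univariate closed form: y = mu, sigma^2 = 1 -> -0.5 log(2 pi) per case
  mu1 <- ram_model("y", "y")
  mu1 <- ram_free(mu1, "S", "y", "y", "v", 1, type = "var")
  mu1 <- ram_free(mu1, "M", "y", param = "mu", start = 0.3)
  y <- matrix(0.3, 5, 1, dimnames = list(NULL, "y"))
  expect_equal(as.numeric(fiml_loglik(c(v = 1, mu = 0.3), mu1, y)),
               5 * (-0.5 * log(2 * pi)), tolerance = 1e-12)
})

test_that("analytic gradient matches central differences for every type", {
  m <- toy_model()
  Y <- toy_data(miss = TRUE, seed = 3)
  par <- m$start
  ll <- fiml_loglik(par, m, Y, gradient = TRUE)
  g <- attr(ll, "grad")
  gn <- vapply(seq_along(par), function(i) {
    h <- 1e-6 * max(1, abs(par[i]))
    up <- par; up[i] <- up[i] + h
    dn <- par; dn[i] <- dn[i] - h
    (as.numeric(fiml_loglik(up, m, Y)) -
       as.numeric(fiml_loglik(dn, m, Y))) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g - gn)), 1e-4)
})

test_that("fit is stationary, bounded by the saturated model, and refittable", {
  m <- toy_model()
  Y <- toy_data(n = 200, seed = 4)
  fit <- fit_sem(m, Y, n_starts = 2)
  expect_true(fit$converged)
  expect_lt(fit$grad_norm, 1e-3)
  # refit from the solution: log-likelihood unchanged
  m2 <- m; m2$start <- fit$par
  fit2 <- fit_sem(m2, Y, n_starts = 1, se = FALSE)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-7)
  # nesting bound
  sat <- fiml_saturated(Y)
  expect_gte(sat$loglik + 1e-6, fit$loglik)
  # SEs present and positive
  expect_true(all(is.finite(fit$se)))
  expect_true(all(fit$se > 0))
})

test_that("saturated EM equals the closed-form MLE on complete data", {
  Y <- toy_data(n = 120, miss = FALSE, seed = 5)
  sat <- fiml_saturated(Y)
  expect_equal(unname(sat$mu), unname(colMeans(Y)), tolerance = 1e-8)
  expect_equal(unname(sat$Sigma),
               unname(cov(Y) * (nrow(Y) - 1) / nrow(Y)), tolerance = 1e-7)
})

test_that("fit indices hit their boundary definitions", {
  Y <- toy_data(n = 200, miss = TRUE, seed = 6)
  m <- toy_model()
  fit <- fit_sem(m, Y, n_starts = 1, se = FALSE)
  fi <- fit_indices(fit, Y)
  expect_gte(fi$chisq, 0)
  expect_lte(fi$cfi, 1)
  expect_gte(fi$rmsea, 0)
  expect_equal(fi$df, 4 * (4 + 3) / 2 - fit$n_free)

  # an independence-structured model scores CFI ~ 0
  ys <- paste0("y", 1:4)
  mi <- ram_model(ys, ys)
  for (y in ys) {
    mi <- ram_free(mi, "S", y, y, paste0("v_", y), 1, type = "var")
    mi <- ram_free(mi, "M", y, param = paste0("m_", y), start = 0)
  }
  fiti <- fit_sem(mi, Y, n_starts = 1, se = FALSE)
  fii <- fit_indices(fiti, Y)
  expect_lt(fii$cfi, 0.05)
})
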