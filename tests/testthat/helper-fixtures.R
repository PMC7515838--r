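# Shared fixtures: a compact 6-test battery (3 domains x 2 tests) for fast
# unit tests, plus extraction of standardized hierarchical loadings from a
# fitted factors-of-curves model.

small_battery <- function() {
  data.frame(
    test = c("va1", "va2", "vm1", "vm2", "sp1", "sp2"),
    domain = rep(c("visuo", "memory", "speed"), each = 2),
    mean0 = c(14, 34, 70, 26, 57, 25),
    sd0 = c(5, 10, 18, 9, 13, 6.4),
    slope_per_year = c(-0.13, -0.42, -0.15, -0.16, -0.83, -0.26),
    stringsAsFactors = FALSE)
}

small_spec <- function(n = 400, ...) {
  generative_spec(n = n, battery = small_battery(),
                  retention = round(n * c(1, 0.79, 0.64, 0.50)), ...)
}

# standardized loadings: one row per test (test-on-domain) and one per
# domain (domain-on-general), for "level" or "slope"
std_loadings <- function(fit, kind = c("level", "slope")) {
  kind <- match.arg(kind)
  foc <- attr(fit$model, "foc")
  bat <- foc$spec$battery
  mm <- cogslope:::ram_fill(fit$model, fit$par)
  vars <- fit$model$vars
  pre_f <- if (kind == "level") "I_" else "S_"
  pre_d <- if (kind == "level") "L_" else "Sl_"
  gen <- if (kind == "level") "g" else "gs"
  test_load <- dom_load <- numeric(nrow(bat))
  for (t in seq_len(nrow(bat))) {
    fac <- match(paste0(pre_f, bat$test[t]), vars)
    dom <- match(paste0(pre_d, bat$domain[t]), vars)
    lam <- mm$A[fac, dom]
    gam <- mm$A[dom, match(gen, vars)]
    vd <- gam^2 + mm$S[dom, dom]
    vt <- lam^2 * vd + mm$S[fac, fac]
    test_load[t] <- lam * sqrt(vd) / sqrt(vt)
    dom_load[t] <- gam / sqrt(vd)
  }
  list(test = test_load, domain = dom_load[!duplicated(bat$domain)])
}

# closed-form MVN log-likelihood oracle used against the FIML path
mvn_loglik_oracle <- function(Y, mu, Sigma) {
  s <- 0
  for (i in seq_len(nrow(Y))) {
    o <- which(is.finite(Y[i, ]))
    S <- Sigma[o, o, drop = FALSE]
    r <- Y[i, o] - mu[o]
    s <- s - 0.5 * (length(o) * log(2 * pi) +
                      as.numeric(determinant(S)$modulus) +
                      drop(crossprod(r, solve(S, r))))
  }
  s
}
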