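# Factors-of-curves model construction, residualization, univariate growth
# curves, variance decomposition and factor scores.

test_that("model structure: fixed time basis, free-parameter enumeration, df", {
  tb <- c(0, 2.98, 6.71, 9.78)
  fspec <- foc_model_spec(default_battery(), tb)
  m <- build_foc_model(fspec)
  # slope-factor loadings on observations are exactly the time basis
  for (tst in c("block_design", "nart")) {
    rows <- match(paste0(tst, "_w", 1:4), m$vars)
    expect_equal(unname(m$A[cbind(rows, match(paste0("S_", tst), m$vars))]), tb)
    expect_equal(unname(m$A[cbind(rows, match(paste0("I_", tst), m$vars))]),
                 rep(1, 4))
  }
  # enumeration oracle: walk the structure and count free cells
  nt <- 13; nd <- 4
  expected_free <- nt * 6 +        # muI, muS, theta, u, v, uv per test
    2 * (nt - nd) +                # non-marker test loadings (level + slope)
    2 * (2 * nd) +                 # domain loadings + residuals, both layers
    1                              # general level-slope covariance
  expect_equal(length(unique(m$free$param)), expected_free)
  expect_identical(length(m$obs), 52L)

  # a domain with one test is unidentified
  bad <- default_battery()[c(1:3, 4), ]
  expect_error(foc_model_spec(bad, tb), "identif")
})

test_that("observed-moment count matches the fit-indices df identity", {
  set.seed(10)
  spec <- small_spec(n = 300)
  co <- simulate_cohort(spec, seed = 1)
  fspec <- foc_model_spec(spec$battery, spec$time_basis)
  fit <- fit_foc(fspec, co, n_starts = 1, se = FALSE)
  expect_true(fit$converged)
  fi <- fit_indices(fit, co)
  p <- length(fit$model$obs)   # 24 observed variables
  expect_equal(fi$df, p * (p + 3) / 2 - fit$n_free)
})

test_that("residualization removes age and sex and honors reversal", {
  set.seed(11)
  spec <- small_spec(n = 250)
  co <- simulate_cohort(spec, seed = 2)
  rd <- residualize_scores(co, spec$battery$test)
  for (cl in c("va1_w1", "sp2_w3")) {
    ok <- is.finite(rd[[cl]])
    w <- sub(".*_(w\\d)$", "\\1", cl)
    expect_lt(abs(cor(rd[[cl]][ok], co[[paste0("age_days_", w)]][ok])), 1e-10)
    expect_lt(abs(cor(rd[[cl]][ok], co$sex[ok])), 1e-10)
    expect_lt(abs(mean(rd[[cl]][ok])), 1e-10)
  }
  # a raw reaction-time trajectory that worsens (rises) becomes a declining
  # reversed score
  co2 <- co
  for (w in 1:4) co2[[paste0("va1_w", w)]] <- 100 + 5 * w + rnorm(nrow(co2), 0, .1)
  rr <- residualize_scores(co2, spec$battery$test, reverse = "va1")
  wave_means <- vapply(1:4, function(w) {
    # reversal happens before residualization; reconstruct the reversed scale
    mean(-co2[[paste0("va1_w", w)]])
  }, numeric(1))
  expect_true(all(diff(wave_means) < 0))
})

test_that("univariate growth curve: exact linear data and degenerate cases", {
  tb <- c(0, 2.98, 6.71, 9.78)
  n <- 80
  set.seed(12)
  icept <- rnorm(n, 30, 3)
  Y <- outer(icept, rep(1, 4)) + outer(rep(-0.1, n), tb) * 1
  g <- fit_univariate_lgc(Y, tb, n_starts = 1, se = FALSE)
  expect_equal(g$mean_slope, -0.1, tolerance = 1e-4)
  expect_equal(g$mean_intercept, mean(icept), tolerance = 1e-3)

  Yflat <- outer(icept, rep(1, 4))
  gf <- fit_univariate_lgc(Yflat, tb, n_starts = 1, se = FALSE)
  expect_equal(gf$mean_slope, 0, tolerance = 1e-6)

  Ybad <- Y; Ybad[, 3:4] <- NA
  expect_error(fit_univariate_lgc(Ybad, tb), "unidentified")
})

test_that("variance decomposition implements the squaring rule and closes", {
  # hand-built parameter values: standardized test loading 0.8 on a domain
  # whose general loading is 0.5 -> general share (0.8 * 0.5)^2 = 0.16
  fspec <- foc_model_spec(small_battery(), c(0, 3, 6, 9))
  m <- build_foc_model(fspec)
  par <- m$start
  bat <- small_battery()
  for (d in unique(bat$domain)) {
    par[paste0("gamL_", d)] <- 0.5
    par[paste0("eL_", d)] <- 0.75          # var(domain) = 1
    par[paste0("gamS_", d)] <- 0.5
    par[paste0("eS_", d)] <- 0.75
  }
  for (tst in bat$test[!bat$test %in% attr(m, "foc")$marker]) {
    par[paste0("lamL_", tst)] <- 0.8
    par[paste0("lamS_", tst)] <- 0.8
    par[paste0("u_", tst)] <- 1 - 0.64     # var(test factor) = 1
    par[paste0("v_", tst)] <- 1 - 0.64
  }
  for (mk in attr(m, "foc")$marker) {      # markers have loading fixed at 1
    par[paste0("u_", mk)] <- 0.5625        # 1/0.64 - 1 scaled: vt = 1.5625
    par[paste0("v_", mk)] <- 0.5625
  }
  fake <- structure(list(par = par, model = m, converged = TRUE),
                    class = "fitted_sem")
  dec <- variance_decomposition(fake)
  nonmark <- !dec$table$test %in% attr(m, "foc")$marker
  expect_equal(dec$table$share_general[nonmark],
               rep(0.16, sum(nonmark)), tolerance = 1e-12)
  # markers: std loading = 1/sqrt(1.5625) = 0.8 as well
  expect_equal(dec$table$share_general,
               rep(0.16, nrow(dec$table)), tolerance = 1e-12)
  # closure
  sums <- with(dec$table, share_general + share_domain + share_test)
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-6)
  # zero domain-on-general loading kills the general share
  par0 <- par
  for (d in unique(bat$domain)) { par0[paste0("gamL_", d)] <- 0
                                  par0[paste0("eL_", d)] <- 1 }
  dec0 <- variance_decomposition(structure(
    list(par = par0, model = m, converged = TRUE), class = "fitted_sem"))
  expect_equal(dec0$table$share_general[dec0$table$outcome == "level"],
               rep(0, 6), tolerance = 1e-12)
})

test_that("factor scores: closed-form oracle, linearity, aggregation", {
  set.seed(13)
  spec <- small_spec(n = 400)
  co <- simulate_cohort(spec, seed = 3)
  rd <- residualize_scores(co, spec$battery$test)
  fspec <- foc_model_spec(spec$battery, spec$time_basis)
  fit <- fit_foc(fspec, rd, n_starts = 1, se = FALSE)
  expect_true(fit$converged)
  fs <- factor_scores(fit, rd)

  # complete-data closed form: mu_eta + Cov(eta, y) Sigma^-1 (y - mu)
  model <- fit$model
  mm <- cogslope:::ram_fill(model, fit$par)
  B <- solve(diag(length(model$vars)) - mm$A)
  V <- B %*% mm$S %*% t(B)
  muf <- drop(B %*% mm$M)
  oi <- match(model$obs, model$vars)
  li <- match(c("g", "gs"), model$vars)
  sc_dat <- cogslope:::scale_for_model(model, rd)
  Y <- as.matrix(sc_dat[, model$obs])
  i <- which(complete.cases(Y))[1]
  oracle <- muf[li] + V[li, oi] %*% solve(V[oi, oi], Y[i, ] - muf[oi])
  expect_equal(as.numeric(fs[i, ]), as.numeric(oracle), tolerance = 1e-8)

  # linearity: doubling observed deviations doubles score deviations
  Y2 <- sweep(sweep(Y, 2, muf[oi]), 2, 1, `*`) * 2
  Y2 <- sweep(Y2, 2, muf[oi], `+`)
  rd2 <- rd
  rd2[, model$obs] <- sweep(Y2, 2, attr(model, "scaling")[model$obs], `*`)
  fs2 <- factor_scores(fit, rd2)
  expect_equal(unname(fs2[i, ] - muf[li]), unname(2 * (fs[i, ] - muf[li])),
               tolerance = 1e-8)

  # the aggregate score tracks the true general factor better than any
  # single test's baseline score does
  tr <- attr(co, "truth")
  r_fs <- cor(fs[, "g"], tr$g, use = "complete.obs")
  r_single <- max(vapply(spec$battery$test, function(tst)
    abs(cor(rd[[paste0(tst, "_w1")]], tr$g, use = "complete.obs")),
    numeric(1)))
  expect_gt(r_fs, r_single)
})
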