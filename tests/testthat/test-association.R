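# FDR adjustment, Williams's test, association standardization properties,
# APOE adjustment behaviour, lifetime-change targeting, mediation algebra.

test_that("BH adjustment: hand-computed examples and properties", {
  expect_equal(fdr_adjust(0.03), 0.03)                      # m = 1
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)),
               rep(0.05, 5))                                # hand step-up
  set.seed(70)
  p <- runif(50)
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q <= 1))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Williams's test: null, frozen oracle value, impossible triple", {
  w0 <- williams_test(0.4, 0.4, 0.2, 80)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)

  # value computed independently from the published formula:
  # |R| = 1 - .25 - .09 - .04 + 2*.5*.3*.2 = 0.68, rbar = 0.4,
  # t = 0.2 * sqrt(99 * 1.2 / (2*0.68*99/97 + 0.16*0.8^3)) = 1.7979817...
  w <- williams_test(0.5, 0.3, 0.2, 100)
  expect_equal(w$t, 1.7979817, tolerance = 1e-6)
  expect_identical(w$df, 97)
  expect_equal(w$p, 2 * pt(-1.7979817, 97), tolerance = 1e-6)

  expect_error(williams_test(0.99, 0.99, -0.99, 100), "positive definite")
  expect_error(williams_test(0.5, 0.3, 0.2, 3), "n must exceed 3")
})

# one small fitted cohort shared across the association tests
assoc_env <- local({
  pe <- data.frame(
    predictor = c("pgs", "alzheimer", "apoe"),
    beta_level = c(0.3, 0, -0.4),
    beta_slope = c(0, 0, -0.3),
    beta_age11 = c(0, 0, 0),
    type = c("continuous", "continuous", "binary"), stringsAsFactors = FALSE)
  spec <- generative_spec(n = 900, battery = small_battery(),
                          retention = round(900 * c(1, .79, .64, .5)),
                          predictor_effects = pe,
                          apoe_alzheimer_r = 0.45,
                          education = list(a = 0, b = 0))
  co <- simulate_cohort(spec, seed = 71)
  co <- apply_dropout(co, seed = 72)
  tr <- attr(co, "truth")
  co$pgs <- tr$x_pgs
  co$alzheimer <- tr$x_alzheimer
  rd <- residualize_scores(co, spec$battery$test)
  fspec <- foc_model_spec(spec$battery, spec$time_basis)
  fit <- fit_foc(fspec, rd, n_starts = 1, se = FALSE)
  list(spec = spec, fspec = fspec, rd = rd, fit = fit, truth = tr)
})

test_that("standardized beta is invariant to predictor rescaling", {
  rd <- assoc_env$rd
  a1 <- single_predictor_association(assoc_env$fspec, rd, "pgs",
                                     method = "factor_score",
                                     base_fit = assoc_env$fit)
  rd$pgs <- rd$pgs * 10
  a2 <- single_predictor_association(assoc_env$fspec, rd, "pgs",
                                     method = "factor_score",
                                     base_fit = assoc_env$fit)
  expect_equal(a1$beta, a2$beta, tolerance = 1e-10)
  expect_identical(a1$method[1], "factor_score_regression")
  # a constant predictor is refused
  rd$flat <- 1
  expect_error(single_predictor_association(assoc_env$fspec, rd, "flat",
                                            base_fit = assoc_env$fit),
               "constant")
})

test_that("level effect is recovered and the null slope stays null", {
  a <- single_predictor_association(assoc_env$fspec, assoc_env$rd, "pgs",
                                    method = "sem", n_starts = 1)
  bl <- a[a$outcome == "level", ]
  bs <- a[a$outcome == "slope", ]
  expect_equal(bl$beta, 0.3, tolerance = 3 * bl$se)
  expect_lt(abs(bs$beta), 3 * bs$se + 0.05)
  expect_identical(bl$method, "sem")
})

test_that("APOE adjustment attenuates a confounded predictor", {
  # alzheimer score has no causal effect; apoe (correlated with it) does
  un <- single_predictor_association(assoc_env$fspec, assoc_env$rd,
                                     "alzheimer", method = "factor_score",
                                     base_fit = assoc_env$fit)
  ad <- apoe_adjusted_association(assoc_env$fspec, assoc_env$rd, "alzheimer",
                                  method = "factor_score",
                                  base_fit = assoc_env$fit)
  b_un <- un$beta[un$outcome == "level" & un$predictor == "alzheimer"]
  b_ad <- ad$beta[ad$outcome == "level" & ad$predictor == "alzheimer"]
  expect_lt(abs(b_ad), abs(b_un))
  # both predictors reported in the adjusted model
  expect_setequal(unique(ad$predictor), c("alzheimer", "apoe"))
})

test_that("simultaneous association: orthogonal equivalence, collinearity", {
  rd <- assoc_env$rd
  set.seed(73)
  rd$null1 <- rnorm(nrow(rd))
  rd$null2 <- rnorm(nrow(rd))
  joint <- simultaneous_association(assoc_env$fspec, rd, c("null1", "null2"),
                                    method = "factor_score",
                                    base_fit = assoc_env$fit)
  single <- rbind(
    single_predictor_association(assoc_env$fspec, rd, "null1",
                                 method = "factor_score",
                                 base_fit = assoc_env$fit),
    single_predictor_association(assoc_env$fspec, rd, "null2",
                                 method = "factor_score",
                                 base_fit = assoc_env$fit))
  for (oc in c("level", "slope")) for (p in c("null1", "null2")) {
    bj <- joint$beta[joint$outcome == oc & joint$predictor == p]
    bs <- single$beta[single$outcome == oc & single$predictor == p]
    expect_lt(abs(bj - bs), 0.02)
  }
  rd$dup <- rd$null1
  expect_error(simultaneous_association(assoc_env$fspec, rd,
                                        c("null1", "dup"),
                                        base_fit = assoc_env$fit),
               "collinear")
})

test_that("lifetime change: independence null and marginal age-11 report", {
  rd <- assoc_env$rd
  set.seed(74)
  rd$nullp <- rnorm(nrow(rd))
  lt <- lifetime_change_association(assoc_env$fspec, rd, "nullp",
                                    method = "factor_score",
                                    base_fit = assoc_env$fit)
  expect_setequal(lt$outcome, c("lifetime_change", "age11"))
  for (i in seq_len(nrow(lt)))
    expect_lt(abs(lt$beta[i]), 3 * lt$se[i] + 0.02)
  expect_error(lifetime_change_association(assoc_env$fspec, rd, "nullp",
                                           age11 = "missing_col"),
               "age-11")
})

test_that("mediation algebra: full, absent, and hand-computed decompositions", {
  # c' = 0: education level effect equals a*b exactly -> proportion 1
  pe1 <- data.frame(predictor = "education", beta_level = 0.3 * 0.2,
                    beta_slope = 0, beta_age11 = 0, type = "continuous",
                    stringsAsFactors = FALSE)
  s1 <- generative_spec(n = 100, battery = small_battery(),
                        predictor_effects = pe1,
                        education = list(a = 0.3, b = 0.2))
  expect_equal(implied_mediation(s1)$proportion_mediated, 1, tolerance = 1e-12)

  # a = 0: indirect = 0 -> proportion 0
  s2 <- generative_spec(n = 100, battery = small_battery(),
                        predictor_effects = pe1,
                        education = list(a = 0, b = 0.2))
  expect_equal(implied_mediation(s2)$indirect, 0)
  expect_equal(implied_mediation(s2)$proportion_mediated, 0)

  # population values a=0.3, b=0.2, c'=0.14 -> 0.06 / 0.20 = 0.30
  pe3 <- data.frame(predictor = "education", beta_level = 0.2,
                    beta_slope = 0, beta_age11 = 0, type = "continuous",
                    stringsAsFactors = FALSE)
  s3 <- generative_spec(n = 100, battery = small_battery(),
                        predictor_effects = pe3,
                        education = list(a = 0.3, b = 0.2))
  im <- implied_mediation(s3)
  expect_equal(im$c_direct, 0.14, tolerance = 1e-12)
  expect_equal(im$proportion_mediated, 0.30, tolerance = 1e-12)
  # exact closure: proportion = a b / (a b + c')
  expect_identical(im$proportion_mediated,
                   im$a * im$b / (im$a * im$b + im$c_direct))
})
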