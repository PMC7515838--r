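# Generic RAM-parameterized SEM machinery: model container, implied moments,
# pattern-grouped FIML log-likelihood (C++ backend), quasi-Newton fitting with
# analytic gradients, observed-information standard errors, and the saturated
# / independence FIML baselines needed for fit indices.

#' Create an empty RAM model
#'
#' A RAM (reticular action model) container holds three structural matrices
#' over the combined set of observed and latent variables: `A` (asymmetric
#' paths, `A[i, j]` is the path j -> i), `S` (symmetric residual
#' variances/covariances) and `M` (means/intercepts of the exogenous residual
#' terms). Free parameters are registered by name against one or more cells,
#' so equality constraints are expressed by mapping one parameter to several
#' cells. Variance parameters are flagged so the optimizer can work on the
#' log scale.
#'
#' @param vars character vector naming every variable (observed and latent).
#' @param obs character vector naming the observed subset of `vars`.
#' @return an object of class `ram_model`.
#' @export
ram_model <- function(vars, obs) {
  stopifnot(all(obs %in% vars), !anyDuplicated(vars))
  t <- length(vars)
  m <- list(
    vars = vars, obs = obs,
    A = matrix(0, t, t, dimnames = list(vars, vars)),
    S = matrix(0, t, t, dimnames = list(vars, vars)),
    M = setNames(numeric(t), vars),
    free = data.frame(param = character(), mat = character(),
                      i = integer(), j = integer(), stringsAsFactors = FALSE),
    ptype = character(),   # named: "var" (log-scale) or "free"
    start = numeric()      # named starting values, natural scale
  )
  class(m) <- "ram_model"
  m
}

#' @export
print.ram_model <- function(x, ...) {
  cat("RAM model:", length(x$obs), "observed,",
      length(x$vars) - length(x$obs), "latent variables;",
      length(unique(x$free$param)), "free parameters\n")
  invisible(x)
}

ram_idx <- function(model, v) {
  i <- match(v, model$vars)
  if (anyNA(i)) stop("unknown variable(s): ", paste(v[is.na(i)], collapse = ", "))
  i
}

#' Set a fixed cell of a RAM matrix
#' @param model a `ram_model`.
#' @param mat one of "A", "S", "M".
#' @param i,j variable names (row = dependent for `A`); `j` ignored for "M".
#' @param value fixed numeric value.
#' @export
ram_fix <- function(model, mat, i, j = NULL, value) {
  ii <- ram_idx(model, i)
  if (mat == "M") {
    model$M[ii] <- value
  } else {
    jj <- ram_idx(model, j)
    model[[mat]][ii, jj] <- value
    if (mat == "S") model$S[jj, ii] <- value
  }
  model
}

#' Register a free parameter mapped to a cell
#'
#' Calling this repeatedly with the same `param` ties the cells to one common
#' parameter (an equality constraint). For `mat = "S"` the symmetric cell is
#' implied automatically.
#'
#' @inheritParams ram_fix
#' @param param parameter name.
#' @param start starting value (natural scale).
#' @param type "free" for unbounded, "var" for a positive variance (optimized
#'   on the log scale).
#' @export
ram_free <- function(model, mat, i, j = NULL, param, start, type = "free") {
  ii <- ram_idx(model, i)
  jj <- if (mat == "M") NA_integer_ else ram_idx(model, j)
  model$free <- rbind(model$free, data.frame(
    param = param, mat = mat, i = ii, j = jj, stringsAsFactors = FALSE))
  if (!param %in% names(model$start)) {
    model$start[param] <- start
    model$ptype[param] <- type
  }
  model
}

ram_par_names <- function(model) names(model$start)

# Fill A, S, M from a natural-scale parameter vector (named or positional).
ram_fill <- function(model, par) {
  pn <- ram_par_names(model)
  if (!is.null(names(par))) par <- par[pn]
  A <- model$A; S <- model$S; M <- model$M
  fr <- model$free
  v <- par[match(fr$param, pn)]
  isA <- fr$mat == "A"; isS <- fr$mat == "S"; isM <- fr$mat == "M"
  if (any(isA)) A[cbind(fr$i[isA], fr$j[isA])] <- v[isA]
  if (any(isS)) {
    S[cbind(fr$i[isS], fr$j[isS])] <- v[isS]
    S[cbind(fr$j[isS], fr$i[isS])] <- v[isS]
  }
  if (any(isM)) M[fr$i[isM]] <- v[isM]
  list(A = A, S = S, M = M)
}

#' Model-implied moments of the observed variables
#'
#' Standard RAM moment algebra: with `B = (I - A)^-1`, the implied covariance
#' of all variables is `B S B'` and the implied mean is `B M`; both are then
#' restricted to the observed rows/columns.
#'
#' @param model a `ram_model`.
#' @param par named (or correctly ordered) natural-scale parameter vector.
#' @return list with `mu` (named mean vector) and `Sigma` (covariance matrix)
#'   over the observed variables.
#' @export
implied_moments <- function(model, par) {
  mm <- ram_fill(model, par)
  t <- length(model$vars)
  B <- solve(diag(t) - mm$A)
  V <- B %*% mm$S %*% t(B)
  mu <- drop(B %*% mm$M)
  oi <- ram_idx(model, model$obs)
  list(mu = setNames(mu[oi], model$obs),
       Sigma = structure(V[oi, oi, drop = FALSE],
                         dimnames = list(model$obs, model$obs)))
}

# Divide observed columns by the model's per-column scaling factors (if
# any). Fitting on a per-SD scale keeps all free parameters within a few
# orders of magnitude, which quasi-Newton optimization needs; estimates are
# then on the scaled metric (standardized quantities are unaffected).
scale_for_model <- function(model, data) {
  sc <- attr(model, "scaling")
  if (is.null(sc)) return(data)
  for (cl in names(sc)) if (cl %in% colnames(data))
    data[[cl]] <- data[[cl]] / sc[[cl]]
  data
}

# Group data rows by missingness pattern over the model's observed columns.
# Rows with no observed entries are dropped (with a count kept).
prepare_fiml_data <- function(data, obs) {
  X <- as.matrix(data[, obs, drop = FALSE])
  storage.mode(X) <- "double"
  ok <- is.finite(X)
  keep <- rowSums(ok) > 0L
  X <- X[keep, , drop = FALSE]; ok <- ok[keep, , drop = FALSE]
  key <- apply(ok, 1L, function(r) paste(which(r), collapse = ","))
  groups <- split(seq_len(nrow(X)), key)
  patterns <- lapply(groups, function(rows) {
    cols <- which(ok[rows[1L], ])
    list(cols = as.integer(cols - 1L),          # 0-based for C++
         Y = X[rows, cols, drop = FALSE],
         rows = rows)
  })
  structure(list(patterns = unname(patterns), n = nrow(X),
                 n_dropped = sum(!keep), p = ncol(X),
                 order = unlist(lapply(unname(patterns), `[[`, "rows"))),
            class = "fiml_data")
}

#' FIML log-likelihood of a RAM model
#'
#' Sums, over missingness patterns, the multivariate-normal log-density of
#' each row's observed sub-vector under the pattern's sub-mean and
#' sub-covariance of the implied moments. A non-positive-definite pattern
#' covariance yields a large negative penalty value (optimizer-safe) rather
#' than `NaN`.
#'
#' @param par natural-scale parameter vector.
#' @param model a `ram_model`.
#' @param data data.frame/matrix containing the model's observed columns
#'   (NA = missing), or a prepared object from the internal pattern grouper.
#' @param gradient if TRUE, attach the analytic gradient as attribute "grad".
#' @return the log-likelihood (numeric scalar).
#' @export
fiml_loglik <- function(par, model, data, gradient = FALSE) {
  pdata <- if (inherits(data, "fiml_data")) data else
    prepare_fiml_data(scale_for_model(model, as.data.frame(data)), model$obs)
  mm <- ram_fill(model, par)
  oi <- ram_idx(model, model$obs)
  res <- fiml_ram_cpp(mm$A, mm$S, mm$M, as.integer(oi - 1L),
                      lapply(pdata$patterns, function(p) p[c("cols", "Y")]),
                      gradient)
  if (!isTRUE(res$ok)) {
    ll <- -1e10
    if (gradient) attr(ll, "grad") <- rep(0, length(ram_par_names(model)))
    return(ll)
  }
  ll <- res$ll
  if (gradient) {
    fr <- model$free
    pn <- ram_par_names(model)
    cell <- numeric(nrow(fr))
    isA <- fr$mat == "A"; isS <- fr$mat == "S"; isM <- fr$mat == "M"
    if (any(isA)) cell[isA] <- res$dA[cbind(fr$i[isA], fr$j[isA])]
    # C++ returns d(ll)/dS with the diagonal already halved, i.e. exactly the
    # derivative w.r.t. one free parameter tied to the symmetric cell pair.
    if (any(isS)) cell[isS] <- res$dS[cbind(fr$i[isS], fr$j[isS])]
    if (any(isM)) cell[isM] <- res$dM[fr$i[isM]]
    g <- vapply(pn, function(p) sum(cell[fr$param == p]), numeric(1))
    attr(ll, "grad") <- g
  }
  ll
}

# Transform helpers: optimizer works on theta where variance params are logged.
to_theta <- function(model, par) {
  ty <- model$ptype[ram_par_names(model)]
  ifelse(ty == "var", log(pmax(par, 1e-10)), par)
}
from_theta <- function(model, theta) {
  ty <- model$ptype[ram_par_names(model)]
  ifelse(ty == "var", exp(theta), theta)
}

#' Fit a RAM model by full-information maximum likelihood
#'
#' Quasi-Newton (L-BFGS-B) maximization with analytic gradients; variance
#' parameters are optimized on the log scale. Multiple jittered starts guard
#' against local optima; the best converged solution is returned. Standard
#' errors come from the inverse of the numerically differentiated observed
#' information (finite differences of the analytic gradient, natural scale).
#'
#' @param model a `ram_model`.
#' @param data data with the model's observed columns; NA = missing.
#' @param n_starts number of jittered starting points (first start unjittered).
#' @param tol relative log-likelihood convergence tolerance passed to the
#'   optimizer (`factr = tol / .Machine$double.eps`).
#' @param se compute observed-information standard errors.
#' @param max_iter optimizer iteration cap per start.
#' @param jitter_sd standard deviation of the start jitter (theta scale).
#' @return an object of class `fitted_sem`: estimates, SEs, log-likelihood,
#'   convergence flag, gradient norm, missingness-pattern inventory.
#' @export
fit_sem <- function(model, data, n_starts = 5, tol = 1e-8, se = TRUE,
                    max_iter = 2000L, jitter_sd = 0.1) {
  pdata <- if (inherits(data, "fiml_data")) data else
    prepare_fiml_data(scale_for_model(model, as.data.frame(data)), model$obs)
  pn <- ram_par_names(model)
  theta0 <- to_theta(model, model$start[pn])

  negll <- function(theta) {
    -as.numeric(fiml_loglik(from_theta(model, theta), model, pdata))
  }
  neggr <- function(theta) {
    par <- from_theta(model, theta)
    ll <- fiml_loglik(par, model, pdata, gradient = TRUE)
    g <- attr(ll, "grad")
    ty <- model$ptype[pn]
    -ifelse(ty == "var", g * par, g)   # chain rule for logged variances
  }

  best <- NULL
  set_jitter <- function(k) {
    if (k == 1L) theta0 else theta0 + rnorm(length(theta0), 0, jitter_sd)
  }
  ty0 <- model$ptype[pn]
  lower <- ifelse(ty0 == "var", log(1e-6), -Inf)   # keep variances positive
  upper <- ifelse(ty0 == "var", log(1e12), Inf)    # and finite
  ctl <- list(maxit = max_iter, factr = tol / .Machine$double.eps, lmm = 25)
  # limited-memory BFGS can stall in long curved valleys; restarting from
  # its own solution rebuilds the Hessian approximation, so polish until the
  # log-likelihood stops improving
  run_one <- function(theta) {
    theta <- pmin(pmax(theta, lower), upper)
    opt <- optim(theta, negll, neggr, method = "L-BFGS-B", control = ctl,
                 lower = lower, upper = upper)
    for (r in 1:8) {
      opt2 <- optim(opt$par, negll, neggr, method = "L-BFGS-B", control = ctl,
                    lower = lower, upper = upper)
      if (opt$value - opt2$value < 1e-6 * (1 + abs(opt2$value)) * 1e-2) {
        opt <- opt2; break
      }
      opt <- opt2
    }
    opt
  }
  trace <- list()
  for (k in seq_len(n_starts)) {
    opt <- tryCatch(run_one(set_jitter(k)), error = function(e) NULL)
    trace[[k]] <- if (is.null(opt)) list(ok = FALSE) else
      list(ok = TRUE, value = -opt$value, convergence = opt$convergence)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best))
    return(structure(list(converged = FALSE, model = model, trace = trace),
                     class = "fitted_sem"))

  # Newton polish: quasi-Newton handles the long valleys poorly near the
  # optimum; a few damped Newton steps on the transformed scale (Hessian by
  # finite differences of the analytic gradient) reach tight stationarity.
  theta <- best$par
  f_cur <- best$value
  for (it in 1:20) {
    g <- neggr(theta)
    # project out infeasible directions at active bounds
    g[theta <= lower + 1e-8 & g > 0] <- 0
    g[theta >= upper - 1e-8 & g < 0] <- 0
    if (max(abs(g)) < 1e-5) break
    H <- num_hessian_from_grad(neggr, theta)
    H <- (H + t(H)) / 2
    step <- tryCatch({
      ev <- eigen(H, symmetric = TRUE)
      lam <- pmax(ev$values, 1e-8 * max(abs(ev$values), 1))
      -drop(ev$vectors %*% ((t(ev$vectors) %*% g) / lam))
    }, error = function(e) NULL)
    if (is.null(step)) break
    alpha <- 1; improved <- FALSE
    for (h in 1:30) {
      cand <- pmin(pmax(theta + alpha * step, lower), upper)
      f_new <- negll(cand)
      if (is.finite(f_new) && f_new < f_cur) {
        theta <- cand; f_cur <- f_new; improved <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!improved) break
  }
  best$par <- theta; best$value <- f_cur

  par <- setNames(from_theta(model, best$par), pn)
  ll <- fiml_loglik(par, model, pdata, gradient = TRUE)
  # projected gradient norm on the optimizer (log-variance) scale: at an
  # active variance bound, the infeasible descent direction does not count
  ty <- model$ptype[pn]
  gth <- ifelse(ty == "var", attr(ll, "grad") * par, attr(ll, "grad"))
  at_lo <- best$par <= lower + 1e-8
  at_hi <- best$par >= upper - 1e-8
  gth[at_lo & gth < 0] <- 0
  gth[at_hi & gth > 0] <- 0
  gnorm <- max(abs(gth))
  # honest convergence: a stationary polished point counts even if L-BFGS-B
  # itself returned a warning code before the Newton polish
  converged <- is.finite(ll) && (best$convergence == 0 || gnorm < 1e-3)

  vc <- NULL; ses <- setNames(rep(NA_real_, length(pn)), pn)
  if (se && converged) {
    H <- num_hessian_from_grad(function(p) {
      attr(fiml_loglik(setNames(p, pn), model, pdata, gradient = TRUE), "grad")
    }, unname(par))
    vc <- tryCatch(solve(-(H + t(H)) / 2), error = function(e) NULL)
    if (!is.null(vc)) {
      d <- diag(vc)
      ses <- setNames(ifelse(d > 0, sqrt(pmax(d, 0)), NA_real_), pn)
      dimnames(vc) <- list(pn, pn)
    }
  }

  structure(list(
    par = par, se = ses, vcov = vc, loglik = as.numeric(ll),
    converged = converged, grad_norm = gnorm, model = model,
    n = pdata$n, n_free = length(pn),
    patterns = vapply(pdata$patterns, function(p) nrow(p$Y), integer(1)),
    trace = trace, method = "sem"), class = "fitted_sem")
}

#' @export
print.fitted_sem <- function(x, ...) {
  cat("Fitted SEM (FIML): n =", x$n, ", free parameters =", x$n_free,
      "\n  log-likelihood =", format(x$loglik, digits = 10),
      "\n  converged:", x$converged, " (max |grad| =",
      format(x$grad_norm, digits = 3), ")\n")
  invisible(x)
}

# Central-difference Jacobian of an analytic gradient -> observed information.
num_hessian_from_grad <- function(gradfun, par, h = 1e-5) {
  p <- length(par)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) {
    hi <- h * max(1, abs(par[i]))
    up <- par; up[i] <- up[i] + hi
    dn <- par; dn[i] <- dn[i] - hi
    H[i, ] <- (gradfun(up) - gradfun(dn)) / (2 * hi)
  }
  H
}

#' Saturated-model FIML estimates via EM
#'
#' EM for an unstructured multivariate normal under arbitrary missingness:
#' the E-step imputes conditional means and adds conditional covariances per
#' missingness pattern; the M-step re-estimates the mean and (1/n) covariance.
#' Supplies the saturated log-likelihood used by the chi-square and fit
#' indices, and the FIML-estimated moments used by SRMR.
#'
#' @param data data with columns to be modelled (NA = missing).
#' @param cols columns to use (default: all).
#' @param tol absolute log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @return list: `mu`, `Sigma` (MLE, divisor n), `loglik`, `iterations`,
#'   `converged`.
#' @export
fiml_saturated <- function(data, cols = colnames(data), tol = 1e-7,
                           max_iter = 500L) {
  X <- as.matrix(data[, cols, drop = FALSE])
  storage.mode(X) <- "double"
  X <- X[rowSums(is.finite(X)) > 0L, , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  obs <- is.finite(X)
  key <- apply(obs, 1L, function(r) paste(which(r), collapse = ","))
  groups <- split(seq_len(n), key)

  mu <- colMeans(X, na.rm = TRUE)
  cc <- X[rowSums(obs) == p, , drop = FALSE]
  Sigma <- if (nrow(cc) > p) cov(cc) * (nrow(cc) - 1) / nrow(cc) else {
    v <- apply(X, 2, var, na.rm = TRUE); diag(v, p)
  }
  ll_old <- -Inf; it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    sum_y <- numeric(p); Syy <- matrix(0, p, p); ll <- 0
    for (rows in groups) {
      o <- which(obs[rows[1L], ]); m <- setdiff(seq_len(p), o)
      Yo <- X[rows, o, drop = FALSE]
      So <- Sigma[o, o, drop = FALSE]
      L <- tryCatch(chol(So), error = function(e) NULL)
      if (is.null(L)) { So <- So + diag(1e-8, length(o)); L <- chol(So) }
      Ro <- sweep(Yo, 2, mu[o])
      Z <- backsolve(L, t(Ro), transpose = TRUE)
      ll <- ll - 0.5 * length(rows) *
        (length(o) * log(2 * pi) + 2 * sum(log(diag(L)))) - 0.5 * sum(Z * Z)
      Yfull <- matrix(0, length(rows), p)
      Yfull[, o] <- Yo
      if (length(m)) {
        K <- backsolve(L, backsolve(L, t(Ro), transpose = TRUE))  # So^-1 Ro'
        Ym <- matrix(mu[m], length(rows), length(m), byrow = TRUE) +
          t(Sigma[m, o, drop = FALSE] %*% K)
        Yfull[, m] <- Ym
        Cm <- Sigma[m, m, drop = FALSE] - Sigma[m, o, drop = FALSE] %*%
          backsolve(L, backsolve(L, Sigma[o, m, drop = FALSE], transpose = TRUE))
        Syy[m, m] <- Syy[m, m] + length(rows) * Cm
      }
      sum_y <- sum_y + colSums(Yfull)
      Syy <- Syy + crossprod(Yfull)
    }
    mu <- sum_y / n
    Sigma <- Syy / n - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  # one clean likelihood evaluation at the final estimates
  ll <- mvn_pattern_loglik(X, obs, groups, mu, Sigma)
  list(mu = setNames(mu, cols), Sigma = structure(Sigma, dimnames = list(cols, cols)),
       loglik = ll, iterations = it, converged = converged)
}

mvn_pattern_loglik <- function(X, obs, groups, mu, Sigma) {
  ll <- 0
  for (rows in groups) {
    o <- which(obs[rows[1L], ])
    L <- chol(Sigma[o, o, drop = FALSE])
    Ro <- sweep(X[rows, o, drop = FALSE], 2, mu[o])
    Z <- backsolve(L, t(Ro), transpose = TRUE)
    ll <- ll - 0.5 * length(rows) *
      (length(o) * log(2 * pi) + 2 * sum(log(diag(L)))) - 0.5 * sum(Z * Z)
  }
  ll
}

# Independence-baseline FIML: the likelihood separates per column, so the MLE
# is each column's observed-case mean and (1/n) variance.
fiml_independence <- function(data, cols = colnames(data)) {
  X <- as.matrix(data[, cols, drop = FALSE])
  ll <- 0; npar <- 0L
  for (j in seq_len(ncol(X))) {
    x <- X[, j]; x <- x[is.finite(x)]
    m <- mean(x); v <- mean((x - m)^2)
    ll <- ll - 0.5 * length(x) * (log(2 * pi) + log(v) + 1)
    npar <- npar + 2L
  }
  list(loglik = ll, n_par = npar)
}

#' Likelihood-based fit indices
#'
#' Chi-square against the FIML saturated model, RMSEA (denominator `N`), CFI,
#' TLI against the independence baseline, and SRMR computed from standardized
#' residuals between the FIML-saturated covariance and the model-implied
#' covariance.
#'
#' @param fitted a converged `fitted_sem`.
#' @param data the data the model was fitted to.
#' @param saturated optional precomputed result of [fiml_saturated()] on the
#'   same columns *on the model's analysis scale* (saves the EM run when
#'   reused across models); when in doubt leave NULL.
#' @return list of class `fit_indices`: `chisq`, `df`, `pvalue`, `rmsea`,
#'   `cfi`, `tli`, `srmr`, plus baseline details.
#' @export
fit_indices <- function(fitted, data, saturated = NULL) {
  if (!isTRUE(fitted$converged)) stop("model did not converge; no fit indices")
  obs <- fitted$model$obs
  data <- scale_for_model(fitted$model, as.data.frame(data))
  if (is.null(saturated)) saturated <- fiml_saturated(data, obs)
  if (!isTRUE(saturated$converged))
    warning("saturated EM hit the iteration cap; indices may be approximate")
  p <- length(obs)
  n_moments <- p * (p + 3) / 2
  chisq <- max(0, 2 * (saturated$loglik - fitted$loglik))
  df <- n_moments - fitted$n_free
  N <- fitted$n
  indep <- fiml_independence(data, obs)
  chisq_b <- 2 * (saturated$loglik - indep$loglik)
  df_b <- n_moments - indep$n_par
  rmsea <- if (df > 0) sqrt(max(chisq - df, 0) / (df * N)) else NA_real_
  num <- max(chisq - df, 0)
  den <- max(chisq_b - df_b, chisq - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  tli <- if (chisq_b / df_b - 1 == 0) 1 else
    ((chisq_b / df_b) - (chisq / df)) / ((chisq_b / df_b) - 1)
  imp <- implied_moments(fitted$model, fitted$par)
  Ssat <- saturated$Sigma; Simp <- imp$Sigma[obs, obs]
  sdv <- sqrt(diag(Ssat))
  D <- (Ssat - Simp) / tcrossprod(sdv)
  srmr <- sqrt(mean(D[lower.tri(D, diag = TRUE)]^2))
  structure(list(chisq = chisq, df = df,
                 pvalue = if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else NA_real_,
                 rmsea = rmsea, cfi = cfi, tli = tli, srmr = srmr,
                 chisq_baseline = chisq_b, df_baseline = df_b,
                 loglik = fitted$loglik, loglik_saturated = saturated$loglik,
                 n = N), class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("chi-square(%d) = %.2f, p = %.3g\nRMSEA = %.3f  CFI = %.3f  TLI = %.3f  SRMR = %.3f\n",
              x$df, x$chisq, x$pvalue, x$rmsea, x$cfi, x$tli, x$srmr))
  invisible(x)
}
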