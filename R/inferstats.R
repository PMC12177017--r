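# Comparison statistics: maximum-likelihood beta regression (logit mean link,
# constant precision on a log link), Wald tests, estimated-marginal-means
# pairwise contrasts with Tukey adjustment, and ordinary least squares.

#' Squeeze proportions off the boundary
#'
#' The beta likelihood is undefined at 0 and 1; accuracies of exactly 0 or 1
#' do occur. The standard transformation `y' = (y * (n - 1) + 0.5) / n`
#' shrinks all observations slightly toward 1/2 and is applied automatically
#' by [fit_beta_regression()] whenever a boundary value is present.
#'
#' @param y Proportions in `[0, 1]`.
#' @param n Sample size used for the squeeze (default `length(y)`).
#' @return Proportions strictly inside `(0, 1)`.
#' @export
squeeze_proportions <- function(y, n = length(y)) {
  (y * (n - 1) + 0.5) / n
}

beta_negloglik <- function(par, X, y) {
  p <- ncol(X)
  mu <- stats::plogis(drop(X %*% par[seq_len(p)]))
  phi <- exp(par[p + 1L])
  -sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
         (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log1p(-y))
}

beta_negloglik_grad <- function(par, X, y) {
  p <- ncol(X)
  mu <- stats::plogis(drop(X %*% par[seq_len(p)]))
  phi <- exp(par[p + 1L])
  ystar <- stats::qlogis(y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  gbeta <- drop(crossprod(X, phi * (ystar - mustar) * mu * (1 - mu)))
  glphi <- phi * sum(mu * (ystar - mustar) + log1p(-y) -
                       digamma((1 - mu) * phi) + digamma(phi))
  -c(gbeta, glphi)
}

#' Fit a beta regression by maximum likelihood
#'
#' The mean model is `mu_i = plogis(x_i' beta)` and the shape parameters are
#' `(mu_i * phi, (1 - mu_i) * phi)` with a single precision `phi = exp(gamma)`.
#' Optimisation is quasi-Newton (BFGS with analytic gradients) from a
#' logit-scale least-squares start, polished by Newton steps until the
#' gradient norm is below 1e-6. The coefficient covariance is the inverse
#' observed information.
#'
#' @param formula Mean-model formula; the response must lie in `[0, 1]`.
#' @param data Data frame of observations.
#' @return A `betareg_fit` with elements `coefficients` (mean model, logit
#'   link), `phi`, `vcov` (mean coefficients), `vcov_full` (including
#'   `log(phi)`), `loglik`, `n`, `converged`, plus the design information
#'   needed by [pairwise_contrasts()].
#' @export
fit_beta_regression <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (any(y < 0 | y > 1)) stop("response must lie in [0, 1]")
  if (any(y <= 0 | y >= 1)) y <- squeeze_proportions(y)
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("more coefficients than observations")
  if (qr(X)$rank < p) stop("model matrix is rank deficient")

  # Start values: least squares on the logit scale; precision by moments.
  ystar <- stats::qlogis(y)
  beta0 <- stats::lm.fit(X, ystar)$coefficients
  mu0 <- stats::plogis(drop(X %*% beta0))
  e <- ystar - stats::qlogis(mu0)
  s2 <- sum(e^2) / max(1, n - p) * (mu0 * (1 - mu0))^2
  phi0 <- max(mean(mu0 * (1 - mu0) / pmax(s2, 1e-10)) - 1, 1.1)
  par <- c(beta0, log(phi0))

  opt <- stats::optim(par, beta_negloglik, beta_negloglik_grad,
                      X = X, y = y, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  par <- opt$par
  # Newton polish to drive the score to ~0.
  for (it in 1:25) {
    g <- beta_negloglik_grad(par, X, y)
    if (sqrt(sum(g^2)) < 1e-8) break
    H <- stats::optimHess(par, beta_negloglik, beta_negloglik_grad, X = X, y = y)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    cand <- par - step
    if (beta_negloglik(cand, X, y) <= beta_negloglik(par, X, y) + 1e-10) {
      par <- cand
    } else {
      par <- par - 0.5 * step
    }
  }
  g <- beta_negloglik_grad(par, X, y)
  H <- stats::optimHess(par, beta_negloglik, beta_negloglik_grad, X = X, y = y)
  vcov_full <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p + 1, p + 1))
  converged <- opt$convergence == 0 && sqrt(sum(g^2)) < 1e-6 &&
    all(is.finite(vcov_full))
  if (!converged) {
    warning("beta regression did not converge cleanly (gradient norm ",
            format(sqrt(sum(g^2))), ")")
  }
  beta <- par[seq_len(p)]
  names(beta) <- colnames(X)
  dimnames(vcov_full) <- list(c(colnames(X), "log(phi)"),
                              c(colnames(X), "log(phi)"))
  structure(
    list(coefficients = beta, phi = exp(par[p + 1L]),
         vcov = vcov_full[seq_len(p), seq_len(p), drop = FALSE],
         vcov_full = vcov_full,
         loglik = -beta_negloglik(par, X, y), n = n,
         converged = converged,
         fitted = stats::plogis(drop(X %*% beta)),
         terms = attr(mf, "terms"),
         xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
         contrasts = attr(X, "contrasts"),
         model = mf),
    class = "betareg_fit")
}

#' @export
print.betareg_fit <- function(x, ...) {
  cat(sprintf("<betareg_fit> n = %d, phi = %.2f, loglik = %.2f%s\n",
              x$n, x$phi, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  print(wald_tests(x))
  invisible(x)
}

#' Per-coefficient Wald tests
#'
#' `Z = estimate / SE` with a two-sided standard-normal p-value (a t test on
#' residual degrees of freedom for OLS fits).
#'
#' @param fit A `betareg_fit` or `ols_fit`.
#' @return Data frame with columns `term`, `estimate`, `se`, `z` (or `t`),
#'   `p_value`.
#' @export
wald_tests <- function(fit) {
  UseMethod("wald_tests")
}

#' @export
wald_tests.betareg_fit <- function(fit) {
  est <- fit$coefficients
  se <- sqrt(diag(fit$vcov))
  z <- est / se
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             z = unname(z), p_value = unname(2 * stats::pnorm(-abs(z))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
wald_tests.ols_fit <- function(fit) {
  s <- summary(fit$lm)$coefficients
  data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
             t = s[, 3], p_value = s[, 4],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit an ordinary linear regression
#'
#' A thin wrapper over [stats::lm()] that errors on rank deficiency (e.g. an
#' interaction requested for a factor observed at one level) and stores the
#' design information used by [pairwise_contrasts()].
#'
#' @param formula Model formula.
#' @param data Data frame.
#' @return An `ols_fit` wrapping the `lm` object.
#' @export
fit_ols <- function(formula, data) {
  fit <- stats::lm(formula, data)
  fit$call$data <- data  # embed data so downstream tools can recover the frame
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  if (fit$df.residual <= 0) stop("no residual degrees of freedom")
  mf <- stats::model.frame(fit)
  structure(
    list(lm = fit, coefficients = stats::coef(fit), vcov = stats::vcov(fit),
         df = fit$df.residual, terms = stats::terms(fit),
         xlevels = fit$xlevels, contrasts = attr(stats::model.matrix(fit), "contrasts"),
         model = mf),
    class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> n = %d, residual df = %d\n", nrow(x$model), x$df))
  print(wald_tests(x))
  invisible(x)
}

# Reference grid: all level combinations of the model's factors, numeric
# covariates at their observed mean.
reference_grid <- function(fit) {
  tt <- stats::delete.response(fit$terms)
  vars <- all.vars(tt)
  cols <- lapply(vars, function(v) {
    if (!is.null(fit$xlevels[[v]])) {
      factor(fit$xlevels[[v]], levels = fit$xlevels[[v]])
    } else {
      mean(fit$model[[v]])
    }
  })
  names(cols) <- vars
  expand.grid(cols, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Pairwise post-hoc contrasts of estimated marginal means
#'
#' Marginal means on the link scale (logit for beta fits, identity for OLS)
#' are obtained for each level of `factor` by averaging model predictions
#' over the levels of every other factor in the design (numeric covariates
#' held at their mean). All pairwise level differences are reported with
#' delta-method standard errors and Tukey (studentised-range) adjusted
#' p-values — the single-factor-family default of standard post-hoc
#' machinery. Degrees of freedom are the OLS residual df, or infinite for
#' the asymptotic beta-regression case.
#'
#' @param fit A `betareg_fit` or `ols_fit`.
#' @param factor Name of a factor in the design with >= 2 levels.
#' @param adjust `"tukey"` (default) or `"none"`.
#' @return Data frame with one row per level pair: `contrast`, `estimate`
#'   (link scale, first minus second level), `se`, `z_ratio`, `p_value`,
#'   `adjustment`, and an `emmeans` attribute holding the marginal means.
#' @export
pairwise_contrasts <- function(fit, factor, adjust = c("tukey", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(fit, c("betareg_fit", "ols_fit")))
  levels <- fit$xlevels[[factor]]
  if (is.null(levels)) stop("'", factor, "' is not a factor in the model")
  if (length(levels) < 2) stop("'", factor, "' has a single level")
  grid <- reference_grid(fit)
  tt <- stats::delete.response(fit$terms)
  mm <- stats::model.matrix(tt, grid, contrasts.arg = fit$contrasts)
  # One averaging functional per level of the target factor.
  L <- t(vapply(levels, function(lv) {
    colMeans(mm[grid[[factor]] == lv, , drop = FALSE])
  }, numeric(ncol(mm))))
  beta <- fit$coefficients
  V <- fit$vcov
  emm <- drop(L %*% beta)
  df <- if (inherits(fit, "ols_fit")) fit$df else Inf
  k <- length(levels)
  pairs <- utils::combn(k, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d <- L[a, ] - L[b, ]
    est <- sum(d * beta)
    se <- sqrt(drop(t(d) %*% V %*% d))
    if (se <= .Machine$double.eps^0.5) {
      z <- if (abs(est) <= .Machine$double.eps^0.5) 0 else sign(est) * Inf
    } else {
      z <- est / se
    }
    p <- if (adjust == "tukey") {
      stats::ptukey(abs(z) * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
    } else if (is.finite(df)) {
      2 * stats::pt(-abs(z), df)
    } else {
      2 * stats::pnorm(-abs(z))
    }
    data.frame(contrast = paste(levels[a], "-", levels[b]),
               estimate = est, se = se, z_ratio = z, p_value = p,
               adjustment = adjust, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "emmeans") <- stats::setNames(emm, levels)
  out
}
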