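# Beta regression by maximum likelihood, Wald tests, Tukey contrasts, OLS.

simulate_beta <- function(n, X, beta, phi) {
  mu <- stats::plogis(drop(X %*% beta))
  stats::rbeta(n, mu * phi, (1 - mu) * phi)
}

test_that("an intercept-only fit recovers the simulated mean and precision", {
  set.seed(10)
  y <- stats::rbeta(2000, 0.8 * 50, 0.2 * 50)
  fit <- fit_beta_regression(y ~ 1, data.frame(y = y))
  expect_true(fit$converged)
  expect_lt(abs(stats::plogis(fit$coefficients[[1]]) - 0.8), 0.02)
  expect_lt(abs(fit$phi - 50) / 50, 0.15)
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
})

test_that("the analytic score vanishes at the optimum and matches finite differences", {
  set.seed(2)
  d <- data.frame(x = rnorm(80))
  d$y <- simulate_beta(80, cbind(1, d$x), c(0.4, 0.6), 20)
  fit <- fit_beta_regression(y ~ x, d)
  X <- cbind(1, d$x)
  par_hat <- c(fit$coefficients, log(fit$phi))
  g_opt <- ethoacc:::beta_negloglik_grad(par_hat, X, d$y)
  expect_lt(sqrt(sum(g_opt^2)), 1e-6)
  # analytic vs central finite differences at a non-optimal point
  par0 <- c(0.1, 0.2, log(5))
  g <- ethoacc:::beta_negloglik_grad(par0, X, d$y)
  h <- 1e-6
  g_num <- vapply(seq_along(par0), function(j) {
    e <- rep(0, length(par0)); e[j] <- h
    (ethoacc:::beta_negloglik(par0 + e, X, d$y) -
       ethoacc:::beta_negloglik(par0 - e, X, d$y)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g - g_num) / pmax(abs(g_num), 1)), 1e-5)
})

test_that("adding a term never decreases the log-likelihood", {
  set.seed(3)
  d <- data.frame(g = rep(c("a", "b"), each = 30))
  d$y <- simulate_beta(60, cbind(1, d$g == "b"), c(0.5, 0.4), 25)
  null_fit <- fit_beta_regression(y ~ 1, d)
  full_fit <- fit_beta_regression(y ~ g, d)
  expect_gte(full_fit$loglik, null_fit$loglik - 1e-8)
})

test_that("small-instance fits match an independent optimiser oracle", {
  set.seed(4)
  d <- data.frame(x = rep(c(0, 1), 6))
  d$y <- simulate_beta(12, cbind(1, d$x), c(0.3, 0.5), 15)
  fit <- fit_beta_regression(y ~ x, d)
  # oracle: independently coded likelihood via dbeta(), Nelder-Mead refined
  oracle_nll <- function(par) {
    mu <- stats::plogis(par[1] + par[2] * d$x)
    -sum(stats::dbeta(d$y, mu * exp(par[3]), (1 - mu) * exp(par[3]), log = TRUE))
  }
  o <- stats::optim(c(0, 0, 1), oracle_nll, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-14))
  o <- stats::optim(o$par, oracle_nll, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-14))
  expect_lt(max(abs(fit$coefficients - o$par[1:2])), 1e-4)
  expect_lt(abs(log(fit$phi) - o$par[3]), 1e-4)
})

test_that("boundary accuracies are squeezed, boundary-free data untouched", {
  y <- c(0.2, 0.5, 1.0, 0.8)
  expect_no_error(fit <- fit_beta_regression(y ~ 1, data.frame(y = y)))
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
  expect_equal(squeeze_proportions(c(0, 1), n = 10), c(0.05, 0.95))
  expect_error(fit_beta_regression(y ~ 1, data.frame(y = c(0.5, 1.2))),
               "lie in")
})

test_that("Wald z-statistics have correct size under the null", {
  set.seed(5)
  reps <- 400
  pvals <- replicate(reps, {
    d <- data.frame(x = rep(c(0, 1), each = 25))
    d$y <- simulate_beta(50, cbind(1, d$x), c(0.3, 0), 30)  # true slope 0
    fit <- fit_beta_regression(y ~ x, d)
    wald_tests(fit)$p_value[2]
  })
  type1 <- mean(pvals < 0.05)
  expect_gt(type1, 0.02)
  expect_lt(type1, 0.09)
})

test_that("pairwise contrasts count C(k,2), negate under relabelling, and close cycles", {
  set.seed(6)
  d <- data.frame(g = rep(c("a", "b", "c"), each = 20),
                  h = rep(c("u", "v"), 30))
  d$y <- simulate_beta(60, cbind(1, d$g == "b", d$g == "c"),
                       c(0.2, 0.4, -0.3), 40)
  fit <- fit_beta_regression(y ~ g + h, d)
  ct <- pairwise_contrasts(fit, "g")
  expect_equal(nrow(ct), 3)
  expect_identical(ct$adjustment, rep("tukey", 3))
  # (a-b) + (b-c) - (a-c) = 0
  expect_equal(ct$estimate[1] + ct$estimate[3] - ct$estimate[2], 0,
               tolerance = 1e-10)

  d2 <- d
  d2$g <- c(a = "b", b = "a", c = "c")[d$g]  # swap labels a and b
  ct2 <- pairwise_contrasts(fit_beta_regression(y ~ g + h, d2), "g")
  expect_equal(ct2$estimate[1], -ct$estimate[1], tolerance = 1e-6)
  expect_equal(ct2$p_value[1], ct$p_value[1], tolerance = 1e-6)

  two <- pairwise_contrasts(fit_beta_regression(y ~ h, d), "h")
  expect_equal(nrow(two), 1)
  expect_error(pairwise_contrasts(fit, "y"), "not a factor")
})

test_that("OLS reproduces exact linear data and rejects rank deficiency", {
  d <- data.frame(U = rep(c(0.2, 0.4, 0.6, 0.8), 2))
  d$cd <- 0.02 + 0.01 * d$U
  fit <- fit_ols(cd ~ U, d)
  expect_equal(unname(fit$coefficients), c(0.02, 0.01), tolerance = 1e-12)
  expect_lt(max(abs(stats::residuals(fit$lm))), 1e-12)

  d$position <- "scute1"  # single level with interaction: unusable design
  expect_error(fit_ols(cd ~ position * U, d), "rank-deficient|contrasts")
  # collinear covariates surface as rank deficiency
  d$U2 <- 2 * d$U
  expect_error(fit_ols(cd ~ U + U2, d), "rank-deficient")
})

test_that("OLS marginal-mean contrasts agree with the emmeans package", {
  set.seed(8)
  d <- data.frame(g = rep(c("none", "scute1", "scute3"), each = 6),
                  U = rep(c(0.2, 0.4, 0.6, 0.8, 1.0, 1.2), 3))
  d$cd <- c(0.02, 0.06, 0.048)[as.integer(factor(d$g))] + 0.005 * d$U +
    rnorm(18, 0, 0.002)
  fit <- fit_ols(cd ~ g * U, d)
  ours <- pairwise_contrasts(fit, "g")
  em <- summary(emmeans::emmeans(fit$lm, pairwise ~ g)$contrasts)
  expect_equal(ours$estimate, em$estimate, tolerance = 1e-8)
  expect_equal(ours$se, em$SE, tolerance = 1e-8)
  expect_equal(ours$p_value, em$p.value, tolerance = 1e-6)
})

test_that("OLS recovery: true slopes fall within 2 SE in most replicates", {
  set.seed(9)
  hits <- replicate(100, {
    d <- data.frame(U = rep(c(0.2, 0.6, 1.0), 20))
    d$cd <- 0.02 + 0.01 * d$U + rnorm(60, 0, 0.003)
    w <- wald_tests(fit_ols(cd ~ U, d))
    abs(w$estimate[2] - 0.01) <= 2 * w$se[2]
  })
  expect_gte(mean(hits), 0.9)
})
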