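# parametric density layer: closed forms, MLE/MAP fitting, KS checks

test_that("densities match their closed forms at hand-computed points", {
  expect_equal(pdf_eval(beta_params(1, 1), 0.37), 1.0)
  expect_equal(pdf_eval(gnd_params(0, 2, 2), 0), 1 / (2 * sqrt(pi)),
               tolerance = 1e-12)
  expect_equal(pdf_eval(gamma_params(1, 1), 1), exp(-1), tolerance = 1e-12)
  # zero outside support
  expect_equal(pdf_eval(gamma_params(2, 1), -1), 0)
  expect_equal(pdf_eval(beta_params(2, 3), 1.5), 0)
})

test_that("every pdf integrates to one over its support", {
  cases <- list(
    list(p = gamma_params(0.7, 2), lo = 0, hi = Inf),
    list(p = gamma_params(5, 0.3), lo = 0, hi = Inf),
    list(p = gnd_params(-1, 0.8, 1.3), lo = -Inf, hi = Inf),
    list(p = gnd_params(2, 3, 4), lo = -Inf, hi = Inf),
    list(p = beta_params(0.6, 2.5), lo = 0, hi = 1),
    list(p = beta_params(8, 3), lo = 0, hi = 1))
  for (cs in cases) {
    val <- integrate(function(x) pdf_eval(cs$p, x), cs$lo, cs$hi,
                     rel.tol = 1e-9)$value
    expect_close(val, 1, tol = 1e-6)
  }
})

test_that("GND cdf is consistent with its density", {
  p <- gnd_params(0.5, 1.4, 2.7)
  for (q in c(-1, 0.2, 0.5, 1.9)) {
    num <- integrate(function(x) pdf_eval(p, x), -Inf, q,
                     rel.tol = 1e-10)$value
    expect_close(cdf_eval(p, q), num, tol = 1e-7)
  }
})

test_that("Gamma MLE recovers parameters and satisfies stationarity", {
  set.seed(101)
  x <- rgamma(5000, shape = 2, scale = 1.5)
  fit <- fit_gamma_mle(x)
  expect_gt(fit$k, 1.8); expect_lt(fit$k, 2.2)
  expect_gt(fit$theta, 1.35); expect_lt(fit$theta, 1.65)
  expect_close(fit$k * fit$theta, mean(x), tol = 1e-9)
  # local optimum: perturbing the shape lowers the log-likelihood
  ll <- function(k, th) sum(dgamma(x, shape = k, scale = th, log = TRUE))
  expect_gt(ll(fit$k, fit$theta), ll(fit$k + 0.05, fit$theta))
  expect_gt(ll(fit$k, fit$theta), ll(fit$k - 0.05, fit$theta))
  expect_error(fit_gamma_mle(c(-1, 2)), "positive")
  expect_error(fit_gamma_mle(rep(3, 10)), "degenerate")
})

test_that("Gamma MLE is scale equivariant", {
  set.seed(102)
  x <- rgamma(2000, shape = 3, scale = 0.7)
  f1 <- fit_gamma_mle(x)
  f2 <- fit_gamma_mle(10 * x)
  expect_close(f2$k, f1$k, tol = 1e-8)
  expect_close(f2$theta, 10 * f1$theta, tol = 1e-7)
})

test_that("GND MLE recovers Gaussian and Laplace samples", {
  set.seed(103)
  g <- rnorm(5000, mean = 1, sd = 2)
  fit <- fit_gnd_mle(g)
  expect_gt(fit$beta, 1.7); expect_lt(fit$beta, 2.4)
  expect_gt(fit$alpha, 2.5); expect_lt(fit$alpha, 3.2)  # sigma * sqrt(2)
  expect_gt(fit$mu, 0.8); expect_lt(fit$mu, 1.2)
  lap <- 1.5 * sign(runif(5000) - 0.5) * rexp(5000)
  fit_l <- fit_gnd_mle(lap)
  expect_gt(fit_l$beta, 0.85); expect_lt(fit_l$beta, 1.25)
  # symmetric two-point sample: median-based position is central
  two <- rep(c(-1, 1), 50)
  expect_equal(fit_gnd_mle(two)$mu, 0)
})

test_that("GND MLE is affine equivariant within tolerance", {
  set.seed(104)
  x <- rgnd(3000, mu = 0.5, alpha = 1.2, beta = 1.6)
  f1 <- fit_gnd_mle(x)
  f2 <- fit_gnd_mle(3 * x - 2)
  expect_close(f2$mu, 3 * f1$mu - 2, tol = 1e-8)
  expect_close(f2$alpha, 3 * f1$alpha, tol = 1e-6)
  expect_close(f2$beta, f1$beta, tol = 1e-6)
})

test_that("Beta MAP with a null prior matches the unconstrained MLE", {
  set.seed(105)
  x <- rbeta(1500, 3, 1.4)
  map <- fit_beta_map(x, prior = beta_prior(K = 0, a = 0, b = 0))
  # independent oracle: generic numeric optimization of the likelihood
  nll <- function(p) -sum(dbeta(x, exp(p[1]), exp(p[2]), log = TRUE))
  mle <- optim(c(0, 0), nll, method = "BFGS")
  expect_close(map$alpha, exp(mle$par[1]), tol = 1e-4)
  expect_close(map$beta, exp(mle$par[2]), tol = 1e-4)
  expect_lte(attr(map, "residual"), 1e-8)
  expect_gt(attr(map, "det_j"), 0)
})

test_that("Beta MAP recovers generating parameters under a weak prior", {
  set.seed(106)
  x <- rbeta(2000, 5, 2)
  fit <- fit_beta_map(x, prior = beta_prior(K = 0, a = 0.1, b = 0.1))
  expect_gt(fit$alpha, 4.2); expect_lt(fit$alpha, 5.8)
  expect_gt(fit$beta, 1.7); expect_lt(fit$beta, 2.3)
  expect_error(fit_beta_map(x, prior = beta_prior(K = length(x))),
               "below the sample count")
})

test_that("the alpha penalty prevents Dirac collapse near the boundary", {
  set.seed(107)
  x <- runif(300, 0.9992, 0.99999)
  with_pen <- fit_beta_map(x, prior = beta_prior(K = 0, a = 0.5, b = 0))
  no_pen <- fit_beta_map(x, prior = beta_prior(K = 0, a = 0, b = 0))
  expect_true(is.finite(with_pen$alpha))
  expect_lte(with_pen$alpha, no_pen$alpha)
  expect_lt(with_pen$alpha, 0.9 * no_pen$alpha)  # a real reduction
})

test_that("KS statistic equals the brute-force ECDF supremum", {
  set.seed(108)
  x <- rgamma(80, shape = 2, scale = 1)
  p <- fit_gamma_mle(x)
  got <- ks_check(x, p)
  xs <- sort(x)
  cdf <- cdf_eval(p, xs)
  n <- length(xs)
  brute <- max(pmax(abs((1:n) / n - cdf), abs((0:(n - 1)) / n - cdf)))
  expect_close(got$statistic, brute, tol = 1e-12)
})

test_that("KS p-values are calibrated under the true model", {
  set.seed(109)
  hits <- 0L
  for (r in 1:60) {
    x <- rbeta(500, 2.5, 1.5)
    p <- beta_params(2.5, 1.5)               # true model, no estimation
    if (ks_check(x, p)$p_value > 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 60, 0.9)
})

test_that("KS statistic vanishes as exact-model samples grow", {
  set.seed(110)
  p <- beta_params(1, 1)
  s_small <- ks_check(runif(100), p)$statistic
  s_big <- ks_check(runif(5000), p)$statistic
  expect_lt(s_big, s_small)
  expect_lt(s_big, 0.03)
})
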