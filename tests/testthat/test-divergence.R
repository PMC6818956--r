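# Kullback-Leibler divergences and fusion weights

# quadrature oracle for D(p || q); log densities keep the tails finite
log_pdf <- function(p, x) {
  if (inherits(p, "beta_params")) dbeta(x, p$alpha, p$beta, log = TRUE)
  else if (inherits(p, "gamma_params"))
    dgamma(x, shape = p$k, scale = p$theta, log = TRUE)
  else log(p$beta) - log(2 * p$alpha) - lgamma(1 / p$beta) -
    (abs(x - p$mu) / p$alpha)^p$beta
}

kld_quad <- function(p, q, lo, hi) {
  f <- function(x) {
    lp <- log_pdf(p, x)
    lq <- log_pdf(q, x)
    out <- exp(lp) * (lp - lq)
    out[!is.finite(lp) | exp(lp) == 0] <- 0
    out
  }
  integrate(f, lo, hi, rel.tol = 1e-10, subdivisions = 1000L)$value
}

test_that("identical distributions have zero divergence", {
  expect_close(kld_beta(beta_params(2, 5), beta_params(2, 5)), 0, 1e-12)
  expect_close(kld_gamma(gamma_params(2, 5), gamma_params(2, 5)), 0, 1e-12)
  expect_close(kld_gnd(gnd_params(1, 2, 3), gnd_params(1, 2, 3)), 0, 1e-10)
})

test_that("Beta divergence matches quadrature and is asymmetric", {
  set.seed(21)
  for (r in 1:20) {
    p <- beta_params(runif(1, 0.5, 6), runif(1, 0.5, 6))
    q <- beta_params(runif(1, 0.5, 6), runif(1, 0.5, 6))
    expect_close(kld_beta(p, q), kld_quad(p, q, 0, 1), tol = 1e-6)
    expect_gte(kld_beta(p, q), -1e-12)
  }
  # note (2,5) vs (5,2) is NOT a valid asymmetry witness: the x -> 1-x
  # reflection maps D(p||q) onto D(q||p) exactly for mirrored pairs
  p <- beta_params(2, 5); q <- beta_params(5, 2)
  expect_close(kld_beta(p, q), kld_beta(q, p), tol = 1e-10)
  p2 <- beta_params(2, 5); q2 <- beta_params(3, 3)
  expect_gt(abs(kld_beta(p2, q2) - kld_beta(q2, p2)), 1e-3)
})

test_that("Gamma divergence matches quadrature and is scale invariant", {
  set.seed(22)
  for (r in 1:20) {
    p <- gamma_params(runif(1, 0.5, 5), runif(1, 0.3, 3))
    q <- gamma_params(runif(1, 0.5, 5), runif(1, 0.3, 3))
    expect_close(kld_gamma(p, q), kld_quad(p, q, 0, Inf), tol = 1e-6)
    expect_gte(kld_gamma(p, q), -1e-12)
  }
  p <- gamma_params(2, 1.2); q <- gamma_params(3.5, 0.4)
  base <- kld_gamma(p, q)
  for (cc in c(0.1, 1, 7, 100))
    expect_close(kld_gamma(gamma_params(p$k, cc * p$theta),
                           gamma_params(q$k, cc * q$theta)), base, 1e-10)
  expect_gt(abs(kld_gamma(p, q) - kld_gamma(q, p)), 1e-6)
})

test_that("GND divergence reduces to the Gaussian closed form", {
  # beta = 2 pair with equal means: sigma_i = alpha_i / sqrt(2)
  for (al in list(c(1, 2), c(0.5, 0.8), c(3, 1))) {
    got <- kld_gnd(gnd_params(0, al[1], 2), gnd_params(0, al[2], 2))
    want <- log(al[2] / al[1]) + al[1]^2 / (2 * al[2]^2) - 0.5
    expect_close(got, want, tol = 1e-10)
  }
})

test_that("GND divergence matches quadrature for integer target shapes", {
  set.seed(23)
  for (r in 1:50) {
    p <- gnd_params(runif(1, -2, 2), runif(1, 0.5, 3), runif(1, 0.7, 4))
    q <- gnd_params(runif(1, -2, 2), runif(1, 0.5, 3), sample(1:4, 1))
    got <- kld_gnd(p, q)
    want <- kld_quad(p, q, -Inf, Inf)
    expect_close(got / max(abs(want), 1e-12), 1, tol = 1e-5)
    expect_gte(got, -1e-10)
  }
})

test_that("non-integer target shapes are bracketed by integer neighbors", {
  set.seed(24)
  for (r in 1:20) {
    ap <- runif(1, 0.5, 3); bp <- runif(1, 0.7, 4)
    aq <- runif(1, 0.5, 3)
    u <- runif(1, 0.05, 2)
    bq <- runif(1, 1.1, 3.9)
    bq <- ifelse(abs(bq - round(bq)) < 0.05, bq + 0.07, bq)
    # the interpolated quantity is the cross-term integral at fixed
    # prefactor: strictly increasing in the shape, hence bracketed
    intg <- function(b) mfpd:::gnd_star_intg(u, ap, bp, aq, b)
    lo <- intg(floor(bq)); hi <- intg(ceiling(bq))
    mid <- mfpd:::gnd_star(u, ap, bp, aq, bq) /
      exp(mfpd:::gnd_log_k2(u, ap, bp, aq, bq))
    expect_gt(hi, lo)                      # monotone in the shape
    expect_gte(mid, lo - 1e-10 * abs(lo))
    expect_lte(mid, hi + 1e-10 * abs(hi))
  }
  # and the interpolated divergence tracks quadrature closely (the
  # integer evaluations are exact; the ratio interpolation between them
  # carries the only approximation error)
  set.seed(26)
  for (r in 1:10) {
    p <- gnd_params(runif(1, -1, 1), runif(1, 0.6, 2), runif(1, 0.8, 3.5))
    q <- gnd_params(runif(1, -1, 1), runif(1, 0.6, 2), runif(1, 1.1, 3.9))
    want <- kld_quad(p, q, -Inf, Inf)
    expect_close(kld_gnd(p, q) / max(want, 1e-9), 1, tol = 5e-3)
  }
})

test_that("the equal-mean branch agrees with the general branch limit", {
  p <- gnd_params(0, 1.3, 1.7); q0 <- gnd_params(0, 2.1, 3)
  q_eps <- gnd_params(1e-7, 2.1, 3)
  expect_close(kld_gnd(p, q_eps), kld_gnd(p, q0), tol = 1e-5)
})

test_that("weight capping enforces the two-thirds ceiling", {
  w <- modified_weights(c(s = 10, a = 1, c = 1))
  expect_equal(unname(w), c(2 / 3, 1 / 6, 1 / 6), tolerance = 1e-12)
  expect_equal(unname(modified_weights(c(1, 1, 1))), rep(1 / 3, 3))
  expect_equal(unname(modified_weights(c(0, 0, 0))), rep(1 / 3, 3))
  set.seed(25)
  for (r in 1:2000) {
    k <- runif(3, 0, 10)^2
    w <- modified_weights(k)
    expect_close(sum(w), 1, tol = 1e-12)
    expect_lte(max(w), 2 / 3 + 1e-12)
  }
  expect_error(modified_weights(c(-1, 1, 1)), "non-negative")
})

test_that("argmax ties break toward the first feature", {
  w <- modified_weights(c(s = 5, a = 5, c = 0))
  # first of the tied maxima is capped: both end at 1/2 here
  expect_equal(unname(w), c(0.5, 0.5, 0))
})
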