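#' Parametric families for the three features
#'
#' Parameter containers for the class-conditional densities: Gamma for
#' the squared slope (support `(0, Inf)`), generalized normal (GND) for
#' the amplitude (support `R`), Beta for the absolute correlation
#' (support `[0, 1]`).
#'
#' @param k,theta Gamma shape and scale (> 0).
#' @name distribution-params
NULL

#' @rdname distribution-params
#' @export
gamma_params <- function(k, theta) {
  stopifnot(is.finite(k), is.finite(theta), k > 0, theta > 0)
  structure(list(k = k, theta = theta),
            class = c("gamma_params", "mfpd_params"))
}

#' @rdname distribution-params
#' @param mu,alpha,beta GND position, scale (> 0) and shape (> 0); for
#'   `beta_params`, `alpha` and `beta` are the two Beta shapes (> 0).
#' @export
gnd_params <- function(mu, alpha, beta) {
  stopifnot(is.finite(mu), is.finite(alpha), is.finite(beta),
            alpha > 0, beta > 0)
  structure(list(mu = mu, alpha = alpha, beta = beta),
            class = c("gnd_params", "mfpd_params"))
}

#' @rdname distribution-params
#' @export
beta_params <- function(alpha, beta) {
  stopifnot(is.finite(alpha), is.finite(beta), alpha > 0, beta > 0)
  structure(list(alpha = alpha, beta = beta),
            class = c("beta_params", "mfpd_params"))
}

#' @export
print.mfpd_params <- function(x, ...) {
  cat(sprintf("<%s> %s\n", class(x)[1L],
              paste(sprintf("%s=%.4g", names(unclass(x)),
                            unlist(unclass(x))), collapse = ", ")))
  invisible(x)
}

#' Density and distribution function of a fitted family
#'
#' Exact closed forms; zero density outside the family's support.
#'
#' @param params a `gamma_params`, `gnd_params` or `beta_params` object.
#' @param x evaluation points.
#' @return densities (`pdf_eval`) or cumulative probabilities
#'   (`cdf_eval`).
#' @export
pdf_eval <- function(params, x) UseMethod("pdf_eval")

#' @export
pdf_eval.gamma_params <- function(params, x)
  dgamma(x, shape = params$k, scale = params$theta)

#' @export
pdf_eval.beta_params <- function(params, x)
  dbeta(x, params$alpha, params$beta)

#' @export
pdf_eval.gnd_params <- function(params, x)
  dgnd(x, params$mu, params$alpha, params$beta)

#' @rdname pdf_eval
#' @export
cdf_eval <- function(params, x) UseMethod("cdf_eval")

#' @export
cdf_eval.gamma_params <- function(params, x)
  pgamma(x, shape = params$k, scale = params$theta)

#' @export
cdf_eval.beta_params <- function(params, x)
  pbeta(x, params$alpha, params$beta)

#' @export
cdf_eval.gnd_params <- function(params, x)
  pgnd(x, params$mu, params$alpha, params$beta)

#' Generalized normal density, distribution and random generation
#'
#' Three-parameter exponential-power family containing the Laplace
#' (`beta = 1`) and Gaussian (`beta = 2`, `alpha = sigma * sqrt(2)`)
#' distributions.
#'
#' @param x,q evaluation points; `n` number of draws.
#' @param mu position; `alpha` scale (> 0); `beta` shape (> 0).
#' @return `dgnd` densities, `pgnd` probabilities, `rgnd` draws.
#' @export
dgnd <- function(x, mu, alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  exp(log(beta) - log(2 * alpha) - lgamma(1 / beta) -
        (abs(x - mu) / alpha)^beta)
}

#' @rdname dgnd
#' @export
pgnd <- function(q, mu, alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  z <- (abs(q - mu) / alpha)^beta
  half <- pgamma(z, 1 / beta) / 2
  ifelse(q >= mu, 0.5 + half, 0.5 - half)
}

#' @rdname dgnd
#' @export
rgnd <- function(n, mu, alpha, beta) {
  g <- rgamma(n, shape = 1 / beta, rate = 1)
  mu + alpha * g^(1 / beta) * sample(c(-1, 1), n, replace = TRUE)
}

#' Gamma maximum-likelihood fit
#'
#' Solves `log(k) - digamma(k) = log(mean(x)) - mean(log(x))` by Newton
#' iteration; the scale follows as `mean(x) / k`.
#'
#' @param x positive samples (n >= 2, non-constant).
#' @param max_iter,tol Newton controls.
#' @return a `gamma_params` object.
#' @export
fit_gamma_mle <- function(x, max_iter = 100L, tol = 1e-12) {
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(x <= 0)) stop("Gamma samples must be positive", call. = FALSE)
  if (var(x) == 0) stop("degenerate (constant) sample", call. = FALSE)
  m <- mean(x)
  s <- log(m) - mean(log(x))
  if (s <= 0) stop("degenerate sample (log-moment gap <= 0)", call. = FALSE)
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in seq_len(max_iter)) {
    f <- log(k) - digamma(k) - s
    fp <- 1 / k - trigamma(k)
    step <- f / fp
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < tol * max(1, k)) { k <- k_new; break }
    k <- k_new
  }
  gamma_params(k, m / k)
}

# Gaussian-family moment ratio m1^2/m2 as a function of the GND shape
gnd_moment_ratio <- function(beta)
  exp(2 * lgamma(2 / beta) - lgamma(1 / beta) - lgamma(3 / beta))

#' Generalized normal maximum-likelihood fit
#'
#' Position by the sample median; shape by matching the absolute-moment
#' ratio `mean(|x - mu|)^2 / mean((x - mu)^2)` (a strictly increasing
#' function of the shape) with a bracketed root find on `[0.2, 10]`;
#' scale by its closed-form conditional MLE
#' `(beta * mean(|x - mu|^beta))^(1/beta)`.
#'
#' @param x real samples (n >= 3, non-constant).
#' @param beta_range search bracket for the shape.
#' @return a `gnd_params` object.
#' @export
fit_gnd_mle <- function(x, beta_range = c(0.2, 10)) {
  if (length(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (var(x) == 0) stop("degenerate (constant) sample", call. = FALSE)
  mu <- median(x)
  d <- abs(x - mu)
  m1 <- mean(d); m2 <- mean(d^2)
  if (m1 == 0 || m2 == 0) stop("degenerate sample around the median",
                               call. = FALSE)
  r <- m1^2 / m2
  f <- function(b) gnd_moment_ratio(b) - r
  lo <- beta_range[1L]; hi <- beta_range[2L]
  beta <- if (f(lo) > 0) lo
  else if (f(hi) < 0) hi
  else uniroot(f, c(lo, hi), tol = 1e-10)$root
  alpha <- (beta * mean(d^beta))^(1 / beta)
  if (alpha <= 0 || !is.finite(alpha))
    stop("degenerate scale estimate", call. = FALSE)
  gnd_params(mu, alpha, beta)
}

#' Conjugate prior for the Beta correlation model
#'
#' Prior density proportional to `B(alpha, beta)^K *
#' exp(-a * alpha) * exp(-b * beta)`.  The `exp(-a * alpha)` term
#' penalizes large `alpha`, preventing the valid-class correlation model
#' from collapsing toward a Dirac at 1 when the signal is clean.
#'
#' @param K integer >= 0, must stay below the sample count at fit time.
#' @param a,b exponential rates (>= 0).
#' @param eps boundary of the feasible region (`alpha, beta >= eps`).
#' @return a `beta_prior` object.
#' @export
beta_prior <- function(K = 0, a = 0.5, b = 0, eps = 1e-3) {
  stopifnot(K >= 0, a >= 0, b >= 0, eps > 0)
  structure(list(K = K, a = a, b = b, eps = eps), class = "beta_prior")
}

#' Beta maximum a posteriori fit via KKT Newton-Raphson
#'
#' Maximizes `alpha * (X - a) + beta * (Y - b) - (N - K) * log B(alpha,
#' beta)` (with `X = sum(log x)`, `Y = sum(log(1 - x))`) subject to
#' `alpha, beta >= eps`, by Newton-Raphson on the KKT system in
#' `z = (alpha, beta, mu1, mu2)`.  The Jacobian determinant is checked to
#' be strictly positive at every accepted step (it is provably so on the
#' feasible set), and steps are halved if a constraint would be violated.
#' Samples are clipped into `(delta, 1 - delta)` before taking logs.
#'
#' @param x samples in `[0, 1]` (n >= 2).
#' @param prior a [beta_prior].
#' @param max_iter,tol iteration cap and KKT residual tolerance.
#' @param delta clipping margin for the logs.
#' @return a `beta_params` object with attributes `residual`, `det_j`,
#'   `iterations`, `mu1`, `mu2`.
#' @export
fit_beta_map <- function(x, prior = beta_prior(), max_iter = 100L,
                         tol = 1e-8, delta = 1e-6) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (prior$K >= n)
    stop("prior pseudo-count K must be below the sample count",
         call. = FALSE)
  if (any(x < 0 | x > 1)) stop("samples must lie in [0, 1]", call. = FALSE)
  xc <- pmin(pmax(x, delta), 1 - delta)
  X <- sum(log(xc)); Y <- sum(log1p(-xc))
  nk <- n - prior$K
  eps <- prior$eps
  # method-of-moments start, clamped into the feasible region
  m <- mean(xc); v <- var(xc)
  v <- min(max(v, 1e-8), m * (1 - m) * 0.999)
  common <- m * (1 - m) / v - 1
  z <- c(max(m * common, eps * 2), max((1 - m) * common, eps * 2), 0, 0)
  kkt_F <- function(z) {
    al <- z[1L]; be <- z[2L]; m1 <- z[3L]; m2 <- z[4L]
    c((X - prior$a) - nk * (digamma(al) - digamma(al + be)) + m1,
      (Y - prior$b) - nk * (digamma(be) - digamma(al + be)) + m2,
      m1 * (eps - al),
      m2 * (eps - be))
  }
  kkt_J <- function(z) {
    al <- z[1L]; be <- z[2L]
    tg <- trigamma(al + be)
    rbind(c(nk * (tg - trigamma(al)), nk * tg, 1, 0),
          c(nk * tg, nk * (tg - trigamma(be)), 0, 1),
          c(-z[3L], 0, eps - al, 0),
          c(0, -z[4L], 0, eps - be))
  }
  fv <- kkt_F(z)
  det_j <- NA_real_
  it <- 0L
  while (it < max_iter && sqrt(sum(fv^2)) > tol) {
    it <- it + 1L
    J <- kkt_J(z)
    step <- tryCatch(solve(J, -fv), error = function(e) NULL)
    if (is.null(step)) stop("singular KKT Jacobian", call. = FALSE)
    lam <- 1
    repeat {
      z_new <- z + lam * step
      ok <- z_new[1L] >= eps && z_new[2L] >= eps &&
        z_new[3L] >= 0 && z_new[4L] >= 0
      if (ok) {
        dj <- det(kkt_J(z_new))
        ok <- is.finite(dj) && dj > 0
        if (ok) det_j <- dj
      }
      if (ok || lam < 1e-8) break
      lam <- lam / 2
    }
    if (lam < 1e-8)
      stop("KKT Newton-Raphson could not find a feasible step",
           call. = FALSE)
    z <- z_new
    fv <- kkt_F(z)
  }
  res <- sqrt(sum(fv^2))
  if (res > tol)
    stop(sprintf("Beta MAP did not converge (residual %.3g after %d iters)",
                 res, it), call. = FALSE)
  if (is.na(det_j)) det_j <- det(kkt_J(z))
  structure(beta_params(z[1L], z[2L]),
            residual = res, det_j = det_j, iterations = it,
            mu1 = z[3L], mu2 = z[4L])
}

#' Kolmogorov-Smirnov diagnostic against a fitted family
#'
#' One-sample KS test of the samples against the fitted distribution
#' function (Gamma/Beta via the regularized incomplete gamma/beta
#' functions, GND via the incomplete gamma function).  Used as a running
#' goodness-of-fit diagnostic; note the usual caveat that the parameters
#' were estimated from the same samples.
#'
#' @param x samples (n >= 5).
#' @param params a fitted parameter object.
#' @return list with `statistic` and `p_value`.
#' @export
ks_check <- function(x, params) {
  stopifnot(length(x) >= 5L)
  ht <- suppressWarnings(ks.test(x, function(q) cdf_eval(params, q)))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}
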