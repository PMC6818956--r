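#' Kullback-Leibler divergence between two Beta distributions
#'
#' Closed form via log-Beta and digamma functions.
#'
#' @param p,q `beta_params` objects (`D(p || q)`).
#' @return divergence in nats (>= 0).
#' @export
kld_beta <- function(p, q) {
  stopifnot(inherits(p, "beta_params"), inherits(q, "beta_params"))
  lbeta(q$alpha, q$beta) - lbeta(p$alpha, p$beta) +
    (p$alpha - q$alpha) * digamma(p$alpha) +
    (p$beta - q$beta) * digamma(p$beta) +
    (q$alpha - p$alpha + q$beta - p$beta) * digamma(p$alpha + p$beta)
}

#' Kullback-Leibler divergence between two Gamma distributions
#'
#' Closed form; invariant to a common rescaling of the two scales.
#'
#' @param p,q `gamma_params` objects (`D(p || q)`).
#' @return divergence in nats (>= 0).
#' @export
kld_gamma <- function(p, q) {
  stopifnot(inherits(p, "gamma_params"), inherits(q, "gamma_params"))
  (p$k - q$k) * digamma(p$k) - lgamma(p$k) + lgamma(q$k) +
    q$k * log(q$theta / p$theta) +
    p$k * (p$theta - q$theta) / q$theta
}

# log lower/upper incomplete gamma functions
log_inc_gamma_lower <- function(s, x) pgamma(x, s, log.p = TRUE) + lgamma(s)
log_inc_gamma_upper <- function(s, x)
  pgamma(x, s, log.p = TRUE, lower.tail = FALSE) + lgamma(s)

# cross term (*) of the GND divergence for integer shape bq >= 0:
# (ap/aq)^bq * bp/(2*Gamma(1/bp)) * int_R exp(-|t|^bp) |t + u|^bq dt.
# Even bq: binomial expansion and complete gamma integrals; odd bq:
# expansion split at t = 1 into lower/upper incomplete gamma pieces.
gnd_star_integer <- function(u, ap, bp, aq, bq) {
  stopifnot(bq == round(bq), bq >= 0, u > 0)
  m <- as.integer(bq)
  lk2 <- bq * log(ap / aq) + log(bp) - log(2) - lgamma(1 / bp) +
    (m + 1) * log(u)
  xi <- u^bp
  lxi <- bp * log(u)
  k <- 0:m
  s <- (k + 1) / bp
  lch <- lchoose(m, k)
  if (m %% 2L == 0L) {
    keep <- k %% 2L == 0L                    # coefficient 2, else 0
    sum(exp(lk2 + log(2) + lch[keep] + lgamma(s[keep]) -
              log(bp) - s[keep] * lxi))
  } else {
    inner <- k %% 2L == 0L                   # [0, 1] piece, coefficient 2
    outer <- k %% 2L == 1L                   # [1, Inf) piece, coefficient 2
    tot <- 0
    if (any(inner))
      tot <- tot + sum(exp(lk2 + log(2) + lch[inner] +
                             log_inc_gamma_lower(s[inner], xi) -
                             log(bp) - s[inner] * lxi))
    if (any(outer))
      tot <- tot + sum(exp(lk2 + log(2) + lch[outer] +
                             log_inc_gamma_upper(s[outer], xi) -
                             log(bp) - s[outer] * lxi))
    tot
  }
}

# log of the analytic prefactor k2 = (ap/aq)^bq * bp/(2 Gamma(1/bp)) *
# u^(bq+1); its bq-dependence is known exactly, so only the remaining
# integral needs interpolation at non-integer bq
gnd_log_k2 <- function(u, ap, bp, aq, bq)
  bq * log(ap / aq) + log(bp) - log(2) - lgamma(1 / bp) +
    (bq + 1) * log(u)

# cross-term integral I(bq) = int_R exp(-xi |t|^bp) |t + 1|^bq dt,
# strictly increasing in bq (the prefactor is held fixed)
gnd_star_intg <- function(u, ap, bp, aq, bq)
  gnd_star_integer(u, ap, bp, aq, bq) / exp(gnd_log_k2(u, ap, bp, aq, bq))

# (*) for arbitrary real bq: exact at integers; otherwise the monotone
# integral is interpolated (shape-preserving PCHIP) across bracketing
# integers and multiplied by the exact prefactor
gnd_star <- function(u, ap, bp, aq, bq, u_min = 1e-8) {
  if (u < u_min)
    return(exp(bq * log(ap / aq) + lgamma((bq + 1) / bp) - lgamma(1 / bp)))
  if (abs(bq - round(bq)) < 1e-12)
    return(gnd_star_integer(u, ap, bp, aq, round(bq)))
  # non-integer shape: interpolate the ratio of the exact cross term to
  # the equal-mean closed form across bracketing integers.  The ratio
  # tends to 1 as the offset vanishes and strips the dominant
  # gamma-function curvature, so its interpolation error is small; the
  # equal-mean structure is then restored exactly at the target shape.
  log_em <- function(b)
    b * log(ap / aq) + lgamma((b + 1) / bp) - lgamma(1 / bp)
  fl <- floor(bq); ce <- ceiling(bq)
  nodes <- unique(pmax(0, c(fl - 1, fl, ce, ce + 1)))
  vals <- vapply(nodes, function(b)
    log(gnd_star_integer(u, ap, bp, aq, b)) - log_em(b), numeric(1))
  est <- exp(log_em(bq) + pracma::pchip(nodes, vals, bq))
  # the true fixed-prefactor integral is increasing in the shape, so the
  # estimate is clamped into the integer-neighbor bracket it must obey
  lk2 <- gnd_log_k2(u, ap, bp, aq, bq)
  i_lo <- gnd_star_intg(u, ap, bp, aq, fl)
  i_hi <- gnd_star_intg(u, ap, bp, aq, ce)
  exp(lk2) * min(max(est / exp(lk2), i_lo), i_hi)
}

#' Kullback-Leibler divergence between two generalized normal
#' distributions
#'
#' Semi-analytic evaluation valid for unequal positions.  The divergence
#' splits into closed-form terms plus a cross term; the cross term has an
#' exact finite expression (binomial expansion into complete or
#' incomplete gamma integrals) whenever the second shape is a
#' non-negative integer, and is monotonously increasing in that shape, so
#' non-integer shapes are evaluated by monotone interpolation between the
#' bracketing integer evaluations.  Near-equal positions switch to the
#' equal-mean closed form.
#'
#' @param p,q `gnd_params` objects (`D(p || q)`).
#' @param u_min threshold on `|mu_p - mu_q| / alpha_p` below which the
#'   equal-mean closed form is used.
#' @return divergence in nats (>= 0).
#' @export
kld_gnd <- function(p, q, u_min = 1e-8) {
  stopifnot(inherits(p, "gnd_params"), inherits(q, "gnd_params"))
  base <- log(p$beta / q$beta) + log(q$alpha / p$alpha) +
    lgamma(1 / q$beta) - lgamma(1 / p$beta) - 1 / p$beta
  u <- abs(p$mu - q$mu) / p$alpha
  base + gnd_star(u, p$alpha, p$beta, q$alpha, q$beta, u_min = u_min)
}

#' Divergence between two fitted parameter objects
#'
#' Dispatches on the family; `reverse = TRUE` gives the reverse KLD
#' `D(q || p)`.
#'
#' @param p,q parameter objects of the same family.
#' @param reverse use the reverse divergence.
#' @return divergence in nats.
#' @export
kld <- function(p, q, reverse = FALSE) {
  if (reverse) { tmp <- p; p <- q; q <- tmp }
  if (inherits(p, "gamma_params")) kld_gamma(p, q)
  else if (inherits(p, "gnd_params")) kld_gnd(p, q)
  else if (inherits(p, "beta_params")) kld_beta(p, q)
  else stop("unsupported parameter family", call. = FALSE)
}

#' Capped, normalized fusion weights from per-feature divergences
#'
#' The largest divergence is capped at twice the sum of the others, so
#' that after normalization no single feature can carry more than 2/3 of
#' the decision.  Ties for the maximum are broken toward the first
#' feature (order `s`, `a`, `c`).  When every divergence is zero the
#' weights fall back to uniform.
#'
#' @param klds numeric vector of divergences (>= 0), typically length 3
#'   named `s`, `a`, `c`.
#' @return weights summing to 1, each in `[0, 2/3]` (or uniform).
#' @export
#' @examples
#' modified_weights(c(s = 10, a = 1, c = 1))  # 2/3, 1/6, 1/6
modified_weights <- function(klds) {
  stopifnot(is.numeric(klds), length(klds) >= 2L)
  if (any(!is.finite(klds)) || any(klds < 0))
    stop("divergences must be finite and non-negative", call. = FALSE)
  d <- klds
  i_star <- which.max(d)
  d[i_star] <- min(d[i_star], 2 * sum(d[-i_star]))
  tot <- sum(d)
  if (tot == 0) return(rep(1 / length(d), length(d)) |>
                         stats::setNames(names(klds)))
  w <- d / tot
  names(w) <- names(klds)
  w
}
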