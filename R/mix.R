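#' Mix a noise record into a clean record at a target SNR
#'
#' Builds `clean + g * noise` with the gain `g` chosen so that the
#' whole-record power ratio of the two added components equals the target:
#' `10*log10(mean(clean^2) / mean((g*noise)^2)) = snr_db`.  An infinite
#' `snr_db` is the zero-noise sentinel and returns the clean record
#' unchanged.
#'
#' If sampling rates differ the noise is resampled by polyphase filtering;
#' if the noise is shorter than the signal it is tiled with a seeded
#' random circular offset; if longer it is trimmed.
#'
#' @param clean,noise [ecg_record] objects.
#' @param snr_db target signal-to-noise ratio in dB (`Inf` = no noise).
#' @param kind optional label stored in the output record id.
#' @param seed integer seed for the circular tiling offset.
#' @return an [ecg_record] of the same length and rate as `clean`.
#' @export
#' @examples
#' clean <- ecg_record(sin(2 * pi * 7 * seq(0, 2, by = 1/250)), 250)
#' noise <- ecg_record(rnorm(501), 250)
#' noisy <- mix_noise(clean, noise, snr_db = 6)
mix_noise <- function(clean, noise, snr_db, kind = "noise", seed = 1L) {
  stopifnot(inherits(clean, "ecg_record"), inherits(noise, "ecg_record"),
            length(snr_db) == 1L)
  if (is.na(snr_db)) stop("snr_db must not be NA", call. = FALSE)
  if (is.infinite(snr_db) && snr_db > 0) return(clean)
  if (!is.finite(snr_db)) stop("snr_db must be finite or +Inf", call. = FALSE)
  x <- clean$samples
  v <- noise$samples
  if (!isTRUE(all.equal(noise$fs, clean$fs))) {
    r <- rational_approx(clean$fs / noise$fs)
    v <- as.numeric(signal::resample(v, r[1L], r[2L]))
  }
  n <- length(x)
  if (length(v) < n) {
    reps <- ceiling(n / length(v))
    v <- rep(v, reps)
  }
  off <- with_seed(seed, sample.int(length(v), 1L)) - 1L
  v <- v[((seq_len(n) - 1L + off) %% length(v)) + 1L]
  p_sig <- mean(x^2)
  p_noise <- mean(v^2)
  if (p_noise <= 0) stop("noise record has zero power", call. = FALSE)
  g <- sqrt(p_sig / (p_noise * 10^(snr_db / 10)))
  out <- ecg_record(x + g * v, clean$fs,
                    sprintf("%s+%s@%gdB", clean$record_id, kind, snr_db))
  attr(out, "noise_gain") <- g
  attr(out, "noise_component") <- g * v
  out
}

# small continued-fraction rational approximation p/q of a ratio
rational_approx <- function(r, tol = 1e-9, max_den = 10000L) {
  stopifnot(is.finite(r), r > 0)
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; x <- r
  repeat {
    a <- floor(x)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - r) < tol * r) break
    frac <- x - a
    if (frac < 1e-12) break
    x <- 1 / frac
  }
  c(as.integer(round(p1)), as.integer(round(q1)))
}

#' Build the SNR-grid benchmark for one record and noise kind
#'
#' Produces one noisy copy of `clean` per grid level (default -6 to 24 dB
#' in 6 dB steps), all sharing the same tiled noise realization so the
#' family differs only by the noise gain.
#'
#' @param clean an [ecg_record].
#' @param noise an [ecg_record] holding the noise recording.
#' @param snr_grid SNR levels in dB.
#' @param kind label for the noise kind.
#' @param seed tiling seed shared across the grid.
#' @return named list of [ecg_record]s, one per SNR level.
#' @export
build_noise_grid <- function(clean, noise, snr_grid = seq(-6, 24, by = 6),
                             kind = "noise", seed = 1L) {
  out <- lapply(snr_grid, function(s)
    mix_noise(clean, noise, s, kind = kind, seed = seed))
  names(out) <- sprintf("%gdB", snr_grid)
  out
}
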