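#' Simulate an annotated single-lead ECG
#'
#' Each beat is a sum of Gaussian bumps (P, Q, R, S, T) placed relative to
#' an R time; the returned annotations are the R times.  RR intervals are
#' drawn from a truncated normal heart-rate model, and per-beat wave
#' amplitudes carry a relative morphology jitter.  Output is deterministic
#' for a given seed.
#'
#' @param duration_s record length in seconds.
#' @param mean_hr,hr_sd mean heart rate and its standard deviation (bpm).
#' @param fs sampling frequency (Hz, >= 250).
#' @param amplitudes named vector of wave amplitudes in mV
#'   (`P`, `Q`, `R`, `S`, `T`).
#' @param widths_ms named vector of Gaussian standard deviations in ms.
#' @param centers_ms named vector of wave centers relative to R in ms.
#' @param morphology_jitter relative sd of per-beat amplitude variation.
#' @param noise_rms RMS of the additive white measurement-noise floor in
#'   mV (sensor and quantization noise; every real acquisition has one).
#' @param seed integer seed.
#' @return list with elements `record` ([ecg_record]) and
#'   `annotations` ([annotation_set]).
#' @export
#' @examples
#' sim <- simulate_ecg(duration_s = 30, mean_hr = 60, hr_sd = 0, seed = 1)
#' length(sim$annotations$beat_times)
simulate_ecg <- function(duration_s = 60, mean_hr = 70, hr_sd = 3,
                         fs = 360,
                         amplitudes = c(P = 0.15, Q = -0.1, R = 1.2,
                                        S = -0.25, T = 0.35),
                         widths_ms = c(P = 22, Q = 9, R = 11, S = 9, T = 60),
                         centers_ms = c(P = -190, Q = -28, R = 0,
                                        S = 32, T = 280),
                         morphology_jitter = 0.05, noise_rms = 0.02,
                         seed = 1L) {
  stopifnot(duration_s > 0, mean_hr > 20, mean_hr < 300, fs >= 250,
            all(widths_ms > 0))
  waves <- names(amplitudes)
  stopifnot(setequal(waves, c("P", "Q", "R", "S", "T")),
            all(waves %in% names(widths_ms)),
            all(waves %in% names(centers_ms)))
  n <- round(duration_s * fs)
  with_seed(seed, {
    # R times from a truncated-normal instantaneous heart rate
    r_times <- numeric(0)
    t_cur <- 0.5
    while (t_cur < duration_s - 0.3) {
      r_times <- c(r_times, t_cur)
      hr <- rnorm(1L, mean_hr, hr_sd)
      hr <- min(max(hr, 20.1), 299.9)
      t_cur <- t_cur + 60 / hr
    }
    x <- numeric(n)
    t_axis <- (seq_len(n) - 1L) / fs
    for (rt in r_times) {
      amp_jit <- amplitudes * (1 + morphology_jitter * rnorm(length(waves)))
      for (w in waves) {
        mu <- rt + centers_ms[[w]] / 1000
        sdv <- widths_ms[[w]] / 1000
        lo <- max(1L, floor((mu - 5 * sdv) * fs) + 1L)
        hi <- min(n, ceiling((mu + 5 * sdv) * fs) + 1L)
        if (lo > hi) next
        idx <- lo:hi
        x[idx] <- x[idx] + amp_jit[[w]] *
          exp(-0.5 * ((t_axis[idx] - mu) / sdv)^2)
      }
    }
    if (noise_rms > 0) x <- x + rnorm(n, sd = noise_rms)
    list(record = ecg_record(x, fs, sprintf("sim%ds", round(duration_s))),
         annotations = annotation_set(r_times, "N"))
  })
}

#' Simulate one of the three benchmark noise classes
#'
#' All kinds are returned zero-mean with unit RMS, so that [mix_noise]
#' alone controls the SNR.
#' \describe{
#'   \item{`baseline_wander`}{sum of sinusoids below 0.5 Hz with random
#'     phases plus a heavily smoothed random walk; essentially all power
#'     below 1 Hz.}
#'   \item{`muscle`}{white noise band-passed 15--120 Hz (capped below
#'     Nyquist): broadband electromyographic artifact.}
#'   \item{`electrode_motion`}{sparse Poisson bursts of low-frequency
#'     lobes plus occasional smoothed step offsets: transient contact
#'     artifact.}
#' }
#'
#' @param kind one of `"baseline_wander"`, `"muscle"`,
#'   `"electrode_motion"`.
#' @param duration_s length in seconds.
#' @param fs sampling frequency (Hz).
#' @param seed integer seed.
#' @param burst_rate electrode-motion burst rate per second.
#' @param step_rate electrode-motion step-offset rate per second.
#' @return numeric amplitude series of length `round(duration_s * fs)`.
#' @export
simulate_noise <- function(kind = c("baseline_wander", "muscle",
                                    "electrode_motion"),
                           duration_s, fs, seed = 1L,
                           burst_rate = 0.4, step_rate = 0.08) {
  kind <- match.arg(kind)
  n <- round(duration_s * fs)
  stopifnot(n >= 2L, fs > 0)
  x <- with_seed(seed, switch(
    kind,
    baseline_wander = {
      t_axis <- (seq_len(n) - 1L) / fs
      freqs <- runif(8L, 0.05, 0.45)
      amps <- runif(8L, 0.3, 1)
      phases <- runif(8L, 0, 2 * pi)
      s <- rowSums(sapply(seq_along(freqs), function(k)
        amps[k] * sin(2 * pi * freqs[k] * t_axis + phases[k])))
      walk <- cumsum(rnorm(n)) / sqrt(n)
      w <- max(3L, round(fs))                 # 1-s moving average
      walk <- stats::filter(walk, rep(1 / w, w), sides = 2L)
      walk[is.na(walk)] <- 0
      s + 2 * as.numeric(walk)
    },
    muscle = {
      hi <- min(120, 0.45 * fs)
      bf <- signal::butter(4L, c(15, hi) / (fs / 2), type = "pass")
      as.numeric(signal::filtfilt(bf, rnorm(n)))
    },
    electrode_motion = {
      s <- numeric(n)
      n_bursts <- rpois(1L, burst_rate * duration_s)
      if (n_bursts > 0) for (b in seq_len(n_bursts)) {
        ctr <- runif(1L, 0, duration_s)
        dur <- runif(1L, 0.5, 2)
        f0 <- runif(1L, 0.8, 3)
        amp <- runif(1L, 0.5, 2)
        ph <- runif(1L, 0, 2 * pi)
        t_axis <- (seq_len(n) - 1L) / fs
        env <- exp(-0.5 * ((t_axis - ctr) / (dur / 4))^2)
        s <- s + amp * env * sin(2 * pi * f0 * (t_axis - ctr) + ph)
      }
      n_steps <- rpois(1L, step_rate * duration_s)
      if (n_steps > 0) for (b in seq_len(n_steps)) {
        pos <- sample.int(n, 1L)
        lvl <- runif(1L, -1.5, 1.5)
        ramp <- max(2L, round(0.05 * fs))     # 50-ms edge
        s[pos:n] <- s[pos:n] + lvl
        lo <- max(1L, pos - ramp %/% 2L)
        hi2 <- min(n, pos + ramp %/% 2L)
        s[lo:hi2] <- s[lo:hi2] - lvl +
          lvl * seq(0, 1, length.out = hi2 - lo + 1L)
      }
      s
    }))
  x <- x - mean(x)
  r <- sqrt(mean(x^2))
  if (r > 0) x <- x / r
  x
}

#' Synthetic noise as an [ecg_record]
#'
#' Convenience wrapper around [simulate_noise] for use with [mix_noise].
#' @inheritParams simulate_noise
#' @return an [ecg_record] (unit RMS).
#' @export
simulate_noise_record <- function(kind, duration_s, fs, seed = 1L, ...) {
  ecg_record(simulate_noise(kind, duration_s, fs, seed = seed, ...),
             fs, paste0("sim_", kind))
}
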