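#' Pan-Tompkins QRS detector (bootstrap labeler)
#'
#' Classic chain -- band-pass (5--15 Hz), five-point derivative,
#' squaring, 150-ms moving-window integration -- followed by dual
#' adaptive amplitude thresholds with a 200-ms refractory period and an
#' RR-based search-back at half threshold.  Deterministic, and invariant
#' to amplitude scaling (thresholds adapt to the signal level).  Used to
#' label the first validated beats during the detector's heating-up
#' phase, and as a fallback when heating fails.
#'
#' @param record an [ecg_record].
#' @return numeric vector of beat times in seconds (possibly empty).
#' @export
pan_tompkins_detect <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  fs <- record$fs
  n <- length(x)
  if (n < 2 * fs) return(numeric(0))
  ord <- max(4L, 2L * round(0.12 * fs))
  lp <- design_fir("lowpass", fs, cutoff = 15, order = ord)
  hp <- design_fir("highpass", fs, cutoff = 5, order = ord)
  bp <- apply_fir(apply_fir(x, lp), hp)
  dk <- c(1, 2, 0, -2, -1) * fs / 8
  attr(dk, "delay") <- 2
  dv <- apply_fir(bp, dk)
  sq <- dv^2
  wl <- max(2L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / wl, wl), sides = 2L))
  mwi[is.na(mwi)] <- 0
  refr <- round(0.200 * fs)
  # local maxima of the integrated signal, refractory-thinned
  pk <- find_candidates(structure(list(sf = mwi, fs = fs),
                                  class = "filtered_signals"),
                        floor_rel = 1e-6, min_spacing_ms = 200)
  if (!length(pk)) return(numeric(0))
  spki <- max(mwi[seq_len(min(n, round(2 * fs)))]) * 0.5
  npki <- mean(mwi[seq_len(min(n, round(2 * fs)))]) * 0.5
  thr <- function() npki + 0.25 * (spki - npki)
  beats <- integer(0)
  rr_hist <- numeric(0)
  miss_from <- pk[1L]
  for (p in pk) {
    v <- mwi[p]
    if (v > thr()) {
      if (length(beats) && (p - beats[length(beats)]) < refr) next
      beats <- c(beats, p)
      spki <- 0.125 * v + 0.875 * spki
      if (length(beats) > 1L)
        rr_hist <- tail(c(rr_hist, diff(tail(beats, 2L))), 8L)
    } else {
      npki <- 0.125 * v + 0.875 * npki
      # search-back: expected beat overdue by 1.66 * average RR
      if (length(beats) && length(rr_hist) >= 2L &&
          (p - beats[length(beats)]) > 1.66 * mean(rr_hist) &&
          v > 0.5 * thr()) {
        beats <- c(beats, p)
        spki <- 0.25 * v + 0.75 * spki
        rr_hist <- tail(c(rr_hist, diff(tail(beats, 2L))), 8L)
      }
    }
  }
  if (!length(beats)) return(numeric(0))
  # refine each beat to the band-passed energy apex near the MWI peak
  half <- round(0.10 * fs)
  refined <- vapply(beats, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    lo + which.max(abs(bp[lo:hi])) - 1L
  }, numeric(1))
  refined <- sort(unique(refined))
  refined[c(TRUE, diff(refined) >= refr)] / fs
}
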