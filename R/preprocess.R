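#' Design a linear-phase FIR filter
#'
#' Lowpass and highpass filters are equiripple (Remez exchange /
#' Parks-McClellan, via [signal::remez]); the derivative filter is a
#' Remez lowpass at the derivative cutoff convolved with a scaled central
#' difference (an antisymmetric, linear-phase band-limited
#' differentiator); the smoother is a plain moving average.
#'
#' @param kind one of `"lowpass"`, `"highpass"`, `"derivative"`,
#'   `"smoother"`.
#' @param fs sampling frequency (Hz).
#' @param cutoff cutoff frequency in Hz (ignored for `smoother`).
#' @param order filter order (taps - 1); forced even so the group delay
#'   is an integer number of samples.  Ignored for `smoother`.
#' @param length_ms smoother length in ms (`smoother` only).
#' @return numeric coefficient vector with attribute `delay` (group
#'   delay in samples).
#' @export
#' @examples
#' h <- design_fir("lowpass", fs = 360, cutoff = 19, order = 92)
#' all.equal(h, rev(h))  # linear phase
design_fir <- function(kind = c("lowpass", "highpass", "derivative",
                                "smoother"),
                       fs, cutoff = NULL, order = NULL, length_ms = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(fs), fs > 0)
  ny <- fs / 2
  if (kind == "smoother") {
    stopifnot(!is.null(length_ms), length_ms > 0)
    l <- max(1L, round(length_ms / 1000 * fs))
    h <- rep(1 / l, l)
    attr(h, "delay") <- (l - 1) / 2
    return(h)
  }
  stopifnot(!is.null(cutoff), !is.null(order), order >= 2)
  if (cutoff >= ny)
    stop(sprintf("cutoff %g Hz is not below Nyquist (%g Hz)", cutoff, ny),
         call. = FALSE)
  order <- 2L * round(order / 2)              # type-I symmetric
  h <- switch(kind,
    lowpass = {
      tw <- max(3, 0.3 * cutoff)
      if (cutoff + tw >= ny) tw <- 0.45 * (ny - cutoff)
      fir_remez(order, c(0, cutoff, cutoff + tw, ny) / ny, c(1, 1, 0, 0),
                w = c(1, 10))
    },
    highpass = {
      tw <- max(2, 0.4 * cutoff)
      lo <- max(cutoff - tw, 0.2 * cutoff)
      g <- fir_remez(order, c(0, lo, cutoff, ny) / ny, c(0, 0, 1, 1),
                     w = c(10, 1))
      g - mean(g)               # pin the DC gain to exactly zero
    },
    derivative = {
      lp <- fir_remez(order, {
        tw <- max(3, 0.3 * cutoff)
        if (cutoff + tw >= ny) tw <- 0.45 * (ny - cutoff)
        c(0, cutoff, cutoff + tw, ny) / ny
      }, c(1, 1, 0, 0), w = c(1, 10))
      # scaled central difference: antisymmetric, exact linear phase
      as.numeric(stats::convolve(lp, rev(c(fs / 2, 0, -fs / 2)),
                                 type = "open"))
    })
  attr(h, "delay") <- (length(h) - 1) / 2
  h
}

fir_remez <- function(order, f, a, w = NULL) {
  res <- tryCatch(
    if (is.null(w)) signal::remez(order, f, a)
    else signal::remez(order, f, a, w = w),
    error = function(e)
      stop(sprintf(paste0("FIR design failed (order %d, bands %s): %s"),
                   order, paste(signif(f, 3), collapse = "/"),
                   conditionMessage(e)), call. = FALSE))
  as.numeric(res)
}

# zero-phase FIR application: FFT convolution then group-delay shift so
# the output is aligned with the input axis; edges are replicate-padded
# (a constant record stays constant through any DC-gain filter, so the
# band-pass removes offsets without boundary transients)
apply_fir <- function(x, h) {
  d <- attr(h, "delay")
  if (is.null(d)) d <- (length(h) - 1) / 2
  l <- length(h)
  xp <- c(rep(x[1L], l), x, rep(x[length(x)], l))
  full <- as.numeric(stats::convolve(xp, rev(as.numeric(h)), type = "open"))
  idx <- seq_len(length(x)) + l + round(d)
  full[idx]
}

#' Preprocess a record into the amplitude and slope signals
#'
#' Builds the two working signals: `sa`, the band-passed ECG
#' (lowpass then highpass), read for the amplitude feature; and `sf`, the
#' squared-slope transform (square of `sa`, band-limited derivative,
#' moving-average smoother, clipped at zero), read for the slope feature.
#' All FIR group delays are compensated so `sa` and `sf` are aligned with
#' the raw time axis.
#'
#' Filter orders in the configuration are stated at `ref_fs` and scaled
#' proportionally to the record's rate (rounded to even), preserving the
#' impulse-response duration in seconds.
#'
#' @param record an [ecg_record].
#' @param config an [mfpd_config].
#' @return a `filtered_signals` list: `sa`, `sf`, `fs`, `delay_sa`,
#'   `delay_sf` (delays already compensated, reported in samples).
#' @export
preprocess <- function(record, config = mfpd_config()) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  scale_ord <- function(o) max(4L, 2L * round(o * fs / config$ref_fs / 2))
  lp <- design_fir("lowpass", fs, config$lp_cutoff, scale_ord(config$lp_order))
  hp <- design_fir("highpass", fs, config$hp_cutoff, scale_ord(config$hp_order))
  dv <- design_fir("derivative", fs, config$deriv_cutoff,
                   scale_ord(config$deriv_order))
  sm <- design_fir("smoother", fs, length_ms = config$smooth_ms)
  min_len <- length(lp) + length(hp)
  if (length(record$samples) <= min_len)
    stop(sprintf("record too short (%d samples) for the filter chain (%d)",
                 length(record$samples), min_len), call. = FALSE)
  sa <- apply_fir(apply_fir(record$samples, lp), hp)
  sf <- if (config$chain_order == "square_first") {
    apply_fir(apply_fir(sa^2, dv), sm)
  } else {
    apply_fir(apply_fir(sa, dv), sm)^2
  }
  sf <- pmax(sf, 0)
  structure(list(sa = sa, sf = sf, fs = fs,
                 delay_sa = attr(lp, "delay") + attr(hp, "delay"),
                 delay_sf = attr(dv, "delay") + attr(sm, "delay")),
            class = "filtered_signals")
}

#' @export
print.filtered_signals <- function(x, ...) {
  cat(sprintf("<filtered_signals> %d samples @ %g Hz\n", length(x$sa), x$fs))
  invisible(x)
}

#' Select QRS candidates as local maxima of the slope signal
#'
#' Every local maximum of `sf` is a potential QRS; plateaus contribute
#' their center index.  Maxima below `floor_rel * max(sf)` are
#' suppressed (they are numerically flat ripple, not waves), and an
#' optional minimum spacing keeps only the larger of two close maxima.
#'
#' @param fsig a `filtered_signals` object from [preprocess].
#' @param floor_rel relative amplitude floor (default `1e-6`).
#' @param min_spacing_ms minimum spacing between candidates
#'   (default 0 = keep all).
#' @return integer vector of candidate sample indices (1-based).
#' @export
find_candidates <- function(fsig, floor_rel = 1e-6, min_spacing_ms = 0) {
  sf <- fsig$sf
  n <- length(sf)
  if (n < 3L) return(integer(0))
  r <- rle(sf)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_max <- logical(k)
  for (j in seq_len(k)) {
    left_ok <- j == 1L || r$values[j - 1L] < r$values[j]
    right_ok <- j < k && r$values[j + 1L] < r$values[j]
    # interior maxima only: runs touching the record edge are not peaks
    is_max[j] <- j > 1L && left_ok && right_ok
  }
  idx <- as.integer(floor((starts[is_max] + ends[is_max]) / 2))
  if (length(idx)) {
    floor_abs <- floor_rel * max(sf)
    idx <- idx[sf[idx] >= floor_abs & sf[idx] > 0]
  }
  if (min_spacing_ms > 0 && length(idx) > 1L) {
    min_gap <- round(min_spacing_ms / 1000 * fsig$fs)
    keep <- integer(0)
    for (i in idx) {
      if (length(keep) && i - keep[length(keep)] < min_gap) {
        if (sf[i] > sf[keep[length(keep)]]) keep[length(keep)] <- i
      } else keep <- c(keep, i)
    }
    idx <- keep
  }
  idx
}
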