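#' Extract the correlation window around a candidate
#'
#' Returns `L = round(0.001 * win_ms * fs)` raw samples centered
#' `win_offset_ms` before the candidate instant: the QRS complex mostly
#' precedes the slope-transform peak, so the window is shifted left.
#'
#' @param record an [ecg_record] (or plain numeric vector).
#' @param t candidate sample index (1-based).
#' @param fs sampling frequency (required when `record` is a vector).
#' @param win_ms window length (ms).
#' @param win_offset_ms center shift before `t` (ms).
#' @return numeric vector of length `L`.
#' @export
extract_window <- function(record, t, fs = NULL, win_ms = 50,
                           win_offset_ms = 20) {
  if (inherits(record, "ecg_record")) {
    x <- record$samples
    fs <- record$fs
  } else {
    x <- record
    stopifnot(!is.null(fs))
  }
  l <- round(win_ms / 1000 * fs)
  ctr <- t - round(win_offset_ms / 1000 * fs)
  start <- ctr - floor(l / 2)
  if (start < 1L || start + l - 1L > length(x))
    stop("window [", start, ", ", start + l - 1L,
         "] crosses the record boundary", call. = FALSE)
  x[start:(start + l - 1L)]
}

#' Absolute Bravais-Pearson correlation
#'
#' `|r(x, y)|` in `[0, 1]`.  If either input has zero variance the
#' correlation is undefined; 0 is returned with attribute
#' `zero_variance = TRUE`.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return scalar in `[0, 1]`.
#' @export
abs_pearson <- function(x, y) {
  if (length(x) != length(y))
    stop("inputs must have equal length", call. = FALSE)
  stopifnot(length(x) >= 2L)
  if (var(x) == 0 || var(y) == 0)
    return(structure(0, zero_variance = TRUE))
  abs(cor(x, y))
}

#' Beat template container
#'
#' @param waveform numeric amplitude series (one correlation window).
#' @param n_updates update counter.
#' @return a `beat_template` object.
#' @export
beat_template <- function(waveform, n_updates = 0L) {
  stopifnot(is.numeric(waveform), all(is.finite(waveform)))
  structure(list(waveform = as.numeric(waveform),
                 n_updates = as.integer(n_updates)),
            class = "beat_template")
}

#' Initialize a beat template from labelled candidate windows
#'
#' Segments are aligned to the first by the integer lag (bounded by
#' `align_max_ms`) maximizing cross-correlation, then averaged pointwise.
#' Samples an aligned segment cannot supply at the edges are taken from
#' the reference segment.
#'
#' @param segments list of equal-length numeric vectors (>= 1).
#' @param fs sampling frequency (Hz).
#' @param align_max_ms alignment lag bound (ms).
#' @return a [beat_template].
#' @export
init_template <- function(segments, fs, align_max_ms = 10) {
  if (!length(segments)) stop("no segments to average", call. = FALSE)
  l <- length(segments[[1L]])
  stopifnot(all(vapply(segments, length, 1L) == l))
  ref <- segments[[1L]]
  max_lag <- min(l - 1L, round(align_max_ms / 1000 * fs))
  aligned <- lapply(segments, function(seg) {
    best_lag <- 0L; best <- -Inf
    for (lag in -max_lag:max_lag) {
      i1 <- max(1L, 1L + lag):min(l, l + lag)
      i2 <- i1 - lag
      sc <- sum(ref[i1] * seg[i2])
      if (sc > best) { best <- sc; best_lag <- lag }
    }
    out <- ref                                 # edge fill from reference
    i1 <- max(1L, 1L + best_lag):min(l, l + best_lag)
    out[i1] <- seg[i1 - best_lag]
    out
  })
  beat_template(Reduce(`+`, aligned) / length(aligned),
                n_updates = length(aligned))
}

#' Blend a new candidate window into a template
#'
#' `waveform' = keep * waveform + (1 - keep) * segment`; the default
#' keeps 80 percent of the previous template.
#'
#' @param tpl a [beat_template].
#' @param segment numeric vector, same length as the template.
#' @param keep retention weight in `[0, 1]`.
#' @return the updated [beat_template].
#' @export
update_template <- function(tpl, segment, keep = 0.8) {
  stopifnot(inherits(tpl, "beat_template"))
  if (length(segment) != length(tpl$waveform))
    stop("segment length does not match template", call. = FALSE)
  beat_template(keep * tpl$waveform + (1 - keep) * segment,
                tpl$n_updates + 1L)
}

#' Compute the feature vector of one candidate
#'
#' `s` is the squared-slope signal at `t`, `a` the band-passed amplitude
#' at `t`, and `c` the absolute correlation between the candidate's raw
#' window and the current valid-beat template.
#'
#' @param record an [ecg_record].
#' @param fsig a `filtered_signals` object for the same record.
#' @param t candidate sample index.
#' @param template_h1 the valid-beat [beat_template].
#' @param config an [mfpd_config].
#' @return list `(t, s, a, c)`, or `NULL` when the correlation window
#'   crosses a record edge (boundary candidates are dropped).
#' @export
extract_features <- function(record, fsig, t, template_h1,
                             config = mfpd_config()) {
  win <- tryCatch(
    extract_window(record, t, win_ms = config$win_ms,
                   win_offset_ms = config$win_offset_ms),
    error = function(e) NULL)
  if (is.null(win)) return(NULL)
  list(t = t,
       s = fsig$sf[t],
       a = fsig$sa[t],
       c = as.numeric(abs_pearson(win, template_h1$waveform)),
       window = win)
}
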