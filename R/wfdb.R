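#' ECG record container
#'
#' @param samples numeric amplitude series in millivolts.
#' @param fs sampling frequency in Hz (> 0).
#' @param record_id text label.
#' @return an `ecg_record` object.
#' @export
ecg_record <- function(samples, fs, record_id = "record") {
  stopifnot(is.numeric(samples), length(samples) >= 1L,
            is.numeric(fs), length(fs) == 1L, fs > 0)
  if (!all(is.finite(samples)))
    stop("record samples must be finite", call. = FALSE)
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs),
                 record_id = as.character(record_id)),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s'> %d samples @ %g Hz (%.1f s)\n",
              x$record_id, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Beat annotation container
#'
#' @param beat_times strictly increasing event times in seconds.
#' @param labels per-beat symbol (recycled if length 1).
#' @return an `annotation_set` object.
#' @export
annotation_set <- function(beat_times, labels = "N") {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) && any(diff(beat_times) <= 0))
    stop("beat times must be strictly increasing", call. = FALSE)
  if (length(labels) == 1L) labels <- rep(labels, length(beat_times))
  stopifnot(length(labels) == length(beat_times))
  structure(list(beat_times = beat_times, labels = as.character(labels)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d beats", length(x$beat_times)))
  if (length(x$beat_times))
    cat(sprintf(" over %.1f s", diff(range(x$beat_times))))
  cat("\n")
  invisible(x)
}

# WFDB annotation type codes <-> symbols (beat subset + common non-beat)
.wfdb_codes <- c(N = 1L, L = 2L, R = 3L, a = 4L, V = 5L, F = 6L, J = 7L,
                 A = 8L, S = 9L, E = 10L, j = 11L, "/" = 12L, Q = 13L,
                 "~" = 14L, "|" = 16L, s = 18L, T = 19L, "*" = 20L,
                 D = 21L, '"' = 22L, "=" = 23L, p = 24L, B = 25L,
                 "^" = 26L, t = 27L, "+" = 28L, u = 29L, "?" = 30L,
                 "!" = 31L, "[" = 32L, "]" = 33L, e = 34L, n = 35L,
                 "@" = 36L, x = 37L, f = 38L, "(" = 39L, ")" = 40L,
                 r = 41L)
.wfdb_beat_codes <- c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L,
                      13L, 25L, 34L, 35L, 38L, 41L)

#' Read a WFDB record (formats 212 and 16)
#'
#' Reads the header/signal pair and returns the first lead in physical
#' units.  Multi-lead files are reduced to lead 1 with a notice.
#'
#' @param path record basename or path to the `.hea` file.
#' @return an [ecg_record].
#' @export
read_record <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("header not found: ", hea, call. = FALSE)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty header: ", hea, call. = FALSE)
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rec_name <- top[1L]
  nsig <- as.integer(top[2L])
  fs <- as.numeric(sub("/.*$", "", top[3L]))
  if (is.na(fs) || fs <= 0) fs <- 250
  nsamp <- if (length(top) >= 4L) as.integer(top[4L]) else NA_integer_
  if (is.na(nsig) || nsig < 1L)
    stop("corrupt header (no signals): ", hea, call. = FALSE)
  sig <- lapply(lines[2L:(1L + nsig)], parse_signal_line)
  fmts <- vapply(sig, `[[`, numeric(1), "format")
  if (length(unique(fmts)) != 1L)
    stop("mixed signal formats are not supported", call. = FALSE)
  fmt <- fmts[1L]
  dat <- file.path(dirname(hea), sig[[1L]]$file)
  if (!file.exists(dat)) stop("signal file not found: ", dat, call. = FALSE)
  raw_bytes <- readBin(dat, "raw", n = file.info(dat)$size)
  adc <- decode_samples(raw_bytes, fmt)
  if (length(adc) < nsig) stop("corrupt signal file: ", dat, call. = FALSE)
  n_frames <- length(adc) %/% nsig
  if (!is.na(nsamp) && nsamp > 0) n_frames <- min(n_frames, nsamp)
  adc <- matrix(adc[seq_len(n_frames * nsig)], ncol = nsig, byrow = TRUE)
  if (nsig > 1L)
    message("record '", rec_name, "' has ", nsig,
            " leads; returning lead 1 only")
  s1 <- sig[[1L]]
  phys <- (adc[, 1L] - s1$baseline) / s1$gain
  ecg_record(phys, fs, rec_name)
}

parse_signal_line <- function(line) {
  f <- strsplit(trimws(line), "\\s+")[[1L]]
  fmt <- as.numeric(sub("[x:+].*$", "", f[2L]))
  gain <- 200; baseline <- NA_real_; adczero <- 0
  if (length(f) >= 3L) {
    gspec <- f[3L]
    units <- sub("^[^/]*", "", gspec)
    gmain <- sub("/.*$", "", gspec)
    if (grepl("\\(", gmain)) {
      baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gmain))
      gmain <- sub("\\(.*$", "", gmain)
    }
    g <- as.numeric(gmain)
    if (!is.na(g) && g != 0) gain <- g
  }
  if (length(f) >= 5L) {
    z <- as.numeric(f[5L])
    if (!is.na(z)) adczero <- z
  }
  if (is.na(baseline)) baseline <- adczero
  list(file = f[1L], format = fmt, gain = gain, baseline = baseline)
}

decode_samples <- function(bytes, fmt) {
  if (fmt == 16) {
    n <- length(bytes) %/% 2L
    readBin(bytes[seq_len(2L * n)], "integer", n = n, size = 2L,
            signed = TRUE, endian = "little")
  } else if (fmt == 212) {
    n3 <- (length(bytes) %/% 3L) * 3L
    b <- as.integer(bytes[seq_len(n3)])
    b1 <- b[seq(1L, n3, by = 3L)]
    b2 <- b[seq(2L, n3, by = 3L)]
    b3 <- b[seq(3L, n3, by = 3L)]
    s1 <- b1 + bitwShiftL(bitwAnd(b2, 0x0FL), 8L)
    s2 <- b3 + bitwShiftL(bitwShiftR(b2, 4L), 8L)
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    as.integer(rbind(s1, s2))
  } else stop("unsupported WFDB signal format: ", fmt, call. = FALSE)
}

#' Write a WFDB record (formats 212 and 16)
#'
#' Amplitudes are quantized with the given ADC gain; the quantization is
#' exactly invertible by [read_record] as long as the ADC range is not
#' exceeded (12 bits for format 212, 16 bits for format 16).
#'
#' @param record an [ecg_record].
#' @param path record basename (files `path.hea` and `path.dat`).
#' @param format 212 or 16.
#' @param gain ADC units per millivolt.
#' @return the basename, invisibly.
#' @export
write_record <- function(record, path, format = 212, gain = 200) {
  stopifnot(inherits(record, "ecg_record"), format %in% c(212, 16))
  adc <- as.integer(round(record$samples * gain))
  lim <- if (format == 212) 2047L else 32767L
  if (any(adc > lim | adc < -lim - 1L))
    stop("amplitude exceeds ADC range for format ", format, call. = FALSE)
  base <- basename(path)
  hea <- paste0(path, ".hea")
  datname <- paste0(base, ".dat")
  writeLines(c(sprintf("%s 1 %.10g %d", base, record$fs, length(adc)),
               sprintf("%s %d %g(0)/mV 12 0 %d 0 0 ECG",
                       datname, as.integer(format), gain,
                       adc[1L])),
             hea)
  con <- file(file.path(dirname(path), datname), "wb")
  on.exit(close(con))
  if (format == 16) {
    writeBin(adc, con, size = 2L, endian = "little")
  } else {
    if (length(adc) %% 2L == 1L) adc <- c(adc, 0L)
    u <- ifelse(adc < 0L, adc + 4096L, adc)
    s1 <- u[seq(1L, length(u), by = 2L)]
    s2 <- u[seq(2L, length(u), by = 2L)]
    b1 <- bitwAnd(s1, 0xFFL)
    b2 <- bitwOr(bitwShiftR(s1, 8L), bitwShiftL(bitwShiftR(s2, 8L), 4L))
    b3 <- bitwAnd(s2, 0xFFL)
    writeBin(as.raw(rbind(b1, b2, b3)), con)
  }
  invisible(path)
}

#' Read a WFDB annotation file
#'
#' Decodes the MIT annotation format.  Beat annotations are kept (with
#' their symbol); non-beat annotations are dropped.  Unknown type codes
#' are kept with a `?` label and a warning.
#'
#' @param path annotation file.
#' @param fs sampling frequency used to convert sample indices to seconds.
#' @param beats_only drop non-beat annotations (default `TRUE`).
#' @return an [annotation_set] (times in seconds).
#' @export
read_annotations <- function(path, fs, beats_only = TRUE) {
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  stopifnot(is.numeric(fs), fs > 0)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  n <- length(bytes) %/% 2L
  if (n == 0L) return(annotation_set(numeric(0), character(0)))
  words <- readBin(bytes[seq_len(2L * n)], "integer", n = n, size = 2L,
                   signed = FALSE, endian = "little")
  sym_of <- names(.wfdb_codes)
  times <- integer(0); codes <- integer(0)
  t_cur <- 0L; i <- 1L
  while (i <= n) {
    w <- words[i]
    code <- bitwShiftR(w, 10L)
    delta <- bitwAnd(w, 1023L)
    if (w == 0L) break                     # end of file
    if (code == 59L) {                     # SKIP: 4-byte interval follows
      if (i + 2L > n) break
      hi <- words[i + 1L]; lo <- words[i + 2L]
      iv <- hi * 65536 + lo
      if (iv > 2^31) iv <- iv - 2^32
      t_cur <- t_cur + iv
      i <- i + 3L
      next
    }
    if (code %in% c(60L, 61L, 62L)) { i <- i + 1L; next }  # NUM/SUB/CHN
    if (code == 63L) {                     # AUX: skip payload
      i <- i + 1L + (delta + delta %% 2L) %/% 2L
      next
    }
    t_cur <- t_cur + delta
    times <- c(times, t_cur)
    codes <- c(codes, code)
    i <- i + 1L
  }
  known <- match(codes, .wfdb_codes)
  if (anyNA(known))
    warning("unknown annotation code(s): ",
            paste(unique(codes[is.na(known)]), collapse = ", "))
  labels <- ifelse(is.na(known), "?", sym_of[known])
  if (beats_only) {
    keep <- codes %in% .wfdb_beat_codes
    times <- times[keep]; labels <- labels[keep]
  }
  annotation_set(times / fs, labels)
}

#' Write detections as a WFDB annotation file
#'
#' Event times are stored at sample resolution as normal-beat (`N`)
#' annotations; the encoding is lossless under [read_annotations].
#'
#' @param detections strictly increasing event times in seconds (or a
#'   `detection_set` from [detect]).
#' @param path output file.
#' @param fs sampling frequency (Hz).
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path, fs) {
  if (inherits(detections, "detection_set")) detections <- detections$t
  if (inherits(detections, "annotation_set")) detections <- detections$beat_times
  detections <- as.numeric(detections)
  stopifnot(is.numeric(fs), fs > 0)
  if (length(detections) && any(diff(detections) <= 0))
    stop("detection times must be strictly increasing", call. = FALSE)
  samp <- round(detections * fs)
  deltas <- diff(c(0, samp))
  con <- file(path, "wb")
  on.exit(close(con))
  words <- integer(0)
  for (d in deltas) {
    if (d > 1023) {
      hi <- d %/% 65536; lo <- d %% 65536
      words <- c(words, bitwShiftL(59L, 10L), as.integer(hi), as.integer(lo),
                 bitwShiftL(1L, 10L))          # SKIP + N at delta 0
    } else {
      words <- c(words, bitwOr(bitwShiftL(1L, 10L), as.integer(d)))
    }
  }
  words <- c(words, 0L)                        # end marker
  writeBin(as.raw(rbind(words %% 256L, words %/% 256L)), con)
  invisible(path)
}
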