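#' Default detector configuration
#'
#' Every tunable constant of the pipeline lives here, each exactly once.
#' Filter cutoffs and orders, the feature-window geometry, the template
#' update weight, the heating-up length, the reset timeout and the SNR
#' benchmark grid default to the values used throughout the package
#' documentation; all can be overridden by name.
#'
#' @param ... named overrides of the defaults (unknown names are an error).
#' @return a validated list of class `mfpd_config`.
#' @details Key groups:
#' \describe{
#'   \item{preprocessing}{`lp_cutoff` (19 Hz), `hp_cutoff` (8 Hz),
#'     `deriv_cutoff` (30 Hz), `smooth_ms` (101 ms), `lp_order`,
#'     `hp_order` (256), `deriv_order` (129) -- orders are stated at the
#'     reference rate `ref_fs` (1000 Hz) and scaled proportionally to the
#'     record's sampling rate; `candidate_floor` suppresses numerically
#'     flat maxima of the slope signal.}
#'   \item{features}{`win_ms` (50), `win_offset_ms` (20), `tpl_keep`
#'     (0.8), `align_max_ms` (10).}
#'   \item{detector}{`lambda` (0.5), `heat_beats` (40), `reset_s` (3.5),
#'     `pt_match_ms` (150), `history_cap` (500), `min_fit` (5),
#'     `prior_clamp`, `min_rr_ms` (0).}
#'   \item{beta prior}{`beta_prior_K` (0), `beta_prior_a` (0.5),
#'     `beta_prior_b` (0), `beta_prior_eps` (1e-3).}
#'   \item{fitting}{`fit_max_iter` (100), `fit_tol` (1e-8),
#'     `clip_delta` (1e-6).}
#'   \item{evaluation}{`match_window_ms` (50), `der_alarm_pct` (60).}
#'   \item{benchmark}{`snr_grid` (-6 to 24 dB by 6 dB).}
#' }
#' @export
#' @examples
#' cfg <- mfpd_config(lambda = 0.6)
#' cfg$lambda
mfpd_config <- function(...) {
  defaults <- list(
    # preprocessing
    lp_cutoff = 19, hp_cutoff = 8, deriv_cutoff = 30, smooth_ms = 101,
    lp_order = 256, hp_order = 256, deriv_order = 129, ref_fs = 1000,
    candidate_floor = 1e-6, min_spacing_ms = 0, chain_order = "square_first",
    # features
    win_ms = 50, win_offset_ms = 20, tpl_keep = 0.8, align_max_ms = 10,
    # detector
    lambda = 0.5, heat_beats = 40, reset_s = 3.5, pt_match_ms = 150,
    history_cap = 500, min_fit = 5, prior_clamp = c(0.05, 0.95),
    min_rr_ms = 0, divergence = "kld",
    # Beta conjugate prior for the correlation feature
    beta_prior_K = 0, beta_prior_a = 0.5, beta_prior_b = 0,
    beta_prior_eps = 1e-3,
    # numerical fitting
    fit_max_iter = 100, fit_tol = 1e-8, clip_delta = 1e-6,
    # evaluation
    match_window_ms = 50, der_alarm_pct = 60,
    # noise benchmark
    snr_grid = seq(-6, 24, by = 6),
    seed = NULL, log_level = "warn"
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over)))
    over <- over[[1L]]
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("configuration overrides must be named", call. = FALSE)
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    defaults <- modifyList(defaults, over, keep.null = TRUE)
  }
  validate_config(defaults)
}

validate_config <- function(cfg) {
  chk <- function(ok, what) if (!isTRUE(ok))
    stop("invalid configuration: ", what, call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(cfg$lambda) && cfg$lambda > 0 && cfg$lambda < 1,
      "'lambda' must lie strictly in (0, 1)")
  for (k in c("lp_cutoff", "hp_cutoff", "deriv_cutoff", "smooth_ms",
              "win_ms", "win_offset_ms", "reset_s", "pt_match_ms",
              "ref_fs", "match_window_ms"))
    chk(num1(cfg[[k]]) && cfg[[k]] > 0, sprintf("'%s' must be > 0", k))
  for (k in c("lp_order", "hp_order", "deriv_order", "heat_beats",
              "history_cap", "min_fit", "fit_max_iter"))
    chk(num1(cfg[[k]]) && cfg[[k]] >= 1 && cfg[[k]] == round(cfg[[k]]),
        sprintf("'%s' must be a positive integer", k))
  chk(num1(cfg$tpl_keep) && cfg$tpl_keep >= 0 && cfg$tpl_keep <= 1,
      "'tpl_keep' must lie in [0, 1]")
  chk(num1(cfg$beta_prior_K) && cfg$beta_prior_K >= 0,
      "'beta_prior_K' must be >= 0")
  chk(num1(cfg$beta_prior_a) && cfg$beta_prior_a >= 0,
      "'beta_prior_a' must be >= 0")
  chk(num1(cfg$beta_prior_b) && cfg$beta_prior_b >= 0,
      "'beta_prior_b' must be >= 0")
  chk(num1(cfg$beta_prior_eps) && cfg$beta_prior_eps > 0,
      "'beta_prior_eps' must be > 0")
  chk(is.numeric(cfg$prior_clamp) && length(cfg$prior_clamp) == 2L &&
        cfg$prior_clamp[1] > 0 && cfg$prior_clamp[2] < 1 &&
        cfg$prior_clamp[1] < cfg$prior_clamp[2],
      "'prior_clamp' must be an increasing pair inside (0, 1)")
  chk(cfg$divergence %in% c("kld", "reverse_kld"),
      "'divergence' must be 'kld' or 'reverse_kld'")
  chk(cfg$chain_order %in% c("square_first", "derivative_first"),
      "'chain_order' must be 'square_first' or 'derivative_first'")
  chk(is.numeric(cfg$snr_grid) && all(is.finite(cfg$snr_grid)),
      "'snr_grid' must be finite numeric")
  structure(cfg, class = "mfpd_config")
}

#' Load a configuration from a YAML file with defaults
#'
#' Missing keys take their defaults; unknown keys are rejected so that a
#' typo in a config file cannot silently be ignored.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file contents.
#' @return an `mfpd_config` list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  vals <- modifyList(vals, overrides, keep.null = TRUE)
  do.call(mfpd_config, vals)
}

#' @export
print.mfpd_config <- function(x, ...) {
  cat("<mfpd_config>\n")
  cat(sprintf("  lambda=%.3g  heat_beats=%d  reset_s=%.3g\n",
              x$lambda, as.integer(x$heat_beats), x$reset_s))
  cat(sprintf("  filters: lp %g Hz / hp %g Hz / deriv %g Hz / smooth %g ms\n",
              x$lp_cutoff, x$hp_cutoff, x$deriv_cutoff, x$smooth_ms))
  cat(sprintf("  window: %g ms centred %g ms before the peak\n",
              x$win_ms, x$win_offset_ms))
  invisible(x)
}
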