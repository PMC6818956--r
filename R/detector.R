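#' Per-feature Bayesian posterior of a valid beat
#'
#' `P(H1 | x) = f1(x) p / (f1(x) p + f0(x) (1 - p))`.  When both
#' likelihoods underflow to zero the observation carries no information
#' and the prior is returned.
#'
#' @param model a `feature_model` (or any list with `params_h0`,
#'   `params_h1`).
#' @param x observed feature value.
#' @param prior_h1 prior probability of a valid beat.
#' @return posterior probability in `[0, 1]`.
#' @export
posterior <- function(model, x, prior_h1) {
  stopifnot(prior_h1 >= 0, prior_h1 <= 1)
  f1 <- pdf_eval(model$params_h1, x)
  f0 <- pdf_eval(model$params_h0, x)
  num <- f1 * prior_h1
  den <- num + f0 * (1 - prior_h1)
  if (!is.finite(den) || den <= 0) return(prior_h1)
  num / den
}

feature_model <- function(family, params_h0, params_h1, kld_value,
                          history_h0, history_h1) {
  structure(list(family = family, params_h0 = params_h0,
                 params_h1 = params_h1, kld = kld_value,
                 history_h0 = history_h0, history_h1 = history_h1),
            class = "feature_model")
}

# fit one feature's class sample with the family-appropriate estimator;
# returns NULL on degenerate/non-convergent samples
fit_feature <- function(family, x, config) {
  tryCatch(switch(family,
    gamma = fit_gamma_mle(pmax(x, 1e-300)),
    gnd = fit_gnd_mle(x),
    beta = fit_beta_map(x,
                        prior = beta_prior(config$beta_prior_K,
                                           config$beta_prior_a,
                                           config$beta_prior_b,
                                           config$beta_prior_eps),
                        max_iter = config$fit_max_iter,
                        tol = config$fit_tol,
                        delta = config$clip_delta)),
    error = function(e) NULL)
}

model_kld <- function(model, config) {
  v <- tryCatch(kld(model$params_h1, model$params_h0,
                    reverse = identical(config$divergence, "reverse_kld")),
                error = function(e) NA_real_)
  if (!is.finite(v) || v < 0) 0 else v
}

cap_history <- function(x, cap) if (length(x) > cap)
  x[(length(x) - cap + 1L):length(x)] else x

clamp_prior <- function(p, clamp) min(max(p, clamp[1L]), clamp[2L])

#' Initialize the online detector state (heating-up)
#'
#' Labels candidates over the heating window using the Pan-Tompkins
#' bootstrap: the candidate nearest each bootstrap beat (within
#' `pt_match_ms`) is a valid beat (H1); every other candidate up to the
#' `heat_beats`-th validation is H0.  The heating window widens past the
#' nominal beat count until each class holds at least `min_fit` samples.
#' Both beat templates are built by aligned averaging, the six density
#' fits are run, divergences computed, and the class prior set to the
#' clamped validated fraction.
#'
#' @param record an [ecg_record].
#' @param fsig its `filtered_signals`.
#' @param candidates candidate sample indices from [find_candidates].
#' @param config an [mfpd_config].
#' @param pt_times optional bootstrap beat times (s); computed if `NULL`.
#' @param from_time ignore candidates and bootstrap beats before this
#'   time (s) -- used when re-heating after a reset.
#' @return a `detector_state` list; error of class `mfpd_heating_error`
#'   when the bootstrap cannot supply enough labelled beats.
#' @export
initialize_state <- function(record, fsig, candidates,
                             config = mfpd_config(), pt_times = NULL,
                             from_time = 0) {
  fs <- record$fs
  if (is.null(pt_times)) pt_times <- pan_tompkins_detect(record)
  pt_times <- pt_times[pt_times >= from_time]
  cand <- candidates[candidates / fs >= from_time]
  heating_fail <- function(msg)
    stop(structure(class = c("mfpd_heating_error", "error", "condition"),
                   list(message = msg, call = NULL)))
  if (length(pt_times) < config$heat_beats)
    heating_fail(sprintf(
      "heating failed: bootstrap found %d beats (< %d)",
      length(pt_times), config$heat_beats))
  tol <- config$pt_match_ms / 1000
  n_pt <- length(pt_times)
  h1_idx <- integer(0)
  used_beats <- 0L
  last_used_t <- from_time
  for (b in seq_len(n_pt)) {
    used_beats <- b
    dt <- abs(cand / fs - pt_times[b])
    free <- setdiff(which(dt <= tol), h1_idx)
    if (length(free))
      h1_idx <- c(h1_idx, free[which.min(dt[free])])
    last_used_t <- pt_times[b]
    n_h1 <- length(h1_idx)
    n_h0 <- sum(cand / fs <= last_used_t) - n_h1
    if (b >= config$heat_beats && n_h1 >= config$heat_beats &&
        n_h0 >= config$min_fit) break
  }
  in_window <- which(cand / fs <= last_used_t)
  h1 <- intersect(in_window, h1_idx)
  h0 <- setdiff(in_window, h1_idx)
  if (length(h1) < config$heat_beats)
    heating_fail(sprintf(
      "heating failed: only %d candidates matched bootstrap beats (< %d)",
      length(h1), config$heat_beats))
  if (length(h0) < config$min_fit)
    heating_fail(sprintf(
      "heating failed: only %d invalid candidates for the H0 fit (< %d)",
      length(h0), config$min_fit))
  win_of <- function(i) tryCatch(
    extract_window(record, cand[i], win_ms = config$win_ms,
                   win_offset_ms = config$win_offset_ms),
    error = function(e) NULL)
  w1 <- Filter(Negate(is.null), lapply(h1, win_of))
  w0 <- Filter(Negate(is.null), lapply(h0, win_of))
  if (!length(w1) || !length(w0))
    heating_fail("heating failed: no usable candidate windows")
  tpl1 <- init_template(w1, fs, config$align_max_ms)
  tpl0 <- init_template(w0, fs, config$align_max_ms)
  feats <- function(idx) {
    out <- lapply(idx, function(i)
      extract_features(record, fsig, cand[i], tpl1, config))
    Filter(Negate(is.null), out)
  }
  f1 <- feats(h1); f0 <- feats(h0)
  hist <- list(
    s = list(h0 = vapply(f0, `[[`, 1, "s"), h1 = vapply(f1, `[[`, 1, "s")),
    a = list(h0 = vapply(f0, `[[`, 1, "a"), h1 = vapply(f1, `[[`, 1, "a")),
    c = list(h0 = vapply(f0, `[[`, 1, "c"), h1 = vapply(f1, `[[`, 1, "c")))
  fams <- c(s = "gamma", a = "gnd", c = "beta")
  models <- lapply(names(fams), function(i) {
    p0 <- fit_feature(fams[[i]], hist[[i]]$h0, config)
    p1 <- fit_feature(fams[[i]], hist[[i]]$h1, config)
    if (is.null(p0)) p0 <- fallback_params(fams[[i]], hist[[i]]$h0)
    if (is.null(p1)) p1 <- fallback_params(fams[[i]], hist[[i]]$h1)
    m <- feature_model(fams[[i]], p0, p1, 0, hist[[i]]$h0, hist[[i]]$h1)
    m$kld <- model_kld(m, config)
    m
  })
  names(models) <- names(fams)
  n1 <- length(f1); n0 <- length(f0)
  state <- structure(list(
    models = models,
    template_h1 = tpl1, template_h0 = tpl0,
    prior_h1 = clamp_prior(n1 / (n1 + n0), config$prior_clamp),
    mode = "running",
    last_detection_t = max(cand[h1]) / fs,
    lambda = config$lambda,
    n_validated = n1, n_invalidated = n0,
    heat_end_t = last_used_t,
    heat_h1_times = sort(cand[h1]) / fs,
    fs = fs), class = "detector_state")
  state
}

# weakly-informative moment-based parameters used when an online refit
# is degenerate (e.g. a near-constant class sample); keeps the detector
# stepping instead of halting
fallback_params <- function(family, x) {
  m <- mean(x); s <- sd(x)
  switch(family,
    gamma = {
      m <- max(m, 1e-12); s <- max(s, 1e-3 * m, 1e-12)
      gamma_params(max((m / s)^2, 1e-3), s^2 / m)
    },
    gnd = {
      s <- max(s, 1e-6, 1e-3 * abs(m))
      gnd_params(m, s * sqrt(2), 2)
    },
    beta = {
      m <- min(max(m, 1e-3), 1 - 1e-3)
      v <- max(min(ifelse(is.na(s), 0, s)^2, m * (1 - m) * 0.99), 1e-6)
      common <- m * (1 - m) / v - 1
      beta_params(max(m * common, 1e-3), max((1 - m) * common, 1e-3))
    })
}

#' @export
print.detector_state <- function(x, ...) {
  cat(sprintf(
    "<detector_state> mode=%s prior=%.3f lambda=%.2f validated=%d\n",
    x$mode, x$prior_h1, x$lambda, x$n_validated))
  cat(sprintf("  KLD: s=%.3g a=%.3g c=%.3g\n",
              x$models$s$kld, x$models$a$kld, x$models$c$kld))
  invisible(x)
}

#' Process one candidate through the fusion rule and update the state
#'
#' Computes the three per-feature posteriors, fuses them with the capped
#' normalized divergence weights, thresholds at `lambda`, then feeds the
#' candidate's features back into the decided class: history append,
#' density refit (previous parameters are kept when a refit is
#' degenerate), divergence update, template blend, prior update.  If the
#' time since the last validated beat exceeds `reset_s` the state mode
#' flips to `"heating"` and the caller must re-initialize.
#'
#' @param state a `detector_state`.
#' @param cand a candidate feature list from [extract_features].
#' @param config an [mfpd_config].
#' @return list `(decision, score, weights, posteriors, state)`.
#' @export
step <- function(state, cand, config = mfpd_config()) {
  stopifnot(inherits(state, "detector_state"))
  t_s <- cand$t / state$fs
  if (state$mode != "running")
    stop("detector is not in running mode", call. = FALSE)
  if (t_s - state$last_detection_t > config$reset_s) {
    state$mode <- "heating"
    return(list(decision = NA, score = NA_real_,
                weights = rep(NA_real_, 3), posteriors = rep(NA_real_, 3),
                state = state))
  }
  xs <- c(s = cand$s, a = cand$a, c = cand$c)
  post <- vapply(names(state$models), function(i)
    posterior(state$models[[i]], xs[[i]], state$prior_h1), numeric(1))
  klds <- vapply(state$models, `[[`, numeric(1), "kld")
  w <- modified_weights(klds)
  score <- sum(w * post)
  d <- score > state$lambda
  cls <- if (d) "h1" else "h0"
  for (i in names(state$models)) {
    m <- state$models[[i]]
    key <- if (d) "history_h1" else "history_h0"
    m[[key]] <- cap_history(c(m[[key]], xs[[i]]), config$history_cap)
    refit <- fit_feature(m$family, m[[key]], config)
    if (!is.null(refit)) {
      if (d) m$params_h1 <- refit else m$params_h0 <- refit
      m$kld <- model_kld(m, config)
    }
    state$models[[i]] <- m
  }
  if (!is.null(cand$window)) {
    if (d) state$template_h1 <- update_template(state$template_h1,
                                                cand$window, config$tpl_keep)
    else state$template_h0 <- update_template(state$template_h0,
                                              cand$window, config$tpl_keep)
  }
  if (d) {
    state$n_validated <- state$n_validated + 1L
    state$last_detection_t <- t_s
  } else state$n_invalidated <- state$n_invalidated + 1L
  state$prior_h1 <- clamp_prior(
    state$n_validated / (state$n_validated + state$n_invalidated),
    config$prior_clamp)
  list(decision = d, score = score, weights = w, posteriors = post,
       state = state)
}

#' Run the full detector over a record
#'
#' Pipeline: preprocess, candidate selection, Pan-Tompkins bootstrap,
#' heating-up labeling, then candidate-by-candidate fusion.  Heating-up
#' validations are emitted as detections (they count in evaluation).  A
#' silent gap longer than `reset_s` wipes the state and re-heats from
#' that point; when re-heating is impossible (too few bootstrap beats
#' left) the remaining bootstrap detections are emitted and flagged.
#'
#' @param record an [ecg_record].
#' @param config an [mfpd_config].
#' @return a `detection_set`: `t` (beat times, s), `score`,
#'   `decision_time` (s; detection time plus the fixed pipeline latency),
#'   and a `diagnostics` list (per-candidate trace, resets, heating
#'   spans, fallback flag).
#' @export
detect <- function(record, config = mfpd_config()) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  fsig <- preprocess(record, config)
  cand <- find_candidates(fsig, config$candidate_floor,
                          config$min_spacing_ms)
  pt_times <- pan_tompkins_detect(record)
  latency_s <- (fsig$delay_sf +
                  round(config$win_ms / 2 / 1000 * fs)) / fs
  det_t <- numeric(0); det_score <- numeric(0)
  trace <- list()
  resets <- 0L; heat_spans <- list(); fallback <- FALSE
  from_time <- 0
  repeat {
    st <- tryCatch(
      initialize_state(record, fsig, cand, config, pt_times = pt_times,
                       from_time = from_time),
      mfpd_heating_error = function(e) e)
    if (inherits(st, "mfpd_heating_error")) {
      rest <- pt_times[pt_times >= from_time]
      rest <- rest[!rest %in% det_t]
      det_t <- c(det_t, rest)
      det_score <- c(det_score, rep(NA_real_, length(rest)))
      fallback <- TRUE
      break
    }
    heat_spans[[length(heat_spans) + 1L]] <- c(from_time, st$heat_end_t)
    det_t <- c(det_t, st$heat_h1_times)
    det_score <- c(det_score, rep(NA_real_, length(st$heat_h1_times)))
    todo <- cand[cand / fs > st$heat_end_t]
    reset_at <- NA_real_
    for (tc in todo) {
      cf <- extract_features(record, fsig, tc, st$template_h1, config)
      if (is.null(cf)) next
      res <- step(st, cf, config)
      st <- res$state
      if (st$mode == "heating") { reset_at <- tc / fs; break }
      trace[[length(trace) + 1L]] <-
        c(t = tc / fs, score = res$score, d = as.numeric(res$decision),
          w = res$weights, post = res$posteriors,
          kld = vapply(st$models, `[[`, numeric(1), "kld"))
      if (isTRUE(res$decision)) {
        det_t <- c(det_t, tc / fs)
        det_score <- c(det_score, res$score)
      }
    }
    if (is.na(reset_at)) break
    resets <- resets + 1L
    from_time <- reset_at
  }
  ord <- order(det_t)
  det_t <- det_t[ord]; det_score <- det_score[ord]
  keep <- !duplicated(det_t)
  structure(list(
    t = det_t[keep],
    score = det_score[keep],
    decision_time = det_t[keep] + latency_s,
    latency_s = latency_s,
    diagnostics = list(
      trace = if (length(trace)) as.data.frame(do.call(rbind, trace))
              else NULL,
      resets = resets, heat_spans = heat_spans,
      heating_fallback = fallback,
      n_candidates = length(cand))),
    class = "detection_set")
}

#' @export
print.detection_set <- function(x, ...) {
  cat(sprintf("<detection_set> %d beats, latency %.0f ms, %d reset(s)%s\n",
              length(x$t), 1000 * x$latency_s, x$diagnostics$resets,
              if (x$diagnostics$heating_fallback)
                " [bootstrap fallback]" else ""))
  invisible(x)
}
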