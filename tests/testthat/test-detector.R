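# online detector: posteriors, heating, stepping, resets, end-to-end

test_that("the posterior is the exact Bayes quotient", {
  m <- list(params_h1 = gamma_params(3, 1), params_h0 = gamma_params(1, 2))
  set.seed(41)
  for (r in 1:20) {
    x <- runif(1, 0.1, 8); pr <- runif(1)
    f1 <- pdf_eval(m$params_h1, x); f0 <- pdf_eval(m$params_h0, x)
    expect_close(posterior(m, x, pr),
                 f1 * pr / (f1 * pr + f0 * (1 - pr)), tol = 1e-12)
  }
  # symmetric likelihoods at even prior
  msym <- list(params_h1 = gamma_params(2, 1), params_h0 = gamma_params(2, 1))
  expect_equal(posterior(msym, 1.3, 0.5), 0.5)
  expect_equal(posterior(m, 2, 0), 0)
  expect_equal(posterior(m, 2, 1), 1)
  # double underflow returns the prior
  tight <- list(params_h1 = gnd_params(0, 1e-4, 2),
                params_h0 = gnd_params(0, 2e-4, 2))
  expect_equal(posterior(tight, 100, 0.42), 0.42)
})

heated_state <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sim <- heated_sim()
    cfg <- mfpd_config()
    fsig <- preprocess(sim$record, cfg)
    cand <- find_candidates(fsig, cfg$candidate_floor)
    st <- initialize_state(sim$record, fsig, cand, cfg)
    cache <<- list(sim = sim, cfg = cfg, fsig = fsig, cand = cand, st = st)
    cache
  }
})

test_that("heating validates the nominal beat count and fits all models", {
  h <- heated_state()
  st <- h$st
  expect_equal(st$n_validated, 40L)
  expect_identical(st$mode, "running")
  expect_length(st$heat_h1_times, 40L)
  for (i in c("s", "a", "c")) {
    m <- st$models[[i]]
    expect_true(is.finite(m$kld) && m$kld >= 0)
    expect_s3_class(m$params_h0, "mfpd_params")
    expect_s3_class(m$params_h1, "mfpd_params")
  }
  expect_gte(st$prior_h1, 0.05); expect_lte(st$prior_h1, 0.95)
  # valid-beat template looks like an R wave: dominant positive peak
  expect_gt(max(st$template_h1$waveform), 0.5)
})

test_that("heating on pure noise raises a heating error", {
  noise <- ecg_record(simulate_noise("muscle", 30, 360, seed = 16) * 0.05,
                      360)
  cfg <- mfpd_config()
  fsig <- preprocess(noise, cfg)
  cand <- find_candidates(fsig, cfg$candidate_floor)
  expect_error(initialize_state(noise, fsig, cand, cfg),
               class = "mfpd_heating_error")
})

test_that("fused decisions respect convexity bounds", {
  h <- heated_state()
  st <- h$st
  # candidate identical to a validated beat: all posteriors near 1
  tc <- h$cand[which.min(abs(h$cand / 360 - st$heat_h1_times[20]))]
  cf <- extract_features(h$sim$record, h$fsig, tc, st$template_h1, h$cfg)
  res <- step(st, cf, h$cfg)
  expect_gte(res$score, 0); expect_lte(res$score, 1)
  expect_close(sum(res$weights), 1, tol = 1e-12)
  expect_lte(max(res$weights), 2 / 3 + 1e-12)
  # direct convexity check of the fusion rule
  expect_close(sum(res$weights * res$posteriors), res$score, tol = 1e-12)
})

test_that("stepping is deterministic under replay of the same prefix", {
  h <- heated_state()
  run_prefix <- function(n) {
    st <- h$st
    out <- numeric(0)
    todo <- h$cand[h$cand / 360 > st$heat_end_t][1:60]
    for (tc in todo) {
      cf <- extract_features(h$sim$record, h$fsig, tc, st$template_h1,
                             h$cfg)
      if (is.null(cf)) next
      res <- step(st, cf, h$cfg)
      st <- res$state
      if (st$mode != "running") break
      out <- c(out, res$score)
      if (length(out) >= n) break
    }
    out
  }
  full <- run_prefix(50)
  again <- run_prefix(50)
  expect_identical(full, again)
  prefix <- run_prefix(20)
  expect_identical(prefix, full[1:20])
})

test_that("a silent gap beyond the timeout flips the state to heating", {
  h <- heated_state()
  st <- h$st
  fake <- list(t = round((st$last_detection_t + 4) * 360), s = 1e-9,
               a = 0, c = 0.1, window = NULL)
  res <- step(st, fake, h$cfg)
  expect_identical(res$state$mode, "heating")
  expect_true(is.na(res$decision))
})

test_that("full detection on a clean record is near perfect and replayable", {
  sim <- heated_sim()
  d1 <- detect(sim$record)
  r <- score_record(match_beats(sim$annotations, d1))
  expect_gte(r$se, 99)
  expect_gte(r$ppv, 99)
  d2 <- detect(sim$record)
  expect_identical(d1$t, d2$t)
  expect_identical(d1$score, d2$score)
  # decision latency is a fixed per-configuration constant
  expect_close(d1$decision_time - d1$t, d1$latency_s, tol = 1e-12)
})

test_that("a constructed silent gap forces a reset and recovery", {
  sim <- simulate_ecg(duration_s = 150, mean_hr = 70, hr_sd = 2, fs = 360,
                      seed = 17)
  x <- sim$record$samples
  gap <- round(70 * 360):round(76 * 360)       # 6 s of flatline + floor
  x[gap] <- x[gap] * 0 + rnorm(length(gap), sd = 0.005)
  rec <- ecg_record(x, 360)
  d <- detect(rec)
  expect_gte(d$diagnostics$resets, 1L)
  keep <- sim$annotations$beat_times < 69 | sim$annotations$beat_times > 78
  m <- match_beats(sim$annotations$beat_times[keep], d$t)
  expect_gte(100 * nrow(m$tp_pairs) / sum(keep), 90)
})
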