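# beat-by-beat scoring

test_that("only one in-window detection becomes the true positive", {
  m <- match_beats(1.000, c(1.010, 1.020))
  expect_equal(nrow(m$tp_pairs), 1L)
  expect_equal(unname(m$tp_pairs[1, "detection"]), 1.010)
  expect_equal(m$fp, 1.020)
  expect_length(m$fn, 0L)
})

test_that("detections outside the half-window are false positives", {
  m <- match_beats(1.000, 1.030)                # beyond +/- 25 ms
  expect_length(m$fn, 1L)
  expect_length(m$fp, 1L)
  expect_equal(nrow(m$tp_pairs), 0L)
})

test_that("identical streams give all true positives with zero jitter", {
  t <- c(0.5, 1.2, 1.9, 2.6)
  m <- match_beats(t, t)
  r <- score_record(m)
  expect_equal(r$tp, 4L); expect_equal(r$fp, 0L); expect_equal(r$fn, 0L)
  expect_equal(r$se, 100); expect_equal(r$ppv, 100); expect_equal(r$der, 0)
  expect_equal(r$jitter_mean, 0); expect_equal(r$jitter_sd, 0)
})

# brute-force optimal assignment by exhaustive enumeration
brute_tp <- function(ann, det, half) {
  ok <- function(i, j) abs(ann[i] - det[j]) <= half
  best <- 0L
  recurse <- function(i, used) {
    if (i > length(ann)) return(0L)
    most <- recurse(i + 1L, used)               # leave ann i unmatched
    for (j in seq_along(det)) {
      if (!used[j] && ok(i, j)) {
        u <- used; u[j] <- TRUE
        most <- max(most, 1L + recurse(i + 1L, u))
      }
    }
    most
  }
  recurse(1L, logical(length(det)))
}

test_that("matching attains the exhaustive-optimal TP count", {
  # the adversarial overlap case where closest-first greedy drops a match
  ann <- c(0, 0.02); det <- c(-0.02, 0.01)
  m <- match_beats(ann, det)
  expect_equal(nrow(m$tp_pairs), 2L)
  set.seed(51)
  for (r in 1:400) {
    n_a <- sample(0:5, 1); n_d <- sample(0:5, 1)
    ann <- sort(round(runif(n_a, 0, 0.3), 3))
    det <- sort(round(runif(n_d, 0, 0.3), 3))
    ann <- ann[!duplicated(ann)]; det <- det[!duplicated(det)]
    m <- match_beats(ann, det)
    expect_equal(nrow(m$tp_pairs), brute_tp(ann, det, 0.025),
                 label = sprintf("ann=%s det=%s", toString(ann),
                                 toString(det)))
  }
})

test_that("published beat tallies reproduce their printed metrics", {
  r1 <- score_record(tp = 1468, fn = 103, fp = 63)
  expect_equal(r1$se, 93.44, tolerance = 0.005)
  expect_equal(r1$ppv, 95.89, tolerance = 0.005)
  expect_equal(r1$der, 10.57, tolerance = 0.005)
  r2 <- score_record(tp = 1038, fn = 533, fp = 74)
  expect_equal(r2$se, 66.07, tolerance = 0.005)
  expect_equal(r2$der, 38.63, tolerance = 0.01)
})

test_that("zero denominators propagate as missing, not zero", {
  r <- score_record(tp = 0, fn = 0, fp = 3)
  expect_true(is.na(r$se))
  expect_true(is.na(r$der))
  expect_equal(r$ppv, 0)
})

test_that("metrics are invariant to a global time shift", {
  set.seed(52)
  ann <- sort(runif(30, 0, 30))
  det <- sort(ann + rnorm(30, 0, 0.01))
  r1 <- score_record(match_beats(ann, det))
  r2 <- score_record(match_beats(ann + 5, det + 5))
  expect_equal(r1$tp, r2$tp)
  expect_equal(r1$jitter_mean, r2$jitter_mean, tolerance = 1e-9)
})

test_that("conservation: tp + fn equals the annotation count", {
  set.seed(53)
  for (r in 1:50) {
    ann <- sort(runif(sample(1:15, 1), 0, 5))
    det <- sort(runif(sample(0:15, 1), 0, 5))
    ann <- ann[!duplicated(ann)]; det <- det[!duplicated(det)]
    m <- match_beats(ann, det)
    expect_equal(nrow(m$tp_pairs) + length(m$fn), length(ann))
    expect_lte(nrow(m$tp_pairs), length(det))
    expect_equal(nrow(m$tp_pairs) + length(m$fp), length(det))
  }
})

test_that("aggregation combines records with n-1 standard deviations", {
  r1 <- score_record(tp = 80, fn = 20, fp = 0)    # Se 80
  r2 <- score_record(tp = 100, fn = 0, fp = 0)    # Se 100
  agg <- aggregate_scores(list(r1, r2))
  expect_equal(agg$se[["mean"]], 90)
  expect_equal(agg$se[["sd"]], sd(c(80, 100)))
  expect_equal(unname(agg$totals), c(180, 0, 20))
  one <- aggregate_scores(list(r1))
  expect_equal(one$se[["mean"]], 80)
  expect_equal(one$se[["sd"]], 0)
  expect_error(aggregate_scores(list()), "no reports")
  # DER exceedance fraction
  bad <- score_record(tp = 30, fn = 70, fp = 10)  # DER 80
  agg2 <- aggregate_scores(list(r1, r2, bad))
  expect_equal(agg2$frac_der_above, 1 / 3)
})
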