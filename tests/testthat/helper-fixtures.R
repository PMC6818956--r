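# shared small fixtures, built in code at test time

short_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_ecg(duration_s = 90, mean_hr = 70, hr_sd = 3,
                             fs = 360, seed = 42)
    cache
  }
})

# a record long enough for heating plus a stretch of running mode
heated_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_ecg(duration_s = 120, mean_hr = 70, hr_sd = 3,
                             fs = 360, seed = 7)
    cache
  }
})

expect_close <- function(object, expected, tol = 1e-8) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("max |diff| = %.3g",
                              max(abs(object - expected))))
}
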