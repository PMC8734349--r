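# Shared fixtures: everything is generated in code at test time.

ll4_timing <- function(rr_ms = 1000, ti1_ms = 100) {
  acquisition_timing("4", rr_ms = rr_ms, ti1_ms = ti1_ms)
}

# Noiseless LL4 signals for a known tissue
ll4_signals <- function(t1_ms, b_over_a = 1.9, rr_ms = 1000, ti1_ms = 100,
                        a = 1) {
  tis <- ll4_timing(rr_ms, ti1_ms)$tis_ms
  list(signals = ir_signal(tis, a, b_over_a * a,
                           apparent_from_true(t1_ms, b_over_a)),
       tis_ms = tis)
}

# A small trained network reused by fast tests (tiny hidden layers keep it
# seconds-scale; the default architecture is exercised in the acceptance
# suite).
small_trained_net <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- simulate_pixels(6000, snr = 50, seed = 401)
      va <- simulate_pixels(1500, snr = 50, seed = 402)
      cache <<- t1net(tr, va, hidden = c(64, 32), max_epochs = 12,
                      patience = 70, seed = 403)
    }
    cache
  }
})

# The full-scale estimator of the acceptance runs, trained once and shared
# by the acceptance tests (training dominates the suite's runtime).
acceptance_net <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- simulate_pixels(200000, snr = 50, seed = 501)
      va <- simulate_pixels(20000, snr = 50, seed = 502)
      cache <<- t1net(tr, va, max_epochs = 60, patience = 70, seed = 503)
    }
    cache
  }
})
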