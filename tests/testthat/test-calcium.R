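make_trace <- function(ratio, sigma, interval = 0.5) {
  tr <- structure(list(roi_id = "t", F = ratio * 100, F0 = 100, ratio = ratio,
                       baseline_window = 1:10, frame_interval_s = interval,
                       noise_sigma = sigma),
                  class = "calcium_trace")
  tr
}

test_that("extract_trace averages ROI pixels, matching a per-pixel loop", {
  frames <- array(100, dim = c(5, 8, 8))
  m <- calcium_movie(frames, 1)
  roi <- neuron_roi("a", rbind(c(2, 3), c(4, 5)))
  expect_equal(extract_trace(m, roi), rep(100, 5))

  frames2 <- array(0, dim = c(2, 4, 4))
  frames2[1, 2, 2] <- 10; frames2[1, 3, 3] <- 30
  m2 <- calcium_movie(frames2, 1)
  expect_equal(extract_trace(m2, neuron_roi("b", rbind(c(1, 1), c(2, 2))))[1], 20)

  set.seed(1)
  frames3 <- array(runif(6 * 10 * 10, 0, 100), dim = c(6, 10, 10))
  m3 <- calcium_movie(frames3, 1)
  px <- unique(cbind(sample(0:9, 12, TRUE), sample(0:9, 12, TRUE)))
  roi3 <- neuron_roi("c", px)
  oracle <- sapply(1:6, function(t) {
    acc <- 0
    for (k in seq_len(nrow(px))) acc <- acc + frames3[t, px[k, 1] + 1, px[k, 2] + 1]
    acc / nrow(px)
  })
  expect_equal(extract_trace(m3, roi3), oracle, tolerance = 1e-12)
  expect_error(extract_trace(m3, neuron_roi("d", rbind(c(50, 50)))), "empty")
})

test_that("F/F0 normalisation fixes the baseline at 1", {
  expect_equal(normalize_f0(rep(80, 40), 1:10)$ratio, rep(1, 40))
  F <- c(rep(50, 20), rep(100, 5), rep(50, 15))
  tr <- normalize_f0(F, 1:20)
  expect_equal(tr$F0, 50)
  expect_equal(max(tr$ratio), 2)
  expect_error(normalize_f0(rep(0, 40), 1:10), "F0")
})

test_that("noise estimation is robust to a linear bleach ramp", {
  expect_equal(estimate_noise(make_trace(rep(1, 50), NA)), 0)
  set.seed(5)
  ratio <- 1 + rnorm(200, sd = 0.004)
  tr <- make_trace(ratio, NA)
  tr$baseline_window <- 1:200
  est <- estimate_noise(tr)
  expect_lt(abs(est - 0.004) / 0.004, 0.15)
  ramp <- make_trace(seq(1, 0.9, length.out = 60), NA)
  ramp$baseline_window <- 1:60
  expect_lt(estimate_noise(ramp), 1e-6)
  expect_lt(abs(estimate_noise(tr, "mad") - 0.004) / 0.004, 0.2)
  short <- make_trace(rep(1, 20), NA); short$baseline_window <- 1:5
  expect_error(estimate_noise(short), "at least 10")
})

test_that("the 5-sigma rule calls a 3.6% peak over 0.4% noise a responder", {
  ratio <- rep(1, 60); ratio[35] <- 1.036
  call <- detect_transient(make_trace(ratio, 0.004), window = c(15, 25))
  expect_true(call$responder)
  expect_equal(call$max_amplitude_pct, 3.6)
  expect_equal(call$threshold_ratio, 1.02)
  expect_equal(call$peak_time_s, 34 * 0.5)
})

test_that("flat traces and exact-threshold peaks are non-responders", {
  flat <- detect_transient(make_trace(rep(1, 60), 0.004), window = c(15, 25))
  expect_false(flat$responder)
  expect_equal(flat$max_amplitude_pct, 0)
  ratio <- rep(1, 60); ratio[32] <- 1 + 5 * 0.004  # exactly at threshold
  at <- detect_transient(make_trace(ratio, 0.004), window = c(15, 25))
  expect_false(at$responder)
  just <- rep(1, 60); just[32] <- 1 + 5 * 0.004 + 1e-12
  expect_true(detect_transient(make_trace(just, 0.004), window = c(15, 25))$responder)
})

test_that("responder percentage arithmetic and label guards", {
  mk <- function(resp, amp = 5) structure(
    list(roi_id = "x", stimulus = "highK", responder = resp,
         max_amplitude_pct = amp, peak_time_s = 1, noise_sigma = 0.004,
         threshold_ratio = 1.02), class = "transient_call")
  s0 <- summarize_stimulus(replicate(10, mk(FALSE, 0), simplify = FALSE))
  expect_equal(s0$pct_responders, 0)
  s <- summarize_stimulus(c(replicate(7, mk(TRUE), simplify = FALSE),
                            replicate(7, mk(FALSE, 0), simplify = FALSE)))
  expect_equal(s$pct_responders, 50)
  expect_equal(s$n_neurons, 14L)
  sr <- summarize_stimulus(c(replicate(7, mk(TRUE, 6), simplify = FALSE),
                             replicate(7, mk(FALSE, 0), simplify = FALSE)),
                           amplitude_over = "responders")
  expect_equal(sr$mean_max_amplitude_pct, 6)
  bad <- list(mk(TRUE), mk(TRUE))
  bad[[2]]$stimulus <- "DMPP"
  expect_error(summarize_stimulus(bad), "mix")
})

test_that("the pipeline is invariant to uniform intensity rescaling", {
  sim <- simulate_calcium_movie(small_calcium_params(n_neurons = 6))
  res1 <- analyze_calcium(sim$movie, sim$rois, register = FALSE)
  m2 <- sim$movie
  m2$frames <- m2$frames * 3.7
  res2 <- analyze_calcium(m2, sim$rois, register = FALSE)
  expect_equal(res1$calls$responder, res2$calls$responder)
  expect_equal(res1$calls$max_amplitude_pct, res2$calls$max_amplitude_pct,
               tolerance = 1e-10)
})

test_that("raising the noise level can only demote responders", {
  set.seed(11)
  for (k in 1:20) {
    ratio <- 1 + abs(rnorm(1, 0.03, 0.02)) * c(rep(0, 30), exp(-(0:29) / 10))
    ratio <- ratio + rnorm(60, sd = 0.002)
    sig <- sort(runif(5, 0.001, 0.02))
    calls <- vapply(sig, function(s)
      detect_transient(make_trace(ratio, s), window = c(15, 30))$responder, TRUE)
    expect_true(all(diff(as.integer(calls)) <= 0))
  }
})

test_that("end-to-end analysis recovers the simulated responder fraction", {
  sim <- simulate_calcium_movie(small_calcium_params(
    n_neurons = 60, responder_fraction = 0.6, field_shape_px = c(160, 160),
    seed = 8L))
  res <- analyze_calcium(sim$movie, sim$rois)
  expect_lt(abs(res$summary$pct_responders - 60), 10)
})
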