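# ITC, the Rayleigh closed form, the CKC metric with FDR, the FFT-based
# estimator, and the epoch-count sweep.

test_that("ITC reproduces closed-form phasor cases", {
  arr <- function(v) array(v, dim = c(length(v), 1, 1, 1))
  expect_equal(as.numeric(itc(arr(rep(0.7, 5)))), 1, tolerance = 1e-12)
  expect_equal(as.numeric(itc(arr(c(0, pi / 2, pi, 3 * pi / 2)))), 0,
               tolerance = 1e-12)
  expect_equal(as.numeric(itc(arr(c(0, pi / 2)))), sqrt(2) / 2, tolerance = 1e-12)
  expect_error(itc(arr(0)), class = "insufficient_trials")
})

test_that("ITC of N copies of one epoch is 1", {
  set.seed(5)
  ph <- runif(30, -pi, pi)
  arr <- array(rep(ph, each = 12), dim = c(12, 1, 1, 30))
  expect_true(all(abs(itc(arr) - 1) < 1e-12))
})

test_that("the Rayleigh closed form matches its printed special cases", {
  expect_identical(rayleigh_p(0, 10), 1)
  expect_identical(rayleigh_p(0, 1000), 1)
  expect_equal(rayleigh_p(0.2, 100), 0.01794748, tolerance = 1e-6)
  expect_lt(rayleigh_p(1, 100), 1e-70)
  expect_error(rayleigh_p(0.5, 1), class = "insufficient_trials")
})

test_that("rayleigh_p is monotone in ITC and in N", {
  itcs <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(rayleigh_p(itcs, 50)) < 0))
  ns <- c(5, 10, 20, 50, 100, 500)
  expect_true(all(diff(rayleigh_p(0.3, ns)) < 0))
})

test_that("the Rayleigh approximation agrees with uniform-phase Monte-Carlo", {
  # empirical P(R >= itc) from 1e6 resultant lengths of N uniform phases
  mc_tail <- function(n, itc_vals, n_draws = 1e6, chunk = 20000) {
    hits <- numeric(length(itc_vals))
    set.seed(1234 + n)
    done <- 0
    while (done < n_draws) {
      m <- min(chunk, n_draws - done)
      ph <- matrix(runif(m * n, -pi, pi), nrow = n)
      r <- sqrt(colMeans(cos(ph))^2 + colMeans(sin(ph))^2)
      for (i in seq_along(itc_vals)) hits[i] <- hits[i] + sum(r >= itc_vals[i])
      done <- done + m
    }
    hits / n_draws
  }
  for (n in c(50, 200)) {
    emp <- mc_tail(n, c(0.1, 0.2, 0.3))
    approx <- rayleigh_p(c(0.1, 0.2, 0.3), n)
    # 15 % relative agreement wherever 1e6 draws can resolve the tail;
    # rarer cells must simply be consistent with a sub-resolution tail
    resolvable <- approx >= 1e-4
    expect_true(all(abs(emp[resolvable] - approx[resolvable]) /
                      approx[resolvable] < 0.15))
    expect_true(all(emp[!resolvable] <= 1e-5))
  }
})

test_that("ckc_metric flags a perfectly locked map and respects the window", {
  # constant phase across epochs at the response bin
  n_t <- 275
  time_ms <- (0:(n_t - 1)) / 250 * 1000 - 200
  ph <- array(0.3, dim = c(50, 3, 1, n_t))
  tfr <- make_tfr(ph, 3.56, time_ms, labels = c("C3", "C4", "Cz"))
  res <- ckc_metric(tfr)
  expect_equal(res$channels$ckc, rep(1, 3))
  expect_true(all(res$channels$significant))
  expect_error(ckc_metric(tfr, response_freq = 5), class = "invalid_parameter")
})

test_that("channel detection at alpha 0.01 is calibrated under the null", {
  # narrowband null: per-epoch random phase, constant within the epoch
  set.seed(77)
  n_rep <- 500; n_ep <- 200; n_ch <- 21
  p_all <- replicate(n_rep, {
    ph <- matrix(runif(n_ep * n_ch, -pi, pi), n_ep, n_ch)
    tfr <- make_tfr(array(ph, dim = c(n_ep, n_ch, 1, 1)), 3.56, 350)
    ckc_metric(tfr, edge_exclusion = 0)$channels$p
  })
  rate <- mean(p_all < 0.01)
  expect_gte(rate, 0.002)
  expect_lte(rate, 0.025)
})

test_that("BH-FDR keeps the flagged fraction at or below q under the null", {
  set.seed(88)
  flagged <- replicate(300, {
    ph <- matrix(runif(100 * 21, -pi, pi), 100, 21)
    tfr <- make_tfr(array(ph, dim = c(100, 21, 1, 1)), 3.56, 350)
    mean(ckc_metric(tfr, edge_exclusion = 0, alpha = 0.05, fdr_q = 0.05)$channels$significant)
  })
  expect_lte(mean(flagged), 0.05)
})

test_that("end-to-end detection is specific to the response channels", {
  rec <- generate_scalp_recording(230, phase_jitter_sd = 1.0, seed = 6)
  res <- run_detection_pipeline(rec)
  expect_gte(res$n_epochs, 195)
  ch <- res$channels
  expect_true(all(ch$significant[ch$channel %in% c("C3", "C4")]))
  others <- ch$significant[!ch$channel %in% c("C3", "C4")]
  expect_gte(mean(!others), 0.9)
})

test_that("zero-amplitude recordings produce no spurious detections", {
  # channel-level inference is conservative on aggregate P values, so the
  # empirical rate must not exceed the alpha band's upper edge
  ps <- unlist(lapply(1:10, function(s) {
    rec <- generate_scalp_recording(70, response_amplitude = 0, seed = 900 + s)
    run_detection_pipeline(rec)$channels$p
  }))
  expect_lte(mean(ps < 0.01), 0.025)
})

test_that("the FFT estimator matches on locked data and shares the machinery", {
  rec <- generate_scalp_recording(60, phase_jitter_sd = 0, noise_amplitude = 0,
                                  response_amplitude = 5, seed = 13)
  res <- run_detection_pipeline(rec)
  fft_res <- ckc_fft(attr(res, "epochs"))
  c3 <- fft_res$channels[fft_res$channels$channel == "C3", ]
  expect_gt(c3$ckc, 0.99)
  expect_true(c3$significant)
  expect_identical(fft_res$method, "fft")
})

test_that("the epoch-count sweep detects early on locked data and never on null", {
  rec <- generate_scalp_recording(70, phase_jitter_sd = 0, noise_amplitude = 0,
                                  response_amplitude = 5, seed = 14)
  res <- run_detection_pipeline(rec)
  sw <- epoch_count_sweep(attr(res, "epochs"), step = 10)
  expect_true(all(sw$any_significant))
  expect_true(all(diff(sw$n_epochs) == 10))

  rec0 <- generate_scalp_recording(70, response_amplitude = 0, seed = 15)
  res0 <- run_detection_pipeline(rec0)
  sw0 <- epoch_count_sweep(attr(res0, "epochs"), step = 10)
  expect_false(any(sw0$any_significant))
})

test_that("detection at in-band SNR 1 and jitter 1.0 rad holds by 100 epochs", {
  rec <- generate_scalp_recording(125, phase_jitter_sd = 1.0, seed = 1)
  res <- run_detection_pipeline(rec)
  sw <- epoch_count_sweep(attr(res, "epochs"), step = 20)
  expect_true(all(sw$any_significant[sw$n_epochs >= 100]))
})
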