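# Narrowband phase extraction, the PTE estimator against a brute-force
# oracle, and dPTE matrix properties.

test_that("narrowband phase of a response-frequency tone advances correctly", {
  fs <- 250
  t <- (0:14999) / fs
  ph <- narrowband_phase(rbind(sin(2 * pi * 3.56 * t)), fs = fs)
  d <- diff(ph[1, ])
  d <- (d + pi) %% (2 * pi) - pi
  expect_equal(mean(d), 2 * pi * 3.56 / fs, tolerance = 1e-3)
})

test_that("the band constraint suppresses out-of-band tones", {
  fs <- 250
  t <- (0:14999) / fs
  x <- sin(2 * pi * 10 * t)
  hp <- signal::fir1(626, (3.56 - 0.3) / 125, type = "high")
  lp <- signal::fir1(626, (3.56 + 0.3) / 125, type = "low")
  y <- ckcnet:::fir_filtfilt_fft(lp, ckcnet:::fir_filtfilt_fft(hp, x))
  mid <- 2000:13000
  expect_lt(sqrt(mean(y[mid]^2)) / sqrt(0.5), 0.01)
})

test_that("FFT-based zero-phase FIR filtering equals signal::filtfilt", {
  set.seed(3)
  x <- rnorm(3000)
  b <- signal::fir1(200, 0.1, type = "low")
  expect_equal(ckcnet:::fir_filtfilt_fft(b, x),
               signal::filtfilt(b, x), tolerance = 1e-10)
})

test_that("white-noise narrowband phase increments centre on the carrier step", {
  set.seed(4)
  ph <- narrowband_phase(rbind(rnorm(15000)), fs = 250)
  d <- diff(ph[1, ])
  d <- (d + pi) %% (2 * pi) - pi
  expect_equal(mean(d), 2 * pi * 3.56 / 250, tolerance = 0.05)
  expect_gt(sd(d), 0)
  expect_error(narrowband_phase(rbind(rnorm(1000)), fs = 250),
               class = "length_error")
})

test_that("PTE is symmetric for identical series and validates inputs", {
  set.seed(6)
  ph <- narrowband_phase(rbind(rnorm(8000)), fs = 250)[1, ]
  p <- pte_pair(ph, ph, delay = 10, n_bins = 8)
  expect_equal(unname(p["pte_xy"]), unname(p["pte_yx"]), tolerance = 1e-12)
  expect_error(pte_pair(ph, ph[-1]), class = "invalid_parameter")
  expect_error(pte_pair(rep(0.5, 1000), ph[1:1000]), class = "degenerate_signal")
  expect_error(pte_pair(ph[1:50], ph[1:50], delay = 10),
               class = "invalid_parameter")
})

test_that("PTE matches the brute-force histogram-entropy oracle to 1e-10", {
  set.seed(7)
  for (rep in 1:3) {
    ph <- narrowband_phase(rbind(rnorm(4000), rnorm(4000)), fs = 250)
    got <- pte_pair(ph[1, ], ph[2, ], delay = 7, n_bins = 8)
    want <- oracle_pte(ph[1, ], ph[2, ], delay = 7, n_bins = 8)
    expect_equal(unname(got), unname(want), tolerance = 1e-10)
  }
})

test_that("a delayed copy is recovered as the information source", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rnorm(16000)
    lag <- 5
    y <- c(rep(0, lag), x[1:(16000 - lag)]) + 0.05 * rnorm(16000)
    ph <- narrowband_phase(rbind(x, y), fs = 250)
    p <- pte_pair(ph[1, ], ph[2, ])
    p["pte_xy"] > p["pte_yx"]
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("independent narrowband noises give dPTE near one half", {
  vals <- vapply(1:12, function(s) {
    set.seed(100 + s)
    ph <- narrowband_phase(rbind(rnorm(15000), rnorm(15000)), fs = 250)
    p <- pte_pair(ph[1, ], ph[2, ])
    unname(p["pte_xy"] / sum(p))
  }, 0)
  expect_true(all(abs(vals - 0.5) < 0.08))
  expect_lt(abs(mean(vals) - 0.5), 0.03)
})

test_that("dpte_matrix is antisymmetric with a masked diagonal", {
  ps <- generate_parcel_signals(40, parcels = parcel_table()[1:5, ], seed = 31)
  im <- dpte_matrix(ps)
  expect_true(all(is.na(diag(im$dpte))))
  s <- im$dpte + t(im$dpte)
  expect_equal(unname(s[im$mask]), rep(1, sum(im$mask)), tolerance = 1e-9)
  expect_true(all(im$dpte[im$mask] >= 0 & im$dpte[im$mask] <= 1))
})

test_that("a moderately coupled parcel pair is recovered as source and sink", {
  hits <- vapply(1:20, function(s) {
    ps <- generate_parcel_signals(
      60, parcels = parcel_table()[1:2, ],
      coupling_edges = data.frame(source = "L_F1", target = "L_F2",
                                  lag = 5, strength = 0.8),
      seed = s)
    im <- dpte_matrix(ps)
    im$dpte[1, 2] > 0.5 && im$dpte[2, 1] < 0.5
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("direction recovery degrades monotonically with phase noise", {
  grid <- c(0.02, 0.05, 0.15)   # informative regime before the 0.5 floor
  mean_dpte <- vapply(grid, function(noise) {
    vals <- vapply(1:6, function(s) {
      ps <- generate_parcel_signals(
        40, parcels = parcel_table()[1:2, ], phase_noise_sd = noise,
        coupling_edges = data.frame(source = "L_F1", target = "L_F2",
                                    lag = 5, strength = 0.8),
        seed = 200 + s)
      dpte_matrix(ps)$dpte[1, 2]
    }, 0)
    mean(vals)
  }, 0)
  expect_true(all(diff(mean_dpte) < 0))
  expect_gt(mean_dpte[1], 0.6)
  # heavy phase noise floors the estimator at no-preferred-direction
  floor_vals <- vapply(1:6, function(s) {
    ps <- generate_parcel_signals(
      40, parcels = parcel_table()[1:2, ], phase_noise_sd = 1.2,
      coupling_edges = data.frame(source = "L_F1", target = "L_F2",
                                  lag = 5, strength = 0.8),
      seed = 300 + s)
    dpte_matrix(ps)$dpte[1, 2]
  }, 0)
  expect_lt(abs(mean(floor_vals) - 0.5), 0.05)
})

test_that("the fidelity mask removes edges from every summary", {
  ps <- generate_parcel_signals(40, parcels = parcel_table()[1:4, ], seed = 32)
  mask <- fidelity_mask_full(4)
  mask[1, 2] <- mask[2, 1] <- FALSE
  im <- dpte_matrix(ps, mask = mask)
  expect_true(is.na(im$dpte[1, 2]) && is.na(im$dpte[2, 1]))
  expect_equal(nrow(tidy(im)), sum(mask))
  expect_error(dpte_matrix(ps, mask = fidelity_mask_full(5)),
               class = "incompatible_inputs")
})

test_that("projection to parcels preserves linear structure", {
  rec <- generate_scalp_recording(10, seed = 33)
  pt <- parcel_table()[1:21, ]
  ps <- project_to_parcels(rec, diag(21), parcels = pt)
  expect_equal(unname(ps$data), unname(rec$signals))

  # random orthonormal operator preserves total energy
  set.seed(34)
  q <- qr.Q(qr(matrix(rnorm(21 * 21), 21)))
  pq <- project_to_parcels(rec, q, parcels = pt)
  expect_equal(sum(pq$data^2), sum(rec$signals^2), tolerance = 1e-9)

  expect_error(project_to_parcels(rec, diag(5)), class = "invalid_operator")
  zeros <- project_to_parcels(rec, matrix(0, 21, 21), parcels = pt)
  expect_error(narrowband_phase(zeros), class = "degenerate_signal")
})

test_that("interaction matrices round-trip through labelled CSV", {
  im <- random_im(6, seed = 41)
  path <- tempfile(fileext = ".csv")
  write_interaction_matrix(im, path)
  back <- read_interaction_matrix(path)
  expect_equal(back, im$dpte, tolerance = 1e-9)
  expect_identical(rownames(back), im$parcels$label)
})

test_that("fidelity mask CSV reading symmetrizes and blanks the diagonal", {
  m <- matrix(1, 4, 4); m[1, 2] <- 0
  path <- tempfile(fileext = ".csv")
  write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  mask <- read_fidelity_mask(path)
  expect_false(mask[1, 2] || mask[2, 1])
  expect_false(any(diag(mask)))
  expect_true(mask[3, 4])
})
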