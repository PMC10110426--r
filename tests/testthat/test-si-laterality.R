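# Reference distribution, control-referenced edge z-scores, Spreading Index
# selection/recovery, and the laterality / symmetry ratios.

test_that("the reference distribution pools valid control edges", {
  im <- random_im(20, sd = 0.03, seed = 101)
  ref <- reference_distribution(im)
  v <- im$dpte[im$mask]
  expect_equal(ref$mu, mean(v), tolerance = 1e-12)
  expect_equal(ref$sigma, sd(v), tolerance = 1e-12)
  expect_equal(ref$n_pooled, length(v))
  expect_lt(abs(ref$mu - 0.5), 0.01)

  expect_error(reference_distribution(NULL), class = "missing_control")
  flat <- make_im(matrix(0.5, 20, 20))
  expect_error(reference_distribution(flat), class = "invalid_parameter")
  expect_error(reference_distribution(random_im(4, seed = 1)),
               class = "invalid_parameter")   # < 30 pooled edges
})

test_that("edge z-scores follow the standardization identities", {
  im <- random_im(20, seed = 102)
  ref <- reference_distribution(im)
  stim <- random_im(20, seed = 103)
  zs <- edge_zscores(stim, ref, alpha = 0.01)

  i <- which(zs$mask, arr.ind = TRUE)[1, ]
  expect_equal(zs$z[i[1], i[2]],
               (stim$dpte[i[1], i[2]] - ref$mu) / ref$sigma, tolerance = 1e-12)

  # dpte = mu => z = 0, not significant; mu + 3 sigma => significant
  stim2 <- stim
  stim2$dpte[1, 2] <- ref$mu
  stim2$dpte[2, 1] <- 1 - ref$mu
  stim2$dpte[1, 3] <- ref$mu + 3 * ref$sigma
  stim2$dpte[3, 1] <- 1 - stim2$dpte[1, 3]
  zs2 <- edge_zscores(stim2, ref, alpha = 0.01)
  expect_equal(zs2$z[1, 2], 0, tolerance = 1e-12)
  expect_false(zs2$significant[1, 2])
  expect_equal(zs2$z[1, 3], 3, tolerance = 1e-12)
  expect_true(zs2$significant[1, 3])

  # antisymmetry identity: z_xy + z_yx = (1 - 2 mu) / sigma
  zsum <- zs$z + t(zs$z)
  expect_equal(unname(zsum[zs$mask]),
               rep((1 - 2 * ref$mu) / ref$sigma, sum(zs$mask)),
               tolerance = 1e-9)
})

test_that("the toy z-matrix gives SI = 60 from 3 of 5 significant edges", {
  pt <- parcel_table()[c(1:3, 30:32), ]   # 3 left, 3 right parcels
  z <- matrix(0, 6, 6)
  # left parcels 1..3; plant significant outbound edges (z = 4 > 2.33)
  z[1, 2] <- 4; z[1, 4] <- 4                   # parcel 1: 2 significant
  z[2, 5] <- 4                                 # parcel 2: 1 significant
  # mask: valid edges only where marked plus enough to make 5 outbound total
  zm <- matrix(NA_real_, 6, 6)
  zm[1, c(2, 4)] <- z[1, c(2, 4)]
  zm[2, c(5, 6)] <- c(z[2, 5], 0)
  zm[3, 4] <- 0
  zs <- make_zs(zm, pt, alpha = 0.01)
  si <- spreading_index(zs, "left", n_sources = 3)
  expect_equal(si$n_possible, 5)
  expect_equal(si$n_significant, 3)
  expect_equal(si$si, 60)
  expect_setequal(si$source_parcels, pt$label[1:3])
})

test_that("SI limits: all-significant gives 100, none gives 0 with a flag", {
  pt <- parcel_table()[1:8, ]
  z_hi <- matrix(5, 8, 8)
  zs <- make_zs(z_hi, pt)
  si <- spreading_index(zs, "left")
  expect_equal(si$si, 100)
  expect_false(si$degenerate)

  z_lo <- matrix(0, 8, 8)
  si0 <- spreading_index(make_zs(z_lo, pt), "left")
  expect_equal(si0$si, 0)
  expect_true(si0$degenerate)
})

test_that("SI recovers planted outbound edge fractions within 10 points", {
  pt <- parcel_table()
  left <- which(pt$hemisphere == "left")
  for (f in c(0.2, 0.5, 0.8)) {
    si_vals <- vapply(1:20, function(s) {
      set.seed(4000 + s + round(1000 * f))
      z <- matrix(rnorm(58 * 58), 58, 58)
      sources <- left[1:4]
      for (src in sources) {
        targets <- setdiff(1:58, src)
        n_sig <- round(f * length(targets))
        hot <- sample(targets, n_sig)
        z[src, hot] <- 5
        z[src, setdiff(targets, hot)] <- -1   # keep the rest quiet
      }
      spreading_index(make_zs(z, pt), "left")$si
    }, 0)
    expect_lt(abs(mean(si_vals) - 100 * f), 10)
  }
})

test_that("SI validates hemisphere membership and outbound-edge availability", {
  pt <- parcel_table()[1:6, ]   # all left
  z <- matrix(1, 6, 6)
  expect_error(spreading_index(make_zs(z, pt), "right"),
               class = "invalid_parameter")
  z_na <- matrix(NA_real_, 6, 6)
  z_na[1, 2] <- 1
  expect_error(spreading_index(make_zs(z_na, pt), "left"),
               class = "undefined_si")
})

test_that("laterality and symmetry reproduce their limiting cases", {
  expect_equal(laterality(0.3, 0.3), 50)
  expect_equal(laterality(0.3, 0), 100)
  expect_equal(laterality(0.3, 0.1), 75)
  expect_error(laterality(0, 0), class = "undefined_laterality")
  expect_error(laterality(-1, 1), class = "invalid_parameter")

  expect_equal(symmetry(0.4, 0.4), 100)
  expect_equal(symmetry(0.2, 0.4), 50)
  expect_equal(symmetry(0, 0.4), 0)
  expect_error(symmetry(0, 0), class = "undefined_symmetry")
})

test_that("laterality is reciprocal across the two hemispheres", {
  set.seed(110)
  for (i in 1:20) {
    a <- runif(1, 0.01, 1); b <- runif(1, 0.01, 1)
    expect_equal(laterality(a, b) + laterality(b, a), 100, tolerance = 1e-12)
  }
})

test_that("hemispheric CKC laterality excludes midline and honours the side", {
  channels <- tibble::tibble(
    channel = c("C3", "P3", "Cz", "C4", "P4"),
    ckc = c(0.6, 0.4, 0.9, 0.2, 0.1),
    p = 0.001, p_adj = 0.001, significant = TRUE)
  res <- structure(list(channels = channels, n_epochs = 100,
                        response_freq = 3.56, method = "wavelet"),
                   class = "ckc_result")
  lat <- ckc_laterality(res, stim_side = "right", statistic = "max")
  expect_equal(lat$contra, 0.6)   # left hemisphere max, Cz ignored
  expect_equal(lat$ipsi, 0.2)
  expect_equal(lat$laterality, 75)
  lat_mean <- ckc_laterality(res, stim_side = "right", statistic = "mean")
  expect_equal(lat_mean$contra, 0.5)
})
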