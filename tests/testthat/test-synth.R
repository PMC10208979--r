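test_that("layout generators produce the stated geometries", {
  pg <- make_layout("pair_grid", n_pairs = 6, pitch = 20, pair_offset = 0.7)
  expect_equal(nrow(pg$sites), 12)
  d <- sqrt(rowSums((pg$sites[seq(1, 11, 2), 1:2] -
                     pg$sites[seq(2, 12, 2), 1:2])^2))
  expect_equal(d, rep(0.7, 6))
  expect_identical(pg$channel, rep(c(0L, 1L), 6))  # orthogonal by design

  rc <- make_layout("ring_complex")
  expect_equal(nrow(rc$sites), 32)  # 8 pairs on each of two rings
  pair_d <- sqrt(rowSums((rc$sites[seq(1, 31, 2), ] -
                          rc$sites[seq(2, 32, 2), ])^2))
  expect_equal(pair_d, rep(sqrt(11.9^2 + 5.4^2), 16), tolerance = 1e-9)
  expect_equal(sort(unique(round(rc$sites[, "z"], 6))),
               c(-27.7, -22.3, 22.3, 27.7))

  expect_equal(nrow(make_layout("csr", density = 0, area = 100)$sites), 0)
  expect_error(make_layout("grid", pitch = -1), "pitch")
})

test_that("csr layout site counts follow the Poisson mean", {
  set.seed(11)
  counts <- replicate(300, nrow(make_layout("csr", density = 200,
                                            area = 25)$sites))
  expect_lt(abs(mean(counts) - 5000), 3 * sqrt(5000 / 300))
})

test_that("stochastic channel assignment is uniform and pairs split at 1-1/n", {
  lay <- make_layout("csr", density = 100, area = 100, seed = 3)
  lay <- assign_channels(lay, 1, seed = 4)
  expect_true(all(lay$channel == 0L))

  big <- make_layout("csr", density = 1000, area = 100, seed = 5)
  big <- assign_channels(big, 4, seed = 6)
  n <- nrow(big$sites)
  freq <- tabulate(big$channel + 1L, 4) / n
  se <- sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(freq - 0.25) < 3.5 * se))
  expect_gt(stats::chisq.test(tabulate(big$channel + 1L, 4))$p.value, 0.001)

  # fraction of pairs with distinct channels ~ 75% for n = 4
  pg <- make_layout("pair_grid", n_pairs = 2000, pitch = 50)
  pg <- assign_channels(pg, 4, seed = 7)
  a <- pg$channel[seq(1, nrow(pg$sites) - 1, 2)]
  b <- pg$channel[seq(2, nrow(pg$sites), 2)]
  expect_lt(abs(mean(a != b) - 0.75), 3 * sqrt(0.75 * 0.25 / 2000))
})

test_that("sampled localization clouds have the requested scatter and frames", {
  lay <- make_layout("grid", nx = 1, ny = 1)
  meta <- acquisition_meta(n_frames = 10000)
  tb <- sample_localizations(lay, sigma_smlm = 3, meta,
                             locs_per_site = 10000, seed = 8)[[1]]
  expect_equal(sd(tb$x), 3, tolerance = 3 / sqrt(2 * 10000) * 3.5 / 3)
  expect_true(all(tb$lp == 3))
  # uniform-frame mode centres the mean frame at half the acquisition
  expect_lt(abs(mean(tb$frame) - 5000), 3 * 10000 / sqrt(12 * 10000))
  # default axial spread is twice the lateral precision
  tb3 <- sample_localizations(lay, sigma_smlm = 3, meta, three_d = TRUE,
                              locs_per_site = 10000, seed = 9)[[1]]
  expect_true(is_3d(tb3))
  expect_equal(sd(tb3$z), 6, tolerance = 0.2)
  # zero sites give an empty, well-formed table
  none <- make_layout("csr", density = 0, area = 10)
  expect_equal(nrow(sample_localizations(none, 3, meta, seed = 1)[[1]]), 0)
})

test_that("generators are reproducible for a fixed seed", {
  lay <- make_layout("csr", density = 50, area = 25, seed = 21)
  lay2 <- make_layout("csr", density = 50, area = 25, seed = 21)
  expect_identical(lay$sites, lay2$sites)
  t1 <- sample_localizations(lay, 3, acquisition_meta(1000), seed = 22)
  t2 <- sample_localizations(lay, 3, acquisition_meta(1000), seed = 22)
  expect_identical(t1, t2)
  p1 <- simulate_mixture(mixture_params(50, 25, 13.5, 5, 0.5, 25), seed = 23)
  p2 <- simulate_mixture(mixture_params(50, 25, 13.5, 5, 0.5, 25), seed = 23)
  expect_identical(p1$xy, p2$xy)
})

test_that("mixture simulation honours thinning, density and dimer distance", {
  expect_equal(nrow(simulate_mixture(mixture_params(100, 50, 10, 2, 0, 25),
                                     seed = 1)$xy), 0)
  expect_error(mixture_params(100, 0, 10, 2, 0.5, -1), "area")

  # CSR null model at the RTX comparison settings: observed ~ 106 per um^2
  pp <- simulate_mixture(mixture_params(212, 0, 0, 5, 0.5, 100), seed = 2)
  expect_lt(abs(pp$density_observed - 106), 3 * sqrt(10600) / 100)

  # dimers only, no uncertainty: intra-pair distance is exactly D
  dd <- simulate_mixture(mixture_params(0, 100, 13.5, 0, 1, 25), seed = 3)
  nn <- knn_distances(dd, max_order = 1)
  expect_equal(median(nn$distances[, 1]), 13.5, tolerance = 1e-9)

  # binomial thinning of the detectable subset
  set.seed(4)
  n_full <- nrow(simulate_mixture(mixture_params(200, 0, 0, 0, 1, 25),
                                  seed = 5)$xy_all)
  n_half <- mean(replicate(40, nrow(simulate_mixture(
    mixture_params(200, 0, 0, 0, 0.5, 25))$xy_all)))
  expect_lt(abs(n_half / n_full - 0.5), 0.04)
})
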