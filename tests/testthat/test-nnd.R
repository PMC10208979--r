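test_that("k-NN distances match brute force and basic geometry", {
  p <- cbind(c(0, 10, 25), c(0, 0, 0))
  expect_equal(knn_distances(p, max_order = 1)$distances[, 1], c(10, 10, 15))
  for (s in 1:25) {
    set.seed(1000 + s)
    pts <- cbind(runif(120, 0, 200), runif(120, 0, 200))
    got <- knn_distances(pts, max_order = 4)$distances
    expect_equal(got, brute_knn(pts, 4), tolerance = 1e-12,
                 ignore_attr = TRUE)
    # order statistics are sorted per point
    expect_true(all(got[, 1] <= got[, 2] & got[, 2] <= got[, 3] &
                    got[, 3] <= got[, 4]))
  }
  expect_error(knn_distances(p, max_order = 3), "more than")
})

test_that("CSR first-NND distances follow 1 - exp(-rho pi d^2)", {
  ref <- csr_reference(density = 100, area = 400, orders = 1, seed = 71)
  d <- ref$distances[, 1]
  rho <- 100e-6  # per nm^2
  ks <- suppressWarnings(stats::ks.test(d, function(q) 1 - exp(-rho * pi * q^2)))
  expect_gt(ks$p.value, 0.01)
  # doubling density scales the median by 1/sqrt(2)
  ref2 <- csr_reference(density = 200, area = 400, orders = 1, seed = 72)
  expect_equal(median(ref2$distances[, 1]) / median(d), 1 / sqrt(2),
               tolerance = 0.05)
})

test_that("guard band removes edge deflation (torus oracle)", {
  # tiny window: without a guard band, edge points lack close neighbours
  set.seed(73)
  side <- 2000; rho <- 200e-6
  n <- rpois(1, rho * side^2)
  pts <- cbind(runif(n, 0, side), runif(n, 0, side))
  # torus-topology oracle via 3x3 tiling, evaluated on the central tile
  tiles <- do.call(rbind, lapply(-1:1, function(i) do.call(rbind,
    lapply(-1:1, function(j) cbind(pts[, 1] + i * side, pts[, 2] + j * side)))))
  torus <- resikit:::cpp_knn_rect(tiles[, 1], tiles[, 2], 1, 0, 0, side, side)
  guarded <- csr_reference(density = 200, area = (side / 1000)^2, orders = 1,
                           seed = 74)
  ks <- suppressWarnings(stats::ks.test(guarded$distances[, 1], torus[, 1]))
  expect_gt(ks$p.value, 0.01)
})

test_that("histogram SSE behaves as a squared distance between samples", {
  edges <- seq(0, 100, 1)
  set.seed(75)
  a <- runif(5000, 0, 80)
  expect_equal(sse_histogram(a, a, edges), 0)
  # disjoint distributions: sum of both squared masses
  left <- runif(2000, 0, 30); right <- runif(2000, 60, 90)
  hl <- resikit:::prob_hist(left, edges); hr <- resikit:::prob_hist(right, edges)
  expect_equal(sse_histogram(left, right, edges), sum(hl^2) + sum(hr^2))
  expect_gt(sse_histogram(left, right, edges), sse_histogram(a, a, edges))
  expect_error(sse_histogram(list(edges = seq(0, 50, 1), counts = rep(1, 50)),
                             a, edges), "do not match")
})

test_that("monomer-only data fit close to zero dimer fraction", {
  pp <- simulate_mixture(mixture_params(212, 0, 0, 5, 0.5, 100), seed = 76)
  fit <- fit_dimer_model(pp, observed_density = pp$density_observed,
                         labelling_efficiency = 0.5, seed = 77)
  expect_lt(coef(fit)[["frac_of_dimers_opt"]], 5)
})

test_that("dimer fit is invariant to translating the point set", {
  mp <- resikit:::mixture_from_fraction(50, 0.5, 47, 13.5, 5.5, 80)
  pp <- simulate_mixture(mp, seed = 78)
  f1 <- fit_dimer_model(pp$xy, 50, 0.5, seed = 79)
  f2 <- fit_dimer_model(sweep(pp$xy, 2, c(5000, -3000), "+"), 50, 0.5,
                        seed = 79)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-9)
  expect_error(fit_dimer_model(matrix(1, 500, 2), 50, 0.5), "degenerate")
})

test_that("refit uncertainties are defined and shrink with more molecules", {
  mp <- resikit:::mixture_from_fraction(50, 0.5, 47, 13.5, 5.5, 100)
  pp <- simulate_mixture(mp, seed = 80)
  fit <- fit_dimer_model(pp, 50, 0.5, seed = 81)
  fit2 <- fit_uncertainty(fit, M = 2, seed = 82)
  expect_true(all(is.finite(fit2$uncertainty)))
  expect_true(fit2$low_M)
  expect_named(fit2$uncertainty,
               c("D_opt", "sigma_label_opt", "frac_of_dimers_opt"))
})
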