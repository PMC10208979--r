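test_that("weighted centre reproduces the closed-form mean and s.e.m.", {
  expect_equal(weighted_center(c(0, 2), c(1, 1))$mean, 1)
  # weights 1 and 1/2: mean = (0 + 0.5 * 3) / 1.5 = 1
  expect_equal(weighted_center(c(0, 3), c(1, sqrt(2)))$mean, 1)
  # equal weights reduce to ordinary mean and Bessel-corrected s.e.m.
  set.seed(51)
  xs <- rnorm(200, 5, 2)
  wc <- weighted_center(xs, rep(1.7, 200))
  expect_equal(wc$mean, mean(xs))
  expect_equal(wc$sem, sd(xs) / sqrt(200))
  # hand-computed heteroscedastic case
  xs <- c(0, 1, 4); lps <- c(1, 2, 2)
  w <- 1 / lps^2
  m <- sum(w * xs) / sum(w)
  v <- 3 / 2 * sum(w * (xs - m)^2) / sum(w)
  wc <- weighted_center(xs, lps)
  expect_equal(wc$mean, m)
  expect_equal(wc$sem, sqrt(v / 3))
  # degenerate inputs
  expect_true(is.na(weighted_center(5, 1)$sem))
  expect_error(weighted_center(c(1, 2), c(1, 0)), "positive")
})

test_that("s.e.m. is consistent for large equal-weight samples", {
  set.seed(52)
  xs <- rnorm(1e4, 0, 3)
  expect_equal(weighted_center(xs, rep(1, 1e4))$sem, 3 / 100,
               tolerance = 0.05)
})

test_that("inverse-variance weighting beats the unweighted mean", {
  set.seed(53)
  err_w <- err_u <- numeric(1000)
  for (i in 1:1000) {
    lps <- runif(30, 0.5, 4)
    xs <- rnorm(30, 0, lps)
    err_w[i] <- weighted_center(xs, lps)$mean
    err_u[i] <- mean(xs)
  }
  expect_lt(var(err_w), var(err_u))
})

test_that("collapse produces one record per kept cluster with correct fields", {
  tb <- two_cloud_table(sep = 30, sigma = 2, K = 120, seed = 54)
  cl <- cluster_locs(tb, cluster_params(r = 4, n_min = 20))
  resi <- collapse_clusters(tb, cl)
  expect_equal(nrow(resi), 2)
  expect_true(all(resi$K > 100))
  expect_equal(sort(round(resi$x / 10) * 10), c(0, 30))
  # precision ~ sigma / sqrt(K)
  expect_equal(resi$lp, 2 / sqrt(resi$K), tolerance = 0.25)

  # identical points collapse to zero precision at the exact point
  same <- loc_table(data.frame(x = rep(7, 30), y = rep(9, 30),
                               frame = sample(0:999, 30), lp = 1),
                    acquisition_meta(1000))
  cl2 <- cluster_locs(same, cluster_params(r = 2, n_min = 5))
  r2 <- collapse_clusters(same, cl2)
  expect_equal(r2$x, 7)
  expect_equal(r2$lp, 0)

  expect_error(collapse_clusters(tb[1:10, ], cl), "match")
})

test_that("3D collapse uses unweighted z and doubled axial precision", {
  set.seed(55)
  df <- data.frame(x = rnorm(200, 0, 2), y = rnorm(200, 0, 2),
                   z = rnorm(200, 10, 4),
                   frame = sample(0:9999, 200, replace = TRUE),
                   lp = runif(200, 1, 3))
  tb <- loc_table(df, acquisition_meta(10000))
  cl <- cluster_locs(tb, cluster_params(r = 5, n_min = 20, r_z = 10))
  resi <- collapse_clusters(tb, cl)
  expect_equal(nrow(resi), 1)
  members <- cl$assignment == resi$cluster_id[1]
  expect_equal(resi$z, mean(df$z[members]))
  expect_equal(resi$lp_z, 2 * resi$lp)
})

test_that("merge keeps channels separate and validates dimensionality", {
  tb <- two_cloud_table(sep = 30, sigma = 2, K = 100, seed = 56)
  cl <- cluster_locs(tb, cluster_params(r = 4, n_min = 20))
  r1 <- collapse_clusters(tb, cl)
  r2 <- r1; r2$channel <- 1L
  merged <- merge_rounds(list(r1, r2))
  expect_equal(nrow(merged), 4)
  expect_equal(sort(unique(merged$channel)), c(0L, 1L))
  expect_equal(nrow(merge_rounds(list())), 0)
  dup <- merge_rounds(list(r1, r1))
  expect_true(attr(dup, "provenance")$duplicate_channels)
})

test_that("grouping K localizations improves precision by sqrt(K)", {
  # end-to-end scaling law over simulated clusters
  set.seed(57)
  sigma <- 3
  for (K in c(10, 100, 381)) {
    est <- replicate(200, {
      xs <- rnorm(K, 0, sigma)
      weighted_center(xs, rep(sigma, K))$mean
    })
    expect_equal(sd(est), sigma / sqrt(K), tolerance = 0.15)
  }
})

test_that("rendering conserves mass and resolves close pairs", {
  meta <- acquisition_meta(10)
  one <- loc_table(data.frame(x = 0, y = 0, frame = 0, lp = 1), meta)
  img <- render_resi(one, bin_size = 0.2)
  expect_equal(sum(img), 1, tolerance = 0.01)

  two <- loc_table(data.frame(x = c(0, 5), y = 0, frame = 0, lp = 0.5), meta)
  img2 <- render_resi(two, bin_size = 0.1)
  profile <- rowSums(img2)
  x0 <- attr(img2, "xlim")[1]
  at <- function(x) profile[1 + floor((x - x0) / 0.1)]
  # resolvable: a clear minimum between the two record positions
  expect_lt(at(2.5), 0.5 * min(at(0), at(5)))
  # histogram mode: integer counts, total = record count
  imgh <- render_resi(two, bin_size = 1, blur = "none")
  expect_equal(sum(imgh), 2)
})
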