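test_that("neighbour counts match the brute-force oracle in 2D and 3D", {
  for (s in 1:25) {
    tb <- random_table(150, seed = 600 + s)
    cp <- cluster_params(r = runif(1, 3, 12), n_min = 3)
    expect_identical(as.integer(neighbor_counts(tb, cp)),
                     as.integer(brute_neighbor_counts(cbind(tb$x, tb$y), cp$r)))
  }
  for (s in 1:25) {
    tb <- random_table(120, three_d = TRUE, seed = 700 + s)
    r <- runif(1, 4, 12); rz <- 2 * r
    cp <- cluster_params(r = r, n_min = 3, r_z = rz)
    expect_identical(as.integer(neighbor_counts(tb, cp)),
                     as.integer(brute_neighbor_counts(cbind(tb$x, tb$y), r,
                                                      z = tb$z, rz = rz)))
  }
  tb3 <- random_table(10, three_d = TRUE, seed = 1)
  expect_error(neighbor_counts(tb3, cluster_params(r = 5, n_min = 1)), "r_z")
})

test_that("local maxima match the oracle and its edge cases", {
  for (s in 1:25) {
    tb <- random_table(150, seed = 800 + s)
    cp <- cluster_params(r = 8, n_min = 3)
    counts <- neighbor_counts(tb, cp)
    expect_identical(as.integer(find_local_maxima(tb, cp, counts)),
                     as.integer(brute_local_maxima(cbind(tb$x, tb$y), 8, counts)))
  }
  # single Gaussian cloud: exactly one maximum, near the densest point
  set.seed(41)
  tb <- loc_table(data.frame(x = rnorm(300, 0, 2), y = rnorm(300, 0, 2),
                             frame = 0, lp = 1), acquisition_meta(1))
  cp <- cluster_params(r = 4, n_min = 5)
  mx <- find_local_maxima(tb, cp)
  expect_length(mx, 1)
  counts <- neighbor_counts(tb, cp)
  expect_equal(counts[mx], max(counts))
  # all isolated points: every point is a maximum with zero neighbours
  iso <- loc_table(data.frame(x = seq(0, 900, by = 100), y = 0,
                              frame = 0, lp = 1), acquisition_meta(1))
  cpi <- cluster_params(r = 10, n_min = 1)
  expect_identical(as.integer(find_local_maxima(iso, cpi)), 1:10)
  expect_true(all(neighbor_counts(iso, cpi) == 0))
  # two clouds far apart: exactly two maxima
  tb2 <- two_cloud_table(sep = 80, sigma = 2, K = 150, seed = 42)
  expect_length(find_local_maxima(tb2, cluster_params(r = 4, n_min = 5)), 2)
})

test_that("clustering separates well-spaced clouds and assigns their members", {
  tb <- two_cloud_table(sep = 20, sigma = 2, K = 100, seed = 43)
  cl <- cluster_locs(tb, cluster_params(r = 4, n_min = 10))
  kept <- cl$clusters[cl$clusters$status == "kept", ]
  expect_equal(nrow(kept), 2)
  # each cluster is pure and holds most of its own cloud: the radius-r
  # assignment around the density maximum captures ~1 - exp(-r^2/2sigma^2)
  # = 86% of a Gaussian cloud at r = 2 sigma
  truth <- rep(1:2, each = 100)
  for (k in kept$id) {
    members <- which(cl$assignment == k)
    expect_gte(length(members), 75)
    expect_equal(length(unique(truth[members])), 1)
  }
  # centroid accuracy ~ sigma / sqrt(K)
  expect_lt(min(abs(kept$x - 0), abs(kept$x - 20)), 5 * 2 / sqrt(100) + 0.5)
})

test_that("kept-cluster count equals site count on well-separated layouts", {
  ok <- 0; total <- 40
  for (s in 1:total) {
    tb <- two_cloud_table(sep = 30, sigma = 2, K = 60, seed = 900 + s)
    cl <- cluster_locs(tb, cluster_params(r = 4, n_min = 10))
    if (sum(cl$clusters$status == "kept") == 2) ok <- ok + 1
  }
  expect_gte(ok / total, 0.99)
})

test_that("temporal filters reject early and bursty clusters with labels", {
  meta <- acquisition_meta(n_frames = 10000)
  set.seed(44)
  mk <- function(cx, frames) data.frame(x = rnorm(80, cx, 2),
                                        y = rnorm(80, 0, 2),
                                        frame = frames, lp = 2)
  good <- mk(0, sample(0:9999, 80, replace = TRUE))
  early <- mk(50, sample(0:999, 80, replace = TRUE))       # first 10% only
  burst <- mk(100, c(sample(4000:4499, 72, replace = TRUE), # 90% in one window
                     sample(0:9999, 8, replace = TRUE)))
  tb <- loc_table(rbind(good, early, burst), meta)
  cl <- cluster_locs(tb, cluster_params(r = 4, n_min = 10))
  st <- cl$clusters$status[order(cl$clusters$x)]
  expect_identical(st, c("kept", "rejected_mean_frame", "rejected_window"))
})

test_that("mean-frame band boundaries reject inclusively", {
  meta <- acquisition_meta(n_frames = 1000)
  at_mean <- function(mf) {
    fr <- rep(c(mf - 100, mf + 100), each = 40)
    loc_table(data.frame(x = rnorm(80, 0, 1), y = rnorm(80, 0, 1),
                         frame = fr, lp = 1), meta)
  }
  cp <- cluster_params(r = 4, n_min = 10)
  expect_identical(cluster_locs(at_mean(200), cp)$clusters$status,
                   "rejected_mean_frame")  # exactly at 20%
  expect_identical(cluster_locs(at_mean(500), cp)$clusters$status, "kept")
})

test_that("clustering is deterministic and monotone in n_min", {
  tb <- two_cloud_table(sep = 25, sigma = 2.5, K = 50, seed = 45)
  cp <- cluster_params(r = 5, n_min = 10)
  a <- cluster_locs(tb, cp)
  b <- cluster_locs(tb[sample(nrow(tb)), ], cp)  # permuted input, same geometry
  expect_identical(a$assignment, cluster_locs(tb, cp)$assignment)
  expect_equal(nrow(a$clusters), nrow(b$clusters))
  kept_at <- vapply(c(5, 20, 40, 60), function(nm)
    sum(cluster_locs(tb, cluster_params(r = 5, n_min = nm))$clusters$status
        == "kept"), numeric(1))
  expect_true(all(diff(kept_at) <= 0))
})

test_that("minimum-size threshold is strict and dissolves small clusters", {
  set.seed(46)
  tb <- loc_table(data.frame(x = rnorm(12, 0, 1), y = rnorm(12, 0, 1),
                             frame = sample(0:999, 12), lp = 1),
                  acquisition_meta(1000))
  # 12 members: kept for n_min = 11 (12 > 11), dissolved for n_min = 12
  cl11 <- cluster_locs(tb, cluster_params(r = 6, n_min = 11))
  expect_equal(sum(cl11$clusters$status == "kept"), 1)
  cl12 <- cluster_locs(tb, cluster_params(r = 6, n_min = 12))
  expect_equal(nrow(cl12$clusters), 0)
  expect_true(all(cl12$assignment == 0L))
})

test_that("n_min suggestion finds the antimode of a bimodal pick histogram", {
  set.seed(47)
  counts <- c(rpois(400, 3), rpois(400, 50))
  s <- suggest_n_min(counts)
  expect_true(s$bimodal)
  expect_gt(s$threshold, 8)
  expect_lt(s$threshold, 40)
  sep <- mean(c(rpois(4000, 3) < s$threshold, rpois(4000, 50) > s$threshold))
  expect_gte(sep, 0.99)
  expect_identical(suggest_n_min(rpois(500, 20))$flag, "unimodal")
  expect_identical(suggest_n_min(c(5))$flag, "insufficient")
})
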