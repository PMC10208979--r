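test_that("rigid transforms apply, compose and invert exactly", {
  tb <- random_table(50, seed = 31)
  t_id <- rigid_transform()
  expect_equal(apply_transform(tb, t_id)$x, tb$x)

  t_shift <- rigid_transform(translation = c(12.5, -3))
  shifted <- apply_transform(tb, t_shift)
  expect_equal(shifted$x, tb$x + 12.5)
  expect_equal(shifted$y, tb$y - 3)
  expect_identical(shifted$frame, tb$frame)
  expect_identical(shifted$lp, tb$lp)

  t_rot <- rigid_transform(rotation = 0.3, translation = c(5, 7),
                           pivot = c(50, 50))
  moved <- apply_transform(tb, t_rot)
  # rigidity: pairwise distances preserved
  expect_equal(as.numeric(dist(cbind(moved$x, moved$y))),
               as.numeric(dist(cbind(tb$x, tb$y))), tolerance = 1e-9)
  # inverse consistency
  back <- apply_transform(moved, invert_transform(t_rot))
  expect_equal(back$x, tb$x, tolerance = 1e-9)
  expect_equal(back$y, tb$y, tolerance = 1e-9)
})

test_that("cross-correlation recovers a known translation to sub-bin accuracy", {
  tb <- two_cloud_table(sep = 200, sigma = 5, K = 500, seed = 32)
  moving <- apply_transform(tb, rigid_transform(translation = c(50, -30)))
  tr <- coarse_translate(tb, moving, bin_size = 5)
  expect_equal(tr$rotation, 0)
  expect_lt(abs(tr$translation[1] + 50), 5)
  expect_lt(abs(tr$translation[2] - 30), 5)

  # identical tables: zero shift
  tr0 <- coarse_translate(tb, tb, bin_size = 5)
  expect_lt(max(abs(tr0$translation)), 1e-6)

  expect_error(coarse_translate(tb, tb[0, ]), "empty")
})

test_that("fields without common structure warn and fall back to zero shift", {
  a <- random_table(60, extent = 50, seed = 33)
  b <- random_table(60, extent = 50, seed = 99)
  b$x <- b$x + 5000  # disjoint extents, unrelated structure
  expect_warning(tr <- coarse_translate(a, b, bin_size = 5), "peak")
  expect_equal(tr$translation, c(0, 0))
})

test_that("Procrustes refinement recovers a known rigid transform", {
  set.seed(34)
  pts <- cbind(runif(12, 0, 500), runif(12, 0, 500))
  theta <- 5 * pi / 180
  ctr <- colMeans(pts)
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  moved <- sweep(sweep(pts, 2, ctr) %*% t(R), 2, ctr + c(8, -4), "+")
  tr <- rigid_refine(pts, moved)
  expect_equal(tr$rotation, -theta, tolerance = 1e-9)
  fit <- resikit:::transform_points(moved, tr)
  expect_lt(max(abs(fit - pts)), 1e-6)
  expect_lt(attr(tr, "rms"), 1e-9)

  # identity on identical sets, exact with only two pairs
  tr_id <- rigid_refine(pts, pts)
  expect_equal(tr_id$rotation, 0, tolerance = 1e-12)
  expect_lt(max(abs(tr_id$translation)), 1e-12)
  tr2 <- rigid_refine(pts[1:2, ], pts[1:2, ])
  expect_lt(attr(tr2, "rms"), 1e-9)
  expect_error(rigid_refine(pts[1, , drop = FALSE], pts[1, , drop = FALSE]),
               "at least 2")
})

test_that("refinement recovers random transforms over random point sets", {
  for (s in 1:20) {
    set.seed(400 + s)
    pts <- cbind(runif(8, 0, 300), runif(8, 0, 300))
    theta <- runif(1, -0.5, 0.5)
    tr_true <- rigid_transform(rotation = theta,
                               translation = runif(2, -50, 50),
                               pivot = colMeans(pts))
    moved <- resikit:::transform_points(pts, tr_true)
    tr <- rigid_refine(pts, moved)
    expect_equal(tr$rotation, -theta, tolerance = 1e-8)
    expect_lt(max(abs(resikit:::transform_points(moved, tr) - pts)), 1e-6)
  }
})

test_that("alignment never increases the fiducial residual", {
  set.seed(35)
  fid <- cbind(runif(10, 0, 1000), runif(10, 0, 1000))
  tb <- random_table(200, extent = 1000, seed = 36)
  true_t <- rigid_transform(rotation = 0.02, translation = c(22, -13),
                            pivot = colMeans(fid))
  mov_tb <- apply_transform(tb, true_t)
  mov_fid <- resikit:::transform_points(fid, true_t)
  res <- align_rounds(list(tb, mov_tb), fiducials = list(fid, mov_fid),
                      bin_size = 5)
  rms0 <- sqrt(mean(rowSums((mov_fid - fid)^2)))
  tr2 <- res$transforms[[2]]
  rms1 <- attr(tr2$refine, "rms")
  expect_lt(rms1, rms0)
  expect_lt(rms1, 0.5)
})

test_that("ambiguous fiducial matches are dropped with a warning", {
  ref <- cbind(c(0, 100), c(0, 0))
  mov <- cbind(c(1, 2, 100), c(0, 0, 0))  # two candidates near ref 1
  expect_warning(m <- match_fiducials(ref, mov, r = 5), "ambiguous")
  expect_equal(nrow(m$ref), 1)
})
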