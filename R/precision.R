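#' Scalar spread of a 2D point set
#'
#' The scalar precision metric used for 2D localization clouds:
#' \deqn{\sigma = \sqrt{\tfrac{1}{2} tr(cov(x, y))}
#'             = \sqrt{(Var(x) + Var(y)) / 2}}
#' with unbiased variances. For an isotropic Gaussian sample this
#' estimates the per-axis s.d.
#'
#' @param points n x 2 matrix (nm), n >= 2.
#' @return Spread in nm (`NA` with a warning for fewer than 2 points).
#' @export
scalar_spread <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) {
    warning("scalar_spread undefined for fewer than 2 points")
    return(NA_real_)
  }
  sqrt(sum(diag(stats::cov(points[, 1:2]))) / 2)
}

#' In-silico precision curve for grouped localizations
#'
#' Simulates the precision gain of collapsing K localizations: for each
#' binding site, M localizations are drawn from an isotropic 2D Gaussian
#' of s.d. `sigma_smlm`; for each K the M localizations are partitioned
#' into `n = M / K` disjoint subsets whose means form n super-
#' localizations, and the spread of those means is measured with
#' [scalar_spread()]. The curve tracks the `sigma_smlm / sqrt(K)` law.
#'
#' @param sigma_smlm Single-localization precision, nm.
#' @param M Localizations simulated per site; must satisfy
#'   `M >= 10 * max(K_values)`.
#' @param K_values Increasing vector of subset sizes.
#' @param n_sites Number of independent binding sites simulated.
#' @param seed RNG seed.
#' @return A `precision_curve` data frame: `K`, `sigma_resi` (mean over
#'   sites), `sigma_site_sd` (s.d. over sites), `sigma_theory`,
#'   `n_subsets`.
#' @export
insilico_curve <- function(sigma_smlm, M = 5120, K_values = c(4, 16, 64, 256),
                           n_sites = 8, seed = NULL) {
  if (sigma_smlm <= 0) stop("sigma_smlm must be > 0")
  K_values <- sort(unique(as.integer(K_values)))
  if (any(K_values < 1)) stop("K must be >= 1")
  if (M < 10 * max(K_values))
    stop("M must be at least 10 * max(K) for a stable spread estimate (K << M)")
  if (!is.null(seed)) set.seed(seed)
  per_site <- array(NA_real_, c(n_sites, length(K_values)))
  for (s in seq_len(n_sites)) {
    pts <- cbind(stats::rnorm(M, 0, sigma_smlm), stats::rnorm(M, 0, sigma_smlm))
    for (j in seq_along(K_values)) {
      K <- K_values[j]
      n_sub <- M %/% K
      idx <- sample.int(M)[seq_len(n_sub * K)]
      grp <- rep(seq_len(n_sub), each = K)
      means <- cbind(tapply(pts[idx, 1], grp, mean),
                     tapply(pts[idx, 2], grp, mean))
      per_site[s, j] <- scalar_spread(means)
    }
  }
  out <- data.frame(K = K_values,
                    sigma_resi = colMeans(per_site),
                    sigma_site_sd = apply(per_site, 2, stats::sd),
                    sigma_theory = sigma_smlm / sqrt(K_values),
                    n_subsets = M %/% K_values)
  class(out) <- c("precision_curve", "data.frame")
  out
}

#' @export
print.precision_curve <- function(x, ...) {
  cat("In-silico precision curve (nm):\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
plot.precision_curve <- function(x, ...) {
  graphics::plot(x$K, x$sigma_resi, log = "xy", xlab = "K",
                 ylab = expression(sigma[RESI] ~ "(nm)"), pch = 19, ...)
  graphics::lines(x$K, x$sigma_theory, lty = 2)
  graphics::legend("topright", legend = c("measured", expression(sigma / sqrt(K))),
                   pch = c(19, NA), lty = c(NA, 2), bty = "n")
  invisible(x)
}

#' Estimate precision of an experimental cluster by resampling
#'
#' The M localizations of one cluster are partitioned into `M / K`
#' disjoint random subsets of size K; the spread of the subset means
#' estimates the precision attainable by grouping K localizations. The
#' final precision of the cluster's super-localization, which uses all M
#' localizations, is extrapolated as `sigma_smlm_hat / sqrt(M)` with the
#' cluster's own scalar spread as the single-localization precision
#' estimate.
#'
#' @param points Cluster localizations, n x 2 matrix (nm), `M >= 10 * K`.
#' @param K Subset size.
#' @param seed RNG seed.
#' @return List with `sigma_resi_K` (spread of subset means),
#'   `sigma_smlm_hat`, `sigma_resi_final` (extrapolated, all M),
#'   `n_subsets`, `M`.
#' @export
resample_cluster <- function(points, K, seed = NULL) {
  points <- as.matrix(points)
  M <- nrow(points)
  if (K < 1) stop("K must be >= 1")
  if (M < 10 * K) stop("cluster must hold at least 10 * K localizations (K << M)")
  if (!is.null(seed)) set.seed(seed)
  n_sub <- M %/% K
  idx <- sample.int(M)[seq_len(n_sub * K)]
  grp <- rep(seq_len(n_sub), each = K)
  means <- cbind(tapply(points[idx, 1], grp, mean),
                 tapply(points[idx, 2], grp, mean))
  s_hat <- scalar_spread(points)
  list(sigma_resi_K = scalar_spread(means),
       sigma_smlm_hat = s_hat,
       sigma_resi_final = s_hat / sqrt(M),
       n_subsets = n_sub, M = M)
}
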