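#' k-th nearest-neighbour distances of a 2D point set
#'
#' Exact Euclidean k-NN distances for orders 1..`max_order`. When given a
#' `point_pattern` (see [simulate_mixture()]), distances are reported for
#' points inside the analysis window while guard-band points still count
#' as candidate neighbours, avoiding edge deflation.
#'
#' @param points n x 2 matrix (nm) or a `point_pattern`.
#' @param max_order Highest neighbour order (default 4).
#' @param bin_edges Optional shared histogram edges (nm); when given,
#'   per-order probability histograms are attached.
#' @return An `nnd_result`: list with `orders`, `distances` (matrix,
#'   column k = k-th NND), `density_observed` (per um^2), and optionally
#'   `histograms` + `bin_edges`.
#' @examples
#' p <- cbind(c(0, 10, 25), 0)
#' knn_distances(p, max_order = 1)$distances[, 1]  # 10 10 15
#' @export
knn_distances <- function(points, max_order = 4, bin_edges = NULL) {
  if (max_order < 1) stop("max_order must be >= 1")
  if (inherits(points, "point_pattern")) {
    if (nrow(points$xy_all) <= max_order)
      stop("need more than max_order points")
    d <- nnd_with_guard(points, max_order)
    dens <- points$density_observed
  } else {
    points <- as.matrix(points)
    if (nrow(points) <= max_order)
      stop("need more than max_order points")
    d <- cpp_knn(points[, 1], points[, 2], max_order)
    bb <- apply(points[, 1:2], 2, range)
    area_um2 <- max(prod(bb[2, ] - bb[1, ]) / 1e6, .Machine$double.eps)
    dens <- nrow(points) / area_um2
  }
  out <- list(orders = seq_len(max_order), distances = d,
              density_observed = dens)
  if (!is.null(bin_edges)) {
    out$bin_edges <- bin_edges
    out$histograms <- apply(d, 2, function(col) prob_hist(col, bin_edges))
  }
  structure(out, class = "nnd_result")
}

#' @export
print.nnd_result <- function(x, ...) {
  cat(sprintf("NND result: %d points, orders 1..%d, density %.1f per um^2\n",
              nrow(x$distances), max(x$orders), x$density_observed))
  cat("  median NND (nm):", paste(sprintf("%.2f", apply(x$distances, 2, stats::median)),
                                  collapse = ", "), "\n")
  invisible(x)
}

# probability mass per bin, normalized by the total sample size so that
# two samples histogrammed on the same edges are comparable
prob_hist <- function(d, edges) {
  n <- length(d)
  idx <- findInterval(d, edges, rightmost.closed = TRUE)
  inside <- idx >= 1 & idx <= length(edges) - 1
  tabulate(idx[inside], nbins = length(edges) - 1) / max(n, 1)
}

#' Simulated CSR nearest-neighbour reference distributions
#'
#' Simulates a homogeneous Poisson (complete spatial randomness) point
#' pattern at the stated density with a guard band and returns its NND
#' distributions, as a reference against which experimental NND curves
#' are compared. The 1st-order distances follow the CSR law
#' `P(NND <= d) = 1 - exp(-rho * pi * d^2)`.
#'
#' @param density Points per um^2 (> 0).
#' @param area Window area, um^2.
#' @param orders Highest neighbour order.
#' @param seed RNG seed.
#' @param bin_edges Optional histogram edges (nm).
#' @return An `nnd_result`.
#' @export
csr_reference <- function(density, area = 100, orders = 4, seed = NULL,
                          bin_edges = NULL) {
  if (density <= 0) stop("density must be > 0")
  if (!is.null(seed)) set.seed(seed)
  pp <- sim_csr_points(density, area)
  knn_distances(pp, max_order = orders, bin_edges = bin_edges)
}

#' Sum of squared differences between two binned distance distributions
#'
#' Both samples are histogrammed on the shared `bin_edges` and normalized
#' to equal totals (probability mass per bin); the statistic is
#' `sum((h_sim - h_exp)^2)`. Pre-binned inputs (lists with `edges` and
#' `counts`) are accepted and their edges must match exactly.
#'
#' @param sim,exp Distance vectors (nm), or lists with `edges`/`counts`.
#' @param bin_edges Shared histogram edges (nm).
#' @return The sum of squared per-bin differences.
#' @export
sse_histogram <- function(sim, exp, bin_edges = seq(0, 100, by = 1)) {
  as_h <- function(v) {
    if (is.list(v)) {
      if (!isTRUE(all.equal(v$edges, bin_edges)))
        stop("histogram bin edges do not match")
      v$counts / max(sum(v$counts), 1)
    } else prob_hist(v, bin_edges)
  }
  h1 <- as_h(sim); h2 <- as_h(exp)
  sum((h1 - h2)^2)
}

# SSE objective: simulate at (D, sigma_label, frac) and compare the
# simulated first-NND probability histogram with the experimental one.
# Replicate simulation histograms are averaged before the SSE. Runs
# through the fused C++ path (one call per simulated pattern, same
# generative core as simulate_mixture).
dimer_objective <- function(h_exp, observed_density, labelling_efficiency,
                            area, bin_edges, guard = 100) {
  side <- sqrt(area) * 1000
  area_enl <- ((side + 2 * guard) / 1000)^2
  function(D, sig, frac, seeds) {
    mp <- mixture_from_fraction(observed_density, labelling_efficiency,
                                frac, D, sig, area)
    h <- 0
    for (s in seeds) {
      set.seed(s)
      h <- h + cpp_mixture_nnd_hist(mp$density_monomers * area_enl,
                                    mp$density_dimers * area_enl,
                                    -guard, side + guard, D, sig,
                                    mp$labelling_efficiency, side, bin_edges)
    }
    sum((h / length(seeds) - h_exp)^2)
  }
}

dimer_grid_search <- function(objective, Ds, sigs, fracs, seeds) {
  grid <- expand.grid(D = Ds, sigma_label = sigs, frac = fracs)
  grid$sse <- vapply(seq_len(nrow(grid)), function(i)
    objective(grid$D[i], grid$sigma_label[i], grid$frac[i], seeds),
    numeric(1))
  i <- which.min(grid$sse)
  list(D = grid$D[i], sigma_label = grid$sigma_label[i],
       frac = grid$frac[i], sse = grid$sse[i], grid = grid)
}

# continuous refinement: least-squares quadratic response surface through
# the evaluated fine grid; its minimizer (when the Hessian is positive
# definite and the minimizer stays inside the searched box) smooths the
# Monte-Carlo noise of individual evaluations. Falls back to the best
# evaluated grid point otherwise.
quad_refine <- function(search) {
  g <- search$grid
  vars <- c("D", "sigma_label", "frac")
  ctr <- vapply(g[vars], function(v) mean(range(v)), numeric(1))
  scl <- vapply(g[vars], function(v) max(diff(range(v)) / 2, 1e-9), numeric(1))
  if (any(vapply(g[vars], function(v) length(unique(v)), integer(1)) < 3))
    return(search)  # a collapsed axis cannot support a quadratic
  Z <- sweep(sweep(as.matrix(g[vars]), 2, ctr), 2, scl, "/")
  X <- cbind(1, Z, Z^2, Z[, 1] * Z[, 2], Z[, 1] * Z[, 3], Z[, 2] * Z[, 3])
  fit <- stats::lm.fit(X, g$sse)
  b <- fit$coefficients
  if (anyNA(b)) return(search)
  grad <- b[2:4]
  H <- matrix(c(2 * b[5], b[8], b[9],
                b[8], 2 * b[6], b[10],
                b[9], b[10], 2 * b[7]), 3, 3)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(search)
  zmin <- -solve(H, grad)
  if (any(abs(zmin) > 1)) return(search)  # outside the searched box
  opt <- zmin * scl + ctr
  list(D = opt[[1]], sigma_label = opt[[2]], frac = opt[[3]],
       sse = sum(b * c(1, zmin, zmin^2, zmin[1] * zmin[2],
                       zmin[1] * zmin[3], zmin[2] * zmin[3])),
       grid = g)
}

fine_axis <- function(center, st, rng, n) {
  v <- seq(center - st, center + st, length.out = n)
  unique(pmin(pmax(v, rng[1]), rng[2]))
}

# molecule densities implied by (observed density, labelling efficiency,
# dimer fraction in % of molecules)
mixture_from_fraction <- function(observed_density, labelling_efficiency,
                                  frac_of_dimers, D, sigma_label, area) {
  rho_gt <- observed_density / labelling_efficiency  # ground-truth molecules
  f <- frac_of_dimers / 100
  mixture_params(density_monomers = (1 - f) * rho_gt,
                 density_dimers = f * rho_gt / 2,  # pairs, 2 molecules each
                 dimer_distance = D, uncertainty = sigma_label,
                 labelling_efficiency = labelling_efficiency, area = area)
}

#' Fit the monomer/dimer mixture model to nearest-neighbour data
#'
#' Iterative nonlinear least-squares fit of the generative model of
#' [simulate_mixture()] to an experimental point set: for every candidate
#' parameter triple (intra-dimer distance D, per-molecule labelling
#' variability sigma_label, percentage of molecules in dimers) a pattern
#' is simulated at the experimentally observed density and labelling
#' efficiency, its first-NND histogram computed, and the sum of squared
#' differences to the experimental histogram evaluated. A coarse grid
#' over D = 1-20 nm, sigma_label = 1-20 nm, frac = 0-100% is followed by
#' a finer grid spanning one coarse step around the coarse optimum, with
#' simulation noise averaged over replicate simulations and common random
#' numbers across evaluations.
#'
#' @param exp Experimental points: n x 2 matrix (nm) or `point_pattern`.
#' @param observed_density Experimental density, molecules per um^2.
#' @param labelling_efficiency Detectable fraction in (0, 1].
#' @param seed RNG seed for the fit's simulations.
#' @param bin_edges First-NND histogram edges (nm); default 1 nm bins
#'   over 0-100 nm.
#' @param coarse_n Grid points per parameter, coarse stage (default 11).
#' @param fine_n Grid points per parameter, fine stage (default 7); the
#'   fine stage additionally fits a quadratic response surface to the
#'   evaluated grid and reports its minimizer, which averages simulation
#'   noise over the whole grid and frees the estimate from the grid
#'   spacing.
#' @param fine_reps Replicate simulations per fine evaluation (default 1;
#'   replicate histograms are averaged before the SSE).
#' @param sim_area_factor Fine-stage variance reduction: each fine (and
#'   refit) evaluation simulates a window enlarged by this area factor
#'   (default 4), shrinking the Monte-Carlo noise of the simulated
#'   histogram without touching the model; the coarse stage uses the
#'   experimental window size.
#' @param ranges List of length-2 ranges for `D`, `sigma_label`, `frac`.
#' @return A `dimer_fit` object: coefficients `D_opt`,
#'   `sigma_label_opt`, `frac_of_dimers_opt`, the final `sse`, and the
#'   fit context. Methods: `print`, `summary`, `coef`, `plot`.
#' @seealso [fit_uncertainty()] for refit-based parameter uncertainties.
#' @export
fit_dimer_model <- function(exp, observed_density, labelling_efficiency,
                            seed = 1, bin_edges = seq(0, 100, by = 1),
                            coarse_n = 11, fine_n = 7, fine_reps = 1,
                            sim_area_factor = 4,
                            ranges = list(D = c(1, 20), sigma_label = c(1, 20),
                                          frac = c(0, 100))) {
  if (labelling_efficiency <= 0 || labelling_efficiency > 1)
    stop("labelling_efficiency must be in (0, 1]")
  if (observed_density <= 0) stop("observed_density must be > 0")
  xy <- if (inherits(exp, "point_pattern")) exp$xy else as.matrix(exp)[, 1:2]
  n_exp <- nrow(xy)
  if (n_exp < 100) stop("too few points for a meaningful fit")
  if (stats::sd(xy[, 1]) < 1e-9 && stats::sd(xy[, 2]) < 1e-9)
    stop("degenerate data: all points coincident")
  area <- n_exp / observed_density  # um^2, square window in simulation
  h_exp <- if (inherits(exp, "point_pattern"))
    prob_hist(knn_distances(exp, 1)$distances[, 1], bin_edges)
  else
    prob_hist(cpp_knn(xy[, 1], xy[, 2], 1)[, 1], bin_edges)

  obj_coarse <- dimer_objective(h_exp, observed_density, labelling_efficiency,
                                area, bin_edges)
  obj_fine <- dimer_objective(h_exp, observed_density, labelling_efficiency,
                              area * sim_area_factor, bin_edges)

  base_seed <- as.integer(seed) %% 1000000L
  coarse_seeds <- base_seed * 1000L + 1L  # common random numbers
  gr <- function(rng, n) seq(rng[1], rng[2], length.out = n)
  coarse <- dimer_grid_search(obj_coarse,
                              gr(ranges$D, coarse_n),
                              gr(ranges$sigma_label, coarse_n),
                              gr(ranges$frac, coarse_n), coarse_seeds)

  step <- vapply(ranges, function(r) diff(r) / (coarse_n - 1), numeric(1))
  fine_seeds <- base_seed * 1000L + 1L + seq_len(fine_reps)
  fine <- quad_refine(dimer_grid_search(
    obj_fine,
    fine_axis(coarse$D, step[1], ranges$D, fine_n),
    fine_axis(coarse$sigma_label, step[2], ranges$sigma_label, fine_n),
    fine_axis(coarse$frac, step[3], ranges$frac, fine_n),
    fine_seeds))
  coarse$grid <- NULL

  structure(list(coefficients = c(D_opt = fine$D,
                                  sigma_label_opt = fine$sigma_label,
                                  frac_of_dimers_opt = fine$frac),
                 sse = fine$sse, coarse = coarse,
                 observed_density = observed_density,
                 labelling_efficiency = labelling_efficiency,
                 n_points = n_exp, area = area,
                 bin_edges = bin_edges, h_exp = h_exp,
                 settings = list(coarse_n = coarse_n, fine_n = fine_n,
                                 fine_reps = fine_reps,
                                 sim_area_factor = sim_area_factor,
                                 ranges = ranges, seed = base_seed),
                 uncertainty = NULL),
            class = "dimer_fit")
}

#' @export
coef.dimer_fit <- function(object, ...) object$coefficients

#' @export
print.dimer_fit <- function(x, ...) {
  co <- x$coefficients
  u <- x$uncertainty
  fmt <- function(name, val, unit) {
    if (!is.null(u)) sprintf("  %s = %.2f +/- %.2f %s\n", name, val, u[[name]], unit)
    else sprintf("  %s = %.2f %s\n", name, val, unit)
  }
  cat("Monomer/dimer mixture fit (first-NND least squares)\n")
  cat(fmt("D_opt", co[["D_opt"]], "nm"))
  cat(fmt("sigma_label_opt", co[["sigma_label_opt"]], "nm"))
  cat(fmt("frac_of_dimers_opt", co[["frac_of_dimers_opt"]], "%"))
  cat(sprintf("  (monomers: %.1f%%), SSE = %.3g, n = %d points at %.1f per um^2\n",
              100 - co[["frac_of_dimers_opt"]], x$sse, x$n_points,
              x$observed_density))
  invisible(x)
}

#' @export
summary.dimer_fit <- function(object, ...) {
  print(object)
  if (is.null(object$uncertainty))
    cat("  uncertainties: not estimated (run fit_uncertainty())\n")
  else if (isTRUE(object$low_M))
    cat(sprintf("  uncertainties from only M = %d refits: treat as indicative\n",
                nrow(object$refits)))
  invisible(object)
}

#' @export
plot.dimer_fit <- function(x, ...) {
  mids <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  co <- x$coefficients
  mp <- mixture_from_fraction(x$observed_density, x$labelling_efficiency,
                              co[["frac_of_dimers_opt"]], co[["D_opt"]],
                              co[["sigma_label_opt"]], x$area)
  pp <- simulate_mixture(mp, seed = x$settings$seed)
  h_fit <- prob_hist(nnd_with_guard(pp, 1)[, 1], x$bin_edges)
  graphics::plot(mids, x$h_exp, type = "h", xlab = "1st NND (nm)",
                 ylab = "probability per bin", ...)
  graphics::lines(mids, h_fit, col = 2, lwd = 2)
  graphics::legend("topright", legend = c("data", "model"), col = c(1, 2),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Refit-based parameter uncertainties for a dimer fit
#'
#' Simulates `M` synthetic datasets at the fitted optimum with the same
#' number of molecules as the data, fine-fits each one (fine grid centred
#' on the optimum), and reports the standard deviation of each parameter
#' across the refits as its uncertainty.
#'
#' @param fit A [fit_dimer_model()] result.
#' @param M Number of refits (default 100; `M < 10` is flagged low).
#' @param seed RNG seed.
#' @return The fit with `uncertainty` (named vector), `refits` (data
#'   frame of per-refit optima) and `low_M` filled in.
#' @export
fit_uncertainty <- function(fit, M = 100, seed = 1) {
  stopifnot(inherits(fit, "dimer_fit"))
  if (M < 2) stop("M must be >= 2")
  co <- fit$coefficients
  st <- fit$settings
  base_seed <- (as.integer(seed) %% 1000000L) * 2000L
  mp <- mixture_from_fraction(fit$observed_density, fit$labelling_efficiency,
                              co[["frac_of_dimers_opt"]], co[["D_opt"]],
                              co[["sigma_label_opt"]], fit$area)
  step <- vapply(st$ranges, function(r) diff(r) / (st$coarse_n - 1), numeric(1))
  Ds <- fine_axis(co[["D_opt"]], step[1], st$ranges$D, st$fine_n)
  sigs <- fine_axis(co[["sigma_label_opt"]], step[2], st$ranges$sigma_label, st$fine_n)
  fracs <- fine_axis(co[["frac_of_dimers_opt"]], step[3], st$ranges$frac, st$fine_n)
  refits <- lapply(seq_len(M), function(i) {
    pp <- simulate_mixture(mp, seed = base_seed + 7L * i)
    h_i <- prob_hist(nnd_with_guard(pp, 1)[, 1], fit$bin_edges)
    obj <- dimer_objective(h_i, fit$observed_density, fit$labelling_efficiency,
                           fit$area * st$sim_area_factor, fit$bin_edges)
    seeds <- base_seed + 7L * i + 3L + seq_len(st$fine_reps)
    b <- quad_refine(dimer_grid_search(obj, Ds, sigs, fracs, seeds))
    c(D_opt = b$D, sigma_label_opt = b$sigma_label, frac_of_dimers_opt = b$frac)
  })
  refits <- as.data.frame(do.call(rbind, refits))
  fit$refits <- refits
  fit$uncertainty <- vapply(refits, stats::sd, numeric(1))
  fit$low_M <- M < 10
  fit
}
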