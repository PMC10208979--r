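#' Ground-truth layouts of binding sites
#'
#' Generates the site geometries used throughout the package's simulations:
#' * `"grid"` — a rectangular grid of single sites (`nx`, `ny`, `pitch` nm).
#' * `"pair_grid"` — a grid of site *pairs* (`n_pairs`, `pitch` nm,
#'   intra-pair `pair_offset` nm along x), emulating DNA-origami rulers
#'   with two directly adjacent orthogonal docking strands; by design the
#'   two members of each pair carry channels 0 and 1 (`n_rounds = 2`).
#' * `"ring_complex"` — nuclear-pore-like complexes: two axially offset
#'   rings (separation `ring_sep` nm), each with `n_fold` angular
#'   positions at radius `ring_radius` nm, each position a site pair
#'   split `pair_lateral` nm tangentially and `pair_axial` nm axially.
#' * `"csr"` — complete spatial randomness: `N ~ Poisson(density * area)`
#'   uniform sites in a square window.
#'
#' @param kind Layout kind, see above.
#' @param nx,ny Grid dimensions (`grid`).
#' @param pitch Grid pitch in nm (`grid`, `pair_grid`).
#' @param n_pairs Number of pairs (`pair_grid`, default 6 on a 3 x 2 grid).
#' @param pair_offset Intra-pair distance in nm (`pair_grid`), down to
#'   sub-nm spacings (a single base pair is about 0.7 nm in-plane).
#' @param n_complexes Number of ring complexes (`ring_complex`).
#' @param complex_spacing Centre-to-centre spacing of complexes, nm.
#' @param n_fold Rotational symmetry (`ring_complex`, default 8).
#' @param ring_radius Ring radius, nm (default 53.5).
#' @param pair_lateral,pair_axial Intra-pair lateral/axial split, nm
#'   (defaults 11.9 and 5.4).
#' @param ring_sep Axial separation of the two rings, nm (default 50).
#' @param density Sites per square micrometre (`csr`).
#' @param area Window area in square micrometres (`csr`).
#' @param seed RNG seed (`csr` only; the other kinds are deterministic).
#' @return A `ground_truth_layout`: list with `sites` (matrix of x, y, z in
#'   nm), `channel` (integer per site, 0-based) and `n_rounds`.
#' @examples
#' make_layout("pair_grid", pair_offset = 0.7)   # 12 sites in 6 pairs
#' @export
make_layout <- function(kind = c("grid", "pair_grid", "ring_complex", "csr"),
                        nx = 4, ny = 4, pitch = 20,
                        n_pairs = 6, pair_offset = 0.7,
                        n_complexes = 1, complex_spacing = 300,
                        n_fold = 8, ring_radius = 53.5,
                        pair_lateral = 11.9, pair_axial = 5.4, ring_sep = 50,
                        density = 100, area = 25, seed = NULL) {
  kind <- match.arg(kind)
  if (pitch <= 0) stop("pitch must be > 0")
  sites <- switch(kind,
    grid = {
      g <- expand.grid(x = (seq_len(nx) - 1) * pitch,
                       y = (seq_len(ny) - 1) * pitch)
      cbind(x = g$x, y = g$y, z = 0)
    },
    pair_grid = {
      if (pair_offset < 0) stop("pair_offset must be >= 0")
      gx <- ceiling(sqrt(n_pairs))
      gy <- ceiling(n_pairs / gx)
      g <- expand.grid(x = (seq_len(gx) - 1) * pitch,
                       y = (seq_len(gy) - 1) * pitch)[seq_len(n_pairs), ]
      left  <- cbind(x = g$x - pair_offset / 2, y = g$y, z = 0)
      right <- cbind(x = g$x + pair_offset / 2, y = g$y, z = 0)
      out <- matrix(0, 2 * n_pairs, 3, dimnames = list(NULL, c("x", "y", "z")))
      out[seq(1, 2 * n_pairs, 2), ] <- left
      out[seq(2, 2 * n_pairs, 2), ] <- right
      out
    },
    ring_complex = {
      one <- local({
        ang <- 2 * pi * (seq_len(n_fold) - 1) / n_fold
        rows <- list()
        for (zc in c(-ring_sep / 2, ring_sep / 2)) {
          cx <- ring_radius * cos(ang); cy <- ring_radius * sin(ang)
          # tangential unit vector at each angular position
          tx <- -sin(ang); ty <- cos(ang)
          a <- cbind(x = cx - tx * pair_lateral / 2,
                     y = cy - ty * pair_lateral / 2,
                     z = zc - pair_axial / 2)
          b <- cbind(x = cx + tx * pair_lateral / 2,
                     y = cy + ty * pair_lateral / 2,
                     z = zc + pair_axial / 2)
          m <- matrix(0, 2 * n_fold, 3, dimnames = list(NULL, c("x", "y", "z")))
          m[seq(1, 2 * n_fold, 2), ] <- a
          m[seq(2, 2 * n_fold, 2), ] <- b
          rows[[length(rows) + 1]] <- m
        }
        do.call(rbind, rows)
      })
      gx <- ceiling(sqrt(n_complexes))
      offs <- expand.grid(x = (seq_len(gx) - 1) * complex_spacing,
                          y = (seq_len(ceiling(n_complexes / gx)) - 1) * complex_spacing)
      offs <- offs[seq_len(n_complexes), , drop = FALSE]
      do.call(rbind, lapply(seq_len(n_complexes), function(i) {
        s <- one
        s[, "x"] <- s[, "x"] + offs$x[i]
        s[, "y"] <- s[, "y"] + offs$y[i]
        s
      }))
    },
    csr = {
      if (density < 0 || area <= 0) stop("density must be >= 0 and area > 0")
      if (!is.null(seed)) set.seed(seed)
      n <- stats::rpois(1, density * area)
      side <- sqrt(area) * 1000  # nm
      cbind(x = stats::runif(n, 0, side), y = stats::runif(n, 0, side),
            z = rep(0, n))
    })
  channel <- if (kind == "pair_grid") rep(c(0L, 1L), n_pairs)
             else rep(0L, nrow(sites))
  n_rounds <- if (kind == "pair_grid") 2L else 1L
  structure(list(sites = sites, channel = channel, n_rounds = n_rounds,
                 kind = kind),
            class = "ground_truth_layout")
}

#' @export
print.ground_truth_layout <- function(x, ...) {
  cat(sprintf("Ground-truth layout (%s): %d sites, %d round(s)\n",
              x$kind, nrow(x$sites), x$n_rounds))
  invisible(x)
}

#' Stochastically assign sites to imaging rounds
#'
#' Emulates stochastic labelling with `n_rounds` orthogonal sequences at
#' equal concentration: each site independently receives channel
#' `0..n_rounds-1` with probability `1/n_rounds`.
#'
#' @param layout A [make_layout()] result.
#' @param n_rounds Number of orthogonal sequences.
#' @param seed RNG seed.
#' @return The layout with `channel` and `n_rounds` replaced.
#' @export
assign_channels <- function(layout, n_rounds, seed = NULL) {
  stopifnot(inherits(layout, "ground_truth_layout"))
  if (n_rounds < 1 || n_rounds != floor(n_rounds))
    stop("n_rounds must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  layout$channel <- sample.int(n_rounds, nrow(layout$sites), replace = TRUE) - 1L
  layout$n_rounds <- as.integer(n_rounds)
  layout
}

#' Blinking model for simulated acquisitions
#'
#' `"uniform"` mode draws each localization's frame i.i.d. uniformly over
#' the acquisition, the limit of fast repetitive blinking (mean frame then
#' centres at half the acquisition). `"kinetic"` mode draws binding events
#' as a Poisson process with rate `k_on * c` and emits
#' `tau_bright / t_exposure` consecutive-frame localizations per event
#' (stochastically rounded). Sticking artifacts — long-lived non-specific
#' imager binding — are injected as *extra* localization clusters at
#' random positions whose frames all fall inside a span of
#' `sticking_span` consecutive frames.
#'
#' @param mode `"uniform"` or `"kinetic"`.
#' @param kinetics A [kinetics_params()] (kinetic mode).
#' @param sticking_fraction Expected number of artifact clusters per true
#'   site (0 disables injection).
#' @param sticking_span Frame span of one artifact (>= 1).
#' @return A `blink_model` list.
#' @export
blink_model <- function(mode = c("uniform", "kinetic"), kinetics = NULL,
                        sticking_fraction = 0, sticking_span = 100) {
  mode <- match.arg(mode)
  if (mode == "kinetic" && !inherits(kinetics, "kinetics_params"))
    stop("kinetic mode requires kinetics_params")
  if (sticking_fraction < 0 || sticking_fraction > 1)
    stop("sticking_fraction must be in [0, 1]")
  if (sticking_span < 1) stop("sticking_span must be >= 1")
  structure(list(mode = mode, kinetics = kinetics,
                 sticking_fraction = sticking_fraction,
                 sticking_span = as.integer(sticking_span)),
            class = "blink_model")
}

draw_frames <- function(k, blink, n_frames) {
  if (blink$mode == "uniform")
    return(sample.int(n_frames, k, replace = TRUE) - 1L)
  # kinetic: not used to set k (k fixed upstream); spread k localizations
  # over Poisson binding events with geometric-ish event lengths
  kin <- blink$kinetics
  per_event <- kin$tau_bright / kin$t_exposure
  frames <- integer(0)
  while (length(frames) < k) {
    start <- sample.int(n_frames, 1) - 1L
    len <- floor(per_event) + stats::rbinom(1, 1, per_event - floor(per_event))
    if (len < 1) len <- 1L
    frames <- c(frames, seq.int(start, min(start + len - 1L, n_frames - 1L)))
  }
  frames[seq_len(k)]
}

#' Simulate DNA-PAINT localization tables from a ground-truth layout
#'
#' Each site emits `locs_per_site` localizations scattered as an isotropic
#' Gaussian of s.d. `sigma_smlm` laterally (and `sigma_z` axially when
#' 3D; default `2 * sigma_smlm`, matching the roughly twofold larger
#' axial spread of astigmatic 3D SMLM). Per-localization precision `lp`
#' is set to `sigma_smlm`. Frames are drawn from the blinking model, and
#' sticking artifacts are appended as temporally compact clusters at
#' random off-site positions.
#'
#' @param layout A [make_layout()] / [assign_channels()] result.
#' @param sigma_smlm Lateral localization precision, nm.
#' @param meta An [acquisition_meta()] (supplies `n_frames`).
#' @param locs_per_site Localizations per site (K). Either a single
#'   integer or a vector recycled over sites; with `blink` in kinetic
#'   mode and `t_measurement` given, K is drawn per site instead as
#'   Poisson around [expected_locs()].
#' @param sigma_z Axial scatter s.d., nm (3D only; default
#'   `2 * sigma_smlm`).
#' @param three_d Force 2D/3D; default: 3D iff the layout has non-zero z.
#' @param blink A [blink_model()].
#' @param t_measurement Optional acquisition duration (s), kinetic mode.
#' @param seed RNG seed.
#' @return A list of [loc_table()], one per channel `0..n_rounds-1`.
#' @export
sample_localizations <- function(layout, sigma_smlm, meta,
                                 locs_per_site = 50,
                                 sigma_z = NULL, three_d = NULL,
                                 blink = blink_model("uniform"),
                                 t_measurement = NULL, seed = NULL) {
  stopifnot(inherits(layout, "ground_truth_layout"),
            inherits(meta, "acquisition_meta"))
  if (sigma_smlm <= 0) stop("sigma_smlm must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n_sites <- nrow(layout$sites)
  if (is.null(three_d)) three_d <- n_sites > 0 && any(layout$sites[, "z"] != 0)
  if (is.null(sigma_z)) sigma_z <- 2 * sigma_smlm
  n_frames <- meta$n_frames

  if (!is.null(t_measurement) && blink$mode == "kinetic") {
    mu <- expected_locs(blink$kinetics, t_measurement)
    K <- stats::rpois(n_sites, mu)
  } else {
    K <- rep_len(as.integer(locs_per_site), max(n_sites, 1L))
  }

  sim_cloud <- function(cx, cy, cz, k, span_frames = NULL) {
    if (k == 0) return(NULL)
    df <- data.frame(x = stats::rnorm(k, cx, sigma_smlm),
                     y = stats::rnorm(k, cy, sigma_smlm),
                     frame = if (is.null(span_frames)) draw_frames(k, blink, n_frames)
                             else sample(span_frames, k, replace = TRUE),
                     lp = sigma_smlm)
    if (three_d) df$z <- stats::rnorm(k, cz, sigma_z)
    df
  }

  per_channel <- vector("list", layout$n_rounds)
  for (ch in seq_len(layout$n_rounds) - 1L) {
    idx <- which(layout$channel == ch)
    parts <- lapply(idx, function(i)
      sim_cloud(layout$sites[i, "x"], layout$sites[i, "y"],
                layout$sites[i, "z"], K[i]))
    # sticking artifacts: extra clusters at random positions, frames
    # confined to a random span of consecutive frames
    n_stick <- if (blink$sticking_fraction > 0)
      stats::rbinom(1, length(idx), blink$sticking_fraction) else 0L
    if (n_stick > 0 && n_sites > 0) {
      rx <- range(layout$sites[, "x"]); ry <- range(layout$sites[, "y"])
      pad <- 10 * sigma_smlm
      for (s in seq_len(n_stick)) {
        start <- sample.int(max(n_frames - blink$sticking_span + 1L, 1L), 1) - 1L
        span <- seq.int(start, min(start + blink$sticking_span - 1L, n_frames - 1L))
        parts[[length(parts) + 1]] <-
          sim_cloud(stats::runif(1, rx[1] - pad, rx[2] + pad),
                    stats::runif(1, ry[1] - pad, ry[2] + pad),
                    if (three_d) stats::runif(1, -sigma_z, sigma_z) else 0,
                    max(1L, round(mean(K))), span_frames = span)
      }
    }
    df <- if (length(parts)) do.call(rbind, parts)
          else data.frame(x = numeric(0), y = numeric(0), frame = integer(0),
                          lp = numeric(0))
    if (three_d && is.null(df$z)) df$z <- numeric(0)
    df$channel <- rep(ch, nrow(df))
    per_channel[[ch + 1L]] <- loc_table(df, meta)
  }
  per_channel
}

#' Monomer/dimer mixture parameters
#'
#' The generative model for membrane-receptor point patterns: monomers
#' with complete spatial randomness at `density_monomers` per um^2, dimer
#' centres CSR at `density_dimers` (pairs) per um^2, each dimer emitting
#' two molecules at distance `dimer_distance` nm with uniform random
#' orientation. Every molecule position is perturbed by an isotropic
#' Gaussian of s.d. `uncertainty` nm (labelling plus localization error),
#' and molecules are independently retained with probability
#' `labelling_efficiency`.
#'
#' @param density_monomers Monomers per um^2.
#' @param density_dimers Dimer pairs per um^2.
#' @param dimer_distance Intra-dimer distance D, nm.
#' @param uncertainty Per-molecule positional s.d., nm.
#' @param labelling_efficiency Detectable fraction in \[0, 1\].
#' @param area Analysis window area, um^2 (square window).
#' @return A `mixture_params` list.
#' @export
mixture_params <- function(density_monomers, density_dimers, dimer_distance,
                           uncertainty, labelling_efficiency, area) {
  if (density_monomers < 0 || density_dimers < 0) stop("densities must be >= 0")
  if (dimer_distance < 0) stop("dimer_distance must be >= 0")
  if (uncertainty < 0) stop("uncertainty must be >= 0")
  if (labelling_efficiency < 0 || labelling_efficiency > 1)
    stop("labelling_efficiency must be in [0, 1]")
  if (area <= 0) stop("area must be > 0")
  structure(list(density_monomers = density_monomers,
                 density_dimers = density_dimers,
                 dimer_distance = dimer_distance,
                 uncertainty = uncertainty,
                 labelling_efficiency = labelling_efficiency,
                 area = area),
            class = "mixture_params")
}

#' Simulate a monomer/dimer membrane point pattern
#'
#' Draws detectable molecule positions from the model of
#' [mixture_params()]. Points are generated in a window enlarged by a
#' `guard` nm band and the pattern is returned with the guard points kept
#' separately, so nearest-neighbour statistics evaluated on the inner
#' window are free of edge deflation.
#'
#' @param params A [mixture_params()].
#' @param seed RNG seed.
#' @param guard Guard-band width, nm (default 100).
#' @return A `point_pattern`: list with `xy` (detectable molecules inside
#'   the window, nm), `xy_all` (including the guard band), `window`
#'   (c(width, height), nm), `guard`, and `density_observed` (per um^2).
#' @export
simulate_mixture <- function(params, seed = NULL, guard = 100) {
  stopifnot(inherits(params, "mixture_params"))
  if (!is.null(seed)) set.seed(seed)
  side <- sqrt(params$area) * 1000  # nm
  lo <- -guard; hi <- side + guard
  area_enl <- ((side + 2 * guard) / 1000)^2  # um^2

  pts <- cpp_sim_mixture(params$density_monomers * area_enl,
                         params$density_dimers * area_enl,
                         lo, hi, params$dimer_distance,
                         params$uncertainty, params$labelling_efficiency)
  colnames(pts) <- c("x", "y")
  inside <- pts[, 1] >= 0 & pts[, 1] <= side & pts[, 2] >= 0 & pts[, 2] <= side
  structure(list(xy = pts[inside, , drop = FALSE],
                 xy_all = pts,
                 window = c(side, side), guard = guard,
                 density_observed = sum(inside) / params$area),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("Point pattern: %d points in %.2f x %.2f um window (%.1f per um^2)\n",
              nrow(x$xy), x$window[1] / 1000, x$window[2] / 1000,
              x$density_observed))
  invisible(x)
}

# CSR point pattern helper shared by unresolved_fraction / csr_reference
sim_csr_points <- function(density_um2, area_um2, guard_nm = 100) {
  simulate_mixture(mixture_params(density_monomers = density_um2,
                                  density_dimers = 0, dimer_distance = 0,
                                  uncertainty = 0, labelling_efficiency = 1,
                                  area = area_um2),
                   guard = guard_nm)
}

# k-NN distances for inside points of a point_pattern, guard points as
# candidate neighbours only
nnd_with_guard <- function(pp, k, dmax = 0) {
  cpp_knn_rect(pp$xy_all[, 1], pp$xy_all[, 2], k,
               0, 0, pp$window[1], pp$window[2], dmax)
}
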