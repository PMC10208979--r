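#' DNA-PAINT binding kinetics parameters
#'
#' Bundles the imager-strand kinetics that set acquisition duration: the
#' on-rate `k_on` (M^-1 s^-1), imager concentration `c` (M), mean bright
#' time `tau_bright` (s) and camera exposure `t_exposure` (s). The mean
#' dark time between binding events is `tau_dark = 1 / (k_on * c)`.
#'
#' @param k_on Imager on-rate, per molar per second.
#' @param c Imager concentration, molar.
#' @param tau_bright Mean bright (bound) time, seconds.
#' @param t_exposure Camera exposure time, seconds.
#' @return A `kinetics_params` list with an additional `tau_dark` field.
#' @examples
#' kinetics_params(k_on = 1e6, c = 5e-10, tau_bright = 0.5, t_exposure = 0.1)
#' @export
kinetics_params <- function(k_on, c, tau_bright, t_exposure) {
  vals <- c(k_on = k_on, c = c, tau_bright = tau_bright, t_exposure = t_exposure)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all kinetics parameters must be strictly positive")
  structure(list(k_on = k_on, c = c, tau_bright = tau_bright,
                 t_exposure = t_exposure, tau_dark = 1 / (k_on * c)),
            class = "kinetics_params")
}

#' Localizations required for a target super-localization precision
#'
#' Grouping K localizations of precision `sigma_smlm` yields a
#' super-localization of precision `sigma_smlm / sqrt(K)` (the s.e.m. of
#' the cloud), so the number needed for a target precision is
#' `ceiling((sigma_smlm / sigma_resi)^2)`. For example, 16 localizations
#' of 4 nm precision give 1 nm.
#'
#' @param sigma_smlm Single-round localization precision (nm).
#' @param sigma_resi Desired super-localization precision (nm),
#'   `<= sigma_smlm`.
#' @return Integer number of localizations.
#' @export
required_localizations <- function(sigma_smlm, sigma_resi) {
  if (!is.finite(sigma_smlm) || sigma_smlm <= 0 ||
      !is.finite(sigma_resi) || sigma_resi <= 0)
    stop("precisions must be positive")
  if (sigma_resi > sigma_smlm)
    stop("sigma_resi exceeds sigma_smlm: no averaging needed")
  as.integer(ceiling((sigma_smlm / sigma_resi)^2))
}

#' Expected acquisition time to collect a number of localizations
#'
#' On average a binding site produces `k_on * c` binding events per second
#' and `tau_bright / t_exposure` localizations per event, so collecting
#' `n_loc` localizations takes
#' `t = t_exposure * n_loc / (tau_bright * k_on * c)` seconds.
#'
#' @param k A [kinetics_params()] object.
#' @param n_loc Number of localizations to collect (>= 1).
#' @return Expected measurement time in seconds.
#' @seealso [expected_locs()] for the algebraic inverse.
#' @export
measurement_time <- function(k, n_loc) {
  stopifnot(inherits(k, "kinetics_params"))
  if (any(n_loc < 1)) stop("n_loc must be >= 1")
  k$t_exposure * n_loc / (k$tau_bright * k$k_on * k$c)
}

#' @rdname measurement_time
#' @param t_measurement Acquisition duration in seconds.
#' @return `expected_locs()`: the mean number of localizations collected
#'   per binding site in `t_measurement` seconds.
#' @export
expected_locs <- function(k, t_measurement) {
  stopifnot(inherits(k, "kinetics_params"))
  t_measurement * k$k_on * k$c * k$tau_bright / k$t_exposure
}

#' Stochastic-labelling probabilities
#'
#' With `n` orthogonal sequences applied at equal concentration, each
#' target independently receives sequence i with probability 1/n.
#' `p_pair_distinct()` is the probability that the two members of a pair
#' receive different sequences, `1 - 1/n` (75% for n = 4).
#' `p_all_distinct()` generalizes to a set of `m` targets: the probability
#' that all m receive distinct sequences is `n! / ((n - m)! * n^m)` for
#' `m <= n`, and 0 otherwise.
#'
#' @param n_rounds Number of orthogonal sequences / imaging rounds n.
#' @return A probability in \[0, 1\].
#' @examples
#' p_pair_distinct(4)     # 0.75
#' p_all_distinct(3, 4)   # 24/64
#' @export
p_pair_distinct <- function(n_rounds) {
  if (n_rounds < 1 || n_rounds != floor(n_rounds)) stop("n_rounds must be a positive integer")
  1 - 1 / n_rounds
}

#' @rdname p_pair_distinct
#' @param m Number of targets closer than the single-round resolution.
#' @export
p_all_distinct <- function(m, n_rounds) {
  if (m < 1 || m != floor(m)) stop("m must be a positive integer")
  if (n_rounds < 1 || n_rounds != floor(n_rounds)) stop("n_rounds must be a positive integer")
  if (m > n_rounds) return(0)
  # n!/(n-m)! n^-m as a product, stable for moderate n
  prod((n_rounds - seq_len(m) + 1) / n_rounds)
}

#' Fraction of targets unresolved in one imaging round
#'
#' For targets distributed with complete spatial randomness at a given
#' density, a target is considered unresolvable when its nearest neighbour
#' in the same round lies closer than `d = resolvability_factor * sigma`.
#' Splitting targets over `n_rounds` sequences reduces the per-round
#' density to `rho = density / n_rounds`; the CSR first-NND CDF then gives
#' the unresolved fraction `F = 1 - exp(-rho * pi * d^2)` in closed form.
#' The `"simulation"` method estimates the same fraction from the
#' empirical first-NND distribution of simulated CSR point patterns.
#'
#' @param density Target density, per square micrometre.
#' @param sigma_smlm Single-round localization precision, nm.
#' @param n_rounds Number of imaging rounds the targets are split over.
#' @param resolvability_factor Multiple of sigma defining the reliably
#'   resolvable distance d (default 4, stricter than the FWHM factor 2.35).
#' @param method `"closed_form"` or `"simulation"`.
#' @param n_points Approximate number of simulated points (simulation).
#' @param seed RNG seed (simulation).
#' @return Fraction F in \[0, 1\].
#' @examples
#' unresolved_fraction(200, sigma_smlm = 5, n_rounds = 4)  # ~0.061
#' @export
unresolved_fraction <- function(density, sigma_smlm, n_rounds = 1,
                                resolvability_factor = 4,
                                method = c("closed_form", "simulation"),
                                n_points = 1e5, seed = NULL) {
  method <- match.arg(method)
  if (density < 0) stop("density must be >= 0")
  if (n_rounds < 1) stop("n_rounds must be >= 1")
  if (sigma_smlm <= 0) stop("sigma_smlm must be > 0")
  rho_um2 <- density / n_rounds
  d_nm <- resolvability_factor * sigma_smlm
  if (rho_um2 == 0) return(0)
  if (method == "closed_form") {
    rho_nm2 <- rho_um2 * 1e-6
    return(1 - exp(-rho_nm2 * pi * d_nm^2))
  }
  if (!is.null(seed)) set.seed(seed)
  area_um2 <- n_points / rho_um2
  pts <- sim_csr_points(rho_um2, area_um2, guard_nm = 10 * d_nm)
  if (nrow(pts$xy) < 2) return(0)
  nnd <- nnd_with_guard(pts, k = 1)
  mean(nnd[, 1] < d_nm)
}
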