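# Brute-force O(N^2) oracles used against the compiled spatial kernels.

brute_neighbor_counts <- function(xy, r, z = NULL, rz = NULL) {
  n <- nrow(xy)
  d2 <- as.matrix(stats::dist(xy))^2
  if (!is.null(z)) d2 <- d2 + outer(z, z, "-")^2 * (r / rz)^2
  rowSums(d2 <= r^2) - 1L
}

brute_knn <- function(xy, k) {
  D <- as.matrix(stats::dist(xy))
  t(apply(D, 1, function(row) sort(row[-which.min(row)])[seq_len(k)]))
}

brute_local_maxima <- function(xy, r, counts, z = NULL, rz = NULL) {
  n <- nrow(xy)
  d2 <- as.matrix(stats::dist(xy))^2
  if (!is.null(z)) d2 <- d2 + outer(z, z, "-")^2 * (r / rz)^2
  out <- integer(0)
  for (i in seq_len(n)) {
    nb <- setdiff(which(d2[i, ] <= r^2), i)
    beat <- counts[nb] > counts[i] | (counts[nb] == counts[i] & nb < i)
    if (!any(beat)) out <- c(out, i)
  }
  out
}

random_table <- function(n, three_d = FALSE, extent = 100, n_frames = 1000,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(x = runif(n, 0, extent), y = runif(n, 0, extent),
                   frame = sample(0:(n_frames - 1), n, replace = TRUE),
                   lp = runif(n, 0.5, 3))
  if (three_d) df$z <- runif(n, 0, extent)
  loc_table(df, acquisition_meta(n_frames))
}

# one well-separated two-cloud table: sites at (0,0) and (sep,0)
two_cloud_table <- function(sep = 20, sigma = 2, K = 100, n_frames = 10000,
                            seed = 1) {
  lay <- make_layout("grid", nx = 2, ny = 1, pitch = sep)
  sample_localizations(lay, sigma_smlm = sigma,
                       acquisition_meta(n_frames), locs_per_site = K,
                       seed = seed)[[1]]
}
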