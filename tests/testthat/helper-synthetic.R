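# Synthetic fixtures built in code: Gaussian shared-signal frame pairs and
# strength-profile builders for field-search scenarios. Uses the session RNG;
# tests seed explicitly.

# side x side pair t_i = s + n_i with shared signal sd `sd_s` and independent
# per-frame noise sd `sd_n` (the model under which the covariance SNR is
# defined; true SNR = sd_s / sd_n)
make_gaussian_pair <- function(side, sd_s = 1, sd_n = 1) {
  s <- matrix(rnorm(side * side, sd = sd_s), side, side)
  list(t1 = s + matrix(rnorm(side * side, sd = sd_n), side, side),
       t2 = s + matrix(rnorm(side * side, sd = sd_n), side, side))
}

# Brute-force oracle for the stability index: empirical squared mean over
# variance of the sample covariance across `n_rep` replicate Gaussian pairs
# of m pixels at a given true SNR, with a delta-method Monte-Carlo standard
# error. Computed from first principles (direct covariance formula),
# independently of the package's estimators.
oracle_stability_mc <- function(snr, m, n_rep) {
  s <- matrix(rnorm(m * n_rep, sd = snr), m, n_rep)
  x <- s + matrix(rnorm(m * n_rep), m, n_rep)
  y <- s + matrix(rnorm(m * n_rep), m, n_rep)
  cv <- (colSums(x * y) - m * colMeans(x) * colMeans(y)) / (m - 1)
  mu <- mean(cv)
  v <- stats::var(cv)
  ratio <- mu^2 / v
  d <- cv - mu
  mu3 <- mean(d^3)
  mu4 <- mean(d^4)
  # delta method for R = mu^2 / v with gradients (2 mu / v, -mu^2 / v^2)
  var_r <- ((2 * mu / v)^2 * v +
            (mu^2 / v^2)^2 * (mu4 - v^2) -
            2 * (2 * mu / v) * (mu^2 / v^2) * mu3) / n_rep
  list(ratio = ratio, se = sqrt(max(var_r, 0)))
}

# uniform strength map with square patches of given strength planted at
# (cx, cy) matrix coordinates (cx = column, cy = row)
plant_profile <- function(n, patches, base = 1) {
  m <- matrix(base, n, n)
  for (p in patches) {
    m[(p$cy - p$half):(p$cy + p$half), (p$cx - p$half):(p$cx + p$half)] <- p$strength
  }
  m
}
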