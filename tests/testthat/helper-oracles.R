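# Independent reference implementations used as oracles. These deliberately
# avoid the package's histogram code path.

# Direct Debye double sum over all unordered pairs (no binning), self terms
# excluded, normalized to 1 at q -> 0.
debye_direct <- function(coords, weights, q) {
  n <- nrow(coords)
  d <- as.vector(dist(coords))
  ww <- numeric(length(d))
  idx <- 1L
  for (j in seq_len(n - 1L)) {
    k <- (j + 1L):n
    ww[idx:(idx + length(k) - 1L)] <- weights[j] * weights[k]
    idx <- idx + length(k)
  }
  sapply(q, function(qq) sum(ww * sin(qq * d) / (qq * d))) / sum(ww)
}

# Analytic sphere form factor [3 (sin x - x cos x)/x^3]^2
sphere_ff <- function(q, R) {
  x <- q * R
  (3 * (sin(x) - x * cos(x)) / x^3)^2
}

# Analytic p(r) of a uniform solid sphere, r in [0, 2R]
sphere_pr <- function(r, R) {
  p <- r^2 * (1 - 3 * r / (4 * R) + r^3 / (16 * R^3))
  p[r < 0 | r > 2 * R] <- 0
  p
}

# Example-3 core-shell cylinder built by overlap exclusion: a -1 contrast
# core cylinder takes precedence inside a +1 outer cylinder.
example3_exclusion_spec <- function(n_points = 3000) {
  model_spec(list(
    subunit("cylinder", c(20, 360), delta_sld = -1),
    subunit("cylinder", c(40, 400), delta_sld = +1)
  ), n_points = n_points)
}

# Same particle from four non-overlapping subunits (core, radial shell ring,
# two end caps).
example3_explicit_spec <- function(n_points = 3000) {
  model_spec(list(
    subunit("cylinder", c(20, 360), delta_sld = -1),
    subunit("cylindrical_ring", c(40, 20, 360), delta_sld = +1),
    subunit("disc", c(40, 20), delta_sld = +1, com = c(0, 0, 190)),
    subunit("disc", c(40, 20), delta_sld = +1, com = c(0, 0, -190))
  ), n_points = n_points)
}

# One virtual experiment + weighted fit of the analytic core-shell cylinder,
# core contrast fixed at -1 (scale and background free).
example3_fit <- function(seed, n_points = 3000) {
  set.seed(seed)
  m <- build_point_model(example3_exclusion_spec(n_points))
  res <- simulate_experiment(m)
  fit_weighted(res$dataset, "core_shell_cylinder",
               start = list(r_core = 20, l_core = 360, t_shell = 20,
                            sld_shell = 1, scale = res$i0, background = 0),
               fixed = list(sld_core = -1))
}
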