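#' Percus-Yevick hard-sphere structure factor
#'
#' Analytic structure factor of a hard-sphere fluid in the Percus-Yevick
#' approximation, describing interparticle repulsion:
#' `S(q) = 1 / (1 + 24 eta G(A) / A)` with `A = 2 q R_hs` and `G` the
#' standard polynomial in `sin A`, `cos A` with coefficients
#' `alpha = (1 + 2 eta)^2 / (1 - eta)^4`,
#' `beta = -6 eta (1 + eta/2)^2 / (1 - eta)^4`, `gamma = eta alpha / 2`.
#' At small `A` the closed form is evaluated through its series limit, so
#' the compressibility limit `S(0) = (1 - eta)^4 / (1 + 2 eta)^2` is exact.
#'
#' @param q Momentum transfer, 1/A.
#' @param r_hs Hard-sphere interaction radius in Angstrom (> 0).
#' @param eta Volume fraction, in (0, 0.74) (above ~0.74 spheres cannot
#'   pack).
#' @return `S(q)`, same length as `q`.
#' @export
hard_sphere_sq <- function(q, r_hs, eta) {
  stopifnot(r_hs > 0)
  if (!(eta > 0 && eta < 0.74)) {
    stop("hard-sphere volume fraction 'eta' must lie in (0, 0.74)", call. = FALSE)
  }
  alpha <- (1 + 2 * eta)^2 / (1 - eta)^4
  beta <- -6 * eta * (1 + eta / 2)^2 / (1 - eta)^4
  gam <- eta * alpha / 2
  a <- 2 * q * r_hs
  g_over_a <- numeric(length(a))
  big <- a > 0.05
  ab <- a[big]
  sa <- sin(ab); ca <- cos(ab)
  g <- alpha * (sa - ab * ca) / ab^2 +
    beta * (2 * ab * sa + (2 - ab^2) * ca - 2) / ab^3 +
    gam * (-ab^4 * ca + 4 * ((3 * ab^2 - 6) * ca + (ab^3 - 6 * ab) * sa + 6)) / ab^5
  g_over_a[big] <- g / ab
  # A -> 0 series: G(A)/A -> alpha/3 + beta/4 + gamma/6
  g_over_a[!big] <- alpha / 3 + beta / 4 + gam / 6
  1 / (1 + 24 * eta * g_over_a)
}

#' Fractal-aggregate structure factor
#'
#' Structure factor of two-dimensional fractal aggregates of `n_agg`
#' particles with effective per-particle radius `r_eff`:
#' `S_agg(q) = 1 + (n_agg - 1) / (1 + (q r_eff)^2 n_agg / 3)`
#' (fractal dimension fixed at 2). A fraction `frac` of the particles sits
#' in aggregates and the rest scatters freely, so the effective structure
#' factor is the intensity-weighted mixture
#' `S(q) = 1 + frac * (S_agg(q) - 1)`. Limits: `S(0) = 1 + frac (n_agg - 1)`
#' and `S -> 1` at large q.
#'
#' @param q Momentum transfer, 1/A.
#' @param frac Fraction of particles in aggregates, in `[0, 1]`.
#' @param n_agg Mean number of particles per aggregate (>= 1).
#' @param r_eff Effective radius of one particle in the aggregate, Angstrom.
#' @return `S(q)`, same length as `q`.
#' @export
fractal_sq <- function(q, frac, n_agg, r_eff) {
  stopifnot(frac >= 0, frac <= 1, n_agg >= 1, r_eff > 0)
  s_agg <- 1 + (n_agg - 1) / (1 + (q * r_eff)^2 * n_agg / 3)
  1 + frac * (s_agg - 1)
}

#' Decoupling factor for non-spherical particles
#'
#' For non-spherical (or polydisperse) particles a structure factor derived
#' for spheres cannot multiply the form factor directly; the decoupling
#' approximation damps it by
#' `beta(q) = <F(q)>^2 / <|F(q)|^2>`, where `<F(q)>` is the
#' orientation-averaged scattering amplitude. From the bead model,
#' `<F(q)> = sum_j db_j sinc(q r_j)` with `r_j` the distance of point `j`
#' from the particle's scattering-weighted center (|db|-weighted centroid,
#' robust when the net contrast is small), and `<|F|^2>` is the normalized
#' intensity of the same point cloud. beta is clamped to `[0, 1]`;
#' `beta(q -> 0) = 1` for any particle.
#'
#' @param model A [build_point_model()] result with nonzero net contrast.
#' @param q Momentum transfer, 1/A.
#' @param n_bins Bins used for the `<|F|^2>` histogram (default 200).
#' @return `beta(q)`, same length as `q`.
#' @export
decoupling_beta <- function(model, q, n_bins = 200) {
  stopifnot(inherits(model, "point_model"))
  w <- model$weights
  sw <- sum(w)
  if (abs(sw) < 1e-12 * sum(abs(w))) {
    stop("net contrast is zero; decoupling amplitude undefined", call. = FALSE)
  }
  center <- colSums(model$coords * abs(w)) / sum(abs(w))
  rj <- sqrt(rowSums(sweep(model$coords, 2, center)^2))
  amp <- as.vector(.sinc(outer(q, rj)) %*% w) / sw
  hist <- pair_histogram(model, n_bins)
  # <F^2> including self terms, normalized consistently with <F>^2:
  # sum over all ordered pairs = 2*sum_p + sum_w2, divided by (sum_w)^2
  qr <- outer(q, hist$r_centers)
  f2 <- (2 * as.vector(.sinc(qr) %*% hist$p_values) + hist$sum_w2) / sw^2
  beta <- amp^2 / f2
  pmin(pmax(beta, 0), 1)
}

#' Apply a structure factor to a normalized intensity
#'
#' Multiplies the form factor by the effective structure factor
#' `S_eff(q) = 1 + beta(q) (S(q) - 1)` (the decoupling approximation;
#' `beta = 1` recovers the plain product `P * S`). The pair distance
#' distribution is never modified: p(r) always describes the
#' non-interacting particle, interactions only reshape I(q). `S_eff` is
#' floored at 1e-6 so numerical noise in beta can never produce negative
#' intensities.
#'
#' @param curve A [scattering_curve()].
#' @param sq Structure factor on the same q grid.
#' @param beta Decoupling factor on the same q grid (default 1 everywhere,
#'   i.e. spherical particles).
#' @return A [scattering_curve()] with intensity `P * S_eff`; the applied
#'   `S_eff` is attached as attribute `"s_eff"`.
#' @export
apply_structure_factor <- function(curve, sq, beta = rep(1, length(sq))) {
  stopifnot(inherits(curve, "scattering_curve"))
  if (length(sq) != length(curve$q) || length(beta) != length(curve$q)) {
    stop("structure factor and beta must be on the same q grid as the curve",
         call. = FALSE)
  }
  s_eff <- pmax(1 + beta * (sq - 1), 1e-6)
  out <- scattering_curve(curve$q, curve$intensity * s_eff)
  attr(out, "s_eff") <- s_eff
  out
}
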