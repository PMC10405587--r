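#' Default momentum-transfer grid
#'
#' 400 logarithmically spaced points between `q_min` and `q_max` (inverse
#' Angstrom), covering the range of a typical SAXS experiment.
#'
#' @param q_min,q_max Grid limits in 1/A (defaults 1e-3 and 0.5).
#' @param n Number of points (default 400).
#' @param spacing `"log"` (default) or `"linear"`.
#' @return Numeric vector of q values.
#' @export
default_q_grid <- function(q_min = 1e-3, q_max = 0.5, n = 400,
                           spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  stopifnot(q_min > 0, q_max > q_min, n >= 2)
  if (spacing == "log") exp(seq(log(q_min), log(q_max), length.out = n))
  else seq(q_min, q_max, length.out = n)
}

# numerically safe sin(x)/x; preserves dim so it works on outer() products
.sinc <- function(x) {
  out <- x
  out[] <- 1
  big <- x >= 1e-4
  out[big] <- sin(x[big]) / x[big]
  small <- !big & x > 0
  out[small] <- 1 - x[small]^2 / 6
  out
}

#' Contrast-weighted pair-distance histogram
#'
#' Bins all `n(n-1)/2` unordered point pairs of a bead model by their
#' distance, each pair weighted by the product of the excess scattering
#' lengths of its two points. Self terms (`j == k`) are excluded; their
#' contribution vanishes in the continuum limit. The histogram is the
#' workhorse behind the Debye sum: intensity evaluation then costs
#' O(n_bins) per q value instead of O(N^2).
#'
#' @param model A [build_point_model()] result with at least 2 points.
#' @param n_bins Number of equal-width bins over `[0, D_max]` (default 200).
#' @return An object of class `"pair_histogram"`: `r_centers`, `p_values`
#'   (sum of weight products per bin), `bin_width`, `d_max` (largest sampled
#'   pair distance), `sum_p` (total pair weight, the q->0 limit of the Debye
#'   sum), `sum_w` and `sum_w2` (sum of point weights and squared weights).
#' @export
pair_histogram <- function(model, n_bins = 200) {
  stopifnot(inherits(model, "point_model"))
  n <- nrow(model$coords)
  if (n < 2L) stop("pair histogram needs at least 2 points", call. = FALSE)
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 1L)
  d_max <- .max_pair_dist_cpp(model$coords)
  if (d_max <= 0) stop("all points coincide; degenerate model", call. = FALSE)
  h <- .pair_hist_cpp(model$coords, model$weights, n_bins, d_max)
  dr <- d_max / n_bins
  structure(list(
    r_centers = (seq_len(n_bins) - 0.5) * dr,
    p_values = h$p,
    bin_width = dr,
    d_max = h$d_max,
    sum_p = sum(h$p),
    sum_w = sum(model$weights),
    sum_w2 = sum(model$weights^2)
  ), class = "pair_histogram")
}

#' @export
print.pair_histogram <- function(x, ...) {
  cat(sprintf("<pair_histogram> %d bins, dr = %.3g A, D_max = %.4g A\n",
              length(x$p_values), x$bin_width, x$d_max))
  invisible(x)
}

#' Pair distance distribution p(r)
#'
#' Returns the histogram as a normalized pair distance distribution: values
#' divided by the maximum so the peak is unity, with a leading `(0, 0)` row
#' (the self terms are excluded, so p(0) = 0 by convention). For
#' multi-contrast particles p(r) can be negative at some r.
#'
#' @param hist A [pair_histogram()] (or the `$pr` component of a
#'   polydisperse result).
#' @return A data frame with columns `r` (Angstrom) and `p` (unitless,
#'   max = 1).
#' @export
p_of_r <- function(hist) {
  r <- hist$r_centers
  p <- hist$p_values
  m <- max(p)
  if (m <= 0) stop("p(r) has no positive values; cannot normalize", call. = FALSE)
  data.frame(r = c(0, r), p = c(0, p / m))
}

#' Radius of gyration from the pair-distance histogram
#'
#' The contrast-weighted second moment of the pair distance distribution,
#' `R_g^2 = sum(p_i r_i^2) / (2 sum(p_i) + sum(db_j^2))`. The squared-weight
#' term restores the self pairs excluded from the histogram, making the
#' estimate exact for the discrete point set (e.g. a two-point dumbbell has
#' `R_g = d/2`); it is an O(1/N) correction that vanishes in the continuum
#' limit `R_g^2 -> sum(p r^2) / (2 sum p)`. Requires positive net pair
#' weight; multi-contrast particles with vanishing net contrast have no
#' defined R_g.
#'
#' @param hist A [pair_histogram()].
#' @return R_g in Angstrom.
#' @export
radius_of_gyration <- function(hist) {
  if (hist$sum_p <= 0) {
    stop("net pair weight is not positive; R_g undefined for this contrast combination",
         call. = FALSE)
  }
  rg2 <- sum(hist$p_values * hist$r_centers^2) /
    (2 * hist$sum_p + hist$sum_w2)
  sqrt(max(rg2, 0))
}

#' Normalized scattering intensity from a pair-distance histogram
#'
#' Evaluates the Debye sum over histogram bins,
#' `I(q) = sum_i p_i sinc(q r_i)`, normalized by `sum_i p_i` so that
#' `I_norm(q -> 0) = 1` (the form factor `P(q)` for a dilute sample).
#'
#' @param hist A [pair_histogram()].
#' @param q Momentum-transfer grid in 1/A, strictly positive.
#' @return An object of class `"scattering_curve"` with elements `q` and
#'   `intensity`.
#' @export
intensity_from_histogram <- function(hist, q = default_q_grid()) {
  stopifnot(all(q > 0))
  if (hist$sum_p == 0) {
    stop("total pair weight is zero; cannot normalize intensity", call. = FALSE)
  }
  qr <- outer(q, hist$r_centers)
  i <- as.vector(.sinc(qr) %*% hist$p_values) / hist$sum_p
  scattering_curve(q, i)
}

#' @rdname intensity_from_histogram
#' @param intensity Intensity values on `q`.
#' @export
scattering_curve <- function(q, intensity) {
  stopifnot(length(q) == length(intensity), all(is.finite(q)), all(q > 0),
            !is.unsorted(q, strictly = TRUE), all(is.finite(intensity)))
  structure(list(q = as.numeric(q), intensity = as.numeric(intensity)),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("<scattering_curve> %d q-points in [%.3g, %.3g] 1/A\n",
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' @export
as.data.frame.scattering_curve <- function(x, ...) {
  data.frame(q = x$q, intensity = x$intensity)
}

#' Scattering with Gaussian size polydispersity
#'
#' Averages the scattering over a Gaussian distribution of a size-scale
#' factor `s` (mean 1, standard deviation `sigma_s`) that rescales all
#' distances in the particle (`r -> s r`). Each scale contributes with
#' weight `G(s; 1, sigma_s) * s^6`: the `s^3` relative volume enters
#' squared because scattering scales with the square of the particle
#' volume (exact for spheres, an approximation otherwise). The integrals
#' run over `s` in `[1 - 3 sigma_s, 1 + 3 sigma_s]` and are evaluated by
#' the trapezoid rule on `n_s` equally spaced scales; the histogram is
#' rescaled per `s`, the point cloud is generated only once. The ensemble
#' intensity is normalized to 1 at q -> 0 after averaging.
#'
#' @param model A [build_point_model()] result.
#' @param q Momentum-transfer grid in 1/A.
#' @param sigma_s Relative size standard deviation, `0 <= sigma_s < 1/3`
#'   (so all scales stay positive).
#' @param n_bins Histogram bins (default 200).
#' @param n_s Number of quadrature scales (default 21).
#' @return A list with `curve` (ensemble [scattering_curve()]), `pr`
#'   (ensemble p(r) data frame, max normalized to 1) and `hist` (the
#'   monodisperse [pair_histogram()]).
#' @export
polydisperse_intensity <- function(model, q = default_q_grid(), sigma_s = 0,
                                   n_bins = 200, n_s = 21) {
  stopifnot(sigma_s >= 0)
  if (sigma_s >= 1 / 3) {
    stop("sigma_s must be < 1/3 so that 1 - 3*sigma_s stays positive",
         call. = FALSE)
  }
  hist <- pair_histogram(model, n_bins)
  if (sigma_s == 0) {
    return(list(curve = intensity_from_histogram(hist, q),
                pr = p_of_r(hist), hist = hist))
  }
  s_grid <- seq(1 - 3 * sigma_s, 1 + 3 * sigma_s, length.out = n_s)
  w_s <- stats::dnorm(s_grid, 1, sigma_s) * s_grid^6
  # trapezoid weights on the uniform s grid
  trap <- rep(1, n_s); trap[c(1, n_s)] <- 0.5
  w_s <- w_s * trap
  w_s <- w_s / sum(w_s)

  # intensity: rescale bin centers r -> s r, same p weights
  i_acc <- numeric(length(q))
  for (k in seq_len(n_s)) {
    qr <- outer(q, s_grid[k] * hist$r_centers)
    i_acc <- i_acc + w_s[k] * as.vector(.sinc(qr) %*% hist$p_values)
  }
  curve <- scattering_curve(q, i_acc / hist$sum_p)

  # ensemble p(r): average the rescaled histograms on a common grid
  r_out <- seq(0, (1 + 3 * sigma_s) * hist$d_max, length.out = n_bins + 1)[-1]
  p_acc <- numeric(length(r_out))
  for (k in seq_len(n_s)) {
    p_k <- stats::approx(s_grid[k] * hist$r_centers, hist$p_values,
                         xout = r_out, yleft = 0, yright = 0)$y
    p_k[r_out > s_grid[k] * hist$d_max] <- 0
    p_acc <- p_acc + w_s[k] * p_k
  }
  m <- max(p_acc)
  if (m <= 0) stop("polydisperse p(r) has no positive values", call. = FALSE)
  pr <- data.frame(r = c(0, r_out), p = c(0, p_acc / m))
  list(curve = curve, pr = pr, hist = hist)
}
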