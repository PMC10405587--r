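#' Geometric subunit of a particle
#'
#' A particle is assembled from one or more geometric subunits, each with its
#' own dimensions, excess scattering-length density (contrast relative to the
#' solvent) and center-of-mass displacement. Supported kinds and the meaning
#' of their `dims` vector:
#'
#' * `sphere`: radius `R`
#' * `triaxial_ellipsoid`: semi-axes `a, b, c` along x, y, z
#' * `cylinder`, `disc`: radius `R`, length `L` (axis along z); a disc is a
#'   cylinder with `L < R` by convention, not enforced
#' * `cube`: side `a`
#' * `cuboid`: sides `a, b, c`
#' * `hollow_sphere`: outer and inner radius `R_out, R_in`
#' * `hollow_cube`: outer and inner side `a_out, a_in`
#' * `cylindrical_ring`, `discoidal_ring`: `R_out, R_in, L`
#'
#' All lengths are in Angstrom. The contrast `delta_sld` is a unitless
#' relative excess scattering-length density; its sign carries through to the
#' pair-distance distribution and the intensity.
#'
#' @param kind Character, one of the kinds above.
#' @param dims Numeric vector of positive lengths (Angstrom); arity depends
#'   on `kind`.
#' @param delta_sld Excess scattering-length density (unitless, default 1).
#' @param com Length-3 numeric, center-of-mass displacement in Angstrom.
#' @return An object of class `"subunit"`.
#' @examples
#' subunit("sphere", 50)
#' subunit("cylinder", c(20, 400), delta_sld = -1, com = c(0, 0, 100))
#' @export
subunit <- function(kind, dims, delta_sld = 1, com = c(0, 0, 0)) {
  kind <- match.arg(kind, names(.subunit_arity))
  dims <- as.numeric(dims)
  arity <- .subunit_arity[[kind]]
  if (length(dims) != arity) {
    stop(sprintf("subunit '%s' needs %d dimension(s) (%s), got %d",
                 kind, arity, .subunit_dimnames[[kind]], length(dims)),
         call. = FALSE)
  }
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    stop(sprintf("subunit '%s': all dimensions must be positive and finite", kind),
         call. = FALSE)
  }
  if (kind %in% c("hollow_sphere", "hollow_cube", "cylindrical_ring",
                  "discoidal_ring") && dims[2] >= dims[1]) {
    stop(sprintf("subunit '%s': inner dimension (%g) must be smaller than outer (%g)",
                 kind, dims[2], dims[1]), call. = FALSE)
  }
  com <- as.numeric(com)
  if (length(com) != 3 || any(!is.finite(com))) {
    stop("'com' must be a finite length-3 numeric vector", call. = FALSE)
  }
  if (!is.finite(delta_sld)) stop("'delta_sld' must be finite", call. = FALSE)
  structure(list(kind = kind, dims = dims, delta_sld = delta_sld, com = com),
            class = "subunit")
}

.subunit_arity <- list(
  sphere = 1L, triaxial_ellipsoid = 3L, cylinder = 2L, disc = 2L,
  cube = 1L, cuboid = 3L, hollow_sphere = 2L, hollow_cube = 2L,
  cylindrical_ring = 3L, discoidal_ring = 3L
)

.subunit_dimnames <- list(
  sphere = "R", triaxial_ellipsoid = "a,b,c", cylinder = "R,L", disc = "R,L",
  cube = "a", cuboid = "a,b,c", hollow_sphere = "R_out,R_in",
  hollow_cube = "a_out,a_in", cylindrical_ring = "R_out,R_in,L",
  discoidal_ring = "R_out,R_in,L"
)

#' @export
print.subunit <- function(x, ...) {
  cat(sprintf("<subunit> %s [%s] = (%s) A, dSLD = %g, com = (%s) A\n",
              x$kind, .subunit_dimnames[[x$kind]],
              paste(format(x$dims), collapse = ", "), x$delta_sld,
              paste(format(x$com), collapse = ", ")))
  invisible(x)
}

#' Analytic volume of a subunit
#'
#' Closed-form volume in cubic Angstrom. Hollow kinds return the volume of
#' the material shell (outer minus inner).
#'
#' @param su A [subunit()].
#' @return Volume in A^3.
#' @examples
#' subunit_volume(subunit("sphere", 50))          # 4/3 pi 50^3
#' subunit_volume(subunit("hollow_sphere", c(50, 30)))
#' @export
subunit_volume <- function(su) {
  stopifnot(inherits(su, "subunit"))
  d <- su$dims
  switch(su$kind,
    sphere             = 4 / 3 * pi * d[1]^3,
    triaxial_ellipsoid = 4 / 3 * pi * d[1] * d[2] * d[3],
    cylinder           = pi * d[1]^2 * d[2],
    disc               = pi * d[1]^2 * d[2],
    cube               = d[1]^3,
    cuboid             = d[1] * d[2] * d[3],
    hollow_sphere      = 4 / 3 * pi * (d[1]^3 - d[2]^3),
    hollow_cube        = d[1]^3 - d[2]^3,
    cylindrical_ring   = pi * (d[1]^2 - d[2]^2) * d[3],
    discoidal_ring     = pi * (d[1]^2 - d[2]^2) * d[3],
    stop("unsupported subunit kind: ", su$kind, call. = FALSE)
  )
}

# Axis-aligned bounding box of the subunit in its local (un-shifted) frame.
.subunit_bbox <- function(su) {
  d <- su$dims
  half <- switch(su$kind,
    sphere             = rep(d[1], 3),
    triaxial_ellipsoid = d,
    cylinder           = c(d[1], d[1], d[2] / 2),
    disc               = c(d[1], d[1], d[2] / 2),
    cube               = rep(d[1] / 2, 3),
    cuboid             = d / 2,
    hollow_sphere      = rep(d[1], 3),
    hollow_cube        = rep(d[1] / 2, 3),
    cylindrical_ring   = c(d[1], d[1], d[3] / 2),
    discoidal_ring     = c(d[1], d[1], d[3] / 2)
  )
  half
}

# Containment test in the local frame; x is an n x 3 matrix.
# Boundary points count as inside (<=); the choice is immaterial at float
# precision but fixed for determinism.
.contains_local <- function(su, x) {
  d <- su$dims
  switch(su$kind,
    sphere = rowSums(x^2) <= d[1]^2,
    triaxial_ellipsoid =
      (x[, 1] / d[1])^2 + (x[, 2] / d[2])^2 + (x[, 3] / d[3])^2 <= 1,
    cylinder = ,
    disc = x[, 1]^2 + x[, 2]^2 <= d[1]^2 & abs(x[, 3]) <= d[2] / 2,
    cube = abs(x[, 1]) <= d[1] / 2 & abs(x[, 2]) <= d[1] / 2 &
      abs(x[, 3]) <= d[1] / 2,
    cuboid = abs(x[, 1]) <= d[1] / 2 & abs(x[, 2]) <= d[2] / 2 &
      abs(x[, 3]) <= d[3] / 2,
    hollow_sphere = {
      r2 <- rowSums(x^2)
      r2 <= d[1]^2 & r2 >= d[2]^2
    },
    hollow_cube = {
      inside_out <- abs(x[, 1]) <= d[1] / 2 & abs(x[, 2]) <= d[1] / 2 &
        abs(x[, 3]) <= d[1] / 2
      inside_in <- abs(x[, 1]) < d[2] / 2 & abs(x[, 2]) < d[2] / 2 &
        abs(x[, 3]) < d[2] / 2
      inside_out & !inside_in
    },
    cylindrical_ring = ,
    discoidal_ring = {
      r2 <- x[, 1]^2 + x[, 2]^2
      r2 <= d[1]^2 & r2 >= d[2]^2 & abs(x[, 3]) <= d[3] / 2
    }
  )
}

#' Point-in-subunit test
#'
#' Tests whether points (given in the global frame) lie inside the subunit
#' volume after the subunit is shifted to its center of mass. Boundary points
#' count as inside.
#'
#' @param su A [subunit()].
#' @param points Length-3 numeric vector or an n x 3 matrix of coordinates
#'   (Angstrom).
#' @return Logical vector, one entry per point.
#' @examples
#' contains(subunit("sphere", 50), c(0, 0, 50))       # TRUE (boundary)
#' contains(subunit("hollow_sphere", c(50, 30)), c(0, 0, 10))  # FALSE (cavity)
#' @export
contains <- function(su, points) {
  stopifnot(inherits(su, "subunit"))
  x <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  stopifnot(ncol(x) == 3)
  local <- sweep(x, 2, su$com)
  .contains_local(su, local)
}

#' Sample uniform points inside a subunit
#'
#' Draws `n` points uniformly distributed over the subunit volume by
#' rejection sampling from its axis-aligned bounding box, then shifts them by
#' the subunit's center of mass. Uses the current R random-number stream, so
#' `set.seed()` makes the draw reproducible.
#'
#' @param su A [subunit()].
#' @param n Number of points (>= 1).
#' @return An n x 3 matrix of coordinates in Angstrom (global frame).
#' @examples
#' set.seed(1)
#' x <- sample_subunit(subunit("sphere", 50), 100)
#' all(sqrt(rowSums(x^2)) <= 50)
#' @export
sample_subunit <- function(su, n) {
  stopifnot(inherits(su, "subunit"), n >= 1)
  n <- as.integer(n)
  half <- .subunit_bbox(su)
  box_vol <- prod(2 * half)
  accept_frac <- subunit_volume(su) / box_vol
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    need <- n - nrow(out)
    # draw a batch sized for the expected acceptance rate plus slack
    m <- max(64L, ceiling(need / accept_frac * 1.2))
    cand <- cbind(stats::runif(m, -half[1], half[1]),
                  stats::runif(m, -half[2], half[2]),
                  stats::runif(m, -half[3], half[3]))
    keep <- .contains_local(su, cand)
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  sweep(out, 2, su$com, "+")
}
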