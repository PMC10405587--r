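#' Particle model specification
#'
#' Bundles an ordered list of subunits into a particle definition. The order
#' matters when `exclude_overlap = TRUE`: points belonging to a later subunit
#' that fall inside an earlier subunit are deleted, so earlier subunits take
#' precedence in overlap regions. This is how multi-contrast particles such
#' as core-shell bodies are built from overlapping primitives.
#'
#' @param subunits A [subunit()] or list of subunits (1 or more), in order of
#'   precedence.
#' @param n_points Total number of scatterer points `N` distributed over all
#'   subunits in proportion to their volumes (default 3000; >= 100).
#' @param exclude_overlap Delete points of later subunits inside earlier
#'   ones (default TRUE).
#' @return An object of class `"model_spec"`.
#' @examples
#' # 30 A core (dSLD -1) inside a 50 A sphere (dSLD +1) -> core-shell particle
#' model_spec(list(
#'   subunit("sphere", 30, delta_sld = -1),
#'   subunit("sphere", 50, delta_sld = +1)
#' ))
#' @export
model_spec <- function(subunits, n_points = 3000, exclude_overlap = TRUE) {
  if (inherits(subunits, "subunit")) subunits <- list(subunits)
  if (!length(subunits) || !all(vapply(subunits, inherits, TRUE, "subunit"))) {
    stop("'subunits' must be a non-empty list of subunit objects", call. = FALSE)
  }
  n_points <- as.integer(n_points)
  if (n_points < 100L) stop("'n_points' must be at least 100", call. = FALSE)
  structure(list(subunits = subunits, n_points = n_points,
                 exclude_overlap = isTRUE(exclude_overlap)),
            class = "model_spec")
}

#' Build the weighted point cloud of a particle
#'
#' Samples the particle as a cloud of point scatterers at constant point
#' density: subunit `i` with volume `V_i` receives `n_i ~ N V_i / sum(V)`
#' points (largest-remainder rounding so the total is exactly `N`). Each
#' point carries an excess scattering length `db = dSLD_i * V_eff`, where the
#' effective volume of one scatterer is `V_eff = sum(V_i) / N`, identical for
#' all points. With `exclude_overlap`, points of a later subunit inside an
#' earlier one are deleted (not resampled), which keeps the density exactly
#' uniform in the surviving region; the effective volume is computed before
#' deletion so the per-point weight is unaffected.
#'
#' @param spec A [model_spec()].
#' @return An object of class `"point_model"` with elements `coords`
#'   (n x 3 matrix, Angstrom), `weights` (excess scattering lengths),
#'   `subunit_id` (integer owner of each point), `effective_volume` (A^3),
#'   `total_volume` (`V_p`, sum of subunit volumes, A^3), and `spec`.
#' @examples
#' set.seed(7)
#' m <- build_point_model(model_spec(subunit("sphere", 50), n_points = 500))
#' nrow(m$coords)
#' @export
build_point_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  vols <- vapply(spec$subunits, subunit_volume, numeric(1))
  v_tot <- sum(vols)
  n_alloc <- .largest_remainder(spec$n_points * vols / v_tot, spec$n_points)
  v_eff <- v_tot / spec$n_points

  coords <- vector("list", length(spec$subunits))
  keep <- vector("list", length(spec$subunits))
  for (i in seq_along(spec$subunits)) {
    if (n_alloc[i] == 0L) {
      coords[[i]] <- matrix(numeric(0), 0, 3)
      keep[[i]] <- logical(0)
      next
    }
    x <- sample_subunit(spec$subunits[[i]], n_alloc[i])
    k <- rep(TRUE, nrow(x))
    if (spec$exclude_overlap && i > 1L) {
      for (j in seq_len(i - 1L)) {
        k <- k & !contains(spec$subunits[[j]], x)
      }
    }
    coords[[i]] <- x
    keep[[i]] <- k
  }
  id <- rep(seq_along(spec$subunits), vapply(coords, nrow, integer(1)))
  coords <- do.call(rbind, coords)
  keep <- unlist(keep)
  coords <- coords[keep, , drop = FALSE]
  id <- id[keep]
  if (nrow(coords) == 0L) {
    stop("all points were deleted by overlap exclusion; empty model", call. = FALSE)
  }
  dsld <- vapply(spec$subunits, `[[`, numeric(1), "delta_sld")
  structure(list(coords = coords,
                 weights = dsld[id] * v_eff,
                 subunit_id = id,
                 effective_volume = v_eff,
                 total_volume = v_tot,
                 spec = spec),
            class = "point_model")
}

# Round positive reals to integers summing to 'total' (largest remainder).
.largest_remainder <- function(x, total) {
  fl <- floor(x)
  rem <- as.integer(total) - as.integer(sum(fl))
  out <- as.integer(fl)
  if (rem > 0L) {
    ord <- order(x - fl, decreasing = TRUE)
    out[ord[seq_len(rem)]] <- out[ord[seq_len(rem)]] + 1L
  }
  out
}

#' @export
print.point_model <- function(x, ...) {
  cat(sprintf(
    "<point_model> %d points, %d subunit(s), V_p = %.4g A^3, V_eff = %.4g A^3\n",
    nrow(x$coords), length(x$spec$subunits), x$total_volume,
    x$effective_volume))
  invisible(x)
}

#' Write a point model as a pseudo-atom PDB file
#'
#' One carbon pseudo-atom per point, fixed-column ATOM records, coordinates
#' in Angstrom, occupancy 1.00 and B-factor 0.00. The file loads in standard
#' structure viewers for 3D inspection of the bead model. PDB serial numbers
#' are limited to five digits, so models above 99999 points are rejected.
#'
#' @param model A [build_point_model()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "point_model"))
  n <- nrow(model$coords)
  if (n == 0L) stop("cannot write an empty point model", call. = FALSE)
  if (n > 99999L) {
    stop("PDB serial numbers overflow above 99999 points; reduce n_points",
         call. = FALSE)
  }
  xyz <- model$coords
  if (any(abs(xyz) >= 10000)) {
    stop("coordinates exceed PDB fixed-column range (|x| < 10000 A)", call. = FALSE)
  }
  lines <- sprintf(
    "ATOM  %5d  C   BEA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), ((seq_len(n) - 1L) %% 9999L) + 1L,
    xyz[, 1], xyz[, 2], xyz[, 3])
  writeLines(c("REMARK   generated by sasbead: bead model, one pseudo-atom per point",
               lines, "END"), path)
  invisible(path)
}
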