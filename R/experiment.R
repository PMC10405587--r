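#' Virtual-experiment parameters
#'
#' Parameters controlling how a normalized intensity becomes a realistic
#' noisy dataset.
#'
#' @param eta Volume fraction of particles (concentration proxy, unitless,
#'   strictly positive; default 0.01, a dilute sample).
#' @param exposure Relative exposure time; 1 corresponds to a typical
#'   synchrotron SAXS exposure, ~0.1 mimics a laboratory source.
#' @param sigma_rough Interface roughness in Angstrom (>= 0; default 0).
#' @param noise_scale Overall multiplier on the simulated errors (default 1).
#' @param noise_c,noise_k Constants of the empirical variance model
#'   `sigma^2(q) = noise_scale^2 (I(q) + c) / (k q exposure)`; defaults
#'   c = 0.85, k = 4500 in the package's arbitrary intensity units, chosen
#'   so the error profile resembles a typical synchrotron SAXS curve at
#'   ~1 mg/ml protein-like contrast.
#' @return An object of class `"experiment_params"`.
#' @export
experiment_params <- function(eta = 0.01, exposure = 1, sigma_rough = 0,
                              noise_scale = 1, noise_c = 0.85,
                              noise_k = 4500) {
  stopifnot(eta > 0, exposure > 0, sigma_rough >= 0, noise_scale > 0,
            noise_c >= 0, noise_k > 0)
  structure(list(eta = eta, exposure = exposure, sigma_rough = sigma_rough,
                 noise_scale = noise_scale, noise_c = noise_c,
                 noise_k = noise_k),
            class = "experiment_params")
}

#' Interface-roughness smearing
#'
#' Damps the intensity by `exp(-(q sigma_rough)^2)` (equivalently an
#' amplitude factor `exp(-(q sigma)^2 / 2)`), emulating soft interfaces
#' between subunits of different contrast instead of the model's sharp
#' boundaries. Only the intensity is smeared; p(r) is untouched.
#'
#' @param curve A [scattering_curve()].
#' @param sigma_rough Roughness in Angstrom (>= 0; 0 is the identity).
#' @return A damped [scattering_curve()].
#' @export
apply_roughness <- function(curve, sigma_rough) {
  stopifnot(inherits(curve, "scattering_curve"), sigma_rough >= 0)
  scattering_curve(curve$q,
                   curve$intensity * exp(-(curve$q * sigma_rough)^2))
}

#' Forward scattering of a bead model
#'
#' Zero-angle intensity in the package's arbitrary units:
#' `I(0) = eta (sum_j db_j)^2 / V_p`, which scales linearly with volume
#' fraction and quadratically with contrast; for a uniform-contrast
#' particle it reduces to `eta dSLD^2 V_p`, i.e. proportional to particle
#' volume.
#'
#' @param model A [build_point_model()] result.
#' @param params An [experiment_params()] (only `eta` is used).
#' @return `I(0)` (arbitrary units, >= 0).
#' @export
forward_scattering <- function(model, params = experiment_params()) {
  stopifnot(inherits(model, "point_model"), model$total_volume > 0)
  params$eta * sum(model$weights)^2 / model$total_volume
}

#' Empirical SAXS error model
#'
#' One-sigma errors for a scaled intensity, from the empirical variance
#' model `sigma^2(q) = noise_scale^2 (I(q) + c) / (k q exposure)`
#' calibrated on synchrotron SAXS noise profiles: variance proportional to
#' intensity plus a constant background floor, decreasing with q (more
#' pixels per q bin at wider angle) and with exposure time as 1/t, so
#' `sigma` scales exactly as `1/sqrt(exposure)`.
#'
#' @param q Momentum transfer, 1/A, strictly positive.
#' @param i_scaled Scaled intensity `I(q) = I(0) I_norm(q)` on `q`,
#'   non-negative.
#' @param params An [experiment_params()].
#' @return `sigma(q) > 0`, same length as `q`.
#' @export
simulate_errors <- function(q, i_scaled, params = experiment_params()) {
  if (any(q <= 0)) stop("q must be strictly positive", call. = FALSE)
  stopifnot(length(q) == length(i_scaled), all(i_scaled >= 0))
  params$noise_scale *
    sqrt((i_scaled + params$noise_c) / (params$noise_k * q * params$exposure))
}

#' Draw a noisy dataset
#'
#' Samples each point independently from a normal distribution with mean
#' `i_scaled[k]` and standard deviation `sigma[k]`. Negative draws are
#' kept: real buffer-subtracted SAS data can be negative. Uses the current
#' R random-number stream.
#'
#' @param q Momentum transfer, 1/A.
#' @param i_scaled Noise-free scaled intensity.
#' @param sigma One-sigma errors (> 0).
#' @return An object of class `"sas_dataset"`: a data frame with columns
#'   `q`, `i_sim`, `sigma`.
#' @export
sample_dataset <- function(q, i_scaled, sigma) {
  stopifnot(length(q) == length(i_scaled), length(q) == length(sigma),
            all(sigma >= 0))
  out <- data.frame(q = q,
                    i_sim = stats::rnorm(length(q), i_scaled, sigma),
                    sigma = sigma)
  class(out) <- c("sas_dataset", "data.frame")
  out
}

#' Full virtual experiment for one bead model
#'
#' Convenience pipeline: normalized (optionally polydisperse) intensity,
#' optional structure factor with decoupling, roughness smearing, forward
#' scattering, empirical errors, and a stochastic draw.
#'
#' @param model A [build_point_model()] result.
#' @param q Momentum-transfer grid (default [default_q_grid()]).
#' @param params An [experiment_params()].
#' @param sigma_s Gaussian size polydispersity (default 0).
#' @param sf Optional structure factor: `NULL`, or a list
#'   `list(type = "hard_sphere", r_hs =, eta =)` or
#'   `list(type = "fractal", frac =, n_agg =, r_eff =)`. The decoupling
#'   approximation is always applied.
#' @param n_bins Histogram bins (default 200).
#' @return A list: `dataset` ([sample_dataset()] result), `curve`
#'   (normalized intensity incl. structure factor and roughness), `pr`
#'   (normalized p(r) of the non-interacting particle), `i0` (forward
#'   scattering), `rg`, `d_max`, `s_eff` (effective structure factor or
#'   NULL), `hist`.
#' @export
simulate_experiment <- function(model, q = default_q_grid(),
                                params = experiment_params(), sigma_s = 0,
                                sf = NULL, n_bins = 200) {
  pd <- polydisperse_intensity(model, q, sigma_s = sigma_s, n_bins = n_bins)
  curve <- pd$curve
  s_eff <- NULL
  if (!is.null(sf)) {
    sq <- switch(sf$type,
      hard_sphere = hard_sphere_sq(q, sf$r_hs, sf$eta),
      fractal = fractal_sq(q, sf$frac, sf$n_agg, sf$r_eff),
      stop("unknown structure factor type: ", sf$type, call. = FALSE))
    beta <- decoupling_beta(model, q, n_bins = n_bins)
    curve <- apply_structure_factor(curve, sq, beta)
    s_eff <- attr(curve, "s_eff")
  }
  curve <- apply_roughness(curve, params$sigma_rough)
  i0 <- forward_scattering(model, params)
  i_scaled <- i0 * pmax(curve$intensity, 0)
  sigma <- simulate_errors(q, i_scaled, params)
  rg <- tryCatch(radius_of_gyration(pd$hist), error = function(e) NA_real_)
  list(dataset = sample_dataset(q, i_scaled, sigma),
       curve = curve, pr = pd$pr, i0 = i0, rg = rg,
       d_max = pd$hist$d_max, s_eff = s_eff, hist = pd$hist)
}

#' Read and write three-column SAS data files
#'
#' Whitespace-separated `q, I, sigma` text with `#` comment headers: the
#' de facto `.dat` format read by standard SAS fitting tools.
#'
#' @param dataset A [sample_dataset()] result.
#' @param path File path.
#' @param header Character vector of comment lines to prepend (without the
#'   leading `#`).
#' @return `path` invisibly (writer); a `sas_dataset` (reader).
#' @export
write_sas_dat <- function(dataset, path, header = character()) {
  stopifnot(inherits(dataset, "sas_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste("#", header), con)
  writeLines("# q [1/A]  I_sim [a.u.]  sigma [a.u.]", con)
  writeLines(sprintf("%.8e %.8e %.8e", dataset$q, dataset$i_sim,
                     dataset$sigma), con)
  invisible(path)
}

#' @rdname write_sas_dat
#' @export
read_sas_dat <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("q", "i_sim", "sigma"))
  out <- data.frame(q = tab$q, i_sim = tab$i_sim, sigma = tab$sigma)
  class(out) <- c("sas_dataset", "data.frame")
  out
}
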