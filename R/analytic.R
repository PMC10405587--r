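#' Analytic form-factor models
#'
#' Closed-form (orientation-averaged) scattering models used to validate
#' the Monte Carlo bead models and to fit simulated data. Supported kinds
#' and parameters (lengths in Angstrom, contrasts unitless; every kind also
#' accepts `scale`, default 1, and `background`, default 0):
#'
#' * `sphere`: `radius`
#' * `cylinder`: `radius`, `length`
#' * `ellipsoid_of_revolution`: `r_equatorial`, `r_polar`
#' * `core_shell_cylinder`: `r_core`, `l_core`, `t_shell` (shell of uniform
#'   thickness on the sides and both end caps), `sld_core`, `sld_shell`
#'   (solvent at 0)
#'
#' The intensity is normalized so the q -> 0 limit equals
#' `scale + background`. Cylindrical kinds are orientation averaged by
#' 64-point Gauss-Legendre quadrature over the cosine of the angle between
#' the symmetry axis and q.
#'
#' @param kind Model kind, see above.
#' @param params Named list/vector of parameters.
#' @return An object of class `"analytic_model"`.
#' @export
analytic_model <- function(kind, params) {
  kind <- match.arg(kind, c("sphere", "cylinder", "ellipsoid_of_revolution",
                            "core_shell_cylinder"))
  params <- as.list(params)
  need <- .analytic_params[[kind]]
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    stop(sprintf("analytic model '%s' needs parameter(s): %s", kind,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (is.null(params$scale)) params$scale <- 1
  if (is.null(params$background)) params$background <- 0
  geom <- setdiff(need, c("sld_core", "sld_shell"))
  if (any(unlist(params[geom]) <= 0)) {
    stop("geometric parameters must be positive", call. = FALSE)
  }
  structure(list(kind = kind, params = params), class = "analytic_model")
}

.analytic_params <- list(
  sphere = "radius",
  cylinder = c("radius", "length"),
  ellipsoid_of_revolution = c("r_equatorial", "r_polar"),
  core_shell_cylinder = c("r_core", "l_core", "t_shell", "sld_core",
                          "sld_shell")
)

# sphere amplitude 3(sin x - x cos x)/x^3, stable near 0
.sphere_amp <- function(x) {
  out <- rep(1, length(x))
  big <- abs(x) >= 1e-3
  xb <- x[big]
  out[big] <- 3 * (sin(xb) - xb * cos(xb)) / xb^3
  sm <- !big
  out[sm] <- 1 - x[sm]^2 / 10
  out
}

# 2 J1(x)/x, stable near 0
.lambda_j1 <- function(x) {
  out <- rep(1, length(x))
  big <- abs(x) >= 1e-5
  out[big] <- 2 * besselJ(x[big], 1) / x[big]
  out
}

# 64-point Gauss-Legendre nodes/weights on [0, 1] for the orientation
# average over u = cos(alpha); cached at load time.
.gl64 <- local({
  gl <- NULL
  function() {
    if (is.null(gl)) gl <<- pracma::gaussLegendre(64, 0, 1)
    gl
  }
})

#' Evaluate an analytic model
#'
#' @param m An [analytic_model()].
#' @param q Momentum transfer, 1/A.
#' @return Intensity vector, `scale * P(q) + background` with `P(0) = 1`.
#' @export
analytic_intensity <- function(m, q) {
  stopifnot(inherits(m, "analytic_model"), all(q > 0))
  p <- m$params
  pq <- switch(m$kind,
    sphere = .sphere_amp(q * p$radius)^2,
    cylinder = .orient_avg(q, function(q, u, s) {
      .sinc(q * p$length * u / 2) * .lambda_j1(q * p$radius * s)
    }),
    ellipsoid_of_revolution = .orient_avg(q, function(q, u, s) {
      .sphere_amp(q * sqrt(p$r_equatorial^2 * s^2 + p$r_polar^2 * u^2))
    }),
    core_shell_cylinder = {
      v_core <- pi * p$r_core^2 * p$l_core
      v_tot <- pi * (p$r_core + p$t_shell)^2 * (p$l_core + 2 * p$t_shell)
      f0 <- (p$sld_core - p$sld_shell) * v_core + p$sld_shell * v_tot
      if (abs(f0) < 1e-12 * (abs(p$sld_core) + abs(p$sld_shell)) * v_tot) {
        stop("core-shell cylinder has zero forward amplitude; cannot normalize",
             call. = FALSE)
      }
      raw <- .orient_avg(q, function(q, u, s) {
        ((p$sld_core - p$sld_shell) * v_core *
           .sinc(q * p$l_core * u / 2) * .lambda_j1(q * p$r_core * s) +
         p$sld_shell * v_tot *
           .sinc(q * (p$l_core / 2 + p$t_shell) * u) *
           .lambda_j1(q * (p$r_core + p$t_shell) * s)) / f0
      })
      raw
    })
  p$scale * pq + p$background
}

# orientation average of amp(q, u, sqrt(1-u^2))^2 over u in [0, 1]
.orient_avg <- function(q, amp) {
  gl <- .gl64()
  out <- numeric(length(q))
  for (i in seq_along(gl$x)) {
    u <- gl$x[i]
    a <- amp(q, u, sqrt(1 - u^2))
    out <- out + gl$w[i] * a^2
  }
  out
}

#' Weighted least-squares fit of an analytic model to a dataset
#'
#' Minimizes `sum(((i_sim - I_model(q)) / sigma)^2)` with the
#' Levenberg-Marquardt algorithm ([minpack.lm::nls.lm]), with positivity
#' bounds on geometric parameters and a small multi-start (jittered
#' restarts) to escape the shallow local minima that contrast-degenerate
#' models can exhibit. Any parameter named in `fixed` is held at the given
#' value; `scale` and `background` are free unless fixed explicitly.
#' Standard errors are square roots of the diagonal of the local covariance
#' `(J' J)^-1` of the sigma-weighted residuals (errors are taken at face
#' value, no chi-square rescaling).
#'
#' @param dataset A `sas_dataset` (columns `q`, `i_sim`, `sigma`).
#' @param kind Analytic model kind, see [analytic_model()].
#' @param start Named list of starting values for the free parameters
#'   (including `scale`/`background` if desired; they default to 1/0).
#' @param fixed Named list of parameters held fixed.
#' @param lower,upper Optional named bounds for free parameters; geometric
#'   parameters default to a lower bound of 1e-6.
#' @param n_starts Number of jittered starts (default 3).
#' @return An object of class `"sas_fit"`: `estimates`, `std_errors`,
#'   `chi2_reduced`, `converged`, `kind`, `fixed`, `n_obs`.
#' @export
fit_weighted <- function(dataset, kind, start, fixed = list(),
                         lower = NULL, upper = NULL, n_starts = 3) {
  stopifnot(inherits(dataset, "sas_dataset"), all(dataset$sigma > 0))
  start <- as.list(start)
  if (!("scale" %in% c(names(start), names(fixed)))) start$scale <- 1
  if (!("background" %in% c(names(start), names(fixed)))) start$background <- 0
  free <- names(start)
  if (nrow(dataset) < length(free) + 1) {
    stop("not enough data points for the number of free parameters",
         call. = FALSE)
  }
  geom <- setdiff(.analytic_params[[
    match.arg(kind, names(.analytic_params))]], c("sld_core", "sld_shell"))
  lo <- stats::setNames(rep(-Inf, length(free)), free)
  lo[free %in% c(geom, "scale")] <- 1e-6
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  hi <- stats::setNames(rep(Inf, length(free)), free)
  if (!is.null(upper)) hi[names(upper)] <- unlist(upper)

  resid_fn <- function(par) {
    pars <- c(as.list(par), fixed)
    m <- analytic_model(kind, pars)
    (dataset$i_sim - analytic_intensity(m, dataset$q)) / dataset$sigma
  }

  best <- NULL
  p0 <- unlist(start)
  set_jitter <- function(i) {
    if (i == 1) return(p0)
    j <- p0 * stats::runif(length(p0), 0.85, 1.15)
    pmin(pmax(j, lo + 1e-9), hi)
  }
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = set_jitter(i), lower = lo, upper = hi,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all fit attempts failed", call. = FALSE)

  est <- best$par
  # covariance of weighted residuals: (J'J)^-1
  jac <- .num_jacobian(resid_fn, est)
  se <- tryCatch(sqrt(diag(solve(crossprod(jac)))),
                 error = function(e) rep(NA_real_, length(est)))
  names(se) <- names(est)
  dof <- nrow(dataset) - length(est)
  structure(list(
    estimates = est,
    std_errors = se,
    chi2_reduced = best$deviance / dof,
    converged = best$info %in% 1:4,
    info = best$info,
    message = best$message,
    kind = kind,
    fixed = fixed,
    n_obs = nrow(dataset)
  ), class = "sas_fit")
}

.num_jacobian <- function(fn, par, rel = 1e-6) {
  f0 <- fn(par)
  jac <- matrix(NA_real_, length(f0), length(par))
  for (i in seq_along(par)) {
    h <- rel * max(abs(par[i]), 1e-4)
    pp <- par; pp[i] <- pp[i] + h
    pm <- par; pm[i] <- pm[i] - h
    jac[, i] <- (fn(pp) - fn(pm)) / (2 * h)
  }
  -jac
}

#' @export
print.sas_fit <- function(x, ...) {
  cat(sprintf("<sas_fit> %s, %d points, reduced chi^2 = %.3f%s\n",
              x$kind, x$n_obs, x$chi2_reduced,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- data.frame(estimate = x$estimates, std_error = x$std_errors)
  print(round(tab, 4))
  if (length(x$fixed)) {
    cat("fixed:", paste(names(x$fixed), unlist(x$fixed), sep = " = ",
                        collapse = ", "), "\n")
  }
  invisible(x)
}
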