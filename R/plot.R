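#' Plot simulation results for one or more models
#'
#' Base-graphics overview: log-log normalized intensity, linear p(r),
#' simulated data with error bars, and 2D projections of the first model's
#' point cloud onto the xy, xz and yz planes. Purely for inspection; the
#' numeric pipeline has no plotting dependency.
#'
#' @param results The list returned by [run_models()].
#' @param file Optional PNG path; if `NULL`, draws on the current device.
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_models <- function(results, file = NULL) {
  stopifnot(length(results) >= 1)
  if (!is.null(file)) {
    grDevices::png(file, width = 1600, height = 1100, res = 140)
    on.exit(grDevices::dev.off())
  }
  old <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  cols <- seq_along(results)

  rs <- lapply(results, `[[`, "result")
  graphics::plot(NA, xlim = range(rs[[1]]$curve$q),
                 ylim = range(unlist(lapply(rs, function(r)
                   pmax(r$curve$intensity, 1e-8)))),
                 log = "xy", xlab = "q [1/A]", ylab = "I_norm(q)",
                 main = "normalized intensity")
  for (i in cols) graphics::lines(rs[[i]]$curve$q,
                                  pmax(rs[[i]]$curve$intensity, 1e-8),
                                  col = i)
  graphics::legend("bottomleft", legend = vapply(results, `[[`, "", "name"),
                   col = cols, lty = 1, bty = "n", cex = 0.8)

  graphics::plot(NA, xlim = c(0, max(unlist(lapply(rs, function(r) max(r$pr$r))))),
                 ylim = range(unlist(lapply(rs, function(r) r$pr$p))),
                 xlab = "r [A]", ylab = "p(r)", main = "pair distance distribution")
  for (i in cols) graphics::lines(rs[[i]]$pr$r, rs[[i]]$pr$p, col = i)

  d <- rs[[1]]$dataset
  graphics::plot(d$q, pmax(d$i_sim, 1e-10), log = "xy", pch = 16, cex = 0.3,
                 xlab = "q [1/A]", ylab = "I_sim(q)",
                 main = sprintf("simulated data (%s)", results[[1]]$name))
  graphics::segments(d$q, pmax(d$i_sim - d$sigma, 1e-10),
                     d$q, d$i_sim + d$sigma, col = "grey60")

  coords <- NULL
  # projections need the coords; rebuild cheaply from stored result if present
  proj <- function(a, b, lab) {
    graphics::plot(a, b, pch = 16, cex = 0.2, asp = 1, xlab = lab[1],
                   ylab = lab[2], main = paste(lab, collapse = ""))
  }
  if (!is.null(results[[1]]$coords)) coords <- results[[1]]$coords
  if (is.null(coords) && !is.null(rs[[1]]$model)) coords <- rs[[1]]$model$coords
  if (!is.null(coords)) {
    proj(coords[, 1], coords[, 2], c("x", "y"))
    proj(coords[, 1], coords[, 3], c("x", "z"))
    proj(coords[, 2], coords[, 3], c("y", "z"))
  }
  invisible(file)
}
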