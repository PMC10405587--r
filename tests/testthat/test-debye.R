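# helper: wrap bare coordinates/weights as a point_model
as_pm <- function(coords, weights) {
  structure(list(coords = coords, weights = weights,
                 effective_volume = 1, total_volume = 1),
            class = "point_model")
}

test_that("a single pair lands in one bin with the product weight", {
  m <- as_pm(rbind(c(0, 0, 0), c(0, 0, 10)), c(1, 1))
  h <- pair_histogram(m, 10)
  expect_equal(h$d_max, 10)
  expect_equal(sum(h$p_values != 0), 1)
  expect_equal(sum(h$p_values), 1)
  expect_equal(h$sum_w2, 2)  # self terms tracked but never binned
  expect_error(pair_histogram(as_pm(rbind(c(0, 0, 0)), 1)), "2 points")
})

test_that("two-point model reproduces the single-pair Debye curve", {
  d <- 25
  m <- as_pm(rbind(c(0, 0, 0), c(0, 0, d)), c(1, 1))
  h <- pair_histogram(m, 1000)
  q <- default_q_grid(1e-3, 0.5, 50)
  cv <- intensity_from_histogram(h, q)
  # bin-center discretization only: generous but tight-in-shape tolerance
  expect_equal(cv$intensity, sin(q * d) / (q * d), tolerance = 1e-3)
  expect_equal(radius_of_gyration(h), d / 2, tolerance = 1e-3)
})

test_that("sphere histogram matches the analytic p(r) and R_g", {
  set.seed(21)
  m <- build_point_model(model_spec(subunit("sphere", 50), n_points = 5000))
  h <- pair_histogram(m, 200)
  pr <- p_of_r(h)
  expect_equal(pr$p[1], 0)
  expect_equal(pr$r[1], 0)
  expect_equal(max(pr$p), 1)
  ref <- sphere_pr(pr$r, 50)
  ref <- ref / max(ref)
  expect_lt(max(abs(pr$p - ref)), 0.02)           # < 2% of peak
  expect_lt(abs(h$d_max - 100), 1)                # support ends at 2R
  expect_equal(radius_of_gyration(h), sqrt(3 / 5) * 50, tolerance = 0.01)
})

test_that("thin hollow sphere approaches the shell limit R_g -> R", {
  set.seed(22)
  m <- build_point_model(model_spec(subunit("hollow_sphere", c(50, 49.5)),
                                    n_points = 3000))
  expect_equal(radius_of_gyration(pair_histogram(m)), 50, tolerance = 0.01)
})

test_that("core-shell contrast combination gives negative p(r) values", {
  # thick negative core: core-shell cross pairs outweigh same-sign pairs
  # in part of the r range
  set.seed(23)
  m <- build_point_model(model_spec(list(
    subunit("sphere", 40, delta_sld = -1),
    subunit("sphere", 50, delta_sld = +1)
  ), n_points = 3000))
  h <- pair_histogram(m)
  expect_true(any(h$p_values < 0))
})

test_that("p(r) is non-negative when all contrasts share one sign", {
  set.seed(24)
  for (spec in list(
    model_spec(subunit("cylinder", c(20, 100)), n_points = 500),
    model_spec(list(subunit("sphere", 30, delta_sld = 2),
                    subunit("sphere", 50, delta_sld = 0.5)), n_points = 500)
  )) {
    h <- pair_histogram(build_point_model(spec))
    expect_true(all(h$p_values >= 0))
  }
})

test_that("intensity is normalized to one at vanishing q", {
  set.seed(25)
  m <- build_point_model(model_spec(subunit("cuboid", c(20, 30, 50)),
                                    n_points = 1000))
  cv <- intensity_from_histogram(pair_histogram(m), 1e-6)
  expect_equal(cv$intensity, 1, tolerance = 1e-6)
})

test_that("histogram intensity agrees with the direct Debye double sum", {
  set.seed(26)
  for (spec in list(
    model_spec(subunit("sphere", 50), n_points = 500),
    model_spec(list(subunit("sphere", 30, delta_sld = -1),
                    subunit("sphere", 50, delta_sld = +1)), n_points = 400),
    model_spec(subunit("cylinder", c(20, 150)), n_points = 300)
  )) {
    m <- build_point_model(spec)
    h <- pair_histogram(m, 2000)   # fine bins: binning error below 0.5%
    q <- default_q_grid(1e-3, 49 / h$d_max, 40)  # q * d_max < 50
    cv <- intensity_from_histogram(h, q)
    ref <- debye_direct(m$coords, m$weights, q)
    expect_lt(max(abs(cv$intensity - ref) / pmax(abs(ref), 1e-3)), 0.005)
  }
})

test_that("rescaling all coordinates is exactly scale-equivariant", {
  set.seed(27)
  m <- build_point_model(model_spec(subunit("triaxial_ellipsoid",
                                            c(20, 30, 40)), n_points = 500))
  lam <- 2.5
  m2 <- m
  m2$coords <- m$coords * lam
  h1 <- pair_histogram(m, 150)
  h2 <- pair_histogram(m2, 150)
  q <- default_q_grid(1e-3, 0.3, 60)
  expect_equal(h2$d_max, lam * h1$d_max, tolerance = 1e-12)
  expect_equal(radius_of_gyration(h2), lam * radius_of_gyration(h1),
               tolerance = 1e-12)
  expect_equal(intensity_from_histogram(h2, q / lam)$intensity,
               intensity_from_histogram(h1, q)$intensity, tolerance = 1e-12)
})

test_that("R_g from the histogram matches the coordinate second moment", {
  set.seed(28)
  m <- build_point_model(model_spec(subunit("cylinder", c(20, 200)),
                                    n_points = 800))
  h <- pair_histogram(m, 200)
  com <- colMeans(m$coords)
  rg_direct <- sqrt(mean(rowSums(sweep(m$coords, 2, com)^2)))
  expect_equal(radius_of_gyration(h), rg_direct, tolerance = h$bin_width / 50)
})

test_that("zero polydispersity reduces exactly to the monodisperse result", {
  set.seed(29)
  m <- build_point_model(model_spec(subunit("sphere", 50), n_points = 500))
  q <- default_q_grid(1e-3, 0.3, 80)
  pd <- polydisperse_intensity(m, q, sigma_s = 0)
  h <- pair_histogram(m, 200)
  expect_identical(pd$curve$intensity,
                   intensity_from_histogram(h, q)$intensity)
  expect_identical(pd$pr, p_of_r(h))
  expect_error(polydisperse_intensity(m, q, sigma_s = 0.34), "1/3")
})

test_that("polydispersity fills in the sharp form-factor minima", {
  set.seed(30)
  m <- build_point_model(model_spec(subunit("sphere", 50), n_points = 3000))
  q_min1 <- 4.493 / 50
  mono <- intensity_from_histogram(pair_histogram(m), q_min1)$intensity
  poly <- polydisperse_intensity(m, q_min1, sigma_s = 0.1)$curve$intensity
  expect_gt(poly, mono)
  expect_gt(poly, 1e-3)   # minimum washed out well above the noise floor
})

test_that("polydispersity quadrature matches a brute-force ensemble", {
  set.seed(31)
  m <- build_point_model(model_spec(subunit("sphere", 50), n_points = 300))
  q <- default_q_grid(1e-3, 0.15, 30)
  sigma_s <- 0.05
  pd <- polydisperse_intensity(m, q, sigma_s = sigma_s)
  # brute force: explicitly rescaled point models, v_s^2-weighted average
  set.seed(32)
  s_draws <- rnorm(5000, 1, sigma_s)
  s_draws <- s_draws[abs(s_draws - 1) <= 3 * sigma_s][1:1500]
  acc <- 0
  for (s in s_draws) {
    ms <- m
    ms$coords <- m$coords * s
    ms$weights <- m$weights * s^3
    hs <- pair_histogram(ms, 200)
    acc <- acc + hs$sum_p * intensity_from_histogram(hs, q)$intensity
  }
  bf <- acc / sum(sapply(s_draws, function(s) s^6) * pair_histogram(m, 200)$sum_p)
  expect_lt(max(abs(pd$curve$intensity - bf) / pmax(bf, 5e-3)), 0.05)
})
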