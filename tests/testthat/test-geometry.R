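test_that("analytic subunit volumes match closed forms", {
  expect_equal(subunit_volume(subunit("sphere", 50)), 4 / 3 * pi * 50^3)
  expect_equal(subunit_volume(subunit("hollow_sphere", c(50, 30))),
               4 / 3 * pi * (50^3 - 30^3))
  expect_equal(subunit_volume(subunit("cylinder", c(20, 360))),
               pi * 20^2 * 360)
  expect_equal(subunit_volume(subunit("cube", 10)), 1000)
  expect_equal(subunit_volume(subunit("cuboid", c(10, 20, 30))), 6000)
  expect_equal(subunit_volume(subunit("triaxial_ellipsoid", c(10, 20, 30))),
               4 / 3 * pi * 6000)
  expect_equal(subunit_volume(subunit("cylindrical_ring", c(40, 20, 360))),
               pi * (40^2 - 20^2) * 360)
  expect_equal(subunit_volume(subunit("hollow_cube", c(10, 5))), 875)
})

test_that("subunit constructor enforces invariants", {
  expect_error(subunit("sphere", c(10, 20)), "1 dimension")
  expect_error(subunit("sphere", -5), "positive")
  expect_error(subunit("hollow_sphere", c(30, 50)), "inner")
  expect_error(subunit("banana", 1))
  expect_error(subunit("sphere", 10, com = c(1, 2)), "length-3")
})

test_that("containment is boundary-inclusive and respects cavities and com", {
  expect_true(contains(subunit("sphere", 50), c(0, 0, 50)))
  expect_false(contains(subunit("sphere", 50), c(0, 0, 50.001)))
  expect_false(contains(subunit("hollow_sphere", c(50, 30)), c(0, 0, 10)))
  expect_true(contains(subunit("hollow_sphere", c(50, 30)), c(0, 0, 40)))
  expect_true(contains(subunit("cuboid", c(10, 20, 30), com = c(100, 0, 0)),
                       c(104, 9, -14)))
  expect_false(contains(subunit("cuboid", c(10, 20, 30), com = c(100, 0, 0)),
                        c(104, 11, -14)))
  expect_false(contains(subunit("cylindrical_ring", c(40, 20, 360)),
                        c(0, 0, 0)))
})

test_that("sampled points lie inside their subunit and are uniform", {
  set.seed(101)
  for (su in list(subunit("sphere", 50),
                  subunit("cylinder", c(20, 400)),
                  subunit("hollow_sphere", c(50, 30)),
                  subunit("triaxial_ellipsoid", c(20, 30, 40)),
                  subunit("cylindrical_ring", c(40, 20, 100),
                          com = c(10, -5, 3)))) {
    x <- sample_subunit(su, 2000)
    expect_true(all(contains(su, x)), info = su$kind)
  }

  # uniform ball: E[r] = 3R/4; octant counts uniform by symmetry
  x <- sample_subunit(subunit("sphere", 50), 1e4)
  r <- sqrt(rowSums(x^2))
  expect_equal(mean(r), 37.5, tolerance = 0.01)
  oct <- table(paste(x[, 1] > 0, x[, 2] > 0, x[, 3] > 0))
  expect_gt(chisq.test(oct)$p.value, 0.01)
})

test_that("Monte Carlo volume from bounding-box acceptance matches analytic", {
  set.seed(77)
  su <- subunit("hollow_sphere", c(50, 30))
  n <- 2e4
  half <- rep(50, 3)
  cand <- matrix(runif(3 * n, -50, 50), ncol = 3)
  frac <- mean(contains(su, cand))
  v_mc <- frac * prod(2 * half)
  se <- sqrt(frac * (1 - frac) / n) * prod(2 * half)
  expect_lt(abs(v_mc - subunit_volume(su)), 3 * se)
})

test_that("points are allocated proportionally to subunit volumes", {
  set.seed(5)
  spec <- model_spec(list(
    subunit("sphere", 50, com = c(200, 0, 0)),
    subunit("sphere", 25, com = c(-200, 0, 0))
  ), n_points = 2700, exclude_overlap = TRUE)
  m <- build_point_model(spec)
  counts <- table(m$subunit_id)
  expect_equal(nrow(m$coords), 2700)   # disjoint: nothing deleted
  expect_equal(as.integer(counts[1]) / as.integer(counts[2]), 8,
               tolerance = 0.01)
  # constant point density across subunits (within rounding of one point)
  dens <- as.integer(counts) / sapply(spec$subunits, subunit_volume)
  expect_equal(dens[1], dens[2], tolerance = 2 / as.integer(counts[2]))
})

test_that("largest-remainder allocation always sums to N", {
  set.seed(8)
  for (i in 1:20) {
    v <- runif(sample(1:6, 1), 0.01, 1)
    n <- sample(100:5000, 1)
    alloc <- sasbead:::.largest_remainder(n * v / sum(v), n)
    expect_equal(sum(alloc), n)
    expect_true(all(alloc >= 0))
  }
})

test_that("overlap exclusion builds a core-shell particle", {
  set.seed(12)
  m <- build_point_model(model_spec(list(
    subunit("sphere", 30, delta_sld = -1),
    subunit("sphere", 50, delta_sld = +1)
  ), n_points = 3000))
  r <- sqrt(rowSums(m$coords^2))
  inner <- r <= 30
  expect_true(all(m$weights[inner] < 0))
  expect_true(all(m$weights[!inner] > 0))
  # every retained point is claimed by exactly one subunit
  expect_true(all(m$weights[m$subunit_id == 1] ==
                    -m$effective_volume))
  # shell points only outside the core
  expect_true(all(r[m$subunit_id == 2] > 30))
  # weight magnitude = |dSLD| * effective volume for all points
  expect_equal(unname(abs(m$weights)), rep(m$effective_volume, length(r)))
})

test_that("single-subunit model keeps exactly N points of equal weight", {
  set.seed(2)
  m <- build_point_model(model_spec(subunit("sphere", 50), n_points = 3000))
  expect_equal(nrow(m$coords), 3000)
  expect_equal(unique(m$weights), 4 / 3 * pi * 50^3 / 3000)
})

test_that("point models are reproducible under a fixed seed", {
  spec <- model_spec(list(subunit("sphere", 30, delta_sld = -1),
                          subunit("sphere", 50)), n_points = 1000)
  set.seed(99); m1 <- build_point_model(spec)
  set.seed(99); m2 <- build_point_model(spec)
  expect_identical(m1, m2)
})

test_that("PDB writer emits fixed-column ATOM records that round-trip", {
  set.seed(4)
  m <- build_point_model(model_spec(subunit("sphere", 20), n_points = 100))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, f)
  lines <- readLines(f)
  atoms <- grep("^ATOM", lines, value = TRUE)
  expect_length(atoms, 100)
  x <- as.numeric(substr(atoms, 31, 38))
  y <- as.numeric(substr(atoms, 39, 46))
  z <- as.numeric(substr(atoms, 47, 54))
  expect_equal(unname(cbind(x, y, z)), unname(m$coords), tolerance = 1e-3)

  m$coords <- m$coords[0, , drop = FALSE]
  expect_error(write_pdb(m, f), "empty")
  big <- list(coords = matrix(0, 1e5 + 1, 3))
  class(big) <- "point_model"
  expect_error(write_pdb(big, f), "99999")
})
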