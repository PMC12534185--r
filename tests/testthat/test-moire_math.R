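test_that("moire period reproduces the printed worked examples", {
  # graphene calibration and the gradient-seed faces, to printed precision
  expect_equal(round(moire_period(0.246, 1.1), 1), 12.8)
  expect_equal(round(moire_period(2.2, 2.8), 1), 45.0)
  expect_equal(round(moire_period(2.2, 13.7), 1), 9.2)
  expect_identical(moire_period(2.2, 0), Inf)
  expect_error(moire_period(-1, 5), "positive")
  expect_error(moire_period(2.2, 181), "\\[0, 180\\]")
})

test_that("twist inversion matches the printed values and is a true inverse", {
  expect_equal(round(twist_from_period(2.2, 45.0), 1), 2.8)
  expect_equal(round(twist_from_period(0.246, 12.8), 1), 1.1)
  th <- c(0.3, 1.1, 2.8, 5, 13.7, 45, 90, 179)
  expect_equal(twist_from_period(2.2, moire_period(2.2, th)), th)
  expect_error(twist_from_period(2.2, 1.0), "no real twist")
})

test_that("moire period is strictly decreasing in twist", {
  th <- seq(0.5, 180, by = 0.5)
  p <- moire_period(3.5, th)
  expect_true(all(diff(p) < 0))
  # small-angle helper agrees below 10 deg to ~0.2%
  expect_lt(max(abs(moire_period_small_angle(2.2, th[th < 10]) /
                    moire_period(2.2, th[th < 10]) - 1)), 0.002)
})

test_that("reciprocal-space duality holds for identical twisted layers", {
  for (a in c(2.2, 2.8)) for (th in c(1.1, 3.9, 8)) {
    rb <- reciprocal_basis(lattice_spec("square", a_sub = a))
    mr <- moire_reciprocal(rb, rb, th)
    expect_equal(mr$p_from_g, moire_period(a, th), tolerance = 1e-9)
  }
  # zero twist: all difference vectors vanish
  rb <- reciprocal_basis(lattice_spec("square", a_sub = 2.2))
  expect_true(is.na(moire_reciprocal(rb, rb, 0)$min_nonzero_g))
  # hexagonal duality carries the sqrt(3)/2 d/a factor
  hb <- reciprocal_basis(lattice_spec("honeycomb", a_sub = 3.5))
  mh <- moire_reciprocal(hb, hb, 5)
  expect_equal(1 / mh$min_nonzero_g,
               moire_period(3.5, 5) * sqrt(3) / 2, tolerance = 1e-9)
})

test_that("hybrid stack moire vectors match a brute-force difference set", {
  sq <- reciprocal_basis(lattice_spec("square", a_sub = 2.2))
  kg <- reciprocal_basis(lattice_spec("kagome", a_sub = 4.4))
  th <- 3.8
  mr <- moire_reciprocal(sq, kg, th)
  # independent oracle: plain rotation-matrix arithmetic over all +/- pairs
  g1 <- rbind(sq$g_vectors, -sq$g_vectors)
  g2 <- rotate_xy(rbind(kg$g_vectors, -kg$g_vectors), th)
  oracle <- c()
  for (i in seq_len(nrow(g1))) for (j in seq_len(nrow(g2)))
    oracle <- c(oracle, sqrt(sum((g1[i, ] - g2[j, ])^2)))
  expect_equal(sort(sqrt(rowSums(mr$g_m^2))), sort(oracle), tolerance = 1e-12)
  expect_equal(mr$min_nonzero_g, min(oracle[oracle > 1e-12]), tolerance = 1e-12)
})

test_that("gradient orientation field interpolates between the face twists", {
  spec <- orientation_field_spec(theta_b = 2.8, theta_a = 13.7,
                                 boundary_azimuth = 0)
  # tilted face a at the boundary azimuth; face b one full turn later
  expect_equal(gradient_orientation_field(spec, 0), 13.7)
  expect_equal(gradient_orientation_field(spec, 360 - 1e-9), 13.7,
               tolerance = 1e-6)
  expect_equal(gradient_orientation_field(spec, 1e-7), 2.8, tolerance = 1e-6)
  # monotone along the gradual direction, single jump at the boundary
  az <- seq(0.5, 359.5, by = 1)
  f <- gradient_orientation_field(spec, az)
  expect_true(all(diff(f) > 0))
  expect_equal(range(f), c(2.8, 13.7), tolerance = 0.05)
  # degenerate field: equal faces give a constant
  flat <- orientation_field_spec(theta_b = 4, theta_a = 4)
  expect_equal(gradient_orientation_field(flat, az), rep(4, length(az)))
})

test_that("local period map applies the exact relation pointwise", {
  spec <- orientation_field_spec(theta_b = 2.8, theta_a = 13.7)
  az <- seq(0.01, 359.9, length.out = 721)
  tw <- gradient_orientation_field(spec, az)
  p <- local_period_map(tw, 2.2)
  expect_equal(round(range(p), 1), c(9.2, 45.0), tolerance = 0.01)
  # strictly decreasing in local twist
  expect_true(all(diff(p[order(tw)]) < 0))
  # constant field maps to a constant, zero twist to the infinite sentinel
  expect_equal(local_period_map(matrix(4, 2, 2), 2.2),
               matrix(moire_period(2.2, 4), 2, 2))
  expect_identical(local_period_map(0, 2.2), Inf)
})
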