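full_grid <- function(nz, nx) matrix(TRUE, nz, nx)

test_that("capture patterns classify into the three cooperativity modes", {
  # all capture pairs present: fully cooperative, z-run spans the grid
  f <- classify_capture_pattern(capture_pattern(full_grid(4, 6), full_grid(4, 6)))
  expect_equal(f$mode, "fully")
  expect_equal(f$pair_count, 24L)
  expect_equal(f$max_z_run, 4L)
  # only capture-0 strands: no pairs, non-cooperative
  n <- classify_capture_pattern(capture_pattern(full_grid(4, 6),
                                                matrix(FALSE, 4, 6)))
  expect_equal(n$mode, "non_cooperative")
  expect_equal(n$pair_count, 0L)
  # checkerboard of pairs: partially cooperative with no vertical adjacency
  cb <- outer(1:4, 1:6, function(i, j) (i + j) %% 2 == 0)
  p <- classify_capture_pattern(capture_pattern(cb, full_grid(4, 6)))
  expect_equal(p$mode, "partially")
  expect_equal(p$max_z_run, 1L)
  # z-continuous partial pattern keeps a long vertical run
  col <- matrix(FALSE, 4, 6); col[, 2] <- TRUE
  pz <- classify_capture_pattern(capture_pattern(col, full_grid(4, 6)))
  expect_equal(pz$mode, "partially")
  expect_equal(pz$max_z_run, 4L)
  expect_error(capture_pattern(matrix(TRUE, 2, 2), matrix(TRUE, 3, 2)),
               "identical dimensions")
})

test_that("wetting factor has the closed-form anchors and is monotone", {
  expect_equal(wetting_factor(180), 1)
  expect_equal(wetting_factor(90), 0.5)
  expect_lt(wetting_factor(0.5), 1e-5)
  psi <- seq(1, 180, by = 1)
  expect_true(all(diff(wetting_factor(psi)) > 0))
  expect_error(wetting_factor(0), "\\(0, 180\\]")
})

test_that("capture mode maps onto the seeding-strength ordering", {
  f <- classify_capture_pattern(capture_pattern(full_grid(4, 4), full_grid(4, 4)))
  col <- matrix(FALSE, 4, 4); col[, 1] <- TRUE
  pz <- classify_capture_pattern(capture_pattern(col, full_grid(4, 4)))
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2 == 0)
  p1 <- classify_capture_pattern(capture_pattern(cb, full_grid(4, 4)))
  n <- classify_capture_pattern(capture_pattern(full_grid(4, 4),
                                                matrix(FALSE, 4, 4)))
  psi <- vapply(list(f, pz, p1, n), contact_angle_for_mode, 0)
  expect_equal(psi, c(30, 90, 180, 180))
  # smaller contact angle = stronger seeding = smaller barrier factor
  expect_true(all(diff(wetting_factor(unique(psi))) > 0))
})

test_that("homogeneous barrier follows the 2D disc closed form", {
  # gamma = 1, delta_h = 1 at nine-tenths of the absolute melting point:
  # dG* = pi / 0.1 = 10 pi
  Tm_K <- 273.15 / 0.9
  th <- tile_thermo(T_m_C = Tm_K - 273.15, delta_h = 1, gamma = 1)
  expect_equal(barrier_homo(0, th), 10 * pi)
  # infinite sentinel at and above the melting point
  expect_identical(barrier_homo(th$T_m_C, th), Inf)
  expect_identical(barrier_homo(th$T_m_C + 5, th), Inf)
  # strictly decreasing as T drops below T_m
  Ts <- seq(th$T_m_C - 1, th$T_m_C - 30, by = -1)
  expect_true(all(diff(barrier_homo(Ts, th)) < 0))
})

test_that("rate curves reproduce the wetting-regime phenomenology", {
  th <- tile_thermo(T_m_C = 45, delta_h = 1, gamma = 8,
                    A_homo = 1, A_het = 1, site_density_ratio = 1)
  Tg <- seq(20, 44, by = 0.5)
  # f = 1 with matched prefactors: the seed confers no advantage, R == 1
  r1 <- nucleation_rates(Tg, th, wetting_spec(f = 1))
  expect_equal(r1$R, rep(1, length(Tg)))
  # f < 1: R strictly increasing in T
  r_low <- nucleation_rates(Tg, th, wetting_spec(f = 0.9))
  r_high <- nucleation_rates(Tg, th, wetting_spec(f = 0.1))
  expect_true(all(diff(r_low$R) > 0))
  expect_true(all(diff(r_high$R) > 0))
  # high wetting dominates low wetting pointwise
  expect_true(all(r_high$R > r_low$R))
  # R peaks toward T_m while both absolute rates collapse there
  expect_equal(which.max(r_high$R), length(Tg))
  expect_lt(r_high$N_homo[length(Tg)], r_high$N_homo[1])
  expect_lt(r_high$N_hetero[length(Tg)], r_high$N_hetero[1])
  # heterogeneous barrier never exceeds the homogeneous one
  expect_true(all(r_high$N_hetero >= r_high$N_homo))
  expect_error(nucleation_rates(numeric(0), th, wetting_spec(f = 0.5)), "empty")
  expect_error(nucleation_rates(c(30, 46), th, wetting_spec(f = 0.5)), "T_m")
})

test_that("wetting spec demands exactly one parameterisation", {
  expect_error(wetting_spec(), "exactly one")
  expect_error(wetting_spec(psi_deg = 90, f = 0.5), "exactly one")
  expect_equal(wetting_spec(psi_deg = 180)$f, 1)
})
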