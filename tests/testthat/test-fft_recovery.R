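test_that("power spectrum is calibrated and concentrates energy correctly", {
  # uniform image: everything at DC, nothing elsewhere
  flat <- structure(matrix(1, 128, 128), pixel_size_nm = 1,
                    class = c("micrograph", "matrix", "array"))
  sp <- power_spectrum(flat, window = "none")
  expect_lt(max(sp$mag), 1e-8)   # DC itself is removed with the mean
  # pure cosine of period 8 px: one conjugate peak pair at 0.125 cycles/px
  x <- outer(rep(1, 128), cos(2 * pi * (0:127) / 8))
  cosim <- structure(x, pixel_size_nm = 1,
                     class = c("micrograph", "matrix", "array"))
  spc <- power_spectrum(cosim, window = "none")
  peak <- which(spc$mag == max(spc$mag), arr.ind = TRUE)
  g <- abs(spc$gx[peak[, 2]])
  expect_equal(unique(round(g, 6)), 0.125)
  expect_error(power_spectrum(matrix(0, 128, 128)), "calibration")
  tiny <- structure(matrix(0, 32, 32), pixel_size_nm = 1,
                    class = c("micrograph", "matrix", "array"))
  expect_error(power_spectrum(tiny), "64x64")
})

test_that("rendered monolayer peaks sit on the predicted reciprocal ring", {
  for (sym in c("square", "honeycomb")) {
    fx <- cached_fixture(paste0("mono512_", sym), function()
      make_fixture("monolayer", rng_seed = 3, symmetry = sym,
                   params = small_params()))
    spec <- attr(fx, "spec")
    a <- fx$truth$layers$a_sub_nm[1]
    g_pred <- sqrt(rowSums(reciprocal_basis(
      lattice_spec(sym, a_sub = a))$g_vectors^2))[1]
    sp <- power_spectrum(fx$image)
    pk <- detect_peaks(sp, min_snr = 5, annulus = c(0.7, 1.3) * g_pred)
    # strongest non-DC peaks within one frequency bin of the prediction
    expect_lt(abs(1 / pk$d_nm[1] - g_pred), sp$g_bin)
    # square: two merged first-order families 90 deg apart
    if (sym == "square") {
      top <- pk[pk$magnitude > 0.5 * max(pk$magnitude), ]
      expect_equal(nrow(top), 2)
      dang <- abs(diff(top$azimuth_deg)) %% 180
      expect_equal(min(dang, 180 - dang), 90, tolerance = 0.2)
    }
  }
})

test_that("noise-only spectra yield no peaks at high thresholds", {
  noise <- structure(matrix(withr::with_seed(1, rnorm(256^2)), 256),
                     pixel_size_nm = 0.5,
                     class = c("micrograph", "matrix", "array"))
  pk <- detect_peaks(power_spectrum(noise), min_snr = 30,
                     annulus = c(0.2, 0.8))
  expect_equal(nrow(pk), 0)
  expect_error(detect_peaks(power_spectrum(noise), annulus = c(0.5, 0.2)),
               "g_lo < g_hi")
})

test_that("bilayer twist and lattice constants are recovered", {
  fx <- cached_fixture("bi512", function()
    make_fixture("bilayer", rng_seed = 7, theta_deg = 5,
                 params = small_params()))
  rpt <- analyze_micrograph(fx$image, "square", a_sub_nm = 2.2)
  expect_false(rpt$monolayer)
  expect_lt(abs(rpt$twist_deg - 5), 0.3)
  expect_true(all(abs(rpt$layers$a_sub_nm / 2.2 - 1) < 0.03))
  # each family splits into two peaks ~5 deg apart in azimuth
  expect_equal(sort(rpt$layers$n_peaks), c(2, 2))
})

test_that("monolayers carry the twist-undefined flag", {
  fx <- cached_fixture("mono512_square", function()
    make_fixture("monolayer", rng_seed = 3, symmetry = "square",
                 params = small_params()))
  rpt <- analyze_micrograph(fx$image, "square", a_sub_nm = 2.2,
                            with_moire = FALSE)
  expect_true(rpt$monolayer)
  expect_true(is.na(rpt$twist_deg))
})

test_that("estimates are invariant to a global rotation of the scene", {
  prm <- small_params(rng_seed = 1)
  L <- prm$image_px * prm$pixel_size_nm
  reg <- c(0, L, 0, L); ctr <- c(L / 2, L / 2)
  sp <- lattice_spec("square", a_sub = 2.2)
  build <- function(base) {
    sets <- lapply(1:2, function(k)
      generate_lattice(sp, reg, orientation = base + c(0, 5)[k],
                       origin = ctr, layer_id = k))
    render_layers(sets, prm)
  }
  r0 <- analyze_micrograph(build(0), "square", a_sub_nm = 2.2, with_moire = FALSE)
  r7 <- analyze_micrograph(build(7), "square", a_sub_nm = 2.2, with_moire = FALSE)
  expect_lt(abs(r7$twist_deg - r0$twist_deg), 0.1)
  shift <- (r7$layers$orientation_deg[1] - r0$layers$orientation_deg[1]) %% 90
  expect_equal(shift, 7, tolerance = 0.2)
})

test_that("moire period estimation matches the closed form and flags theta = 0", {
  fx <- cached_fixture("bi512", function()
    make_fixture("bilayer", rng_seed = 7, theta_deg = 5,
                 params = small_params()))
  est <- estimate_moire_period(fx$image, "square", a_sub_nm = 2.2)
  expect_true(est$detected)
  expect_lt(abs(est$p_M_nm / moire_period(2.2, 5) - 1), 0.10)
  # coincident layers produce no moire peak: not-detected sentinel
  aligned <- make_fixture("bilayer", rng_seed = 9, theta_deg = 0,
                          params = small_params())
  est0 <- estimate_moire_period(aligned$image, "square", a_sub_nm = 2.2)
  expect_false(est0$detected)
  expect_true(is.na(est0$p_M_nm))
})

test_that("real/reciprocal duality links recovered period and twist", {
  fx <- cached_fixture("bi512", function()
    make_fixture("bilayer", rng_seed = 7, theta_deg = 5,
                 params = small_params()))
  rpt <- analyze_micrograph(fx$image, "square", a_sub_nm = 2.2)
  a_hat <- mean(rpt$layers$a_sub_nm)
  expect_lt(abs((1 / rpt$p_M_nm) /
                (2 * (1 / a_hat) * sin(rpt$twist_deg * pi / 360)) - 1), 0.10)
})

test_that("orientation maps are flat for uniform bilayers", {
  fx <- cached_fixture("bi1024", function()
    make_fixture("bilayer", rng_seed = 4, theta_deg = 5,
                 params = render_params(image_px = 1024)))
  fld <- orientation_map(fx$image, "square", a_sub_nm = 2.2,
                         window_px = 256, stride_px = 256)
  expect_true(all(fld$ok))
  expect_lt(max(fld$local_twist_deg) - min(fld$local_twist_deg), 0.5)
  expect_lt(abs(mean(fld$local_twist_deg) - 5), 0.3)
  expect_warning(orientation_map(fx$image, "square", 2.2, window_px = 256,
                                 stride_px = 512), "gaps")
})
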