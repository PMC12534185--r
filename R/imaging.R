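#' Rendering parameters for synthetic micrographs
#'
#' @param pixel_size_nm Pixel calibration, nm per pixel.
#' @param image_px Image side length in pixels (square images).
#' @param spot_sigma_nm Gaussian spot width (standard deviation) in nm.
#' @param layer_weights Optional intensity weight per rendered layer
#'   (recycled; default all 1).
#' @param gaussian_sd Additive Gaussian read-noise standard deviation as a
#'   fraction of the noise-free dynamic range (0 disables).
#' @param poisson_scale Shot-noise scale: expected counts at unit intensity
#'   (0 disables Poisson noise).
#' @param seed_disc Optional central seed disc, list `(radius_nm, intensity)`.
#' @param rng_seed Integer RNG seed (required when any noise is enabled).
#' @return An object of class `render_params`.
#' @export
render_params <- function(pixel_size_nm = 0.5, image_px = 1024,
                          spot_sigma_nm = 0.6, layer_weights = NULL,
                          gaussian_sd = 0.02, poisson_scale = 0,
                          seed_disc = NULL, rng_seed = NULL) {
  if (pixel_size_nm <= 0 || spot_sigma_nm <= 0 || image_px < 8)
    stop("invalid render parameters")
  structure(list(pixel_size_nm = pixel_size_nm, image_px = as.integer(image_px),
                 spot_sigma_nm = spot_sigma_nm, layer_weights = layer_weights,
                 gaussian_sd = gaussian_sd, poisson_scale = poisson_scale,
                 seed_disc = seed_disc, rng_seed = rng_seed),
            class = "render_params")
}

# stamp unit-integral Gaussian spots (sd sigma_px, truncated at 5 sigma) at
# continuous pixel positions (cy, cx) onto an n x n accumulator; exact per
# spot, so the spectrum carries no splat-aliasing ghosts
.stamp_gaussians <- function(n, cy, cx, sigma_px, weight = 1) {
  r <- ceiling(5 * sigma_px)
  i0 <- round(cy); j0 <- round(cx)
  norm <- weight / (2 * pi * sigma_px^2)
  img <- matrix(0, n, n)
  for (di in -r:r) {
    ii <- i0 + di
    wy <- exp(-(ii - cy)^2 / (2 * sigma_px^2))
    trips_i <- integer(0); trips_j <- integer(0); trips_w <- numeric(0)
    for (dj in -r:r) {
      jj <- j0 + dj
      w <- wy * exp(-(jj - cx)^2 / (2 * sigma_px^2))
      ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= n & w > 0
      trips_i <- c(trips_i, ii[ok]); trips_j <- c(trips_j, jj[ok])
      trips_w <- c(trips_w, w[ok])
    }
    if (length(trips_i))
      img <- img + as.matrix(Matrix::sparseMatrix(
        i = trips_i, j = trips_j, x = trips_w, dims = c(n, n)))
  }
  img * norm
}

#' Render point layers as a synthetic micrograph
#'
#' Each lattice point becomes an isotropic Gaussian spot of unit integrated
#' intensity (times its layer weight); layers are summed, an optional central
#' seed disc is added, then optional Poisson and Gaussian noise. The
#' noise-free rendering is strictly linear in the point sets. Points are
#' deposited by bilinear splatting and blurred with the exact Gaussian kernel
#' in the Fourier domain.
#'
#' The image covers `[0, image_px * pixel_size_nm]` in both axes; pixel
#' `(i, j)` (row = y, column = x) is centred at `((j - 0.5), (i - 0.5)) *
#' pixel_size_nm`.
#'
#' @param point_sets A `point_set` or list of them (coordinates in nm).
#' @param params A [render_params()]. Sampling must satisfy
#'   `pixel_size_nm <= a_sub / 4` for every layer that carries a spec.
#' @return A `micrograph`: numeric matrix with attributes `pixel_size_nm`.
#' @export
render_layers <- function(point_sets, params = render_params()) {
  stopifnot(inherits(params, "render_params"))
  if ((params$gaussian_sd > 0 || params$poisson_scale > 0) &&
      is.null(params$rng_seed))
    stop("rng_seed is required when noise is enabled")
  if (inherits(point_sets, "point_set")) point_sets <- list(point_sets)
  for (ps in point_sets) {
    spec <- attr(ps, "spec")
    if (!is.null(spec) && params$pixel_size_nm > spec$a_sub / 4)
      stop(sprintf(paste0("pixel size %.3g nm undersamples a_sub = %.3g nm; ",
                          "use pixel_size_nm <= %.3g"),
                   params$pixel_size_nm, spec$a_sub, spec$a_sub / 4))
  }
  n <- params$image_px
  px <- params$pixel_size_nm
  w <- params$layer_weights
  if (is.null(w)) w <- rep(1, length(point_sets))
  w <- rep_len(w, length(point_sets))
  img <- matrix(0, n, n)
  for (k in seq_along(point_sets)) {
    ps <- point_sets[[k]]
    if (nrow(ps) == 0) next
    cx <- ps$x_nm / px + 0.5   # continuous column index
    cy <- ps$y_nm / px + 0.5   # continuous row index
    keep <- cx >= 0 & cx <= n + 1 & cy >= 0 & cy <= n + 1
    cx <- cx[keep]; cy <- cy[keep]
    if (!length(cx)) next
    img <- img + .stamp_gaussians(n, cy, cx, params$spot_sigma_nm / px, w[k])
  }
  if (!is.null(params$seed_disc)) {
    ctr <- n / 2 + 0.5
    rr <- outer(((seq_len(n) - ctr) * px)^2, ((seq_len(n) - ctr) * px)^2, "+")
    img <- img + params$seed_disc$intensity * (rr <= params$seed_disc$radius_nm^2)
  }
  if (params$gaussian_sd > 0 || params$poisson_scale > 0) {
    img <- withr::with_seed(params$rng_seed, {
      out <- img
      if (params$poisson_scale > 0) {
        lam <- pmax(out, 0) * params$poisson_scale
        out <- matrix(stats::rpois(length(lam), lam), nrow(out)) / params$poisson_scale
      }
      if (params$gaussian_sd > 0) {
        rng <- max(out) - min(out)
        if (rng == 0) rng <- 1
        out <- out + stats::rnorm(length(out), sd = params$gaussian_sd * rng)
      }
      out
    })
  }
  structure(img, pixel_size_nm = px, class = c("micrograph", "matrix", "array"))
}

#' Swap a lattice spec between hydrated and dried constants
#'
#' Lattice constants measured on dried TEM grids are smaller than the
#' hydrated (cryo) values due to structural shrinkage upon drying; this swaps
#' a spec between the two printed presets (square 2.8 <-> 2.2, kagome
#' 5.4 <-> 4.4, honeycomb 4.4 <-> 3.5 nm).
#'
#' @param spec A [lattice_spec()].
#' @param preset Target preset, `"cryo"` or `"dried"`.
#' @return A [lattice_spec()] with the target preset's constant.
#' @export
shrinkage <- function(spec, preset = c("dried", "cryo")) {
  preset <- match.arg(preset)
  stopifnot(inherits(spec, "lattice_spec"))
  if (!spec$symmetry %in% names(.LATTICE_CONSTANTS[[preset]]))
    stop("unknown symmetry: ", spec$symmetry)
  if (identical(spec$hydration, preset)) return(spec)
  out <- spec
  out$a_sub <- unname(.LATTICE_CONSTANTS[[preset]][spec$symmetry])
  out$hydration <- preset
  out
}

#' Compose a standard fixture scene with ground truth
#'
#' Builds the stacked point sets for one of the standard scenarios, renders
#' them, and returns the image together with its exact ground-truth record.
#' Default scenes use dried (TEM-grid) lattice constants: square bilayer at
#' 3.9 deg, trilayer at 0/3.8/7.6 deg (the square-seed stack), hybrid
#' square 2.2 nm + kagome 4.4 nm at 3.8 deg, gradient square bilayer with
#' face twists 2.8 / 13.7 deg.
#'
#' @param scenario One of `"monolayer"`, `"bilayer"`, `"trilayer"`,
#'   `"hybrid"`, `"gradient"`.
#' @param rng_seed Integer RNG seed for the rendering noise.
#' @param symmetry Sublattice symmetry for the uniform scenarios.
#' @param a_sub Lattice constant override (nm); defaults to the dried preset.
#' @param theta_deg Twist override for `"bilayer"` (default 3.9).
#' @param field An [orientation_field_spec()] for `"gradient"` (default
#'   theta_b = 2.8, theta_a = 13.7, boundary at azimuth 0, clockwise).
#' @param params A [render_params()]; `rng_seed` is injected.
#' @return List with `image` (micrograph) and `truth` (list: `layers`
#'   data.frame, `twist_deg`, `expected_p_M_nm`, and for gradient scenes the
#'   field spec and endpoint periods).
#' @export
make_fixture <- function(scenario = c("monolayer", "bilayer", "trilayer",
                                      "hybrid", "gradient"),
                         rng_seed = 1L,
                         symmetry = "square", a_sub = NULL, theta_deg = NULL,
                         field = orientation_field_spec(theta_b = 2.8,
                                                        theta_a = 13.7),
                         params = render_params()) {
  scenario <- match.arg(scenario)
  params$rng_seed <- rng_seed
  L <- params$image_px * params$pixel_size_nm
  region <- c(0, L, 0, L)
  ctr <- c(L / 2, L / 2)
  spec <- lattice_spec(symmetry, a_sub = a_sub, hydration = "dried")

  orientations <- switch(scenario,
    monolayer = 0,
    bilayer   = c(0, theta_deg %||% 3.9),
    trilayer  = c(0, 3.8, 7.6),
    hybrid    = c(0, theta_deg %||% 3.8),
    gradient  = NULL)

  if (scenario == "gradient") {
    layer1 <- generate_lattice(spec, region, orientation = 0, origin = ctr,
                               layer_id = 1L)
    base2 <- generate_lattice(spec, region + c(-L, L, -L, L) * 0.25,
                              orientation = 0, origin = ctr, layer_id = 2L)
    az <- atan2(base2$y_nm - ctr[2], base2$x_nm - ctr[1]) * 180 / pi
    # rotating a point moves its azimuth, so the field must be evaluated at
    # the point's final azimuth: solve psi = az + field(psi) by fixed-point
    # iteration (the field slope is ~0.03 deg/deg, a strong contraction)
    psi <- az
    for (it in 1:30) psi <- az + gradient_orientation_field(field, psi)
    alpha <- psi - az
    rel <- cbind(base2$x_nm - ctr[1], base2$y_nm - ctr[2])
    a_rad <- alpha * pi / 180
    rot <- cbind(cos(a_rad) * rel[, 1] - sin(a_rad) * rel[, 2],
                 sin(a_rad) * rel[, 1] + cos(a_rad) * rel[, 2])
    layer2 <- data.frame(x_nm = rot[, 1] + ctr[1], y_nm = rot[, 2] + ctr[2],
                         layer_id = 2L)
    keep <- layer2$x_nm >= 0 & layer2$x_nm <= L & layer2$y_nm >= 0 & layer2$y_nm <= L
    layer2 <- layer2[keep, ]
    attr(layer2, "spec") <- spec
    class(layer2) <- c("point_set", class(layer2))
    sets <- list(layer1, layer2)
    truth <- list(
      scenario = scenario,
      layers = data.frame(layer = 1:2, symmetry = symmetry, a_sub_nm = spec$a_sub,
                          orientation_deg = c(0, NA)),
      field = field,
      twist_range_deg = sort(c(field$theta_b, field$theta_a)),
      expected_p_M_range_nm = sort(moire_period(
        spec$a_sub, c(field$theta_b, field$theta_a))))
  } else {
    specs <- rep(list(spec), length(orientations))
    if (scenario == "hybrid")
      specs[[2]] <- lattice_spec("kagome", hydration = "dried")
    sets <- lapply(seq_along(orientations), function(k)
      generate_lattice(specs[[k]], region, orientation = orientations[k],
                       origin = ctr, layer_id = k))
    twist <- if (length(orientations) >= 2) diff(orientations)[1] else NA_real_
    truth <- list(
      scenario = scenario,
      layers = data.frame(layer = seq_along(orientations),
                          symmetry = vapply(specs, function(s) s$symmetry, ""),
                          a_sub_nm = vapply(specs, function(s) s$a_sub, 0),
                          orientation_deg = orientations),
      twist_deg = twist,
      expected_p_M_nm = if (!is.na(twist) && scenario != "hybrid")
        moire_period(spec$a_sub, twist) else NA_real_)
  }
  list(image = render_layers(sets, params), truth = truth)
}

#' Write a micrograph as 16-bit grayscale TIFF (plus optional PNG preview)
#'
#' Intensities are scaled to the full 16-bit range; the pixel calibration is
#' stored in a JSON sidecar with the same basename.
#'
#' @param image A `micrograph`.
#' @param path Output `.tif` path.
#' @param png_preview Also write an 8-bit PNG preview next to it.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(image, path, png_preview = FALSE) {
  lo <- min(image); hi <- max(image)
  scaled <- if (hi > lo) (unclass(image) - lo) / (hi - lo) else unclass(image) * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 16)
  jsonlite::write_json(list(pixel_size_nm = attr(image, "pixel_size_nm")),
                       sub("\\.tiff?$", ".json", path, ignore.case = TRUE),
                       auto_unbox = TRUE, digits = NA)
  if (png_preview && requireNamespace("png", quietly = TRUE))
    png::writePNG(scaled, sub("\\.tiff?$", ".png", path, ignore.case = TRUE))
  invisible(path)
}

#' Read a micrograph written by [write_micrograph()]
#'
#' @param path TIFF path; pixel size is taken from the JSON sidecar unless
#'   given explicitly.
#' @param pixel_size_nm Optional pixel calibration override.
#' @return A `micrograph` matrix.
#' @export
read_micrograph <- function(path, pixel_size_nm = NULL) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  if (is.null(pixel_size_nm)) {
    sidecar <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
    if (file.exists(sidecar))
      pixel_size_nm <- jsonlite::read_json(sidecar)$pixel_size_nm
  }
  structure(img, pixel_size_nm = pixel_size_nm,
            class = c("micrograph", "matrix", "array"))
}
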