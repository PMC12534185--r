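#' Moire periodicity of two identical twisted lattices
#'
#' Exact relation `p_M = a_sub / (2 sin(theta / 2))` for two identical
#' sublattices of constant `a_sub` overlaid at twist `theta`. At `theta = 0`
#' the pattern is infinite and `Inf` is returned.
#'
#' @param a_sub Sublattice constant in nm (> 0). Vectorised.
#' @param theta_deg Twist angle in degrees, in `[0, 180]`. Vectorised.
#' @return Moire periodicity in nm (`Inf` where `theta_deg == 0`).
#' @seealso [twist_from_period()] for the inverse,
#'   [moire_period_small_angle()] for the small-angle approximation.
#' @export
moire_period <- function(a_sub, theta_deg) {
  if (any(a_sub <= 0)) stop("a_sub must be positive")
  if (any(theta_deg < 0 | theta_deg > 180)) stop("theta_deg must lie in [0, 180]")
  ifelse(theta_deg == 0, Inf, a_sub / (2 * sin(theta_deg * pi / 360)))
}

#' Small-angle approximation of the moire period
#'
#' `p_M ~ a_sub / theta` (theta in radians), accurate to ~0.1% below 10 deg.
#' Provided for comparison; all pipeline computations use the exact
#' [moire_period()].
#'
#' @inheritParams moire_period
#' @return Approximate moire periodicity in nm.
#' @export
moire_period_small_angle <- function(a_sub, theta_deg) {
  if (any(a_sub <= 0)) stop("a_sub must be positive")
  ifelse(theta_deg == 0, Inf, a_sub / (theta_deg * pi / 180))
}

#' Twist angle from an observed moire period
#'
#' Inverts the exact moire relation: `theta = 2 asin(a_sub / (2 p_M))`.
#'
#' @param a_sub Sublattice constant in nm (> 0).
#' @param p_M Moire periodicity in nm; must satisfy `p_M >= a_sub / 2`.
#' @return Twist angle in degrees.
#' @export
twist_from_period <- function(a_sub, p_M) {
  if (any(a_sub <= 0)) stop("a_sub must be positive")
  if (any(p_M < a_sub / 2))
    stop("p_M < a_sub/2 has no real twist solution")
  2 * asin(a_sub / (2 * p_M)) * 180 / pi
}

# rotate rows of a 2-column matrix by phi degrees (right-handed)
.rotate_rows <- function(m, phi_deg) {
  phi <- phi_deg * pi / 180
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  t(R %*% t(m))
}

#' Moire reciprocal vectors of a twisted stack
#'
#' All pairwise difference vectors `g1 - R(theta) g2` between the first-order
#' families of two layers (including sign partners). For identical layers the
#' smallest non-zero moire vector has `|g_m| = 2 |g| sin(theta/2)`, the
#' reciprocal-space dual of the moire period.
#'
#' @param layer1,layer2 `reciprocal_peaks` from [reciprocal_basis()].
#' @param theta_deg Twist of layer 2 relative to layer 1, degrees.
#' @return List with `g_m` (matrix of difference vectors, nm^-1),
#'   `min_nonzero_g` (nm^-1, NA if all vanish) and `p_from_g` = 1/min |g_m|.
#' @export
moire_reciprocal <- function(layer1, layer2, theta_deg) {
  stopifnot(inherits(layer1, "reciprocal_peaks"),
            inherits(layer2, "reciprocal_peaks"))
  g1 <- rbind(layer1$g_vectors, -layer1$g_vectors)
  g2 <- .rotate_rows(rbind(layer2$g_vectors, -layer2$g_vectors), theta_deg)
  diffs <- do.call(rbind, lapply(seq_len(nrow(g1)), function(i)
    t(t(-g2) + g1[i, ])))
  mag <- sqrt(rowSums(diffs^2))
  tol <- 1e-12 * max(mag, 1)
  if (any(mag <= tol)) {
    # some family pair coincides exactly: the moire fundamental is the zero
    # vector and the pattern period is infinite (aligned identical layers)
    return(list(g_m = diffs, min_nonzero_g = NA_real_, p_from_g = Inf))
  }
  min_g <- min(mag)
  list(g_m = diffs, min_nonzero_g = min_g, p_from_g = 1 / min_g)
}

#' Orientation-field specification of a gradient bilayer
#'
#' Describes the azimuthal variation of the local second-layer twist around a
#' gradient seed: the field runs from `theta_a` (tilted face) at
#' `boundary_azimuth` to `theta_b` (parallel face) after a full turn in the
#' gradual direction, with a single sharp discontinuity at the boundary.
#'
#' @param theta_b Twist at the non-tilted face b, degrees.
#' @param theta_a Twist at the tilted face a, degrees.
#' @param boundary_azimuth Azimuth of the discontinuity, degrees.
#' @param gradual_direction `"cw"` (clockwise, the default observed case) or
#'   `"ccw"`.
#' @return An object of class `orientation_field_spec`.
#' @export
orientation_field_spec <- function(theta_b, theta_a, boundary_azimuth = 0,
                                   gradual_direction = c("cw", "ccw")) {
  gradual_direction <- match.arg(gradual_direction)
  structure(list(theta_b = theta_b, theta_a = theta_a,
                 boundary_azimuth = boundary_azimuth,
                 gradual_direction = gradual_direction),
            class = "orientation_field_spec")
}

#' Local twist as a function of azimuth for a gradient bilayer
#'
#' Linear interpolation in azimuth from `theta_a` at the boundary azimuth to
#' `theta_b` one full turn later along the gradual direction; the jump
#' (magnitude `theta_a - theta_b`) sits at the boundary azimuth.
#'
#' @param spec An [orientation_field_spec()].
#' @param azimuth_deg Azimuths (degrees, any range; reduced mod 360).
#' @return Local twist in degrees, same length as `azimuth_deg`.
#' @export
gradient_orientation_field <- function(spec, azimuth_deg) {
  stopifnot(inherits(spec, "orientation_field_spec"))
  rel <- (azimuth_deg - spec$boundary_azimuth) %% 360
  u <- if (spec$gradual_direction == "cw") (360 - rel) %% 360 / 360 else rel / 360
  # u = 0 at the boundary (face a side), u -> 1 approaching it from the
  # gradual direction (face b side)
  spec$theta_a + (spec$theta_b - spec$theta_a) * u
}

#' Local moire-period map of an orientation field
#'
#' Pointwise application of the exact moire relation to a field of local
#' twists: larger local twist gives smaller local period; zero twist maps to
#' the infinite sentinel.
#'
#' @param local_twist_deg Field of local twists (any shape), degrees in
#'   `[0, 180]`.
#' @param a_sub Sublattice constant in nm.
#' @return Local `p_M` values of the same shape (nm, `Inf` at zero twist).
#' @export
local_period_map <- function(local_twist_deg, a_sub) {
  out <- moire_period(a_sub, c(local_twist_deg))
  if (!is.null(dim(local_twist_deg))) dim(out) <- dim(local_twist_deg)
  out
}

#' Write a moire prediction record as JSON
#'
#' @param a_sub,theta_deg Inputs to [moire_period()].
#' @param path Output path.
#' @return The record (list), invisibly.
#' @export
write_moire_record <- function(a_sub, theta_deg, path) {
  rec <- list(a_sub_nm = a_sub, theta_deg = theta_deg,
              p_M_nm = moire_period(a_sub, theta_deg))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(rec)
}
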