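#' Capture pattern on a seed growth face
#'
#' Modular capture sites are laid out on a grid over the seed's lateral
#' surface: columns index positions along a helix row (x), rows index axial
#' (z) positions. A site forms a capture pair -- enabling cooperative
#' double-domain tile binding -- only when both its capture-0 and capture-1
#' strands are present.
#'
#' @param has_capture0,has_capture1 Logical matrices of identical dimensions
#'   (rows = z positions, columns = x positions).
#' @return An object of class `capture_pattern`.
#' @export
capture_pattern <- function(has_capture0, has_capture1) {
  if (!is.matrix(has_capture0) || !is.matrix(has_capture1) ||
      !identical(dim(has_capture0), dim(has_capture1)))
    stop("capture flags must be two matrices of identical dimensions")
  if (any(dim(has_capture0) < 1)) stop("capture grid must be at least 1x1")
  structure(list(has_capture0 = has_capture0, has_capture1 = has_capture1),
            class = "capture_pattern")
}

#' Classify the cooperativity mode of a capture pattern
#'
#' A site is a capture pair iff both flags are present. The pattern is
#' `fully` cooperative when every site is a pair, `non_cooperative` when no
#' site is, and `partially` cooperative otherwise. `max_z_run`, the longest
#' vertical (axial) run of pairs in any column, captures the z-continuity
#' criterion that separates effective partial seeds from ineffective ones.
#'
#' @param p A [capture_pattern()].
#' @return List with `mode`, `pair_count`, `max_z_run`.
#' @export
classify_capture_pattern <- function(p) {
  stopifnot(inherits(p, "capture_pattern"))
  pairs <- p$has_capture0 & p$has_capture1
  n_pair <- sum(pairs)
  mode <- if (n_pair == length(pairs)) "fully"
          else if (n_pair == 0) "non_cooperative"
          else "partially"
  max_run <- 0L
  for (j in seq_len(ncol(pairs))) {
    r <- rle(pairs[, j])
    runs <- r$lengths[r$values]
    if (length(runs)) max_run <- max(max_run, max(runs))
  }
  list(mode = mode, pair_count = as.integer(n_pair), max_z_run = as.integer(max_run))
}

#' Heterogeneous-nucleation wetting factor (2D)
#'
#' Shape factor `f(psi) = (psi - sin psi cos psi) / pi` (psi in radians) by
#' which a seed surface with contact angle `psi` reduces the 2D disc-nucleus
#' barrier. Monotone increasing: perfect wetting (psi -> 0) removes the
#' barrier, psi = 180 deg recovers the homogeneous barrier (f = 1).
#'
#' @param psi_deg Contact angle in degrees, in (0, 180].
#' @return `f` in (0, 1]. Vectorised.
#' @export
wetting_factor <- function(psi_deg) {
  if (any(psi_deg <= 0 | psi_deg > 180)) stop("psi_deg must lie in (0, 180]")
  psi <- psi_deg * pi / 180
  (psi - sin(psi) * cos(psi)) / pi
}

#' Default contact angle for a capture cooperativity mode
#'
#' Maps the classified nucleation mode to an effective contact angle: fully
#' cooperative seeds wet strongly (30 deg); partially cooperative seeds with a
#' z-continuous pair run (`max_z_run >= 2`) wet moderately (90 deg); patterns
#' without z-continuity and non-cooperative patterns do not seed (180 deg).
#' The defaults are pragmatic calibration choices, configurable per call.
#'
#' @param classification Result of [classify_capture_pattern()].
#' @param psi_map Named numeric: `fully`, `partial_continuous`, `none`.
#' @return Contact angle psi in degrees.
#' @export
contact_angle_for_mode <- function(classification,
                                   psi_map = c(fully = 30, partial_continuous = 90,
                                               none = 180)) {
  m <- classification$mode
  if (m == "fully") unname(psi_map["fully"])
  else if (m == "partially" && classification$max_z_run >= 2)
    unname(psi_map["partial_continuous"])
  else unname(psi_map["none"])
}

#' Tile thermodynamic parameters (reduced units)
#'
#' @param T_m_C Melting temperature of the tile lattice, deg C.
#' @param delta_h Per-tile condensation enthalpy (reduced, > 0).
#' @param gamma Edge free energy per unit nucleus perimeter (reduced, > 0).
#' @param A_homo,A_het Kinetic prefactors (reduced).
#' @param site_density_ratio Ratio of seed nucleation-site density to bulk
#'   (dimensionless).
#' @return An object of class `tile_thermo`.
#' @export
tile_thermo <- function(T_m_C = 45, delta_h = 1, gamma = 1,
                        A_homo = 1, A_het = 1, site_density_ratio = 1) {
  if (delta_h <= 0 || gamma <= 0) stop("delta_h and gamma must be positive")
  if (T_m_C <= -273.15) stop("T_m must be above absolute zero")
  structure(list(T_m_C = T_m_C, delta_h = delta_h, gamma = gamma,
                 A_homo = A_homo, A_het = A_het,
                 site_density_ratio = site_density_ratio),
            class = "tile_thermo")
}

#' Wetting specification
#'
#' Exactly one of contact angle `psi_deg` or direct factor `f` is given.
#'
#' @param psi_deg Contact angle in degrees, (0, 180].
#' @param f Direct barrier-reduction factor in (0, 1].
#' @return An object of class `wetting_spec` with the resolved factor `f`.
#' @export
wetting_spec <- function(psi_deg = NULL, f = NULL) {
  if (is.null(psi_deg) == is.null(f))
    stop("supply exactly one of psi_deg or f")
  if (is.null(f)) f <- wetting_factor(psi_deg)
  if (f <= 0 || f > 1) stop("f must lie in (0, 1]")
  structure(list(psi_deg = psi_deg, f = f), class = "wetting_spec")
}

.to_kelvin <- function(T_C) T_C + 273.15

#' Homogeneous 2D nucleation barrier
#'
#' Disc-nucleus barrier `dG* = pi gamma^2 / dg(T)` with supersaturation
#' `dg(T) = delta_h (T_m - T) / T_m` on the absolute temperature scale.
#' Above the melting temperature there is no barrier crossing and the
#' infinite sentinel is returned.
#'
#' @param T_C Temperature in deg C. Vectorised.
#' @param thermo A [tile_thermo()].
#' @return Barrier in reduced energy units (`Inf` for `T >= T_m`).
#' @export
barrier_homo <- function(T_C, thermo) {
  stopifnot(inherits(thermo, "tile_thermo"))
  T_K <- .to_kelvin(T_C); Tm_K <- .to_kelvin(thermo$T_m_C)
  dg <- thermo$delta_h * (Tm_K - T_K) / Tm_K
  ifelse(dg <= 0, Inf, pi * thermo$gamma^2 / dg)
}

#' Homogeneous and heterogeneous nucleation-rate curves
#'
#' Arrhenius-type CNT rates over a temperature grid:
#' `N_homo = A_homo exp(-dG*/kT)` and
#' `N_hetero = A_het site_density_ratio exp(-f dG*/kT)` with `k = 1`
#' (reduced units, absolute temperature). The ratio `R = N_hetero / N_homo`
#' quantifies seeding selectivity; with `f = 1` and matched prefactors the
#' seed confers no advantage and `R` is identically 1.
#'
#' @param T_grid_C Temperatures in deg C (all below `T_m`).
#' @param thermo A [tile_thermo()].
#' @param wetting A [wetting_spec()].
#' @return A `nucleation_curves` data.frame with columns `T_C`, `N_homo`,
#'   `N_hetero`, `R`.
#' @export
nucleation_rates <- function(T_grid_C, thermo, wetting) {
  stopifnot(inherits(thermo, "tile_thermo"), inherits(wetting, "wetting_spec"))
  if (length(T_grid_C) == 0) stop("empty temperature grid")
  if (any(T_grid_C >= thermo$T_m_C))
    stop("temperature grid must lie below T_m")
  dG <- barrier_homo(T_grid_C, thermo)
  T_K <- .to_kelvin(T_grid_C)
  N_homo <- thermo$A_homo * exp(-dG / T_K)
  N_het <- thermo$A_het * thermo$site_density_ratio * exp(-wetting$f * dG / T_K)
  out <- data.frame(T_C = T_grid_C, N_homo = N_homo, N_hetero = N_het,
                    R = N_het / N_homo)
  class(out) <- c("nucleation_curves", class(out))
  out
}
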