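# SST sublattice constants measured by cryo-EM (hydrated) and on dried TEM
# grids, in nm, per symmetry.
.LATTICE_CONSTANTS <- list(
  cryo  = c(square = 2.8, kagome = 5.4, honeycomb = 4.4),
  dried = c(square = 2.2, kagome = 4.4, honeycomb = 3.5)
)

#' Sublattice lattice constant presets
#'
#' @param symmetry `"square"`, `"kagome"` or `"honeycomb"`.
#' @param hydration `"cryo"` (hydrated) or `"dried"` (TEM-grid, shrunken).
#' @return Lattice constant in nm.
#' @export
lattice_constant <- function(symmetry = c("square", "kagome", "honeycomb"),
                             hydration = c("dried", "cryo")) {
  symmetry <- match.arg(symmetry)
  hydration <- match.arg(hydration)
  unname(.LATTICE_CONSTANTS[[hydration]][symmetry])
}

#' Sublattice specification
#'
#' Describes one SST sublattice layer: its symmetry, lattice constant (the
#' Bravais cell constant; for the hexagonal symmetries the first-order
#' d-spacing is `sqrt(3)/2 * a_sub`), and the site basis.
#'
#' The canonical nets are: square (one site per cell), kagome (trihexagonal;
#' hexagonal Bravais cell with three sites), honeycomb (hexagonal cell with
#' two sites). [kagome_from_square()] builds the alternative voided-square
#' view of the kagome net.
#'
#' @param symmetry `"square"`, `"kagome"` or `"honeycomb"`.
#' @param a_sub Lattice constant in nm; defaults to the hydration preset.
#' @param hydration `"dried"` or `"cryo"` preset used when `a_sub` is missing.
#' @param net Bravais net override: `"square"` or `"hex"`. Defaults to the
#'   canonical net of the symmetry.
#' @param basis Fractional site coordinates (matrix with 2 columns) override.
#' @return An object of class `lattice_spec`.
#' @export
lattice_spec <- function(symmetry = c("square", "kagome", "honeycomb"),
                         a_sub = NULL, hydration = c("dried", "cryo"),
                         net = NULL, basis = NULL) {
  symmetry <- match.arg(symmetry)
  hydration <- match.arg(hydration)
  if (is.null(a_sub)) a_sub <- lattice_constant(symmetry, hydration)
  if (!is.numeric(a_sub) || length(a_sub) != 1 || a_sub <= 0)
    stop("a_sub must be a single positive length in nm")
  if (is.null(net)) net <- if (symmetry == "square") "square" else "hex"
  if (is.null(basis)) {
    basis <- switch(symmetry,
      square    = matrix(c(0, 0), ncol = 2),
      kagome    = matrix(c(0, 0, 0.5, 0, 0, 0.5), ncol = 2, byrow = TRUE),
      honeycomb = matrix(c(0, 0, 1/3, 1/3), ncol = 2, byrow = TRUE))
  }
  structure(list(symmetry = symmetry, a_sub = as.numeric(a_sub),
                 hydration = hydration, net = net, basis = basis),
            class = "lattice_spec")
}

# direct Bravais vectors (columns) for a spec
.bravais_matrix <- function(spec) {
  a <- spec$a_sub
  if (spec$net == "square") {
    cbind(c(a, 0), c(0, a))
  } else {
    cbind(c(a, 0), c(a / 2, a * sqrt(3) / 2))
  }
}

# first-order d-spacing / a_sub ratio per net
.d_factor <- function(net_or_symmetry) {
  if (net_or_symmetry %in% c("square")) 1 else sqrt(3) / 2
}

#' Generate lattice points inside a rectangular region
#'
#' Enumerates all lattice + basis sites of the rotated, translated lattice
#' that fall inside the closed region (boundary points included). The lattice
#' passes through `origin` before rotation about `origin`.
#'
#' @param spec A [lattice_spec()].
#' @param region Rectangle `c(xmin, xmax, ymin, ymax)` in nm.
#' @param orientation In-plane rotation in degrees (right-handed).
#' @param origin Lattice anchor / rotation centre, `c(x, y)` nm.
#' @param layer_id Integer tag stored with the points.
#' @return A `point_set` data.frame with columns `x_nm`, `y_nm`, `layer_id`;
#'   the generating spec, orientation and origin are kept as attributes.
#' @export
generate_lattice <- function(spec, region, orientation = 0, origin = c(0, 0),
                             layer_id = 1L) {
  stopifnot(inherits(spec, "lattice_spec"))
  if (length(region) != 4) stop("region must be c(xmin, xmax, ymin, ymax)")
  if (region[2] <= region[1] || region[4] <= region[3])
    stop("region area must be positive")
  A <- .bravais_matrix(spec)
  phi <- orientation * pi / 180
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  # map region corners into (unrotated) lattice coordinates to bound n1, n2
  corners <- rbind(c(region[1], region[3]), c(region[2], region[3]),
                   c(region[1], region[4]), c(region[2], region[4]))
  rel <- t(t(corners) - origin)
  lat <- t(solve(A) %*% t(R) %*% t(rel))
  pad <- 2  # covers basis offsets
  n1 <- seq(floor(min(lat[, 1])) - pad, ceiling(max(lat[, 1])) + pad)
  n2 <- seq(floor(min(lat[, 2])) - pad, ceiling(max(lat[, 2])) + pad)
  cells <- as.matrix(expand.grid(n1 = n1, n2 = n2))
  pts <- do.call(rbind, lapply(seq_len(nrow(spec$basis)), function(b) {
    frac <- t(t(cells) + spec$basis[b, ])
    t(A %*% t(frac))
  }))
  pts <- t(R %*% t(pts) + origin)
  tol <- 1e-9 * max(1, abs(region))
  keep <- pts[, 1] >= region[1] - tol & pts[, 1] <= region[2] + tol &
          pts[, 2] >= region[3] - tol & pts[, 2] <= region[4] + tol
  out <- data.frame(x_nm = pts[keep, 1], y_nm = pts[keep, 2],
                    layer_id = as.integer(layer_id))
  attr(out, "spec") <- spec
  attr(out, "orientation_deg") <- orientation
  attr(out, "origin_nm") <- origin
  class(out) <- c("point_set", class(out))
  out
}

#' First-order reciprocal-space families of a sublattice
#'
#' Returns the first-order g-vector families of the lattice at orientation 0:
#' for the square net two families 90 deg apart with d = a; for the hexagonal
#' nets (kagome, honeycomb) three families at mutual 60/120 deg with
#' d = sqrt(3)/2 a. `|g| = 1/d` (crystallographic convention, no 2 pi).
#'
#' @param spec A [lattice_spec()].
#' @return An object of class `reciprocal_peaks`: list with `g_vectors`
#'   (one row per family, nm^-1), `d_spacings` (nm), `interplane_angles`
#'   (unique pairwise angles, deg).
#' @export
reciprocal_basis <- function(spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  A <- .bravais_matrix(spec)
  B <- t(solve(A))           # columns b1, b2 with a_i . b_j = delta_ij
  g <- if (spec$net == "square") {
    rbind(B[, 1], B[, 2])
  } else {
    rbind(B[, 1], B[, 2], B[, 1] + B[, 2])
  }
  colnames(g) <- c("gx", "gy")
  d <- 1 / sqrt(rowSums(g^2))
  az <- atan2(g[, 2], g[, 1]) * 180 / pi
  n <- nrow(g)
  ang <- c()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    a <- abs(az[i] - az[j]) %% 180
    ang <- c(ang, round(min(a, 180 - a) , 9), round(max(a, 180 - a) %% 180, 9))
  }
  ang <- sort(unique(ang[ang > 0]))
  structure(list(g_vectors = g, d_spacings = d, interplane_angles = ang),
            class = "reciprocal_peaks")
}

#' Kagome net as a voided square lattice
#'
#' Constructive view of the kagome sublattice as a loosely packed square
#' lattice with a periodic void sublattice removed: one site of every 2x2
#' block is dropped (void fraction 1/4) and the cell constant doubles to the
#' kagome constant `a_k = 2 a_s`.
#'
#' @param square_spec A square [lattice_spec()].
#' @param void_pattern `"block_2x2"` (default) or `"none"` (no voids; the site
#'   set stays identical to the square lattice).
#' @return A [lattice_spec()] with `symmetry = "kagome"` on a square net.
#' @export
kagome_from_square <- function(square_spec, void_pattern = "block_2x2") {
  stopifnot(inherits(square_spec, "lattice_spec"))
  if (square_spec$symmetry != "square") stop("input spec must be square")
  a_k <- 2 * square_spec$a_sub
  if (void_pattern == "block_2x2") {
    basis <- matrix(c(0, 0, 0.5, 0, 0, 0.5), ncol = 2, byrow = TRUE)
  } else if (void_pattern == "none") {
    basis <- matrix(c(0, 0, 0.5, 0, 0, 0.5, 0.5, 0.5), ncol = 2, byrow = TRUE)
  } else {
    stop("unknown void_pattern: ", void_pattern)
  }
  spec <- lattice_spec("kagome", a_sub = a_k, hydration = square_spec$hydration,
                       net = "square", basis = basis)
  attr(spec, "void_fraction") <- 1 - nrow(basis) / 4
  spec
}

#' Write a point set as CSV
#'
#' @param points A `point_set` from [generate_lattice()].
#' @param path Output CSV path (columns `x_nm`, `y_nm`, `layer_id`).
#' @return `path`, invisibly.
#' @export
write_point_set <- function(points, path) {
  utils::write.csv(as.data.frame(points)[, c("x_nm", "y_nm", "layer_id")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a point set from CSV
#'
#' @param path CSV with columns `x_nm`, `y_nm`, `layer_id`.
#' @return A `point_set` data.frame.
#' @export
read_point_set <- function(path) {
  out <- utils::read.csv(path)
  stopifnot(all(c("x_nm", "y_nm", "layer_id") %in% names(out)))
  class(out) <- c("point_set", class(out))
  out
}
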