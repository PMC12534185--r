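# Canonical B-DNA axial rise (nm per base pair). Matches all printed bp -> nm
# pairs of the seed designs (128 -> 43.5, 32 -> 10.9, 36 -> 12.2, 126 -> 42.8)
# to 0.1 nm.
.B_DNA_RISE <- 0.34

# Interhelical centre-to-centre pitch of packed origami helices (nm). Affects
# only cross-section rendering, never helix counts.
.HELIX_PITCH <- 2.6

#' Cross-section specification for a hollow origami seed
#'
#' A seed cross-section is a rectangular rim of parallel DNA helices with a
#' centred rectangular pore removed, packed on either a square or a honeycomb
#' helix arrangement.
#'
#' @param array_type `"square"` or `"honeycomb"` helix packing.
#' @param rim_cols,rim_rows Rim extent in helices.
#' @param pore_cols,pore_rows Pore extent in helices (must fit inside the rim).
#' @param taper Optional [gradient_taper()] describing a trapezoidal face.
#' @return An object of class `cross_section_spec`.
#' @export
cross_section_spec <- function(array_type = c("square", "honeycomb"),
                               rim_cols, rim_rows, pore_cols = 0, pore_rows = 0,
                               taper = NULL) {
  array_type <- match.arg(array_type)
  counts <- c(rim_cols, rim_rows, pore_cols, pore_rows)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("helix counts must be non-negative integers")
  if (pore_cols > rim_cols || pore_rows > rim_rows)
    stop("invalid cross-section: pore exceeds rim")
  if (!is.null(taper) && !inherits(taper, "gradient_taper"))
    stop("taper must be a gradient_taper object")
  structure(list(array_type = array_type,
                 rim_cols = as.integer(rim_cols), rim_rows = as.integer(rim_rows),
                 pore_cols = as.integer(pore_cols), pore_rows = as.integer(pore_rows),
                 taper = taper),
            class = "cross_section_spec")
}

#' Gradient (trapezoid) taper of a seed growth face
#'
#' A trapezoidal cross-section tilts one growth face, adding an extra in-plane
#' rotation `delta_theta` to lattices grown from that face. The tilt angle is
#' taken as a design input; the bp-level trapezoid construction is not
#' modelled.
#'
#' @param delta_theta Additional tilt contribution in degrees (>= 0).
#' @param tilted_face Which face is tilted, `"a"` or `"b"`.
#' @return An object of class `gradient_taper`.
#' @export
gradient_taper <- function(delta_theta, tilted_face = c("a", "b")) {
  tilted_face <- match.arg(tilted_face)
  if (!is.numeric(delta_theta) || length(delta_theta) != 1 || delta_theta < 0)
    stop("delta_theta must be a single non-negative angle in degrees")
  structure(list(delta_theta = as.numeric(delta_theta), tilted_face = tilted_face),
            class = "gradient_taper")
}

#' Build the helix layout of a seed cross-section
#'
#' Places helix centres on the requested packing (2.6 nm pitch by default) and
#' removes the centred pore. For square packing the helix count is exactly
#' `rim_cols * rim_rows - pore_cols * pore_rows`.
#'
#' @param spec A [cross_section_spec()].
#' @param pitch Centre-to-centre helix spacing in nm.
#' @return A `helix_layout`: list with `centres` (matrix, nm), `helix_count`,
#'   and `degenerate` flag (TRUE when the pore swallows the whole rim).
#' @export
build_cross_section <- function(spec, pitch = .HELIX_PITCH) {
  stopifnot(inherits(spec, "cross_section_spec"))
  nc <- spec$rim_cols; nr <- spec$rim_rows
  ij <- expand.grid(col = seq_len(nc), row = seq_len(nr))
  # centred pore: integer offset, exact when rim and pore share parity
  c0 <- floor((nc - spec$pore_cols) / 2)
  r0 <- floor((nr - spec$pore_rows) / 2)
  in_pore <- ij$col > c0 & ij$col <= c0 + spec$pore_cols &
             ij$row > r0 & ij$row <= r0 + spec$pore_rows
  keep <- ij[!in_pore, , drop = FALSE]
  x <- (keep$col - 1) * pitch
  y <- (keep$row - 1) * pitch
  if (spec$array_type == "honeycomb") {
    # honeycomb helix packing: alternate rows offset by half a pitch,
    # rows compressed to keep the nearest-neighbour distance at `pitch`
    x <- x + ifelse(keep$row %% 2 == 0, pitch / 2, 0)
    y <- (keep$row - 1) * pitch * sqrt(3) / 2
  }
  centres <- cbind(x_nm = x, y_nm = y)
  structure(list(centres = centres,
                 helix_count = nrow(centres),
                 degenerate = nrow(centres) == 0L),
            class = "helix_layout")
}

#' Height of a seed segment
#'
#' @param bp Segment length in base pairs (>= 0).
#' @param rise Axial rise in nm/bp (> 0), 0.34 by default.
#' @return Exact height `bp * rise` in nm. Printed design heights are this
#'   product rounded to 0.1 nm.
#' @export
segment_height <- function(bp, rise = .B_DNA_RISE) {
  if (any(bp < 0)) stop("bp must be non-negative")
  if (any(rise <= 0)) stop("rise must be positive")
  bp * rise
}

#' Twist introduced by a spacer/twister segment
#'
#' Right-handed rotation about +z is positive. Twist-per-bp rates are
#' calibration constants per array type (3.8 deg per 32 bp for the square-array
#' seed, 1.2 deg per 36 bp for the honeycomb-array seed).
#'
#' @param bp Segment length in base pairs (>= 0).
#' @param twist_rate Twist rate in degrees per bp.
#' @return Twist angle in degrees, `bp * twist_rate`.
#' @export
segment_twist <- function(bp, twist_rate) {
  if (any(bp < 0)) stop("bp must be non-negative")
  bp * twist_rate
}

#' Construct a seed segment
#'
#' @param id Label (e.g. "Z1").
#' @param role `"growth"` or `"spacer_twister"`.
#' @param bp Length in base pairs.
#' @param twist Twist carried by the segment in degrees. Growth segments relax
#'   to the untwisted sublattice and must carry 0.
#' @param captures Optional [capture_pattern()] attached to a growth segment.
#' @return An object of class `seed_segment`.
#' @export
seed_segment <- function(id, role = c("growth", "spacer_twister"), bp,
                         twist = 0, captures = NULL) {
  role <- match.arg(role)
  if (bp < 0) stop("bp must be non-negative")
  if (role == "growth" && twist != 0)
    stop("growth segments carry no twist after relaxation")
  structure(list(id = id, role = role, bp = as.integer(bp),
                 twist = as.numeric(twist), captures = captures),
            class = "seed_segment")
}

#' Construct a full seed design
#'
#' Segments must alternate growth / spacer_twister, starting and ending with a
#' growth segment (an empty list is allowed and compiles to an empty stack).
#'
#' @param name Design label.
#' @param cross_section A [cross_section_spec()].
#' @param segments List of [seed_segment()]s, bottom (z = 0) first.
#' @param rise Axial rise, nm/bp.
#' @param twist_rate Calibrated twist rate, degrees/bp (informational; segment
#'   twists are stored explicitly).
#' @return An object of class `seed_design`.
#' @export
seed_design <- function(name, cross_section, segments = list(),
                        rise = .B_DNA_RISE, twist_rate = NA_real_) {
  stopifnot(inherits(cross_section, "cross_section_spec"))
  if (rise <= 0) stop("rise must be positive")
  roles <- vapply(segments, function(s) s$role, character(1))
  if (length(roles) > 0) {
    expected <- rep(c("growth", "spacer_twister"), length.out = length(roles))
    if (!identical(roles, expected) || roles[length(roles)] != "growth")
      stop("segments must alternate growth/spacer_twister, starting and ending with growth")
  }
  structure(list(name = name, cross_section = cross_section,
                 segments = segments, rise = rise, twist_rate = twist_rate),
            class = "seed_design")
}

#' Compile a seed design into a layer stack
#'
#' Growth segments become sublattice layers. The z-interval of layer k starts
#' at the cumulative height of all preceding segments; its in-plane orientation
#' is the cumulative sum of all preceding spacer twists (layer 1 at 0 deg).
#'
#' @param seed A [seed_design()].
#' @return A `stack_spec` data.frame with columns `layer`, `z_lo_nm`, `z_hi_nm`,
#'   `orientation_deg`, `symmetry` (the array type, carried for convenience).
#' @export
compile_stack <- function(seed) {
  stopifnot(inherits(seed, "seed_design"))
  segs <- seed$segments
  out <- data.frame(layer = integer(0), z_lo_nm = numeric(0),
                    z_hi_nm = numeric(0), orientation_deg = numeric(0),
                    symmetry = character(0), stringsAsFactors = FALSE)
  z <- 0; ori <- 0; k <- 0L
  for (s in segs) {
    h <- segment_height(s$bp, seed$rise)
    if (s$role == "growth") {
      k <- k + 1L
      out <- rbind(out, data.frame(layer = k, z_lo_nm = z, z_hi_nm = z + h,
                                   orientation_deg = ori,
                                   symmetry = seed$cross_section$array_type,
                                   stringsAsFactors = FALSE))
    } else {
      ori <- ori + s$twist
    }
    z <- z + h
  }
  class(out) <- c("stack_spec", class(out))
  attr(out, "total_height_nm") <- z
  attr(out, "seed_name") <- seed$name
  out
}

#' Face orientations of a gradient (trapezoid) seed
#'
#' For a seed whose second growth segment has one tilted face, the non-tilted
#' face b carries only the spacer twist theta, while the tilted face a carries
#' theta + delta_theta.
#'
#' @param seed A [seed_design()] whose cross-section has a taper.
#' @return Named numeric `c(theta_b, theta_a)` in degrees.
#' @export
gradient_face_orientations <- function(seed) {
  stopifnot(inherits(seed, "seed_design"))
  taper <- seed$cross_section$taper
  if (is.null(taper))
    stop("seed has no taper; use compile_stack() for uniform (parallel-face) seeds")
  spacers <- Filter(function(s) s$role == "spacer_twister", seed$segments)
  theta <- sum(vapply(spacers, function(s) s$twist, numeric(1)))
  c(theta_b = theta, theta_a = theta + taper$delta_theta)
}

#' Built-in seed design presets
#'
#' `"S"`: square-array seed, 48 helices (8x8 rim, 4x4 pore), three 128-bp
#' growth segments separated by 32-bp spacers twisting 3.8 deg each.
#' `"H"`: honeycomb-array seed, 54 helices (12x6 rim, 6x3 pore), 126-bp growth
#' segments and 36-bp spacers twisting 1.2 deg.
#' `"SG"`: gradient variant of seed S — two growth segments separated by one
#' spacer twisting 2.8 deg, with a trapezoidal second segment adding
#' delta_theta = 10.9 deg on the tilted a face.
#'
#' @param name `"S"`, `"H"` or `"SG"`.
#' @param n_layers Number of growth layers for `"S"`/`"H"` (2 or 3).
#' @return A [seed_design()].
#' @export
seed_preset <- function(name = c("S", "H", "SG"), n_layers = 3) {
  name <- match.arg(name)
  file <- system.file("extdata", paste0("seed_", name, ".yaml"), package = "dnamoire")
  design <- read_seed_design(file)
  if (name != "SG" && n_layers == 2) {
    design$segments <- design$segments[1:3]
  } else if (!n_layers %in% c(2, 3)) {
    stop("n_layers must be 2 or 3")
  }
  design
}

#' Read a seed design from a YAML or JSON config file
#'
#' Keys mirror the [seed_design()] fields: `name`, `cross_section`
#' (`array_type`, `rim_cols`, `rim_rows`, `pore_cols`, `pore_rows`, optional
#' `taper` with `delta_theta`/`tilted_face`), `segments` (list of `id`, `role`,
#' `bp`, `twist`), `rise`, `twist_rate`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [seed_design()].
#' @export
read_seed_design <- function(path) {
  if (!file.exists(path)) stop("seed design file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  cs <- raw$cross_section
  taper <- if (!is.null(cs$taper))
    gradient_taper(cs$taper$delta_theta, cs$taper$tilted_face)
  spec <- cross_section_spec(cs$array_type, cs$rim_cols, cs$rim_rows,
                             cs$pore_cols %||% 0, cs$pore_rows %||% 0, taper)
  segs <- lapply(raw$segments, function(s)
    seed_segment(s$id, s$role, s$bp, s$twist %||% 0))
  seed_design(raw$name, spec, segs,
              rise = raw$rise %||% .B_DNA_RISE,
              twist_rate = raw$twist_rate %||% NA_real_)
}

#' Export a compiled stack as JSON
#'
#' @param stack A `stack_spec` from [compile_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack_json <- function(stack, path) {
  rec <- list(seed = attr(stack, "seed_name"),
              total_height_nm = attr(stack, "total_height_nm"),
              layers = as.data.frame(stack))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
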