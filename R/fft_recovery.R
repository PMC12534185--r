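# fundamental azimuthal zone (deg) of a lattice symmetry: twists are folded
# into [0, zone); square nets repeat every 90 deg, hexagonal nets every 60
.symmetry_zone <- function(symmetry) {
  switch(symmetry, square = 90, kagome = 60, honeycomb = 60,
         stop("unknown symmetry: ", symmetry))
}

# fftshift index order for length n
.fftshift_idx <- function(n) c((floor(n / 2) + 1):n, 1:floor(n / 2))

#' Calibrated 2D power spectrum of a micrograph
#'
#' Windowed 2D discrete Fourier transform magnitude with frequency axes in
#' nm^-1, DC at the centre.
#'
#' @param image A `micrograph` (matrix with `pixel_size_nm` attribute) of at
#'   least 64 x 64 pixels.
#' @param window `"hann"` (default) or `"none"`.
#' @param pixel_size_nm Calibration override if the image carries none.
#' @return A `spectrum2d`: list with `mag` (matrix, DC-centred), `gx`, `gy`
#'   (axis vectors, nm^-1), `g_bin` (frequency bin width) and
#'   `pixel_size_nm`.
#' @export
power_spectrum <- function(image, window = c("hann", "none"),
                           pixel_size_nm = NULL) {
  window <- match.arg(window)
  px <- pixel_size_nm %||% attr(image, "pixel_size_nm")
  if (is.null(px)) stop("missing pixel calibration: supply pixel_size_nm")
  m <- unclass(image)
  if (nrow(m) < 64 || ncol(m) < 64) stop("image must be at least 64x64 px")
  m <- m - mean(m)
  if (window == "hann") {
    wr <- 0.5 * (1 - cos(2 * pi * (seq_len(nrow(m)) - 1) / (nrow(m) - 1)))
    wc <- 0.5 * (1 - cos(2 * pi * (seq_len(ncol(m)) - 1) / (ncol(m) - 1)))
    m <- m * outer(wr, wc)
  }
  F <- stats::fft(m)
  mag <- Mod(F)
  nr <- nrow(m); nc <- ncol(m)
  mag <- mag[.fftshift_idx(nr), .fftshift_idx(nc)]
  fy <- ((seq_len(nr) - 1 - floor(nr / 2)) / nr) / px
  fx <- ((seq_len(nc) - 1 - floor(nc / 2)) / nc) / px
  structure(list(mag = mag, gx = fx, gy = fy, g_bin = 1 / (nr * px),
                 pixel_size_nm = px),
            class = "spectrum2d")
}

#' Detect reciprocal-space peaks in an annulus
#'
#' Finds local maxima of the spectrum magnitude within the annulus
#' `g_lo <= |g| <= g_hi` that exceed `min_snr` times the annulus median,
#' refines each to sub-bin precision by a 3x3 centre of mass, and merges
#' conjugate (+g/-g) partners, keeping the representative with azimuth in
#' (-90, 90].
#'
#' @param spectrum A `spectrum2d` from [power_spectrum()].
#' @param min_snr Peak threshold relative to the annulus median magnitude.
#' @param annulus `c(g_lo, g_hi)` in nm^-1, `g_lo < g_hi`.
#' @return A `peak_list` data.frame sorted by magnitude (descending):
#'   `gx`, `gy` (nm^-1), `magnitude`, `azimuth_deg`, `d_nm`.
#' @export
detect_peaks <- function(spectrum, min_snr = 5, annulus) {
  stopifnot(inherits(spectrum, "spectrum2d"))
  if (length(annulus) != 2 || annulus[1] >= annulus[2])
    stop("annulus must be c(g_lo, g_hi) with g_lo < g_hi")
  mag <- spectrum$mag
  G2 <- outer(spectrum$gy^2, spectrum$gx^2, "+")
  in_ann <- G2 >= annulus[1]^2 & G2 <= annulus[2]^2
  if (!any(in_ann)) stop("empty annulus for this spectrum")
  med <- stats::median(mag[in_ann])
  thr <- min_snr * max(med, .Machine$double.eps)
  nr <- nrow(mag); nc <- ncol(mag)
  core <- mag[2:(nr - 1), 2:(nc - 1)]
  is_max <- core >= thr & in_ann[2:(nr - 1), 2:(nc - 1)]
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & core >= mag[2:(nr - 1) + di, 2:(nc - 1) + dj]
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(structure(data.frame(gx = numeric(0), gy = numeric(0),
                                magnitude = numeric(0), azimuth_deg = numeric(0),
                                d_nm = numeric(0)),
                     class = c("peak_list", "data.frame")))
  idx <- idx + 1L  # back to full-matrix indices
  peaks <- t(apply(idx, 1, function(rc) {
    i <- rc[1]; j <- rc[2]
    w <- mag[(i - 1):(i + 1), (j - 1):(j + 1)]
    sw <- sum(w)
    gyy <- sum(rowSums(w) * spectrum$gy[(i - 1):(i + 1)]) / sw
    gxx <- sum(colSums(w) * spectrum$gx[(j - 1):(j + 1)]) / sw
    c(gx = gxx, gy = gyy, magnitude = mag[i, j])
  }))
  peaks <- as.data.frame(peaks)
  peaks$azimuth_deg <- atan2(peaks$gy, peaks$gx) * 180 / pi
  # merge conjugate partners: keep azimuth in (-90, 90]
  keep <- peaks$azimuth_deg > -90 + 1e-9 & peaks$azimuth_deg <= 90 + 1e-9
  peaks <- peaks[keep, , drop = FALSE]
  peaks$d_nm <- 1 / sqrt(peaks$gx^2 + peaks$gy^2)
  # ties: larger magnitude first, then smaller |g|
  peaks <- peaks[order(-peaks$magnitude, -peaks$d_nm), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(peaks, class = c("peak_list", "data.frame"))
}

# circular mean of angles (deg) with period `zone`, weighted
.circ_mean <- function(a_deg, zone, w = NULL) {
  if (is.null(w)) w <- rep(1, length(a_deg))
  ph <- a_deg * 2 * pi / zone
  m <- atan2(sum(w * sin(ph)), sum(w * cos(ph))) * zone / (2 * pi)
  m %% zone
}

# circular difference a - b (deg) folded into (-zone/2, zone/2]
.circ_diff <- function(a, b, zone) {
  d <- (a - b) %% zone
  ifelse(d > zone / 2, d - zone, d)
}

#' Estimate per-layer lattice parameters and twist from a peak list
#'
#' Folds peak azimuths into the symmetry's fundamental zone (90 deg for the
#' square net, 60 deg for hexagonal nets), clusters them into layer families
#' by cutting the largest circular gaps, and reports each family's lattice
#' constant (from the mean d-spacing, corrected by the symmetry's d/a
#' factor) and orientation. The twist is the circular separation of the two
#' family orientations. With a single resolvable family the twist is flagged
#' undefined (monolayer).
#'
#' @param peaks A `peak_list` restricted to the sublattice band.
#' @param symmetry `"square"`, `"kagome"` or `"honeycomb"`.
#' @param n_layers Expected number of layer families (default 2).
#' @param min_split Minimum angular separation (deg) for two families to be
#'   considered resolved.
#' @param rel_mag Peaks weaker than this fraction of the strongest peak are
#'   discarded before clustering (Bragg families of the layers have
#'   comparable strength; residual noise maxima do not).
#' @return A `recovery_report`: list with `layers` (data.frame
#'   `orientation_deg`, `a_sub_nm`, `n_peaks`), `twist_deg` (NA when
#'   monolayer), `monolayer` flag, `symmetry`.
#' @export
estimate_lattice <- function(peaks, symmetry, n_layers = 2, min_split = 0.5,
                             rel_mag = 0.05) {
  stopifnot(inherits(peaks, "peak_list"))
  zone <- .symmetry_zone(symmetry)
  d_fac <- .d_factor(if (symmetry == "square") "square" else "hex")
  if (nrow(peaks) >= 1)
    peaks <- peaks[peaks$magnitude >= rel_mag * max(peaks$magnitude), ,
                   drop = FALSE]
  if (nrow(peaks) < 1)
    return(structure(list(layers = NULL, twist_deg = NA_real_,
                          monolayer = NA, symmetry = symmetry),
                     class = "recovery_report"))
  az <- peaks$azimuth_deg %% zone
  ord <- order(az)
  azs <- az[ord]
  gaps <- c(diff(azs), azs[1] + zone - azs[length(azs)])
  k <- min(n_layers, length(azs))
  cut_at <- sort(order(gaps, decreasing = TRUE)[seq_len(k)])
  cluster <- integer(length(azs))
  cl <- 1L
  for (i in seq_along(azs)) {
    cluster[i] <- cl
    if (i %in% cut_at) cl <- cl + 1L
  }
  cluster[cluster > k] <- 1L   # wrap: last group joins the first
  groups <- split(seq_along(azs), cluster)
  layers <- do.call(rbind, lapply(groups, function(ix) {
    sel <- ord[ix]
    data.frame(
      orientation_deg = .circ_mean(az[sel], zone, peaks$magnitude[sel]),
      a_sub_nm = stats::weighted.mean(peaks$d_nm[sel], peaks$magnitude[sel]) / d_fac,
      n_peaks = length(sel),
      magnitude = sum(peaks$magnitude[sel]))
  }))
  layers <- layers[order(-layers$magnitude), , drop = FALSE]
  rownames(layers) <- NULL
  if (nrow(layers) >= 2) {
    tw <- abs(.circ_diff(layers$orientation_deg[1], layers$orientation_deg[2], zone))
    if (tw < min_split) {
      # unresolved split: collapse to a single family
      layers <- data.frame(
        orientation_deg = .circ_mean(az, zone, peaks$magnitude),
        a_sub_nm = stats::weighted.mean(peaks$d_nm, peaks$magnitude) / d_fac,
        n_peaks = nrow(peaks), magnitude = sum(peaks$magnitude))
      tw <- NA_real_
    }
  } else {
    tw <- NA_real_
  }
  structure(list(layers = layers, twist_deg = tw,
                 monolayer = is.na(tw), symmetry = symmetry),
            class = "recovery_report")
}

#' Estimate the moire periodicity from an image
#'
#' The rendered (and physical) image is a linear superposition of the two
#' sublattice spot fields, whose spectrum contains no difference frequencies;
#' the moire beat is demodulated by squaring the mean-subtracted image, whose
#' spectrum carries peaks at all pairwise sublattice g-vector differences.
#' The dominant peak in the low-frequency band below the sublattice ring
#' gives `p_M = d_factor(symmetry) / |g_m|` (the moire superlattice inherits
#' the sublattice symmetry, so its d-spacing carries the same d/a factor).
#'
#' @param image A `micrograph`.
#' @param symmetry Sublattice symmetry of the stack.
#' @param a_sub_nm Expected sublattice constant (nm), used to place the band
#'   ceiling below the sublattice ring.
#' @param min_snr Peak threshold for the moire band.
#' @param pixel_size_nm Calibration override.
#' @return List with `p_M_nm` (NA sentinel if no moire peak is detected),
#'   `detected`, `g_m` (nm^-1) and the band used.
#' @export
estimate_moire_period <- function(image, symmetry, a_sub_nm,
                                  min_snr = 8, pixel_size_nm = NULL) {
  px <- pixel_size_nm %||% attr(image, "pixel_size_nm")
  if (is.null(px)) stop("missing pixel calibration: supply pixel_size_nm")
  d_fac <- .d_factor(if (symmetry == "square") "square" else "hex")
  g_sub <- 1 / (a_sub_nm * d_fac)
  demod <- unclass(image) - mean(image)
  demod <- structure(demod^2, pixel_size_nm = px,
                     class = c("micrograph", "matrix", "array"))
  spec <- power_spectrum(demod, window = "hann")
  L <- nrow(image) * px
  band <- c(max(4 / L, 2 * spec$g_bin), 0.6 * g_sub)
  if (band[1] >= band[2]) stop("field of view too small to resolve a moire band")
  pk <- detect_peaks(spec, min_snr = min_snr, annulus = band)
  if (nrow(pk) == 0)
    return(list(p_M_nm = NA_real_, detected = FALSE, g_m = NA_real_, band = band))
  g_m <- sqrt(pk$gx[1]^2 + pk$gy[1]^2)
  # the moire superlattice inherits the sublattice symmetry: its smallest
  # reciprocal vector relates to the moire cell constant by the same d/a
  # factor, so p_M = 1 / (d_fac * |g_m|)
  list(p_M_nm = 1 / (d_fac * g_m), detected = TRUE, g_m = g_m, band = band)
}

#' One-call lattice + twist + moire recovery from an image
#'
#' Runs [power_spectrum()], [detect_peaks()] in the sublattice band
#' (`a_sub` +/- 30% when given, full band otherwise), [estimate_lattice()],
#' and [estimate_moire_period()].
#'
#' @param image A `micrograph`.
#' @param symmetry Sublattice symmetry.
#' @param a_sub_nm Expected sublattice constant (nm), optional.
#' @param n_layers Expected layer families.
#' @param min_snr Peak threshold for the sublattice band.
#' @param with_moire Also estimate the moire period (default TRUE for
#'   multi-layer analysis).
#' @return A `recovery_report` with `p_M_nm` added.
#' @export
analyze_micrograph <- function(image, symmetry, a_sub_nm = NULL, n_layers = 2,
                               min_snr = 5, with_moire = TRUE) {
  px <- attr(image, "pixel_size_nm")
  spec <- power_spectrum(image, window = "hann")
  d_fac <- .d_factor(if (symmetry == "square") "square" else "hex")
  ann <- if (!is.null(a_sub_nm)) {
    g0 <- 1 / (a_sub_nm * d_fac)
    c(0.7 * g0, 1.3 * g0)
  } else {
    c(4 * spec$g_bin, 1 / (2 * px))
  }
  pk <- detect_peaks(spec, min_snr = min_snr, annulus = ann)
  rpt <- estimate_lattice(pk, symmetry, n_layers = n_layers)
  rpt$p_M_nm <- if (with_moire && !is.null(a_sub_nm)) {
    estimate_moire_period(image, symmetry, a_sub_nm)$p_M_nm
  } else NA_real_
  rpt$peaks <- pk
  rpt
}

#' Windowed local orientation / twist / period map
#'
#' Slides a square analysis window over the image (regular grid), estimates
#' the local layer families in each window, and derives the local moire
#' period from the local twist via the exact moire relation. Windows where
#' two families cannot be resolved carry NA sentinels.
#'
#' @param image A `micrograph`.
#' @param symmetry Sublattice symmetry.
#' @param a_sub_nm Expected sublattice constant (nm).
#' @param window_px Window side (>= 128 px recommended).
#' @param stride_px Grid stride; a stride larger than the window leaves gaps
#'   (warning, not an error).
#' @param min_snr Peak threshold per window.
#' @param r_range_nm Optional radial band `c(r_lo, r_hi)`: only windows whose
#'   centres fall in this distance range from the image centre are analysed
#'   (used for azimuthal ring profiles around a central seed).
#' @return An `orientation_field` data.frame: window centres (`x_nm`,
#'   `y_nm`), `azimuth_deg` (of the centre, relative to the image centre),
#'   `local_twist_deg`, `local_p_M_nm`, `ok`.
#' @export
orientation_map <- function(image, symmetry, a_sub_nm, window_px = 256,
                            stride_px = window_px, min_snr = 4,
                            r_range_nm = NULL) {
  px <- attr(image, "pixel_size_nm")
  if (is.null(px)) stop("missing pixel calibration")
  if (stride_px > window_px)
    warning("stride larger than window: field will have gaps")
  n <- nrow(image)
  if (window_px > n) stop("window larger than image")
  starts <- seq(1, n - window_px + 1, by = stride_px)
  ctr <- (n / 2 + 0.5) * px
  d_fac <- .d_factor(if (symmetry == "square") "square" else "hex")
  g0 <- 1 / (a_sub_nm * d_fac)
  rows <- list()
  for (i0 in starts) for (j0 in starts) {
    if (!is.null(r_range_nm)) {
      r_ctr <- sqrt(((j0 - 1 + window_px / 2) * px - ctr)^2 +
                    ((i0 - 1 + window_px / 2) * px - ctr)^2)
      if (r_ctr < r_range_nm[1] || r_ctr > r_range_nm[2]) next
    }
    sub <- unclass(image)[i0:(i0 + window_px - 1), j0:(j0 + window_px - 1)]
    sub <- structure(sub, pixel_size_nm = px,
                     class = c("micrograph", "matrix", "array"))
    spec <- power_spectrum(sub, window = "hann")
    rpt <- tryCatch({
      pk <- detect_peaks(spec, min_snr = min_snr,
                         annulus = c(0.7 * g0, 1.3 * g0))
      estimate_lattice(pk, symmetry)
    }, error = function(e) NULL)
    cx <- (j0 - 1 + window_px / 2) * px
    cy <- (i0 - 1 + window_px / 2) * px
    tw <- if (!is.null(rpt)) rpt$twist_deg else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      x_nm = cx, y_nm = cy,
      azimuth_deg = (atan2(cy - ctr, cx - ctr) * 180 / pi) %% 360,
      local_twist_deg = tw,
      local_p_M_nm = if (!is.na(tw)) moire_period(a_sub_nm, tw) else NA_real_,
      ok = !is.na(tw))
  }
  out <- do.call(rbind, rows)
  attr(out, "window_px") <- window_px
  attr(out, "stride_px") <- stride_px
  class(out) <- c("orientation_field", class(out))
  out
}

#' Azimuthal twist profile of an orientation field
#'
#' Restricts an orientation field to windows whose centres lie in a radial
#' band around the image centre, orders them by azimuth along the requested
#' direction, and counts discontinuities (circular steps exceeding
#' `jump_threshold`).
#'
#' @param field An `orientation_field` from [orientation_map()].
#' @param centre_nm Image centre `c(x, y)` in nm.
#' @param r_range_nm Radial band `c(r_lo, r_hi)` in nm.
#' @param direction `"cw"` or `"ccw"` ordering.
#' @param jump_threshold Step size (deg) counted as a discontinuity.
#' @return List with `profile` (data.frame ordered along the direction:
#'   `azimuth_deg`, `local_twist_deg`, `local_p_M_nm`), `n_jumps`, and
#'   `monotone_fraction` (fraction of non-jump steps moving monotonically).
#' @export
azimuthal_twist_profile <- function(field, centre_nm, r_range_nm,
                                    direction = c("cw", "ccw"),
                                    jump_threshold = 3) {
  direction <- match.arg(direction)
  r <- sqrt((field$x_nm - centre_nm[1])^2 + (field$y_nm - centre_nm[2])^2)
  sel <- field[r >= r_range_nm[1] & r <= r_range_nm[2] & field$ok, , drop = FALSE]
  if (nrow(sel) < 3) stop("too few resolvable windows in the radial band")
  sel <- sel[order(sel$azimuth_deg, decreasing = (direction == "cw")), ,
             drop = FALSE]
  tw <- sel$local_twist_deg
  steps <- diff(c(tw, tw[1]))          # circular sequence of steps
  jumps <- abs(steps) > jump_threshold
  n_jumps <- sum(jumps)
  sgn <- sign(steps[!jumps & steps != 0])
  monotone_fraction <- if (length(sgn)) max(mean(sgn > 0), mean(sgn < 0)) else 1
  list(profile = sel, n_jumps = n_jumps, monotone_fraction = monotone_fraction)
}
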