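#' Configuration of a seeded-growth simulation
#'
#' Well-mixed stochastic model of competing seeded and homogeneous nucleation
#' with growth, in reduced units. Events: homogeneous nucleation (rate
#' `A_homo N_homo(T) u`, `u` = free tile fraction), per-seed heterogeneous
#' nucleation (rate `A_het site_density_ratio exp(-f dG*/kT)` per seed; each
#' seed nucleates at most once), and per-structure growth (rate
#' `growth_rate_const perimeter(size) u`, perimeter = sqrt(size) for a 2D
#' disc, or 1 for area-independent growth).
#'
#' @param seed_count Number of origami seeds.
#' @param tile_pool Total tiles available.
#' @param T_C Incubation temperature, deg C (below `thermo$T_m_C`).
#' @param thermo A [tile_thermo()].
#' @param wetting A [wetting_spec()].
#' @param growth_rate_const Per-structure attachment rate constant (reduced).
#' @param duration Simulated reduced time (> 0).
#' @param rng_seed Integer RNG seed (mandatory for reproducibility).
#' @param growth_mode `"perimeter"` (attachment rate proportional to
#'   sqrt(size)) or `"constant"`.
#' @param method `"ssa"` (exact Gillespie) or `"tau"` (tau-leaping).
#' @param tau Leap interval for `method = "tau"`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed_count, tile_pool, T_C,
                       thermo = tile_thermo(T_m_C = 45, delta_h = 1, gamma = 8,
                                            A_homo = 1e10, A_het = 1e5,
                                            site_density_ratio = 1),
                       wetting = wetting_spec(psi_deg = 30),
                       growth_rate_const = 50, duration = 10, rng_seed,
                       growth_mode = c("perimeter", "constant"),
                       method = c("ssa", "tau"), tau = 0.01) {
  growth_mode <- match.arg(growth_mode)
  method <- match.arg(method)
  if (missing(rng_seed) || is.null(rng_seed))
    stop("rng_seed is required for reproducibility")
  if (seed_count < 0 || tile_pool < 0) stop("counts must be non-negative")
  if (duration <= 0) stop("duration must be positive")
  stopifnot(inherits(thermo, "tile_thermo"), inherits(wetting, "wetting_spec"))
  structure(list(seed_count = as.integer(seed_count),
                 tile_pool = as.integer(tile_pool), T_C = T_C,
                 thermo = thermo, wetting = wetting,
                 growth_rate_const = growth_rate_const, duration = duration,
                 rng_seed = as.integer(rng_seed), growth_mode = growth_mode,
                 method = method, tau = tau),
            class = "sim_config")
}

# per-event base rates at the configured temperature
.sim_rates <- function(config) {
  th <- config$thermo
  dG <- barrier_homo(config$T_C, th)
  T_K <- config$T_C + 273.15
  list(homo = th$A_homo * exp(-dG / T_K),
       het_per_seed = th$A_het * th$site_density_ratio *
         exp(-config$wetting$f * dG / T_K))
}

#' Run a seeded-growth simulation
#'
#' Exact stochastic simulation (or tau-leaping) of the reduced nucleation +
#' growth model; see [sim_config()] for the event set. Mass is conserved on
#' every trajectory: the sizes of all structures plus the remaining free
#' tiles always sum to the initial pool.
#'
#' @param config A [sim_config()].
#' @return A `sim_result`: list with `structures` (data.frame `seeded`,
#'   `size`), `free_tiles_final`, `n_events`, and the config.
#' @export
simulate_growth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$rng_seed, .simulate_growth_impl(config))
}

.simulate_growth_impl <- function(config) {
  base <- .sim_rates(config)
  pool <- config$tile_pool
  free <- pool
  seeds_left <- config$seed_count
  sizes <- numeric(0)
  seeded <- logical(0)
  t <- 0; n_events <- 0L
  perim <- if (config$growth_mode == "perimeter") sqrt else function(s) rep(1, length(s))
  tau_mode <- config$method == "tau"
  repeat {
    u <- free / pool
    r_homo <- base$homo * u
    r_het <- base$het_per_seed * seeds_left
    r_grow <- if (length(sizes)) config$growth_rate_const * perim(sizes) * u else numeric(0)
    total <- r_homo + r_het + sum(r_grow)
    if (total <= 0 || free == 0) break
    if (tau_mode) {
      dt <- min(config$tau, config$duration - t)
      if (dt <= 0) break
      t <- t + dt
      n_homo <- stats::rpois(1, r_homo * dt)
      n_het <- min(stats::rpois(1, r_het * dt), seeds_left)
      n_grow <- if (length(sizes)) stats::rpois(length(sizes), r_grow * dt) else integer(0)
      need <- n_homo + n_het + sum(n_grow)
      if (need > free) {  # thin events uniformly to respect the pool
        keep <- free / need
        n_homo <- stats::rbinom(1, n_homo, keep)
        n_het <- min(stats::rbinom(1, n_het, keep), seeds_left)
        n_grow <- stats::rbinom(length(n_grow), n_grow, keep)
      }
      if (n_homo > 0) { sizes <- c(sizes, rep(1, n_homo)); seeded <- c(seeded, rep(FALSE, n_homo)) }
      if (n_het > 0) { sizes <- c(sizes, rep(1, n_het)); seeded <- c(seeded, rep(TRUE, n_het)); seeds_left <- seeds_left - n_het }
      if (length(n_grow)) sizes[seq_along(n_grow)] <- sizes[seq_along(n_grow)] + n_grow
      free <- pool - sum(sizes)
      n_events <- n_events + n_homo + n_het + sum(n_grow)
      if (t >= config$duration) break
    } else {
      dt <- stats::rexp(1, total)
      if (t + dt > config$duration) break
      t <- t + dt
      pick <- stats::runif(1) * total
      if (pick < r_homo) {
        sizes <- c(sizes, 1); seeded <- c(seeded, FALSE); free <- free - 1
      } else if (pick < r_homo + r_het) {
        sizes <- c(sizes, 1); seeded <- c(seeded, TRUE)
        seeds_left <- seeds_left - 1; free <- free - 1
      } else {
        i <- findInterval(pick - r_homo - r_het, cumsum(r_grow),
                          rightmost.closed = FALSE) + 1L
        i <- min(i, length(sizes))
        sizes[i] <- sizes[i] + 1; free <- free - 1
      }
      n_events <- n_events + 1L
    }
  }
  structure(list(structures = data.frame(seeded = seeded, size = sizes),
                 free_tiles_final = free, n_events = n_events,
                 config = config),
            class = "sim_result")
}

#' Summarise a growth-simulation result
#'
#' @param result A `sim_result` from [simulate_growth()].
#' @param min_size Only structures of at least this many tiles are counted
#'   (small sub-critical clusters are not scored as lattices).
#' @return List with `seeded_fraction` (percent), `mean_size`, `sd_size`,
#'   `n_structures`. All `NA` (undefined sentinel) when no structure reaches
#'   `min_size`.
#' @export
summarize_growth <- function(result, min_size = 1) {
  stopifnot(inherits(result, "sim_result"))
  s <- result$structures[result$structures$size >= min_size, , drop = FALSE]
  if (nrow(s) == 0)
    return(list(seeded_fraction = NA_real_, mean_size = NA_real_,
                sd_size = NA_real_, n_structures = 0L))
  list(seeded_fraction = 100 * mean(s$seeded),
       mean_size = mean(s$size),
       sd_size = if (nrow(s) > 1) stats::sd(s$size) else 0,
       n_structures = nrow(s))
}

#' Run replicate simulations and collect summaries
#'
#' Replicate r uses `rng_seed + r` so paired comparisons across configs share
#' seeds.
#'
#' @param config A [sim_config()] (its `rng_seed` is the base seed).
#' @param n_rep Number of replicates.
#' @param min_size Passed to [summarize_growth()].
#' @return A data.frame with one row per replicate: `replicate`,
#'   `seeded_fraction`, `mean_size`, `sd_size`, `n_structures`.
#' @export
run_replicates <- function(config, n_rep = 20, min_size = 1) {
  rows <- lapply(seq_len(n_rep), function(r) {
    cfg <- config
    cfg$rng_seed <- config$rng_seed + r
    sm <- summarize_growth(simulate_growth(cfg), min_size = min_size)
    data.frame(replicate = r, seeded_fraction = sm$seeded_fraction,
               mean_size = sm$mean_size, sd_size = sm$sd_size,
               n_structures = sm$n_structures)
  })
  do.call(rbind, rows)
}
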