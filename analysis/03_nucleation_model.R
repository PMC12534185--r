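#!/usr/bin/env Rscript
# CNT wetting model: classify the capture-pattern cooperativity modes, map
# them to contact angles, and compute nucleation-rate curves in the low- and
# high-wetting regimes.
#
# Outputs: results/nucleation_curves_{high,low}_wetting.csv,
#          results/capture_modes.csv

library(dnamoire)
dir.create("results", showWarnings = FALSE)

grid <- function(nz, nx) matrix(TRUE, nz, nx)
patterns <- list(
  `S(F)`  = capture_pattern(grid(8, 8), grid(8, 8)),
  `S(P1)` = capture_pattern({m <- grid(8, 8); m[, seq(2, 8, 2)] <- FALSE; m},
                            grid(8, 8)),
  `S(P3)` = capture_pattern(outer(1:8, 1:8, function(i, j) (i + j) %% 2 == 0),
                            grid(8, 8)),
  `S(N)`  = capture_pattern(grid(8, 8), matrix(FALSE, 8, 8)))

rows <- lapply(names(patterns), function(nm) {
  cl <- classify_capture_pattern(patterns[[nm]])
  psi <- contact_angle_for_mode(cl)
  data.frame(seed = nm, mode = cl$mode, pairs = cl$pair_count,
             max_z_run = cl$max_z_run, psi_deg = psi,
             f = wetting_factor(psi))
})
modes <- do.call(rbind, rows)
write.csv(modes, "results/capture_modes.csv", row.names = FALSE)
print(modes, row.names = FALSE)

th <- tile_thermo(T_m_C = 45, delta_h = 1, gamma = 8)
Tg <- seq(25, 44.5, by = 0.1)
high <- nucleation_rates(Tg, th, wetting_spec(psi_deg = 30))   # fully cooperative
low <- nucleation_rates(Tg, th, wetting_spec(psi_deg = 90))    # partial, z-continuous
write_curves_csv(high, "results/nucleation_curves_high_wetting.csv")
write_curves_csv(low, "results/nucleation_curves_low_wetting.csv")
cat(sprintf("selectivity R at %.1f C: high wetting %.3g, low wetting %.3g\n",
            max(Tg), high$R[length(Tg)], low$R[length(Tg)]))
cat("R rises toward T_m in both regimes; the high-wetting curve dominates pointwise:",
    all(high$R > low$R), "\n")
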