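#!/usr/bin/env Rscript
# Closed-form moire predictions: the graphene anchor point, the square
# bilayer, the gradient-seed faces, and the hybrid square+kagome stack in
# reciprocal space.
#
# Outputs: results/moire_predictions.csv, results/hybrid_moire_g.csv

library(dnamoire)
dir.create("results", showWarnings = FALSE)

cases <- data.frame(
  case  = c("graphene_magic_angle", "square_bilayer_dried",
            "gradient_face_b", "gradient_face_a"),
  a_sub = c(0.246, 2.2, 2.2, 2.2),
  theta = c(1.1, 3.9, 2.8, 13.7))
cases$p_M_nm <- round(moire_period(cases$a_sub, cases$theta), 1)
cases$theta_back <- round(twist_from_period(cases$a_sub, cases$p_M_nm), 2)
write.csv(cases, "results/moire_predictions.csv", row.names = FALSE)
print(cases, row.names = FALSE)

# hybrid stack: all first-order difference vectors of square(2.2) over
# kagome(4.4) at the square-seed spacer twist
sq <- reciprocal_basis(lattice_spec("square", hydration = "dried"))
kg <- reciprocal_basis(lattice_spec("kagome", hydration = "dried"))
mr <- moire_reciprocal(sq, kg, 3.8)
gm <- data.frame(gx = mr$g_m[, 1], gy = mr$g_m[, 2],
                 mag = sqrt(rowSums(mr$g_m^2)))
write.csv(gm, "results/hybrid_moire_g.csv", row.names = FALSE)
cat(sprintf("hybrid square+kagome at 3.8 deg: fundamental |g_m| = %.4f nm^-1 (%.1f nm)\n",
            mr$min_nonzero_g, mr$p_from_g))
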