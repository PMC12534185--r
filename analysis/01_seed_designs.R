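#!/usr/bin/env Rscript
# Seed geometry: compile the built-in origami seed designs into layer stacks
# and tabulate their cross-sections.
#
# Outputs: results/seed_stacks/*.json, results/seed_cross_sections.csv

library(dnamoire)
dir.create("results/seed_stacks", showWarnings = FALSE, recursive = TRUE)

rows <- list()
for (name in c("S", "H", "SG")) {
  seed <- seed_preset(name)
  hl <- build_cross_section(seed$cross_section)
  st <- compile_stack(seed)
  write_stack_json(st, file.path("results/seed_stacks",
                                 paste0(seed$name, "_stack.json")))
  rows[[name]] <- data.frame(
    seed = seed$name, array = seed$cross_section$array_type,
    helices = hl$helix_count, layers = nrow(st),
    total_height_nm = round(attr(st, "total_height_nm"), 1),
    top_orientation_deg = if (nrow(st)) st$orientation_deg[nrow(st)] else NA)
  cat(sprintf("%s: %d helices (%s array), %d layers, %.1f nm tall, top layer at %.1f deg\n",
              seed$name, hl$helix_count, seed$cross_section$array_type,
              nrow(st), attr(st, "total_height_nm"),
              st$orientation_deg[nrow(st)]))
}
cs <- do.call(rbind, rows)
write.csv(cs, "results/seed_cross_sections.csv", row.names = FALSE)

faces <- gradient_face_orientations(seed_preset("SG"))
cat(sprintf("gradient seed faces: b = %.1f deg, a = %.1f deg\n",
            faces["theta_b"], faces["theta_a"]))
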