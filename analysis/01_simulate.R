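#!/usr/bin/env Rscript
# Stage 1: simulate the study inputs.
#
# Builds the synthetic basis-spectra library (plasma, RBC, filter, ice),
# renders three thrombus-aspirate scenes as ENVI cubes with ground-truth
# label maps, and draws a 40-patient cohort whose IMR follows the
# exponential model in the k-fractions. Everything downstream
# (02_cluster, 03_unmix, 04_cohort_models) reads from results/sim/.

library(thrombospectra)

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2026L

basis <- make_basis_spectra(seed = seed)
write_basis_library(basis, file.path(out, "basis.csv"))
cat("basis library written:", paste(names(basis$components), collapse = ", "), "\n")

clean <- make_cube(demo_scene(64, 64, noise_sd = 0, seed = seed), basis)
noise_sd <- 0.03 * diff(range(clean$cube$values))
cat(sprintf("scene noise sd: %.4f reflectance units (3%% of signal range)\n",
            noise_sd))

for (i in 1:3) {
  sc <- demo_scene(64, 64, noise_sd = noise_sd, seed = seed + i)
  sim <- make_cube(sc, basis, sample_id = sprintf("P%03d", i))
  write_cube(sim$cube, file.path(out, sprintf("cube_P%03d", i)))
  write.csv(data.frame(row = as.vector(row(sim$truth$label_map)),
                       col = as.vector(col(sim$truth$label_map)),
                       kind = as.vector(sim$truth$label_map)),
            file.path(out, sprintf("truth_P%03d.csv", i)), row.names = FALSE)
  cat(sprintf("cube P%03d: true thrombus area fraction %.3f\n",
              i, sim$truth$true_area_fraction))
}

spec <- cohort_spec(40, model = "exp",
                    noise_sd = noise_sd_from_range(
                      cohort_spec(40, model = "exp", noise_sd = 0, seed = seed),
                      0.1),
                    score_levels = 3:5, seed = seed)
cohort <- make_cohort(spec)
write.csv(cohort, file.path(out, "cohort.csv"), row.names = FALSE)
cat(sprintf("cohort: %d patients, IMR %.1f-%.1f U, %d with score 4-5\n",
            nrow(cohort), min(cohort$imr), max(cohort$imr),
            sum(cohort$thrombus_score %in% 4:5)))
cat("done; inputs in", out, "\n")
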