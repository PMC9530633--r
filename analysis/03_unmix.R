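#!/usr/bin/env Rscript
# Stage 3: per-pixel basis-spectrum unmixing.
#
# Decomposes each pixel of the first simulated cube into offset + plasma +
# RBC + filter + ice contributions by non-negative least squares, writes
# the coefficient maps as CSV matrices and false-colour rasters, and
# summarises goodness of fit (chi2 per degree of freedom).

library(thrombospectra)

sim <- "results/sim"; out <- "results/unmix"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

basis <- read_basis_library(file.path(sim, "basis.csv"))
cube <- read_cube(Sys.glob(file.path(sim, "cube_*.hdr"))[1])
cat("unmixing", cube$sample_id, "\n")

cm <- fit_cube(cube, basis, mode = "nnls")
for (nm in names(cm$maps)) {
  write.csv(cm$maps[[nm]], file.path(out, paste0(nm, ".csv")),
            row.names = FALSE)
}
imgs <- render_coefficient_maps(cm, shared_scale = FALSE)
for (nm in names(imgs))
  write_raster(imgs[[nm]], file.path(out, paste0(nm, ".png")))

cat(sprintf("mean chi2/dof = %.4g (dof = %d); coefficient means:\n",
            mean(cm$maps$chi2) / cm$dof, cm$dof))
for (nm in c("c0", "plasma", "rbc", "filter", "ice"))
  cat(sprintf("  %-7s %.4f\n", nm, mean(cm$maps[[nm]])))
cat("maps written to", out, "\n")
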