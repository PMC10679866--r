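#!/usr/bin/env Rscript
# Steady-state phase grid: fraction of baseline mitochondrial TMRM
# retained over an 8x8 grid of bath ThT dose x light-level multiplier.
# Grid CSV layout: dose as first column, one column per light level.

suppressMessages(library(thtmito))
dir.create("results", showWarnings = FALSE)

grid <- run_phase_grid()
doses <- attr(grid, "dose_axis")
levels <- attr(grid, "photo_axis")

out <- data.frame(dose_uM = doses, unclass(grid), check.names = FALSE)
names(out)[-1] <- paste0("light_", format(levels, trim = TRUE))
utils::write.csv(out, "results/phase_grid.csv", row.names = FALSE)

cat("normalized steady-state mitochondrial TMRM (rows: dose uM):\n")
plain <- matrix(grid, nrow(grid), dimnames = dimnames(grid))
print(round(plain, 3))
cat(sprintf("\nthreshold dose (norm < 0.5 at max light): %.2g uM\n",
            threshold_dose(grid)))
write_manifest("phase_grid",
               list(doses = doses, photo_levels = levels),
               seed = NULL, outputs = "results/phase_grid.csv",
               path = "results/phase_grid_manifest.json")
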