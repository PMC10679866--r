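#!/usr/bin/env Rscript
# Sensitivity of the dose/light phase grid to the Hill-term parameters:
# half-saturations (Km, Kc scaled together) and cooperativity n.

suppressMessages(library(thtmito))
dir.create("results", showWarnings = FALSE)

rows <- list()
for (spec in list(list(vary = "K", values = c(0.5, 1, 2)),
                  list(vary = "n", values = c(2, 4, 6)))) {
  sens <- run_sensitivity(vary = spec$vary, values = spec$values)
  for (k in seq_along(spec$values)) {
    g <- sens$grids[[k]]
    doses <- attr(g, "dose_axis")
    grad <- max(abs(diff(g[, ncol(g)]) / diff(doses)))
    rows[[length(rows) + 1L]] <- data.frame(
      varied = spec$vary, value = spec$values[k],
      threshold_dose_uM = sens$threshold_dose[k],
      max_dose_gradient = grad)
    utils::write.csv(
      data.frame(dose_uM = doses, unclass(g), check.names = FALSE),
      sprintf("results/sensitivity_%s_%g.csv", spec$vary, spec$values[k]),
      row.names = FALSE)
  }
}
tab <- do.call(rbind, rows)
utils::write.csv(tab, "results/sensitivity_summary.csv", row.names = FALSE)
cat("sensitivity of the depolarization threshold:\n")
print(tab, row.names = FALSE)
cat("\nlarger K shifts the threshold dose up; larger n sharpens the\n")
cat("dose transition (steeper maximum gradient along the dose axis).\n")
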