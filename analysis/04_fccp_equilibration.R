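#!/usr/bin/env Rscript
# Dye handling controls: equilibration curves after bath addition, and
# the FCCP depolarization time course against a mock injection.

suppressMessages(library(thtmito))
dir.create("results", showWarnings = FALSE)

eq <- run_equilibration(horizon = 1200)
utils::write.csv(eq$summary, "results/equilibration_curves.csv",
                 row.names = FALSE)
s <- eq$summary
t50 <- function(v) s$time_s[min(which(v >= 0.5))] - 120
cat(sprintf("equilibration half-rise after addition: ThT %.1f s, TMRM %.1f s\n",
            t50(s$tht_norm), t50(s$tmrm_norm)))

fccp <- run_fccp_experiment(mock = FALSE)
mock <- run_fccp_experiment(mock = TRUE)
both <- rbind(cbind(condition = "fccp", fccp$summary),
              cbind(condition = "mock", mock$summary))
utils::write.csv(both, "results/fccp_timecourse.csv", row.names = FALSE)

norm <- function(x) x / x[1]
cat(sprintf("final mitochondrial TMRM (fold of first frame): FCCP %.3f, mock %.3f\n",
            tail(norm(fccp$summary$tmrm_mito), 1),
            tail(norm(mock$summary$tmrm_mito), 1)))
cat(sprintf("final mitochondrial ThT  (fold of first frame): FCCP %.3f, mock %.3f\n",
            tail(norm(fccp$summary$tht_mito), 1),
            tail(norm(mock$summary$tht_mito), 1)))
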