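#!/usr/bin/env Rscript
# Calibration scan for the default parameter set.
#
# The package's defaults were fixed by requiring, in order:
#   (1) the critical actin activity on a single junction (closed form,
#       critical_beta_single) inside the 5-6 operating window;
#   (2) the onset of stick-slip migration on an infinite line near
#       beta0 = 10, above the junction-triggered band;
#   (3) within-episode total-length excursions of about a factor 2 in the
#       stick-slip / slow-mode regimes, with the slow-mode onset detected
#       inside the 9-12 activity window;
#   (4) a mean junction escape time that first decreases with beta0 and
#       then rises sharply once the slow mode dominates.
# This script re-derives the relevant scans for the shipped defaults and a
# few neighbouring parameter sets, so the choice can be audited or redone.

suppressMessages(library(branchtax))

candidates <- list(
  default = model_params(),
  softer  = update_params(model_params(), k = 0.6),
  stiffer = update_params(model_params(), k = 1.1, D = 2.2),
  lower_fs = update_params(model_params(), f_s = 15)
)

for (nm in names(candidates)) {
  p <- candidates[[nm]]
  cat("==", nm, "\n")
  bc <- tryCatch(critical_beta_single(p), error = function(e) NA)
  cat(sprintf("  beta_c = %.4f\n", bc))
  ss <- stick_slip_threshold_1d(p, beta_grid = seq(8, 13, by = 0.5),
                                t_run = 100)
  cat(sprintf("  1D stick-slip onset = %s\n", format(ss$threshold)))
  sw <- run_junction_sweep(beta0_grid = c(7, 8, 9.5, 11), p = p,
                           sigma = 0.1, reps = 25, seed = 1)
  print(sw[, c("beta0", "T_esc_mean", "P_slow", "ratio_median")], digits = 3)
}
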