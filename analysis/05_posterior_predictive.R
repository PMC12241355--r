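#!/usr/bin/env Rscript
# Posterior predictive check: simulate replicate sessions at each fitted
# subject-session's MAP parameters on the subject's own realised design and
# compare accuracy-by-iteration-by-set-size learning curves with the
# "observed" (simulated-cohort) curves.

library(rlwm)
set.seed(20260929)

pop <- readRDS("results/population.rds")
fits <- readRDS("results/fits.rds")

ppc <- run_ppc(pop, fits, n_ppc_draws = 20)
print(ppc)
write_trials(ppc$cells, "results/ppc_cells.csv")

worst <- ppc$cells[which.max(ppc$cells$abs_diff), ]
cat(sprintf("worst cell: set size %d, iteration %d (observed %.3f vs simulated %.3f)\n",
            worst$set_size, worst$iteration, worst$observed, worst$simulated))
cat(if (ppc$max_abs_diff < 0.05)
  "fitted model reproduces the learning curves within 5 percentage points everywhere\n"
  else "systematic misfit detected in at least one cell\n")
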