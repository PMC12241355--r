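#!/usr/bin/env Rscript
# Simulate the study cohort: 30 subjects, three counterbalanced drug sessions
# (placebo, methylphenidate, sulpiride), a standardised dopamine-synthesis
# proxy per subject, and the default covariate->parameter effect map (higher
# synthesis capacity -> more WM reliance; sulpiride -> less reliance, faster
# decay; methylphenidate x synthesis -> higher learning rate). Writes the
# trial tables and covariates that the later scripts consume.

library(rlwm)
dir.create("results", showWarnings = FALSE)
set.seed(20260925)

spec <- population_spec(n_subjects = 30, kappa_effort = 0.05)
pop <- generate_population(spec)

write_trials(pop$training, "results/training_trials.csv")
write_trials(pop$test, "results/test_trials.csv")
write_trials(pop$subjects, "results/subjects.csv")
write_trials(pop$params, "results/generative_params.csv")
saveRDS(pop, "results/population.rds")   # designs for refitting / PPC

cat(sprintf("simulated %d subjects x %d sessions: %d training and %d test trials\n",
            spec$n_subjects, length(spec$sessions),
            nrow(pop$training), nrow(pop$test)))
cat(sprintf("overall training accuracy %.3f; +2-point share on correct %.3f\n",
            mean(pop$training$correct),
            mean(pop$training$points[pop$training$correct == 1] == 2)))
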