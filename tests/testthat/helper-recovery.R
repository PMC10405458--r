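# Heavy shared fixtures for the recovery/adaptation/determinism checks:
# a 22-subject cohort of which the first 12 are used for 4-fold
# cross-validation training and the remaining 10 act as new individuals for
# the gated adaptation. Built once and memoized across test files.

recovery_config <- function() {
  pipeline_config(seed = 42, n_adapt = 0,
                  simulation = list(n_subjects = 22),
                  model = list(split_ratio = 1))
}

recovery_cohort <- function() memo("recovery_cohort", {
  generate_cohort(nirgait:::sim_config_of(recovery_config()))
})

recovery_fit <- function() memo("recovery_fit", {
  suppressMessages(run_fit(recovery_cohort()[1:12], recovery_config()))
})

recovery_adapt <- function() memo("recovery_adapt", {
  run_adapt(recovery_fit(), recovery_cohort(), subject_ids = 13:22)
})

# two independent end-to-end runs of the small pipeline, same config + seed
determinism_pair <- function() memo("determinism_pair", {
  run_once <- function(dir) {
    pc <- pipeline_config(seed = 99, n_adapt = 0,
                          simulation = list(n_subjects = 4, trial_duration = 30),
                          model = list(split_ratio = 1, hidden_units = 16,
                                       max_iterations = 12, patience = 4,
                                       sequence_length = 5),
                          selection = list(k = 40, latent_dim = 10, ae_epochs = 60))
    cohort <- generate_cohort(nirgait:::sim_config_of(pc))
    suppressMessages(run_fit(cohort, pc, out_dir = dir))
    file.path(dir, "metrics.json")
  }
  d1 <- file.path(tempdir(), "det_run1"); d2 <- file.path(tempdir(), "det_run2")
  list(f1 = run_once(d1), f2 = run_once(d2))
})
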