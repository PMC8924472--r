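# Calibrated study conditions for the synthetic cohorts, fixed by a pilot
# sweep of the generator (effect size vs. window-level decoding accuracy at
# the informative latency band, 3-4 participants, 10 seeds per cell):
#
#   code       effect  target feature     acc    off-target feature  acc
#   mean         12    mean              ~0.74   variance           ~0.52
#   variance     12    variance          ~0.81   mean               ~0.50
#   frequency    16    mean_frequency    ~0.64   mean               ~0.54
#   multiscale   16    wavelet           ~0.64   mean               ~0.50
#
# The behavior-recovery conditions use a stronger, low-noise reaction-time
# link so the across-participant rank correlation is detectable with the
# permutation test at the cohort sizes below.
calib <- list(
  mean_es = 12,
  variance_es = 12,
  frequency_es = 16,
  multiscale_es = 16,
  # specificity runs
  spec_participants = 4, spec_trials = 30, spec_electrodes = 8,
  spec_band = c(75, 250), spec_step = 25,
  # behavior-recovery runs
  rt_participants = 12, rt_trials = 50, rt_electrodes = 8,
  rt_link = list(intercept = 1146, slope = 400, noise_sd = 20),
  rt_step = 20, rt_band = c(50, 300), rt_nperm = 4999
)

# small cohort shared by structural tests
tiny_cohort <- function(n_participants = 2, n_categories = 2,
                        trials_per_category = 20, n_electrodes = 4,
                        code = "mean", effect_size = calib$mean_es,
                        seed = 42, ...) {
  cfg <- suppressWarnings(      # deliberately small desk-scale cohorts
    synth_config(n_participants = n_participants,
                 n_categories = n_categories,
                 trials_per_category = trials_per_category,
                 n_electrodes = n_electrodes, code = code,
                 effect_size = effect_size, seed = seed, ...))
  list(config = cfg, cohort = generate_cohort(cfg))
}
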