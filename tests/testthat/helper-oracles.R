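## Small independent helpers used by the tests (kept separate from the
## package implementation on purpose).

## plain polynomial evaluation, ascending coefficients
polyval_asc_test <- function(coefs, x) {
  sapply(x, function(xi) sum(coefs * xi^(seq_along(coefs) - 1)))
}

## standard trial of the validation experiments: 5.8 s flexion-extension,
## 20% excitation amplitude distortion, seed 42
standard_trial <- function(seed = 42, perturbation = 0.2, model = default_model()) {
  generate_trial(trial_spec(seed = seed, excitation_perturbation = perturbation),
                 model = model)
}

## adjustment input (modelling view of a trial) using the true angle
trial_view <- function(tr, theta = tr$theta_true) {
  list(theta = theta, e_meas = tr$e_meas, tau_exp = tr$tau_exp)
}
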