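# Shared expensive fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Noise-free phantom cohorts with varying apex / angles.
phantom_set <- function(n, seed, noise = FALSE) {
  generate_cohort(n, seed = seed, noise = noise,
                  ranges = list(iliac_angle_deg = c(85, 95)))$frames
}

reference_model <- function() {
  if (is.null(.fixtures$model)) {
    train <- phantom_set(200, seed = 4001)
    .fixtures$model <- train_apex_estimator(train, apex_config(seed = 7))
  }
  .fixtures$model
}

heldout_set <- function() {
  if (is.null(.fixtures$heldout))
    .fixtures$heldout <- phantom_set(50, seed = 4900)
  .fixtures$heldout
}
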