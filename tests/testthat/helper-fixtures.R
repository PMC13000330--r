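# Shared fixtures: a generic stimulus space and small simulated datasets.

test_space <- function() build_space(0.05)

# quick synthetic generalisation block with known ground truth
make_block <- function(model, params, v = 0.7, seed = 42, space = test_space()) {
  simulate_generalisation(model, params, v, space, seed = seed)
}

# fast fitting settings for unit tests
fast_fit <- function(trials, model, v, ...) {
  fit_gradient(trials, model, v = v, space = test_space(),
               n_restarts = 2, maxeval_global = 120, ...)
}
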