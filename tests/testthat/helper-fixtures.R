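# Fixtures are always generated in code from the forward models.

mono_syl <- function(A0 = 1000, k = 0.3, duration = 5, rate = 100) {
  simulate_syllectogram(mono_exp_params(A0, k), duration = duration,
                        sampling_rate = rate)
}

noisy_mono_syl <- function(A0 = 1000, k = 0.3, sd = 0.005 * A0, seed = NULL,
                           duration = 5, rate = 100) {
  simulate_syllectogram(mono_exp_params(A0, k), duration = duration,
                        sampling_rate = rate,
                        noise = noise_spec("gaussian-additive", sd),
                        seed = seed)
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_true(all(abs(actual - expected) <= rel_tol * abs(expected)),
              label = sprintf("max rel err %.3g <= %.3g",
                              max(abs(actual - expected) / abs(expected)),
                              rel_tol))
}
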