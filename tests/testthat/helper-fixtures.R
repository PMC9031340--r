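# Shared fixtures: tiny configurations that keep the full pipeline fast.

tiny_network_config <- function(...) {
  args <- utils::modifyList(
    list(volume_shape = c(8L, 8L, 8L), encoder_channels = c(2L, 3L, 4L),
         fc_widths = c(6L, 3L), epochs = 2L, seed = 7L),
    list(...)
  )
  do.call(network_config, args)
}

tiny_cohort <- function(n = 12L, signal_strength = 2, seed = 42L, ...) {
  args <- utils::modifyList(
    list(n_patients = n, volume_shape = c(8L, 8L, 8L),
         signal_strength = signal_strength, seed = seed),
    list(...)
  )
  generate_cohort(do.call(cohort_config, args))
}

# random probability vector from softmax logits, mixed with the uniform
# distribution so every entry is >= 0.01/k: the alpha -> 1 expansion error of
# the THC family, (alpha - 1)/2 * sum(p * log(q)^2), is then provably below
# the 1e-3 test tolerance at alpha = 1 +/- 1e-4
random_prob_vector <- function(k, logit_sd = 1) {
  z <- exp(stats::rnorm(k, sd = logit_sd))
  0.95 * z / sum(z) + 0.05 / k
}

cohort_labels <- function(cohort) {
  vapply(cohort, function(r) as.numeric(r$label), numeric(1))
}
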