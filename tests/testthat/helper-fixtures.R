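# Shared fixture builders.

two_module_config <- function(n_samples = 12, noise_sd = 0,
                              background = 0, seed = 7,
                              pathway = 3, regulators = 2) {
  half <- n_samples %/% 2
  atlas_config(
    modules = list(
      atlas_module("M1", pathway, regulators,
                   block_profile(n_samples, seq_len(half))),
      atlas_module("M2", pathway, regulators,
                   block_profile(n_samples, (half + 1):n_samples))),
    background_genes = background, n_samples = n_samples,
    noise_sd = noise_sd, seed = seed)
}

recovery_config <- function(seed = 1, noise_sd = 0.05) {
  atlas_config(
    modules = list(
      atlas_module("iridoid", 8, 5, block_profile(82, 1:28)),
      atlas_module("vindoline", 8, 5, block_profile(82, 29:55)),
      atlas_module("root", 8, 5, block_profile(82, 56:82))),
    background_genes = 100, n_samples = 82, noise_sd = noise_sd, seed = seed)
}
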