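# Shared fixtures: small scenarios for fast property tests, and a cache so
# the heavyweight full-size runs in the acceptance file are computed once.

tiny_scenario <- function(...) {
  args <- list(h = 7e-3, d = 1.7e-2, k = 10e-3, r0 = 1e-3,
               rd = 0.025 * 0.0254, T = 5e-2, mesh_n = 9, n_freqs = 8)
  over <- list(...)
  args[names(over)] <- over
  do.call(scenario, args)
}

# homogeneous fluid everywhere (water = tissue), no skull layer
homogeneous_scenario <- function(...) {
  tis <- medium("tissue-lossless", 1000, 1500)
  args <- list(h = 0, d = 1.7e-2, k = 10e-3, r0 = 1e-3, rd = 0.025 * 0.0254,
               T = 5e-2, mesh_n = 9, n_freqs = 8,
               media = list(tissue = tis, skull = tis, water = tis))
  over <- list(...)
  args[names(over)] <- over
  do.call(scenario, args)
}

.run_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) assign(key, expr, envir = .run_cache)
  get(key, envir = .run_cache)
}
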