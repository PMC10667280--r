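# Small fixtures shared across test files. Everything is generated in code;
# the expensive baseline fit is computed once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

# fast training configuration for plumbing tests (not for accuracy checks)
quick_config <- function(seed = 1, ...)
  pinn_config(hidden_layers = 2, nodes_per_layer = 10, adam_iters = 300,
              lbfgs_max_iters = 150, polish_iters = 60, seed = seed, ...)

# the scaled-down baseline synthetic case (nx = 100, noise 0.025)
baseline_case <- function(noise_level = 0.025, seed = 11, nx = 100) {
  key <- sprintf("case_%g_%d_%d", noise_level, seed, nx)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- synthetic_tumour_case(nx = nx,
                                                   noise_level = noise_level,
                                                   seed = seed)
  .fixture_cache[[key]]
}

# one full desk-profile fit of the baseline case, shared by several tests
cached_baseline_fit <- function() {
  if (is.null(.fixture_cache$fit)) {
    case <- baseline_case()
    .fixture_cache$fit <- ifp_pinn(case$pair, case$params, case$plasma,
                                   q = 20, config = pinn_config(seed = 1))
  }
  .fixture_cache$fit
}
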