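# Shared simulated fixtures, built once per test run.

.fx_cache <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (!exists(name, envir = .fx_cache)) {
    assign(name, build(), envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

# small pedigree for unit/property tests (1 Mb diploid, 4 offspring)
fx_small <- function() {
  fx_get("small", function() {
    cfg <- sim_config(genome_length = 5e5, n_no_variant_intervals = 5,
                      no_variant_length = 1e4, n_offspring = 4,
                      shared_ancestry_fraction = 0.08, seed = 101)
    sim <- simulate_pedigree(cfg)
    state <- run_pipeline(sim)
    list(cfg = cfg, sim = sim, state = state)
  })
}

# study-scale pedigree for the acceptance checks (10 Mb diploid genome at
# 3% heterozygosity, 80x depth, default noise, 30 offspring)
fx_big <- function() {
  fx_get("big", function() {
    cfg <- sim_config(genome_length = 5e6, n_offspring = 30, seed = 2024)
    sim <- simulate_pedigree(cfg)
    state <- run_pipeline(sim)
    list(cfg = cfg, sim = sim, state = state)
  })
}

# spiked mutations + observations + detection on the small fixture
fx_small_detect <- function() {
  fx_get("small_detect", function() {
    fx <- fx_small()
    set.seed(7)
    spikes <- spike_mutations(fx$sim, fx$state)
    bundle <- simulate_observations(fx$sim, fx$state, spikes)
    # counterpart-less PZM candidates warn by design; expected on this scale
    det <- suppressWarnings(
      detect_mutations(fx$sim, fx$state, bundle, contig_cap = Inf))
    list(spikes = spikes, bundle = bundle, det = det)
  })
}
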