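# Shared fixtures, built once per test run and cached. The default
# fixture is the generator's own default study condition; the small
# fixture keeps unit tests fast.

.fixture_cache <- new.env(parent = emptyenv())

small_sim_config <- function(seed, ...) {
  sim_config(genome_length = 6e5, n_regions = 100L, n_background = 40L,
             seed = seed, ...)
}

default_fixture <- function() {
  if (is.null(.fixture_cache$default)) {
    dir <- file.path(tempdir(), "bindscape_default_fixture")
    .fixture_cache$default <- gen_fixture(sim_config(seed = 20160411L), dir)
  }
  .fixture_cache$default
}

default_pipeline_result <- function() {
  if (is.null(.fixture_cache$pipeline)) {
    fx <- default_fixture()
    cfg <- pipeline_config(
      ref_rep1 = fx$paths$ref_rep1, ref_rep2 = fx$paths$ref_rep2,
      alt_rep1 = fx$paths$alt_rep1, alt_rep2 = fx$paths$alt_rep2,
      control = fx$paths$control, regions = fx$paths$regions,
      genome = fx$paths$genome, pwm = fx$paths$pwm,
      open_bed = fx$paths$open_bed, dhs_bedgraph = fx$paths$dhs_bedgraph,
      seed = 20160411L)
    out <- file.path(tempdir(), "bindscape_default_out")
    .fixture_cache$pipeline <- suppressMessages(run_pipeline(cfg, out))
  }
  .fixture_cache$pipeline
}

small_fixture <- function() {
  if (is.null(.fixture_cache$small)) {
    dir <- file.path(tempdir(), "bindscape_small_fixture")
    .fixture_cache$small <- gen_fixture(small_sim_config(seed = 101L), dir)
  }
  .fixture_cache$small
}

noise_free_fixture <- function() {
  if (is.null(.fixture_cache$noise_free)) {
    dir <- file.path(tempdir(), "bindscape_nf_fixture")
    .fixture_cache$noise_free <-
      gen_fixture(small_sim_config(seed = 202L, noise = "none",
                                   n_zero_occupancy = 0L), dir)
  }
  .fixture_cache$noise_free
}
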