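# Small simulation configs shared across suites; scaled for fast unit runs.
tiny_config <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, pathogen_genome_len = 8000L,
                   host_genome_len = 20000L, reads_per_sample = 1000L,
                   timepoints = c("3h", "12h"),
                   replicates_per_timepoint = 2L,
                   pathogen_read_fraction = c(0.01, 0.02),
                   n_genes = c(pathogen = 6L, host = 15L))
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

one_sample_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(timepoints = "3h",
                                 replicates_per_timepoint = 1L,
                                 pathogen_read_fraction = 0.01),
                            list(...))
  do.call(tiny_config, c(list(seed = seed), args))
}
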