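# Shared fixtures, built in code and memoized across test files.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# mid-size simulated dataset shared by several test files
shared_sim <- function() {
  memo("sim60", simulate_dataset(
    sim_config(n_cells = 60, events = sim_events(n = 15)), seed = 7
  ))
}

# full pipeline result on the shared dataset
shared_result <- function() {
  memo("res60", {
    sim <- shared_sim()
    suppressMessages(scoval_pipeline(
      sim$counts, sim$bins, sim$layout, sim$snps, sim$depths,
      bulk = sim$bulk, seed = 3
    ))
  })
}

# tiny single-chromosome layout helpers
toy_layout <- function(lengths = c(toy1 = 5e7)) {
  genome_layout(tibble::tibble(chrom = names(lengths),
                               length = unname(lengths)))
}

toy_bins <- function(lengths = c(toy1 = 5e7), target = 5e5) {
  make_variable_bins(toy_layout(lengths), target)
}

# window statistics tibble from explicit haplotype read counts
toy_window_stats <- function(cell_id, window_id, h1, h2) {
  window_log2_ratio(tibble::tibble(
    cell_id = cell_id, window_id = window_id,
    hap1_reads = as.integer(h1), hap2_reads = as.integer(h2)
  ))
}
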