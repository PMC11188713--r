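# Shared fixtures for the test suite.  Everything is generated in code; no
# stored data.

# spike raster from a list of per-cell spike-time vectors
make_raster <- function(spike_list, n_cells = length(spike_list),
                        duration_ms = 1000) {
  cell <- rep(seq_along(spike_list), lengths(spike_list))
  spike_raster(cell, unlist(spike_list), n_cells, duration_ms)
}

# brute-force interval oracle: scan a binary row left to right and record
# the gap preceding every active bin after the first
oracle_intervals <- function(row) {
  out <- integer(0)
  last <- NA_integer_
  for (i in seq_along(row)) {
    if (row[i] == 1) {
      if (!is.na(last)) out <- c(out, i - last - 1L)
      last <- i
    }
  }
  out
}

# surrogate training records for inference tests
surrogate_records <- function(n, seed, noise = 0.05) {
  sw <- sample_sweep(n, seed = seed)
  fx <- surrogate_features(sw$g_i, sw$g_e, surrogate_spec(noise_sd = noise),
                           seed = derive_seed(seed, "feat"))
  cbind(sw, fx, fluct = 1)
}

# planted two-assembly raster: blocks of cells active in alternating epochs
planted_raster <- function(n_per_block = 12, n_bins = 60, period = 10) {
  phase <- ((seq_len(n_bins) - 1) %/% period) %% 2
  a <- matrix(rep(as.integer(phase == 0), each = n_per_block), n_per_block)
  b <- matrix(rep(as.integer(phase == 1), each = n_per_block), n_per_block)
  ca_raster(rbind(a, b))
}
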