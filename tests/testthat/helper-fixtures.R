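# Shared fixture builders. Tests use a shrunken well (fewer partitions,
# smaller rolling window) wherever the full 20,480-partition platform size
# is not itself the thing under test.

test_panel <- function(partitions = 2048L, window_size = 201L, ...) {
  p <- default_prototype_panel()
  p$partitions_per_well <- as.integer(partitions)
  p$normalization <- normalization_config(window_size = window_size)
  p
}

all_probe_ids <- function(panel = default_prototype_panel()) {
  vapply(panel$probes, `[[`, "", "probe_id")
}

# constant-fluorescence partition table: every channel reads `level` RFU at
# all four temperatures (+ optional per-row jitter matrix)
flat_table <- function(n = 64L, level = 3000, well_id = "flat") {
  fl <- matrix(level, n, 16L,
               dimnames = list(NULL, meltplex:::fluor_columns()))
  partition_table(well_id, fl)
}

# a valid single-probe spec for mutation in validation tests
base_probe <- function(...) {
  args <- list(probe_id = "PX-A", locus_id = "PX", allele = "A",
               channel = "blue", melt_window = 1L, threshold = 1.08,
               tm_final_hairpin = 66, amplitude = 1)
  args[names(list(...))] <- list(...)
  do.call(probe_spec, args)
}
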