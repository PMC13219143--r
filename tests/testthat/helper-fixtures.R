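# Shared fixtures built in code.

# Degenerate spec: all SDs 0, so every replicate equals its cell mean.
degenerate_spec <- function(replicates = 3L, seed = 1L) {
  cells <- default_cell_parameters()
  cells$soil_sd <- 0
  cells$baf_sd <- 0
  cells$veg_sd <- ifelse(is.na(cells$veg_sd), NA, 0)
  cells$ph_sd <- 0
  cells$som_sd <- 0
  synthetic_spec(cells = cells, replicates = replicates, seed = seed)
}

# A small mixed-phase UBM record table.
mixed_phase_records <- function() {
  tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 2),
    phase = rep(c("gastric", "gastrointestinal"), 2),
    pb_bac_mgkg = c(250, 120, 110, 60),
    pb_total_mgkg = rep(c(550, 260), each = 2)
  )
}

# QC batch whose arithmetic echoes typical assay performance.
qc_batch <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3", "s2", "s3", "blank1", "blank2", "ref1"),
    role = c("sample", "sample", "sample", "duplicate", "duplicate",
             "blank", "blank", "reference"),
    pb_bac_mgkg = c(100, 100, 100, 100, 110, 2, 2, 43.45)
  )
}
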