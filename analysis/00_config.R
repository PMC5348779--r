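# Shared settings for the numbered analysis scripts. Every script
# re-creates the dataset deterministically from this config, so the steps
# are independently re-runnable. Scale: nine breeds at a balanced 48
# animals each and 6,000 SNPs -- small enough that every script runs in
# seconds while keeping the multi-breed structure of a 50K-array study.

library(capripop)

STUDY_SEED <- 20260924
OUT_DIR <- "results"
dir.create(OUT_DIR, showWarnings = FALSE, recursive = TRUE)

study_config <- function() {
  sim_config(n_breeds = 9, n_per_breed = 48, n_snps = 6000,
             breed_labels = default_breed_design()$breed,
             seed = STUDY_SEED)
}

# One breed carries a selective sweep on chromosome 7 (40 consecutive
# SNPs), giving the scan and the local trees a known target.
SWEEP_BREED <- "LA"
sweep_region <- function(map) {
  cols <- which(map$chromosome == 7)[61:100]
  c(start = map$position_bp[cols[1]], end = map$position_bp[cols[40]])
}

study_dataset <- function(with_sweep = TRUE) {
  ds <- simulate_breeds(study_config())
  if (with_sweep) {
    r <- sweep_region(ds$map)
    ds <- inject_sweep(ds, sweep_spec(SWEEP_BREED, 7, r["start"], r["end"],
                                      s = 0.9), seed = STUDY_SEED + 1)
  }
  qc_filter(ds)$dataset
}

ear_codes <- function() {
  des <- default_breed_design()
  stats::setNames(des$ear_code, des$breed)
}

write_tsv <- function(x, name) {
  path <- file.path(OUT_DIR, name)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
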