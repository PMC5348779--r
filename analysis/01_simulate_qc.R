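#!/usr/bin/env Rscript
# Simulate the nine-breed study dataset and apply array QC.

source("analysis/00_config.R")

ds_raw <- simulate_breeds(study_config())
qc <- qc_filter(ds_raw)

message(sprintf("simulated %d animals x %d SNPs across %d breeds",
                n_individuals(ds_raw), n_markers(ds_raw),
                length(unique(ds_raw$samples$breed))))
message(sprintf("QC retained %d / %d SNPs (MAF >= 0.01, call rate >= 0.95, autosomal)",
                qc$report$n_retained, qc$report$n_input_snps))

write_tsv(qc$report, "qc_report.tsv")
write_tsv(as.data.frame(table(breed = qc$dataset$samples$breed)),
          "sample_counts.tsv")
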