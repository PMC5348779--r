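#!/usr/bin/env Rscript
# Runs of homozygosity: false-positive-controlled detection, planted
# ground truth, per-breed summaries and length categories.

source("analysis/00_config.R")

ds <- study_dataset(with_sweep = FALSE)
het <- mean(observed_heterozygosity(ds, per = "snp"), na.rm = TRUE)
bound <- lencz_min_snps(n_markers(ds), n_individuals(ds), alpha = 0.05,
                        het = het)
message(sprintf("minimum ROH length: %.2f SNPs (ceiling %d) at mean het %.3f",
                bound$l_real, bound$l, het))

# plant one long homozygous segment in a handful of animals
set.seed(STUDY_SEED)
targets <- sample(ds$samples$sample_id, 12)
plan <- data.frame(sample_id = targets,
                   chromosome = sample(29, 12, replace = TRUE),
                   start_bp = 2e6)
plan$end_bp <- plan$start_bp + round(runif(12, 3e6, 8e6))
planted <- plant_roh(ds, plan, seed = STUDY_SEED + 2)

segments <- detect_roh(planted, roh_params(min_snps = bound$l,
                                           min_length_kb = 500))
write_tsv(segments, "roh_segments.tsv")
message(sprintf("detected %d segments in %d carriers (12 planted)",
                nrow(segments), length(unique(segments$sample_id))))

write_tsv(summarize_roh(segments, planted), "roh_summary.tsv")
if (nrow(segments)) {
  cats <- roh_length_categories(segments)
  write_tsv(cbind(breed = rownames(cats), as.data.frame(cats)),
            "roh_length_categories.tsv")
}
froh <- f_roh(planted, segments)
message(sprintf("mean F_ROH among carriers: %.4f",
                mean(froh[targets])))
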