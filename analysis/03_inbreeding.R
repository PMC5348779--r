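#!/usr/bin/env Rscript
# Five inbreeding estimators and their correlations. The genomic
# estimators use within-breed allele frequencies; pedigree inbreeding
# comes from a simulated pedigree with occasional full-sib matings, so a
# subset of individuals carries known inbreeding loops.

source("analysis/00_config.R")

ds <- study_dataset(with_sweep = FALSE)
segments <- detect_roh(ds, roh_params(min_snps = 25))

tab <- data.frame(sample_id = ds$samples$sample_id,
                  breed = ds$samples$breed,
                  F_EH = f_excess_homozygosity(ds, per_breed = TRUE),
                  F_VR = f_vanraden(ds, per_breed = TRUE),
                  F_LEUT = f_leutenegger(ds, per_breed = TRUE),
                  F_ROH = f_roh(ds, segments), row.names = NULL)

# pedigree counterpart on a matched-size population
ped <- simulate_pedigree(n_founders = 108, n_generations = 3,
                         full_sib_mating_rate = 0.1, seed = STUDY_SEED)
fped <- f_pedigree(ped)
last_gen <- utils::tail(ped$id, nrow(ds$samples))
tab$F_PED <- unname(fped[as.character(last_gen)])

write_tsv(tab, "inbreeding.tsv")
by_breed <- aggregate(tab[c("F_EH", "F_VR", "F_LEUT", "F_ROH", "F_PED")],
                      list(breed = tab$breed), mean)
write_tsv(by_breed, "inbreeding_by_breed.tsv")
print(by_breed, digits = 3)

cors <- inbreeding_correlations(tab[c("F_EH", "F_VR", "F_LEUT",
                                      "F_ROH", "F_PED")])
utils::write.table(round(cors, 3), file.path(OUT_DIR,
                                             "inbreeding_correlations.tsv"),
                   sep = "\t", quote = FALSE, col.names = NA)
message(sprintf("corr(F_VR, F_LEUT) = %.3f (the two share a formula core)",
                cors["F_VR", "F_LEUT"]))
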