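#!/usr/bin/env Rscript
# Per-breed genetic diversity: polymorphism, heterozygosity, allele
# sharing. On neutral multi-breed data H_O tracks H_E closely; breeds with
# larger drift show lower heterozygosity.

source("analysis/00_config.R")

ds <- study_dataset(with_sweep = FALSE)
div <- breed_diversity_table(ds)
write_tsv(div, "diversity.tsv")
print(div, digits = 3)
message(sprintf("overall mean H_O = %.3f, H_E = %.3f (max |H_O - H_E| = %.4f)",
                mean(div$H_O), mean(div$H_E), max(abs(div$H_O - div$H_E))))

spec <- maf_spectrum(ds, seq(0, 0.5, 0.05))
write_tsv(cbind(breed = rownames(spec), as.data.frame(spec)),
          "maf_spectrum.tsv")
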