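#!/usr/bin/env Rscript
# Reynolds-distance population trees (genome-wide and local to the sweep
# region), the tree-derived kinship, and the single-SNP FLK scan with
# empirically standardized p-values.

source("analysis/00_config.R")

ds <- study_dataset(with_sweep = TRUE)
pf <- allele_freq(ds, per_breed = TRUE)

genome <- nj_tree(reynolds_distance(pf))
write_newick(genome, file.path(OUT_DIR, "genome_tree.nwk"))

r <- sweep_region(ds$map)
loc <- local_tree(ds, 7, r["start"], r["end"])
write_newick(loc, file.path(OUT_DIR, "local_tree_chr7.nwk"))
tip_edge <- match(seq_along(loc$tip.label), loc$edge[, 2])
longest <- loc$tip.label[which.max(loc$edge.length[tip_edge])]
message("longest terminal branch in the local tree: ", longest,
        " (sweep planted in ", SWEEP_BREED, ")")

K <- kinship_from_tree(genome)
flk <- flk_statistic(pf, K)
pv <- pvalues_by_standardization(flk)
out <- cbind(ds$map[c("marker_id", "chromosome", "position_bp")],
             flk = flk, pv)
write_tsv(out, "flk.tsv")

top <- out[order(out$p), ][1:10, ]
message(sprintf("%d of the 10 smallest FLK p-values lie in the sweep region",
                sum(top$chromosome == 7 & top$position_bp >= r["start"] &
                      top$position_bp <= r["end"])))
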