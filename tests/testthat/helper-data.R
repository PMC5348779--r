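# Small random fixtures built in code.

rand_map <- function(m, n_chrom = 3, spacing = 50000) {
  chrom <- sort(rep_len(seq_len(n_chrom), m))
  pos <- unlist(lapply(split(seq_len(m), chrom),
                       function(ix) seq_along(ix) * spacing))
  data.frame(marker_id = sprintf("m%04d", seq_len(m)),
             chromosome = chrom, position_bp = as.integer(pos),
             allele_a = "A", allele_b = "C", row.names = NULL)
}

rand_dataset <- function(n, m, seed = 1, miss_rate = 0.05, n_breeds = 2,
                         n_chrom = 3) {
  set.seed(seed)
  p <- runif(m, 0.05, 0.95)
  d <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  if (miss_rate > 0) d[runif(n * m) < miss_rate] <- NA_integer_
  genotype_dataset(
    d, rand_map(m, n_chrom),
    data.frame(sample_id = sprintf("s%03d", seq_len(n)),
               breed = rep_len(paste0("B", seq_len(n_breeds)), n)))
}

toy_dataset <- function(dosages, n_breeds = 1, spacing = 50000) {
  d <- as.matrix(dosages)
  genotype_dataset(
    d, rand_map(ncol(d), 1, spacing),
    data.frame(sample_id = sprintf("s%03d", seq_len(nrow(d))),
               breed = rep_len(paste0("B", seq_len(n_breeds)), nrow(d))))
}
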