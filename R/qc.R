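#' Quality-control filter for SNPs
#'
#' Retains autosomal SNPs (chromosomes 1-29) with known position, call rate
#' at or above `call_rate_min` and minor allele frequency at or above
#' `maf_min`, mirroring the standard array QC for goat 50K data. A SNP
#' failing several rules is counted once in the report, at the first
#' failure, in the order: position/autosome, call rate, MAF.
#'
#' @param dataset a [genotype_dataset()].
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param call_rate_min minimum call rate (default 0.95).
#' @param autosomes_only drop SNPs outside chromosomes 1-29 (default TRUE).
#' @return list with elements `dataset` (filtered) and `report` (one-row
#'   data.frame of removal counts).
#' @export
qc_filter <- function(dataset, maf_min = 0.01, call_rate_min = 0.95,
                      autosomes_only = TRUE) {
  stopifnot(n_markers(dataset) > 0)
  st <- marker_stats(dataset)
  map <- dataset$map
  bad_pos <- if (autosomes_only) {
    is.na(map$chromosome) | map$chromosome < 1 | map$chromosome > 29 |
      is.na(map$position_bp) | map$position_bp < 1
  } else rep(FALSE, nrow(map))
  bad_cr <- !bad_pos & (st$call_rate < call_rate_min)
  bad_maf <- !bad_pos & !bad_cr & (is.na(st$maf) | st$maf < maf_min)
  keep <- !(bad_pos | bad_cr | bad_maf)
  if (!any(keep))
    stop("empty after QC: no SNPs satisfy the filters")
  report <- data.frame(n_input_snps = nrow(map),
                       n_removed_nonautosomal = sum(bad_pos),
                       n_removed_callrate = sum(bad_cr),
                       n_removed_maf = sum(bad_maf),
                       n_retained = sum(keep))
  list(dataset = subset_dataset(dataset, markers = which(keep)),
       report = report)
}

#' Randomly subsample each breed to a common size
#'
#' Draws `n_per_breed` individuals from every breed without replacement,
#' reproducibly for a given seed; used to compare diversity metrics at a
#' balanced sample size.
#'
#' @param dataset a [genotype_dataset()].
#' @param n_per_breed individuals to keep per breed.
#' @param seed integer RNG seed.
#' @return a [genotype_dataset()] with equal breed sizes.
#' @export
subsample_balanced <- function(dataset, n_per_breed, seed) {
  counts <- table(dataset$samples$breed)
  small <- names(counts)[counts < n_per_breed]
  if (length(small))
    stop("breed(s) smaller than n_per_breed: ", paste(small, collapse = ", "))
  set.seed(seed)
  keep <- unlist(lapply(split(seq_len(nrow(dataset$samples)),
                              dataset$samples$breed),
                        sample, size = n_per_breed))
  subset_dataset(dataset, samples = sort(unname(keep)))
}
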