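resolve_freqs <- function(dataset, freqs, per_breed) {
  if (!is.null(freqs)) return(freqs)
  if (per_breed) allele_freq(dataset, per_breed = TRUE)
  else allele_freq(dataset)
}

# Expand a frequency spec (vector, or breeds x markers matrix) to an
# individuals x markers matrix aligned with the dosage matrix.
freq_matrix <- function(dataset, freqs) {
  n <- nrow(dataset$dosages)
  if (is.matrix(freqs)) {
    freqs[dataset$samples$breed, , drop = FALSE]
  } else {
    matrix(freqs, n, length(freqs), byrow = TRUE)
  }
}

#' Inbreeding from excess of homozygosity (F_EH)
#'
#' Per individual, (1/m) * sum over usable SNPs of
#' 1 - c(2 - c) / (2 p (1 - p)), where c is the dosage and p the reference
#' allele frequency. Missing calls and SNPs monomorphic in the reference
#' set are skipped and m adjusted accordingly. 1 for a fully homozygous
#' individual, negative for an excess of heterozygotes.
#'
#' @param dataset a [genotype_dataset()].
#' @param freqs optional frequency reference: vector over markers, or a
#'   breeds x markers matrix. Default: observed frequencies over all
#'   samples (set `per_breed = TRUE` for within-breed references).
#' @param per_breed use within-breed allele frequencies.
#' @return named numeric vector, one value per individual (`NA` when no
#'   SNP is usable).
#' @export
f_excess_homozygosity <- function(dataset, freqs = NULL, per_breed = FALSE) {
  p <- freq_matrix(dataset, resolve_freqs(dataset, freqs, per_breed))
  d <- dataset$dosages
  denom <- 2 * p * (1 - p)
  usable <- !is.na(d) & !is.na(denom) & denom > 0
  term <- 1 - (d * (2 - d)) / denom
  term[!usable] <- 0
  m <- rowSums(usable)
  out <- rowSums(term) / m
  out[m == 0] <- NA_real_
  stats::setNames(out, dataset$samples$sample_id)
}

#' VanRaden inbreeding (F_VR)
#'
#' Ratio of sums: sum (c - 2p)^2 over the numerator divided by
#' 2 * sum p (1 - p), minus 1. Missing dosages contribute zero to the
#' numerator (equivalent to imputing the mean 2p) while the denominator
#' runs over all polymorphic reference SNPs; this makes the estimate equal
#' to the individual's diagonal of the VanRaden genomic relationship
#' matrix minus one, exactly.
#'
#' @inheritParams f_excess_homozygosity
#' @return named numeric vector per individual.
#' @export
f_vanraden <- function(dataset, freqs = NULL, per_breed = FALSE) {
  p <- freq_matrix(dataset, resolve_freqs(dataset, freqs, per_breed))
  d <- dataset$dosages
  pq <- p * (1 - p)
  poly <- !is.na(pq) & pq > 0
  dev2 <- (d - 2 * p)^2
  dev2[is.na(d) | !poly] <- 0
  denom <- 2 * rowSums(pq * poly, na.rm = TRUE)
  out <- rowSums(dev2) / denom - 1
  out[denom == 0] <- NA_real_
  stats::setNames(out, dataset$samples$sample_id)
}

#' Leutenegger-style inbreeding (F_LEUT)
#'
#' Mean over usable SNPs of (c - 2p)^2 / (2 p (1 - p)). The raw mean has
#' expectation 1 under Hardy-Weinberg, so by default 1 is subtracted to
#' centre the estimator at zero (the scale on which goat-panel breed means
#' are reported); `literal = TRUE` returns the uncentred mean-of-ratios.
#' Missing calls and monomorphic reference SNPs are skipped.
#'
#' @inheritParams f_excess_homozygosity
#' @param literal return the uncentred mean of ratios.
#' @return named numeric vector per individual.
#' @export
f_leutenegger <- function(dataset, freqs = NULL, per_breed = FALSE,
                          literal = FALSE) {
  p <- freq_matrix(dataset, resolve_freqs(dataset, freqs, per_breed))
  d <- dataset$dosages
  denom <- 2 * p * (1 - p)
  usable <- !is.na(d) & !is.na(denom) & denom > 0
  ratio <- (d - 2 * p)^2 / denom
  ratio[!usable] <- 0
  m <- rowSums(usable)
  out <- rowSums(ratio) / m
  out[m == 0] <- NA_real_
  if (!literal) out <- out - 1
  stats::setNames(out, dataset$samples$sample_id)
}

#' Genomic inbreeding from runs of homozygosity (F_ROH)
#'
#' Sum of an individual's ROH segment lengths divided by the total genome
#' length covered by SNPs: the sum over chromosomes of (last SNP position
#' minus first SNP position).
#'
#' @param dataset a [genotype_dataset()] (supplies the SNP-covered genome
#'   length).
#' @param segments data.frame of ROH segments as returned by
#'   [detect_roh()] (columns `sample_id`, `start_bp`, `end_bp`).
#' @return named numeric vector in `[0,1]`, one value per individual
#'   (0 when an individual has no segment).
#' @export
f_roh <- function(dataset, segments) {
  genome_bp <- sum(tapply(dataset$map$position_bp, dataset$map$chromosome,
                          function(x) max(x) - min(x)))
  out <- stats::setNames(rep(0, nrow(dataset$samples)),
                         dataset$samples$sample_id)
  if (nrow(segments)) {
    tot <- tapply(segments$end_bp - segments$start_bp, segments$sample_id,
                  sum)
    out[names(tot)] <- tot / genome_bp
  }
  out
}

#' Pearson correlations among inbreeding estimators
#'
#' Pairwise-complete Pearson correlations across individuals; estimators
#' with zero variance yield `NA` in their row/column.
#'
#' @param table data.frame/matrix of per-individual inbreeding values,
#'   one column per estimator.
#' @return symmetric correlation matrix.
#' @export
inbreeding_correlations <- function(table) {
  x <- as.matrix(table)
  stopifnot(nrow(x) >= 3)
  suppressWarnings(stats::cor(x, use = "pairwise.complete.obs",
                              method = "pearson"))
}
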