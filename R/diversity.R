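#' Observed heterozygosity
#'
#' The number of heterozygous calls divided by the number of non-missing
#' calls. Computed per individual, per SNP, or per breed (mean over the
#' breed's individuals). Individuals (or SNPs) with zero usable calls get
#' `NA` rather than a silent zero.
#'
#' @param dataset a [genotype_dataset()].
#' @param per one of `"individual"`, `"snp"`, `"breed"`.
#' @return named numeric vector.
#' @export
observed_heterozygosity <- function(dataset,
                                    per = c("individual", "snp", "breed")) {
  per <- match.arg(per)
  d <- dataset$dosages
  het <- d == 1L
  if (per == "snp") {
    n <- unname(colSums(!is.na(d)))
    out <- unname(colSums(het, na.rm = TRUE)) / n
    out[n == 0] <- NA_real_
    return(out)
  }
  n <- rowSums(!is.na(d))
  ho <- rowSums(het, na.rm = TRUE) / n
  ho[n == 0] <- NA_real_
  names(ho) <- dataset$samples$sample_id
  if (per == "individual") return(ho)
  c(tapply(ho, dataset$samples$breed, mean, na.rm = TRUE)[
    sort(unique(dataset$samples$breed))])
}

#' Expected heterozygosity under Hardy-Weinberg
#'
#' Per SNP, 2 * p * (1 - p) with p estimated from non-missing calls (no
#' small-sample correction). With `per_breed = TRUE`, frequencies are
#' estimated within each breed and the breed value is the mean over SNPs
#' (monomorphic SNPs contribute 0).
#'
#' @param dataset a [genotype_dataset()].
#' @param per_breed return one value per breed (default) or the per-SNP
#'   vector pooled over all samples.
#' @return named numeric vector (breeds), or numeric vector over SNPs.
#' @export
expected_heterozygosity <- function(dataset, per_breed = TRUE) {
  if (!per_breed) {
    p <- allele_freq(dataset)
    return(2 * p * (1 - p))
  }
  pf <- allele_freq(dataset, per_breed = TRUE)
  he <- 2 * pf * (1 - pf)
  c(rowMeans(he, na.rm = TRUE))
}

#' Proportion of polymorphic SNPs per breed
#'
#' Fraction of SNPs whose within-breed MAF exceeds `maf_threshold`,
#' computed from the breed's calls only.
#'
#' @param dataset a [genotype_dataset()].
#' @param maf_threshold MAF above which a SNP counts as polymorphic
#'   (default 0.01, strict inequality).
#' @return named numeric vector, one value per breed.
#' @export
proportion_polymorphic <- function(dataset, maf_threshold = 0.01) {
  pf <- allele_freq(dataset, per_breed = TRUE)
  maf <- pmin(pf, 1 - pf)
  apply(maf, 1, function(x) mean(x > maf_threshold, na.rm = TRUE))
}

#' Minor-allele-frequency spectrum per breed
#'
#' Histogram of within-breed MAF. Bins are left-closed, right-open, except
#' the last which is closed; counts over SNPs with defined frequency.
#'
#' @param dataset a [genotype_dataset()].
#' @param bin_edges increasing edges within `[0, 0.5]`.
#' @return matrix breeds x bins of counts.
#' @export
maf_spectrum <- function(dataset, bin_edges = seq(0, 0.5, by = 0.1)) {
  stopifnot(all(diff(bin_edges) > 0), min(bin_edges) >= 0,
            max(bin_edges) <= 0.5)
  pf <- allele_freq(dataset, per_breed = TRUE)
  maf <- pmin(pf, 1 - pf)
  nb <- length(bin_edges) - 1
  out <- t(apply(maf, 1, function(x) {
    x <- x[!is.na(x)]
    tabulate(findInterval(x, bin_edges, rightmost.closed = TRUE,
                          all.inside = FALSE), nbins = nb)
  }))
  colnames(out) <- paste0("[", bin_edges[-length(bin_edges)], ",",
                          bin_edges[-1],
                          c(rep(")", nb - 1), "]"))
  out
}

#' Pairwise allele-sharing genetic distance
#'
#' For each pair of individuals, over the m loci where both calls are
#' present, IBS2 and IBS1 count loci sharing two or one allele identical
#' by state; the similarity is D_ST = (IBS2 + 0.5 IBS1) / m and the
#' distance D = 1 - D_ST. On biallelic dosages this is |d1 - d2| / 2
#' averaged over loci. Pairs with no co-called locus get `NA`.
#'
#' @param dataset a [genotype_dataset()] with at least 2 individuals.
#' @return symmetric matrix of D with zero diagonal.
#' @export
pairwise_distance <- function(dataset) {
  d <- dataset$dosages
  n <- nrow(d)
  stopifnot(n >= 2)
  if (!anyNA(d)) {
    m <- ncol(d)
    # sum |di - dj| via decomposition on indicator matrices
    I0 <- (d == 0) + 0; I2 <- (d == 2) + 0
    cnt02 <- tcrossprod(I0, I2)               # opposite homozygotes
    het <- (d == 1) + 0
    hom <- 1 - het
    cnt1 <- tcrossprod(het, hom)              # het vs hom pairs
    s <- 2 * (cnt02 + t(cnt02)) + cnt1 + t(cnt1)
    D <- s / (2 * m)
  } else {
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      di <- d[i, ]
      for (j in (i + 1):n) {
        dj <- d[j, ]
        ok <- !is.na(di) & !is.na(dj)
        m <- sum(ok)
        D[i, j] <- D[j, i] <-
          if (m == 0) NA_real_ else sum(abs(di[ok] - dj[ok])) / (2 * m)
      }
    }
  }
  diag(D) <- 0
  dimnames(D) <- list(dataset$samples$sample_id, dataset$samples$sample_id)
  D
}

#' Per-breed genetic diversity summary table
#'
#' One row per breed: sample size, proportion of polymorphic SNPs, mean
#' observed and expected heterozygosity, and mean pairwise genetic
#' distance among the breed's individuals.
#'
#' @param dataset a [genotype_dataset()].
#' @param maf_threshold threshold for [proportion_polymorphic()].
#' @return data.frame with columns `breed`, `n_samples`, `P_N`, `H_O`,
#'   `H_E`, `D`.
#' @export
breed_diversity_table <- function(dataset, maf_threshold = 0.01) {
  breeds <- sort(unique(dataset$samples$breed))
  ho <- observed_heterozygosity(dataset, per = "breed")
  he <- expected_heterozygosity(dataset, per_breed = TRUE)
  pn <- proportion_polymorphic(dataset, maf_threshold)
  dd <- vapply(breeds, function(b) {
    rows <- which(dataset$samples$breed == b)
    if (length(rows) < 2) return(NA_real_)
    M <- pairwise_distance(subset_dataset(dataset, samples = rows))
    mean(M[upper.tri(M)], na.rm = TRUE)
  }, numeric(1))
  data.frame(breed = breeds,
             n_samples = as.integer(table(dataset$samples$breed)[breeds]),
             P_N = unname(pn[breeds]), H_O = unname(ho[breeds]),
             H_E = unname(he[breeds]), D = unname(dd), row.names = NULL)
}
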