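#' @keywords internal
"_PACKAGE"

#' Construct a genotype dataset
#'
#' The central container of the workflow: an individuals x SNPs matrix of
#' allele-B dosages (0, 1, 2 or `NA` for a missing call), a marker map and a
#' sample table with breed labels. Dosage counts copies of `allele_b`, the
#' second allele observed for the marker; every statistic downstream is
#' invariant to flipping that orientation.
#'
#' @param dosages integer matrix, individuals in rows, markers in columns;
#'   values in `{0, 1, 2, NA}`.
#' @param map data.frame with columns `marker_id`, `chromosome`,
#'   `position_bp`, `allele_a`, `allele_b`. Positions must be strictly
#'   increasing within each chromosome.
#' @param samples data.frame with columns `sample_id`, `breed`.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(dosages, map, samples) {
  dosages <- as.matrix(dosages)
  stopifnot(is.data.frame(map), is.data.frame(samples))
  if (nrow(dosages) != nrow(samples))
    stop("dosages has ", nrow(dosages), " rows but samples has ",
         nrow(samples), " entries")
  if (ncol(dosages) != nrow(map))
    stop("dosages has ", ncol(dosages), " columns but map has ",
         nrow(map), " markers")
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id")
  if (anyDuplicated(map$marker_id))
    stop("duplicated marker_id")
  if (any(is.na(samples$breed)) || any(!nzchar(samples$breed)))
    stop("every sample needs a nonempty breed label")
  bad <- !(dosages %in% c(0L, 1L, 2L)) & !is.na(dosages)
  if (any(bad))
    stop("dosage values must be 0, 1, 2 or NA")
  ord_ok <- all(tapply(map$position_bp, map$chromosome,
                       function(x) all(diff(x) > 0)))
  if (!ord_ok)
    stop("positions must be strictly increasing within each chromosome")
  rownames(dosages) <- samples$sample_id
  colnames(dosages) <- map$marker_id
  structure(list(dosages = dosages, map = map, samples = samples),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "SNPs,", length(unique(x$samples$breed)),
      "breed(s),", sum(is.na(x$dosages)), "missing calls\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$dosages)

#' Number of individuals / markers
#' @param dataset a `genotype_dataset`.
#' @return integer count.
#' @export
n_individuals <- function(dataset) nrow(dataset$dosages)

#' @rdname n_individuals
#' @export
n_markers <- function(dataset) ncol(dataset$dosages)

#' Subset a genotype dataset
#'
#' @param dataset a `genotype_dataset`.
#' @param samples index vector into the sample table (default all).
#' @param markers index vector into the marker map (default all).
#' @return a `genotype_dataset`.
#' @export
subset_dataset <- function(dataset, samples = NULL, markers = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(dataset$dosages)) else samples
  mi <- if (is.null(markers)) seq_len(ncol(dataset$dosages)) else markers
  genotype_dataset(dataset$dosages[si, mi, drop = FALSE],
                   dataset$map[mi, , drop = FALSE],
                   dataset$samples[si, , drop = FALSE])
}

#' Per-marker allele frequency, MAF and call rate
#'
#' Frequency is that of allele B (the allele counted by the dosage); it is
#' estimated from non-missing calls only. Markers with zero calls get `NA`
#' frequency.
#'
#' @param dataset a `genotype_dataset`.
#' @return data.frame with columns `marker_id`, `p`, `maf`, `call_rate`.
#' @export
marker_stats <- function(dataset) {
  d <- dataset$dosages
  n_called <- unname(colSums(!is.na(d)))
  p <- unname(colMeans(d, na.rm = TRUE)) / 2
  p[n_called == 0] <- NA_real_
  data.frame(marker_id = dataset$map$marker_id,
             p = p,
             maf = pmin(p, 1 - p),
             call_rate = n_called / nrow(d),
             row.names = NULL)
}

#' Allele-B frequencies, overall or per breed
#'
#' @param dataset a `genotype_dataset`.
#' @param per_breed if `TRUE`, return a breeds x markers matrix of
#'   within-breed frequencies; otherwise a single vector pooled over all
#'   samples.
#' @return numeric vector, or matrix with breed row names.
#' @export
allele_freq <- function(dataset, per_breed = FALSE) {
  d <- dataset$dosages
  if (!per_breed) {
    p <- unname(colMeans(d, na.rm = TRUE)) / 2
    p[colSums(!is.na(d)) == 0] <- NA_real_
    return(p)
  }
  breeds <- sort(unique(dataset$samples$breed))
  out <- matrix(NA_real_, length(breeds), ncol(d),
                dimnames = list(breeds, colnames(d)))
  for (b in breeds) {
    rows <- dataset$samples$breed == b
    db <- d[rows, , drop = FALSE]
    n_called <- colSums(!is.na(db))
    p <- colMeans(db, na.rm = TRUE) / 2
    p[n_called == 0] <- NA_real_
    out[b, ] <- p
  }
  out
}

#' Put a dataset in reader-canonical allele orientation
#'
#' [read_plink_text()] orients each marker so that allele A is the first
#' allele observed in file order. This helper applies the same convention to
#' an in-memory dataset (flipping markers whose first non-missing genotype
#' is homozygous for allele B, and blanking allele B where it is never
#' observed), so that write-then-read reproduces the dataset exactly.
#' Orientation is a free convention: every statistic in the package is
#' invariant to it.
#'
#' @param dataset a `genotype_dataset`.
#' @return a `genotype_dataset` in canonical orientation.
#' @export
canonicalize_alleles <- function(dataset) {
  d <- dataset$dosages
  map <- dataset$map
  flip <- logical(ncol(d))
  for (j in seq_len(ncol(d))) {
    dj <- d[, j]
    obs <- dj[!is.na(dj)]
    if (length(obs) == 0) {
      map$allele_a[j] <- NA_character_
      map$allele_b[j] <- NA_character_
      next
    }
    if (obs[1] == 2) flip[j] <- TRUE
  }
  if (any(flip)) {
    d[, flip] <- 2L - d[, flip]
    tmp <- map$allele_a[flip]
    map$allele_a[flip] <- map$allele_b[flip]
    map$allele_b[flip] <- tmp
  }
  for (j in seq_len(ncol(d))) {
    dj <- d[, j]
    if (!all(is.na(dj)) && all(dj[!is.na(dj)] == 0))
      map$allele_b[j] <- NA_character_
  }
  genotype_dataset(d, map, dataset$samples)
}

#' Flip the allele orientation of selected markers
#'
#' Swaps allele A/B and replaces dosage d by 2 - d. Used to assert
#' orientation invariance of downstream statistics.
#'
#' @param dataset a `genotype_dataset`.
#' @param markers indices of markers to flip.
#' @return a `genotype_dataset`.
#' @export
flip_alleles <- function(dataset, markers) {
  d <- dataset$dosages
  d[, markers] <- 2L - d[, markers]
  map <- dataset$map
  tmp <- map$allele_a[markers]
  map$allele_a[markers] <- map$allele_b[markers]
  map$allele_b[markers] <- tmp
  genotype_dataset(d, map, dataset$samples)
}
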