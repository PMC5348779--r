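#' Pooled allele frequencies per contrast group
#'
#' Frequencies pooled over each group's non-missing calls (individuals
#' weighted by their call counts within the group). Groups with no call at
#' a SNP get `NA` there.
#'
#' @param dataset a [genotype_dataset()].
#' @param scheme named character vector/list mapping `sample_id` to a
#'   group label; samples absent from the scheme are ignored.
#' @return matrix groups x markers of allele-B frequencies.
#' @export
group_allele_frequencies <- function(dataset, scheme) {
  scheme <- unlist(scheme)
  unknown <- setdiff(names(scheme), dataset$samples$sample_id)
  if (length(unknown))
    stop("scheme refers to unknown sample(s): ",
         paste(utils::head(unknown, 3), collapse = ", "))
  groups <- sort(unique(scheme))
  if (length(groups) < 2) stop("need at least two groups")
  out <- matrix(NA_real_, length(groups), n_markers(dataset),
                dimnames = list(groups, dataset$map$marker_id))
  for (g in groups) {
    rows <- which(dataset$samples$sample_id %in% names(scheme)[scheme == g])
    db <- dataset$dosages[rows, , drop = FALSE]
    n_called <- colSums(!is.na(db))
    p <- colMeans(db, na.rm = TRUE) / 2
    p[n_called == 0] <- NA_real_
    out[g, ] <- p
  }
  out
}

# Scheme mapping every sample to its breed.
breed_scheme <- function(dataset) {
  stats::setNames(dataset$samples$breed, dataset$samples$sample_id)
}

#' Per-SNP group-deviation FST
#'
#' For each group g at each SNP, FST(g) = (p_g - pbar)^2 / (pbar (1 -
#' pbar)) with pbar the unweighted mean frequency over the groups defined
#' at that SNP: the squared deviation of the group frequency from the
#' across-group average, scaled by the allele-frequency variance term.
#' SNPs where pbar is 0 or 1, or where fewer than two groups are defined,
#' score 0; a group undefined at a SNP keeps `NA` there.
#'
#' @param group_freqs matrix groups x markers, e.g. from
#'   [group_allele_frequencies()].
#' @return matrix groups x markers of non-negative FST values.
#' @export
fst_per_snp <- function(group_freqs) {
  stopifnot(nrow(group_freqs) >= 2)
  defined <- !is.na(group_freqs)
  n_def <- colSums(defined)
  pbar <- colMeans(group_freqs, na.rm = TRUE)
  denom <- pbar * (1 - pbar)
  fst <- sweep(group_freqs, 2, pbar)^2
  fst <- sweep(fst, 2, denom, "/")
  fst[, denom == 0 | !is.finite(denom)] <- 0
  fst[, n_def < 2] <- 0
  fst[!defined] <- NA_real_
  fst
}

#' Scenario-1 FST: each breed against all others, pairwise-averaged
#'
#' For a focal breed b, the per-SNP value is the mean over every other
#' breed b' of the two-group FST for the pair (b, b'). Pairs where either
#' breed's frequency is undefined at a SNP are skipped from that SNP's
#' mean; SNPs monomorphic within a pair contribute zero (configurable via
#' `skip_monomorphic_pairs`).
#'
#' @param dataset a [genotype_dataset()].
#' @param skip_monomorphic_pairs drop pair terms whose pooled frequency is
#'   0 or 1 instead of counting them as zero.
#' @return matrix breeds x markers of FST1 values.
#' @export
fst_scenario1 <- function(dataset, skip_monomorphic_pairs = FALSE) {
  pf <- group_allele_frequencies(dataset, breed_scheme(dataset))
  K <- nrow(pf)
  stopifnot(K >= 2)
  m <- ncol(pf)
  acc <- matrix(0, K, m, dimnames = dimnames(pf))
  cnt <- matrix(0, K, m)
  for (a in seq_len(K - 1)) {
    for (b in (a + 1):K) {
      pa <- pf[a, ]; pb <- pf[b, ]
      ok <- !is.na(pa) & !is.na(pb)
      pbar <- (pa + pb) / 2
      denom <- pbar * (1 - pbar)
      v <- ((pa - pbar)^2) / denom          # symmetric in the pair
      mono <- ok & denom == 0
      v[mono] <- 0
      use <- ok & (!skip_monomorphic_pairs | denom > 0)
      acc[a, use] <- acc[a, use] + v[use]
      acc[b, use] <- acc[b, use] + v[use]
      cnt[a, use] <- cnt[a, use] + 1
      cnt[b, use] <- cnt[b, use] + 1
    }
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Grouped-scenario FST (pooled contrast groups)
#'
#' Pools allele frequencies within each contrast group (e.g. breeds merged
#' by breeding goal), then applies the per-SNP group-deviation FST.
#'
#' @param dataset a [genotype_dataset()].
#' @param scheme named map `sample_id` to group label, or a named map
#'   breed to group label (expanded over the breed's samples).
#' @return matrix groups x markers.
#' @export
fst_scenarios_grouped <- function(dataset, scheme) {
  scheme <- unlist(scheme)
  if (all(names(scheme) %in% dataset$samples$breed)) {
    scheme <- stats::setNames(
      scheme[dataset$samples$breed], dataset$samples$sample_id)
    scheme <- scheme[!is.na(scheme)]
  }
  fst_per_snp(group_allele_frequencies(dataset, scheme))
}

#' Moving-average smoothing of a per-SNP track
#'
#' Centred moving average over SNP index within each chromosome (default
#' five SNPs: two on each side); windows are truncated at chromosome ends.
#' A window of 1 is the identity.
#'
#' @param values numeric vector aligned to the marker map.
#' @param map marker map (`chromosome` column) aligned with `values`.
#' @param window_snps odd window size >= 1.
#' @return numeric vector of smoothed values.
#' @export
smooth_track <- function(values, map, window_snps = 5) {
  stopifnot(window_snps >= 1, window_snps %% 2 == 1,
            length(values) == nrow(map))
  if (window_snps == 1) return(values)
  half <- (window_snps - 1) %/% 2
  out <- numeric(length(values))
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    x <- values[idx]
    n <- length(x)
    cs <- c(0, cumsum(ifelse(is.na(x), 0, x)))
    cn <- c(0, cumsum(!is.na(x)))
    j <- seq_len(n)
    lo <- pmax(1L, j - half); hi <- pmin(n, j + half)
    s <- cs[hi + 1] - cs[lo]
    k <- cn[hi + 1] - cn[lo]
    out[idx] <- ifelse(k > 0, s / k, NA_real_)
  }
  out
}

#' Call selection regions from a smoothed track
#'
#' Threshold = mean + `k_sd` standard deviations of the smoothed values
#' over all SNPs; regions are maximal runs of consecutive above-threshold
#' SNPs within a chromosome. Each region records its peak SNP and is
#' classed `"3SD"` when its peak also exceeds the mean + 3 SD threshold,
#' else `"2SD"`.
#'
#' @param values smoothed per-SNP values aligned to `map`.
#' @param map marker map aligned with `values`.
#' @param k_sd threshold multiplier (2 or 3).
#' @param group_label label copied into the output.
#' @return data.frame with columns `group`, `chromosome`, `start_bp`,
#'   `end_bp`, `n_snps`, `peak_marker_id`, `peak_value`, `threshold_class`.
#' @export
call_regions <- function(values, map, k_sd = 3, group_label = "group") {
  stopifnot(length(values) == nrow(map), length(values) > 0)
  mu <- mean(values, na.rm = TRUE)
  sdv <- stats::sd(values, na.rm = TRUE)
  thr <- mu + k_sd * sdv
  thr3 <- mu + 3 * sdv
  above <- !is.na(values) & values > thr
  if (!any(above))
    return(data.frame(group = character(0), chromosome = integer(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_snps = integer(0), peak_marker_id = character(0),
                      peak_value = numeric(0), threshold_class = character(0)))
  runs <- cumsum(c(TRUE, diff(which(above)) > 1 |
                     diff(map$chromosome[above]) != 0))
  idx_above <- which(above)
  out <- lapply(split(idx_above, runs), function(snps) {
    pk <- snps[which.max(values[snps])]
    data.frame(group = group_label,
               chromosome = map$chromosome[snps[1]],
               start_bp = map$position_bp[snps[1]],
               end_bp = map$position_bp[snps[length(snps)]],
               n_snps = length(snps),
               peak_marker_id = map$marker_id[pk],
               peak_value = values[pk],
               threshold_class = if (values[pk] > thr3) "3SD" else "2SD")
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Annotate regions shared across contrast groups
#'
#' Two regions are shared when they come from different groups, lie on the
#' same chromosome and overlap by at least one bp. Adds a `shared_with`
#' column (comma-separated group labels, empty when exclusive).
#'
#' @param regions data.frame of regions from [call_regions()] (possibly
#'   row-bound across groups).
#' @return the input with a `shared_with` column.
#' @export
shared_regions <- function(regions) {
  n <- nrow(regions)
  shared <- character(n)
  if (n > 1) {
    for (i in seq_len(n)) {
      hits <- regions$group != regions$group[i] &
        regions$chromosome == regions$chromosome[i] &
        regions$start_bp <= regions$end_bp[i] &
        regions$end_bp >= regions$start_bp[i]
      shared[i] <- paste(sort(unique(regions$group[hits])), collapse = ",")
    }
  }
  regions$shared_with <- shared
  regions
}

#' Distribution of raw per-SNP FST values in fixed bins
#'
#' Proportions of SNPs per FST category (left-open bins up to each edge,
#' plus a final "above the last edge" bin); proportions sum to 1 over SNPs
#' with defined values.
#'
#' @param values per-SNP raw FST values for one group.
#' @param edges increasing bin edges (default 0.05 to 0.40 by 0.05).
#' @return named numeric vector of proportions.
#' @export
fst_distribution_bins <- function(values, edges = seq(0.05, 0.40, 0.05)) {
  x <- values[!is.na(values)]
  br <- c(-Inf, edges, Inf)
  counts <- table(cut(x, breaks = br, right = TRUE))
  props <- as.numeric(counts) / length(x)
  names(props) <- c(paste0("<=", edges[1]),
                    paste0(utils::head(edges, -1), "-", edges[-1]),
                    paste0(">", edges[length(edges)]))
  props
}

#' Regional linkage disequilibrium per breed
#'
#' Within a genomic interval and one breed at a time, SNPs with
#' within-breed MAF below `maf_min` are dropped, then r^2 is the squared
#' Pearson correlation of dosage vectors over pairwise-complete calls:
#' reported for adjacent retained SNPs and for all syntenic pairs in the
#' region.
#'
#' @param dataset a [genotype_dataset()].
#' @param chromosome,start_bp,end_bp interval (1-based, inclusive).
#' @param maf_min within-breed MAF filter (default 0.05).
#' @return data.frame per breed: `breed`, `n_snps`, `adjacent_r2_mean`,
#'   `adjacent_r2_sd`, `syntenic_r2_mean`, `syntenic_r2_sd` (`NA` when
#'   fewer than two SNPs survive the filter).
#' @export
regional_ld <- function(dataset, chromosome, start_bp, end_bp,
                        maf_min = 0.05) {
  cols <- which(dataset$map$chromosome == chromosome &
                dataset$map$position_bp >= start_bp &
                dataset$map$position_bp <= end_bp)
  if (length(cols) < 2) stop("region contains fewer than 2 SNPs")
  breeds <- sort(unique(dataset$samples$breed))
  out <- lapply(breeds, function(b) {
    rows <- which(dataset$samples$breed == b)
    db <- dataset$dosages[rows, cols, drop = FALSE]
    p <- colMeans(db, na.rm = TRUE) / 2
    keep <- !is.na(p) & pmin(p, 1 - p) >= maf_min
    if (sum(keep) < 2)
      return(data.frame(breed = b, n_snps = sum(keep),
                        adjacent_r2_mean = NA_real_,
                        adjacent_r2_sd = NA_real_,
                        syntenic_r2_mean = NA_real_,
                        syntenic_r2_sd = NA_real_))
    db <- db[, keep, drop = FALSE]
    r2 <- suppressWarnings(
      stats::cor(db, use = "pairwise.complete.obs")^2)
    adj <- r2[cbind(seq_len(ncol(db) - 1), 2:ncol(db))]
    syn <- r2[upper.tri(r2)]
    data.frame(breed = b, n_snps = ncol(db),
               adjacent_r2_mean = mean(adj, na.rm = TRUE),
               adjacent_r2_sd = stats::sd(adj, na.rm = TRUE),
               syntenic_r2_mean = mean(syn, na.rm = TRUE),
               syntenic_r2_sd = stats::sd(syn, na.rm = TRUE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
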