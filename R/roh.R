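#' Minimum SNP count for a run of homozygosity (false-positive bound)
#'
#' l = ln(alpha / (n_s * n_i)) / ln(1 - het): the run length at which the
#' expected number of chance all-homozygous stretches across n_i
#' individuals scanned at n_s SNPs each falls below alpha, given mean SNP
#' heterozygosity `het`. The integer bound is the ceiling.
#'
#' @param n_s SNPs per individual.
#' @param n_i number of individuals.
#' @param alpha tolerated number of false-positive ROH (default 0.05).
#' @param het mean heterozygosity across SNPs, in (0,1).
#' @return list with `l_real` and integer `l` (at least 2).
#' @export
lencz_min_snps <- function(n_s, n_i, alpha = 0.05, het) {
  stopifnot(n_s >= 1, n_i >= 1, alpha > 0, alpha < 1)
  if (het <= 0 || het >= 1) stop("het must be in (0,1)")
  l_real <- log(alpha / (n_s * n_i)) / log(1 - het)
  list(l_real = l_real, l = max(2L, as.integer(ceiling(l_real))))
}

#' ROH detection parameters
#'
#' Sliding-window scan settings. The minimum SNP count defaults to the
#' ceiling of the false-positive bound of [lencz_min_snps()] when computed
#' by [detect_roh()]; the remaining defaults are the standard PLINK-style
#' settings (50-SNP window tolerating 1 heterozygote and 5 missing calls,
#' 1000 kb minimum length, 1000 kb maximum gap, at most 50 kb per SNP).
#'
#' @param alpha false-positive tolerance for the minimum-SNP bound.
#' @param min_snps minimum SNPs per segment; `NULL` = derive via the bound.
#' @param window_snps sliding window size in SNPs.
#' @param window_het_allowed heterozygous calls tolerated per window.
#' @param window_missing_allowed missing calls tolerated per window.
#' @param min_length_kb minimum segment length.
#' @param max_gap_kb maximum gap between consecutive SNPs in a segment.
#' @param max_kb_per_snp maximum average spacing (density constraint).
#' @return list of class `roh_params`.
#' @export
roh_params <- function(alpha = 0.05, min_snps = NULL, window_snps = 50,
                       window_het_allowed = 1, window_missing_allowed = 5,
                       min_length_kb = 1000, max_gap_kb = 1000,
                       max_kb_per_snp = 50) {
  structure(list(alpha = alpha, min_snps = min_snps,
                 window_snps = as.integer(window_snps),
                 window_het_allowed = as.integer(window_het_allowed),
                 window_missing_allowed = as.integer(window_missing_allowed),
                 min_length_kb = min_length_kb, max_gap_kb = max_gap_kb,
                 max_kb_per_snp = max_kb_per_snp),
            class = "roh_params")
}

# Qualifying-SNP mask for one individual's chromosome: TRUE where some
# covering window has <= het_allowed heterozygotes and <= miss_allowed
# missing calls.
roh_qualifying <- function(g, w, het_allowed, miss_allowed) {
  n <- length(g)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  if (n <= w) {
    ok <- sum(het) <= het_allowed && sum(mis) <= miss_allowed
    return(rep(ok, n))
  }
  ch <- cumsum(het); cm <- cumsum(mis)
  nw <- n - w + 1L
  hw <- ch[w:n] - c(0, ch[seq_len(nw - 1)])
  mw <- cm[w:n] - c(0, cm[seq_len(nw - 1)])
  pass <- hw <= het_allowed & mw <= miss_allowed
  cp <- c(0, cumsum(pass))
  j <- seq_len(n)
  lo <- pmax(1L, j - w + 1L)
  hi <- pmin(j, nw)
  covered <- hi >= lo
  qual <- rep(FALSE, n)
  qual[covered] <- (cp[hi[covered] + 1L] - cp[lo[covered]]) > 0
  qual
}

#' Detect runs of homozygosity
#'
#' PLINK-style scan: within each chromosome a SNP qualifies when it is
#' covered by at least one sliding window of `window_snps` calls with at
#' most `window_het_allowed` heterozygotes and `window_missing_allowed`
#' missing calls. Maximal runs of qualifying SNPs, split where the gap
#' between consecutive SNPs exceeds `max_gap_kb`, become segments when
#' they hold at least `min_snps` SNPs (default: the ceiling of the
#' false-positive bound computed from this dataset's mean SNP
#' heterozygosity), span at least `min_length_kb` and satisfy the density
#' constraint. Deterministic; an empty result is valid.
#'
#' @param dataset a [genotype_dataset()] sorted by chromosome/position.
#' @param params a [roh_params()].
#' @param het_override mean heterozygosity to feed the minimum-SNP bound
#'   (default: computed from the dataset; supply e.g. a per-breed value).
#' @return data.frame with columns `sample_id`, `breed`, `chromosome`,
#'   `start_bp`, `end_bp`, `n_snps`, `length_kb`.
#' @export
detect_roh <- function(dataset, params = roh_params(),
                       het_override = NULL) {
  min_snps <- params$min_snps
  if (is.null(min_snps)) {
    het <- het_override
    if (is.null(het))
      het <- mean(observed_heterozygosity(dataset, per = "snp"),
                  na.rm = TRUE)
    min_snps <- lencz_min_snps(n_markers(dataset), n_individuals(dataset),
                               params$alpha, het)$l
  }
  map <- dataset$map
  chroms <- unique(map$chromosome)
  res <- vector("list", 0)
  for (chr in chroms) {
    cols <- which(map$chromosome == chr)
    pos <- map$position_bp[cols]
    gap_break <- c(FALSE, diff(pos) > params$max_gap_kb * 1000)
    for (i in seq_len(nrow(dataset$samples))) {
      g <- dataset$dosages[i, cols]
      qual <- roh_qualifying(g, params$window_snps,
                             params$window_het_allowed,
                             params$window_missing_allowed)
      # run ids: break at non-qualifying SNPs and at large gaps
      newrun <- !qual | gap_break
      run_id <- cumsum(newrun)
      run_id[!qual] <- NA
      if (all(is.na(run_id))) next
      for (r in unique(run_id[!is.na(run_id)])) {
        snps <- which(!is.na(run_id) & run_id == r)
        len_kb <- (pos[snps[length(snps)]] - pos[snps[1]]) / 1000
        if (length(snps) < min_snps) next
        if (len_kb < params$min_length_kb) next
        if (len_kb / length(snps) > params$max_kb_per_snp) next
        res[[length(res) + 1]] <- data.frame(
          sample_id = dataset$samples$sample_id[i],
          breed = dataset$samples$breed[i],
          chromosome = chr,
          start_bp = pos[snps[1]], end_bp = pos[snps[length(snps)]],
          n_snps = length(snps), length_kb = len_kb)
      }
    }
  }
  if (!length(res))
    return(data.frame(sample_id = character(0), breed = character(0),
                      chromosome = integer(0), start_bp = integer(0),
                      end_bp = integer(0), n_snps = integer(0),
                      length_kb = numeric(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-breed ROH summary
#'
#' For each breed: mean/SD/min/max of the per-individual segment count,
#' mean and SD of the per-individual total ROH length (kb), mean segment
#' length, mean SNPs per segment, average density (kb per SNP), and PHOM,
#' the genome-wide proportion of homozygous among non-missing calls per
#' individual. Individuals without segments contribute zero counts and
#' lengths.
#'
#' @param segments data.frame from [detect_roh()].
#' @param dataset the [genotype_dataset()] the segments came from.
#' @return data.frame, one row per breed.
#' @export
summarize_roh <- function(segments, dataset) {
  breeds <- sort(unique(dataset$samples$breed))
  d <- dataset$dosages
  hom <- rowSums(d != 1L, na.rm = TRUE) / rowSums(!is.na(d))
  out <- lapply(breeds, function(b) {
    ids <- dataset$samples$sample_id[dataset$samples$breed == b]
    seg <- segments[segments$sample_id %in% ids, , drop = FALSE]
    nseg <- stats::setNames(rep(0, length(ids)), ids)
    kb <- nseg
    if (nrow(seg)) {
      tn <- table(seg$sample_id)
      nseg[names(tn)] <- as.numeric(tn)
      tk <- tapply(seg$length_kb, seg$sample_id, sum)
      kb[names(tk)] <- tk
    }
    data.frame(
      breed = b, n_individuals = length(ids),
      nseg_mean = mean(nseg), nseg_sd = stats::sd(nseg),
      nseg_min = min(nseg), nseg_max = max(nseg),
      kb_mean = mean(kb), kb_sd = stats::sd(kb),
      kb_aver = if (nrow(seg)) mean(seg$length_kb) else NA_real_,
      nsnp_mean = if (nrow(seg)) mean(seg$n_snps) else NA_real_,
      density_kb_per_snp = if (nrow(seg))
        mean(seg$length_kb / seg$n_snps) else NA_real_,
      phom = mean(hom[dataset$samples$breed == b], na.rm = TRUE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-breed proportions of ROH in length categories
#'
#' Three bins: short (below `edges_kb[1]`), intermediate, and long (above
#' `edges_kb[2]`). Proportions per breed sum to 1; breeds without
#' segments get `NA`.
#'
#' @param segments data.frame from [detect_roh()] (needs `breed`).
#' @param edges_kb two increasing cut points in kb (default 5000, 15000).
#' @return matrix breeds x 3 of proportions.
#' @export
roh_length_categories <- function(segments, edges_kb = c(5000, 15000)) {
  stopifnot(length(edges_kb) == 2, diff(edges_kb) > 0)
  breeds <- sort(unique(segments$breed))
  out <- t(vapply(breeds, function(b) {
    x <- segments$length_kb[segments$breed == b]
    if (!length(x)) return(rep(NA_real_, 3))
    c(mean(x < edges_kb[1]),
      mean(x >= edges_kb[1] & x <= edges_kb[2]),
      mean(x > edges_kb[2]))
  }, numeric(3)))
  colnames(out) <- c(paste0("<", edges_kb[1], "kb"),
                     paste0(edges_kb[1], "-", edges_kb[2], "kb"),
                     paste0(">", edges_kb[2], "kb"))
  rownames(out) <- breeds
  out
}
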