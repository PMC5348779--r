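#' Reynolds distance matrix between populations
#'
#' For populations a, b with allele-B frequencies p_al, p_bl:
#' D(a,b) = sum_l (p_al - p_bl)^2 / sum_l (p_al + p_bl - 2 p_al p_bl),
#' frequencies treated as known (no sample-size correction). Loci with an
#' undefined frequency in either population are skipped; identical
#' populations get 0.
#'
#' @param freqs matrix populations x markers of allele frequencies, e.g.
#'   [allele_freq()] with `per_breed = TRUE` or
#'   [group_allele_frequencies()].
#' @return symmetric non-negative matrix with zero diagonal.
#' @export
reynolds_distance <- function(freqs) {
  K <- nrow(freqs)
  stopifnot(K >= 2)
  D <- matrix(0, K, K, dimnames = list(rownames(freqs), rownames(freqs)))
  for (a in seq_len(K - 1)) {
    for (b in (a + 1):K) {
      pa <- freqs[a, ]; pb <- freqs[b, ]
      ok <- !is.na(pa) & !is.na(pb)
      if (!any(ok)) stop("no co-defined locus for populations ",
                         rownames(freqs)[a], " and ", rownames(freqs)[b])
      num <- sum((pa[ok] - pb[ok])^2)
      den <- sum(pa[ok] + pb[ok] - 2 * pa[ok] * pb[ok])
      D[a, b] <- D[b, a] <- if (den == 0) 0 else num / den
    }
  }
  D
}

#' Neighbour-joining population tree
#'
#' Saitou-Nei neighbour joining on a population distance matrix, with
#' negative branch lengths clamped to zero and the deficit transferred to
#' the sibling branch so path lengths between the joined pair are
#' preserved.
#'
#' @param distances symmetric distance matrix (>= 3 populations).
#' @return an `ape` `phylo` tree with the populations as tips.
#' @export
nj_tree <- function(distances) {
  stopifnot(nrow(distances) >= 3)
  tree <- ape::nj(stats::as.dist(distances))
  clamp_negative_branches(tree)
}

# Move negative terminal/internal branch lengths onto the sibling edge.
clamp_negative_branches <- function(tree) {
  el <- tree$edge.length
  neg <- which(el < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1]
    sibs <- which(tree$edge[, 1] == parent & seq_along(el) != e)
    if (length(sibs)) el[sibs[1]] <- el[sibs[1]] + el[e]
    el[e] <- 0
  }
  tree$edge.length <- el
  tree
}

#' Population tree from SNPs in a genomic interval ("local tree")
#'
#' Reynolds distances computed from within-breed allele frequencies of the
#' SNPs inside the interval, then neighbour joining.
#'
#' @param dataset a [genotype_dataset()].
#' @param chromosome,start_bp,end_bp interval (1-based, inclusive).
#' @return an `ape` `phylo` tree.
#' @export
local_tree <- function(dataset, chromosome, start_bp, end_bp) {
  cols <- which(dataset$map$chromosome == chromosome &
                dataset$map$position_bp >= start_bp &
                dataset$map$position_bp <= end_bp)
  if (length(cols) < 2) stop("region contains fewer than 2 SNPs")
  sub <- subset_dataset(dataset, markers = cols)
  nj_tree(reynolds_distance(allele_freq(sub, per_breed = TRUE)))
}

#' Population kinship from a rooted tree
#'
#' The tree is midpoint-rooted, then kinship(i, j) is the shared branch
#' length from the root down to the most recent common ancestor of tips i
#' and j; the diagonal is each tip's root-to-tip distance. Always positive
#' semidefinite.
#'
#' @param tree an `ape` `phylo` tree with branch lengths.
#' @return symmetric PSD matrix with tip labels as dimnames.
#' @export
kinship_from_tree <- function(tree) {
  rooted <- phangorn::midpoint(tree)
  ntip <- length(rooted$tip.label)
  depth <- ape::node.depth.edgelength(rooted)   # root-to-node distances
  K <- matrix(0, ntip, ntip,
              dimnames = list(rooted$tip.label, rooted$tip.label))
  mrca <- ape::mrca(rooted)
  for (i in seq_len(ntip)) {
    K[i, i] <- depth[i]
    if (i < ntip) for (j in (i + 1):ntip)
      K[i, j] <- K[j, i] <- depth[mrca[i, j]]
  }
  K
}

#' Single-SNP FLK statistic
#'
#' Tests per-SNP allele-frequency differentiation against the drift
#' expected under a population kinship matrix K: with p the vector of
#' population frequencies at a SNP, the ancestral frequency p0 is the
#' kinship-GLS estimate (1' K^-1 p) / (1' K^-1 1), clipped away from 0 and
#' 1, and FLK = (p - p0 1)' [p0 (1 - p0) K]^-1 (p - p0 1). Under neutral
#' drift the statistic is approximately chi-square with
#' (n_populations - 1) degrees of freedom. Monomorphic SNPs score 0.
#'
#' @param group_freqs matrix populations x markers of frequencies.
#' @param kinship population kinship, e.g. from [kinship_from_tree()];
#'   a ridge of 1e-8 is added before inversion.
#' @return numeric vector of per-SNP FLK values.
#' @export
flk_statistic <- function(group_freqs, kinship) {
  K <- nrow(group_freqs)
  stopifnot(nrow(kinship) == K)
  if (!is.null(rownames(kinship)) && !is.null(rownames(group_freqs)))
    kinship <- kinship[rownames(group_freqs), rownames(group_freqs)]
  Ki <- tryCatch(solve(kinship + diag(1e-8, K)),
                 error = function(e) stop("singular kinship matrix"))
  one <- rep(1, K)
  w <- as.vector(Ki %*% one)
  denom1 <- sum(w)
  p0 <- as.vector(crossprod(w, group_freqs)) / denom1
  p0 <- pmin(pmax(p0, 1e-6), 1 - 1e-6)
  Dev <- sweep(group_freqs, 2, p0)
  quad <- colSums(Dev * (Ki %*% Dev))
  out <- quad / (p0 * (1 - p0))
  rng <- apply(group_freqs, 2, function(x) diff(range(x, na.rm = TRUE)))
  mono <- rng == 0
  out[mono] <- 0
  unname(out)
}

#' P-values by empirical standardization of a statistic
#'
#' Standardizes the genome-wide statistic by its own mean and standard
#' deviation and reads upper-tail p-values off the standard normal
#' distribution (large values indicate selection). Returns the z-scores,
#' p-values and -log10 p.
#'
#' @param stat numeric vector with at least two distinct values.
#' @return data.frame with columns `z`, `p`, `neglog10p`.
#' @export
pvalues_by_standardization <- function(stat) {
  mu <- mean(stat, na.rm = TRUE)
  sdv <- stats::sd(stat, na.rm = TRUE)
  if (!is.finite(sdv) || sdv == 0) stop("statistic has zero variance")
  z <- (stat - mu) / sdv
  p <- stats::pnorm(z, lower.tail = FALSE)
  data.frame(z = z, p = p, neglog10p = -log10(p))
}

#' Write / read a Newick tree
#'
#' Thin wrappers over `ape`'s Newick serialization; round trips preserve
#' topology and branch lengths.
#'
#' @param tree an `ape` `phylo` tree.
#' @param path optional file path; if `NULL`, the string is returned.
#' @return `write_newick`: the Newick string (invisibly when written to a
#'   file); `read_newick`: a `phylo` tree.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' @rdname write_newick
#' @param text Newick string (used when `path` is `NULL`).
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tree <- tryCatch(
    suppressWarnings(if (!is.null(path)) ape::read.tree(path)
                     else ape::read.tree(text = text)),
    error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, c("phylo", "multiPhylo")))
    stop("malformed Newick input")
  tree
}
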