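# Topological order of a pedigree (parents before offspring), with cycle
# detection. Returns integer positions into ped rows.
pedigree_order <- function(ped) {
  n <- nrow(ped)
  idx <- match(ped$id, ped$id)
  sire <- match(ped$sire, ped$id)   # NA when unknown / founder
  dam <- match(ped$dam, ped$id)
  placed <- logical(n)
  order_out <- integer(0)
  remaining <- seq_len(n)
  while (length(remaining)) {
    ready <- remaining[
      (is.na(sire[remaining]) | placed[sire[remaining]]) &
      (is.na(dam[remaining]) | placed[dam[remaining]])]
    if (!length(ready))
      stop("pedigree cycle involving id ", ped$id[remaining[1]])
    placed[ready] <- TRUE
    order_out <- c(order_out, ready)
    remaining <- setdiff(remaining, ready)
  }
  order_out
}

#' Pedigree inbreeding by Colleau's indirect method
#'
#' Wright's inbreeding coefficient F of an individual equals half the
#' additive relationship between its parents. Relationship entries are
#' obtained without building the full numerator relationship matrix A:
#' using the decomposition A = T D T' (T the gene-flow matrix, D the
#' Mendelian-sampling variances), the product A x for x an indicator
#' vector is computed by one backward and one forward sweep over the
#' pedigree. Animals are processed in topological order so every
#' Mendelian-sampling variance d_i = 0.5 - 0.25 (F_sire + F_dam) (with the
#' usual adjustments for unknown parents) is available when needed.
#'
#' @param pedigree data.frame with columns `id`, `sire`, `dam`
#'   (0 or `NA` = unknown parent). Must be acyclic.
#' @return named numeric vector of inbreeding coefficients, in the input
#'   row order. Founders and individuals with an unknown parent get 0.
#' @export
f_pedigree <- function(pedigree) {
  ped <- data.frame(id = pedigree$id,
                    sire = ifelse(is.na(pedigree$sire), 0, pedigree$sire),
                    dam = ifelse(is.na(pedigree$dam), 0, pedigree$dam))
  n <- nrow(ped)
  ord <- pedigree_order(ped)
  pos <- integer(n); pos[ord] <- seq_len(n)      # topological rank of row
  # re-index in topological order
  sire <- match(ped$sire, ped$id)[ord]
  dam <- match(ped$dam, ped$id)[ord]
  sire <- ifelse(is.na(sire), 0L, pos[sire])
  dam <- ifelse(is.na(dam), 0L, pos[dam])
  Fcoef <- rep(0, n)
  dvec <- function() {
    fs <- rep(NA_real_, n); fs[sire > 0] <- Fcoef[sire[sire > 0]]
    fd <- rep(NA_real_, n); fd[dam > 0] <- Fcoef[dam[dam > 0]]
    d <- rep(1, n)
    both <- sire > 0 & dam > 0
    one <- xor(sire > 0, dam > 0)
    d[both] <- 0.5 - 0.25 * (fs[both] + fd[both])
    fk <- ifelse(sire > 0, fs, fd)
    d[one] <- 0.75 - 0.25 * fk[one]
    d
  }
  # children lists for the backward sweep
  for (i in seq_len(n)) {
    s <- sire[i]; dm <- dam[i]
    if (s == 0 || dm == 0) next       # unknown parent => F = 0
    D <- dvec()
    # v = A e_dm ; need entry at s
    u <- numeric(n); u[dm] <- 1
    for (k in n:1) {
      if (u[k] == 0) next
      if (sire[k] > 0) u[sire[k]] <- u[sire[k]] + 0.5 * u[k]
      if (dam[k] > 0) u[dam[k]] <- u[dam[k]] + 0.5 * u[k]
    }
    t <- D * u
    v <- numeric(n)
    for (k in seq_len(n)) {
      v[k] <- t[k] +
        (if (sire[k] > 0) 0.5 * v[sire[k]] else 0) +
        (if (dam[k] > 0) 0.5 * v[dam[k]] else 0)
    }
    Fcoef[i] <- 0.5 * v[s]
  }
  out <- numeric(n)
  out[ord] <- Fcoef
  stats::setNames(out, as.character(ped$id))
}
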