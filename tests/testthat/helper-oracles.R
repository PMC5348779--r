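# Independent direct-transcription oracles: deliberately naive loop
# implementations of every printed formula, kept free of any package
# internals so they can certify the vectorized code paths.

o_freq <- function(d) {
  vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]; x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else sum(x) / (2 * length(x))
  }, numeric(1))
}

o_ho_individual <- function(d) {
  vapply(seq_len(nrow(d)), function(i) {
    x <- d[i, ]; x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else sum(x == 1) / length(x)
  }, numeric(1))
}

o_he_per_snp <- function(d) {
  p <- o_freq(d)
  2 * p * (1 - p)
}

o_pn <- function(d, thr = 0.01) {
  p <- o_freq(d)
  maf <- pmin(p, 1 - p)
  mean(maf[!is.na(maf)] > thr)
}

# IBS distance for one pair, counting IBS classes per the printed formula
o_ibs_distance <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  m <- length(x)
  if (m == 0) return(NA_real_)
  ibs2 <- sum(x == y)
  ibs1 <- sum(abs(x - y) == 1)
  1 - (ibs2 + 0.5 * ibs1) / m
}

o_f_eh <- function(d, p) {
  vapply(seq_len(nrow(d)), function(i) {
    tot <- 0; m <- 0
    for (j in seq_len(ncol(d))) {
      c_ <- d[i, j]; pj <- if (is.matrix(p)) p[i, j] else p[j]
      if (is.na(c_) || is.na(pj) || pj <= 0 || pj >= 1) next
      tot <- tot + 1 - c_ * (2 - c_) / (2 * pj * (1 - pj))
      m <- m + 1
    }
    if (m == 0) NA_real_ else tot / m
  }, numeric(1))
}

o_f_vr <- function(d, p) {
  vapply(seq_len(nrow(d)), function(i) {
    num <- 0; den <- 0
    for (j in seq_len(ncol(d))) {
      c_ <- d[i, j]; pj <- if (is.matrix(p)) p[i, j] else p[j]
      if (is.na(pj) || pj <= 0 || pj >= 1) next
      den <- den + pj * (1 - pj)
      if (!is.na(c_)) num <- num + (c_ - 2 * pj)^2
    }
    if (den == 0) NA_real_ else num / (2 * den) - 1
  }, numeric(1))
}

o_f_leut <- function(d, p, literal = FALSE) {
  vapply(seq_len(nrow(d)), function(i) {
    tot <- 0; m <- 0
    for (j in seq_len(ncol(d))) {
      c_ <- d[i, j]; pj <- if (is.matrix(p)) p[i, j] else p[j]
      if (is.na(c_) || is.na(pj) || pj <= 0 || pj >= 1) next
      tot <- tot + (c_ - 2 * pj)^2 / (2 * pj * (1 - pj))
      m <- m + 1
    }
    if (m == 0) NA_real_ else (tot / m) - (if (literal) 0 else 1)
  }, numeric(1))
}

o_fst <- function(freqs) {
  out <- freqs * NA_real_
  for (j in seq_len(ncol(freqs))) {
    p <- freqs[, j]
    def <- which(!is.na(p))
    if (length(def) < 2) { out[def, j] <- 0; next }
    pbar <- mean(p[def])
    den <- pbar * (1 - pbar)
    out[def, j] <- if (den == 0) 0 else (p[def] - pbar)^2 / den
  }
  out
}

o_reynolds <- function(pa, pb) {
  ok <- !is.na(pa) & !is.na(pb)
  num <- den <- 0
  for (l in which(ok)) {
    num <- num + (pa[l] - pb[l])^2
    den <- den + 1 - pa[l] * pb[l] - (1 - pa[l]) * (1 - pb[l])
  }
  unname(if (den == 0) 0 else num / den)
}

o_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  mx <- mean(x); my <- mean(y)
  num <- sum((x - mx) * (y - my))
  (num / sqrt(sum((x - mx)^2) * sum((y - my)^2)))^2
}

o_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# Tabular relationship-matrix method: builds the full numerator
# relationship matrix row by row (parents must precede offspring).
o_tabular_f <- function(ped) {
  n <- nrow(ped)
  s <- match(ped$sire, ped$id)
  d <- match(ped$dam, ped$id)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    Asd <- if (!is.na(s[i]) && !is.na(d[i])) A[s[i], d[i]] else 0
    A[i, i] <- 1 + 0.5 * Asd
    if (i > 1) for (j in seq_len(i - 1)) {
      a <- 0
      if (!is.na(s[i])) a <- a + 0.5 * A[j, s[i]]
      if (!is.na(d[i])) a <- a + 0.5 * A[j, d[i]]
      A[i, j] <- A[j, i] <- a
    }
  }
  stats::setNames(diag(A) - 1, as.character(ped$id))
}
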