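#' VanRaden genomic relationship matrix
#'
#' Dosages are centred by twice the allele frequency; missing calls are
#' imputed to the mean (zero after centring). G = Z Z' / (2 sum p(1-p)),
#' summing over polymorphic SNPs. diag(G) - 1 equals [f_vanraden()]
#' exactly.
#'
#' @param dataset a post-QC [genotype_dataset()].
#' @param freqs optional frequency vector over markers (default: observed
#'   over all samples).
#' @return symmetric n x n matrix with sample ids as dimnames.
#' @export
grm_vanraden <- function(dataset, freqs = NULL) {
  p <- if (is.null(freqs)) allele_freq(dataset) else freqs
  pq <- p * (1 - p)
  poly <- !is.na(pq) & pq > 0
  if (!any(poly)) stop("all SNPs monomorphic: GRM undefined")
  Z <- sweep(dataset$dosages[, poly, drop = FALSE], 2, 2 * p[poly])
  Z[is.na(Z)] <- 0
  G <- tcrossprod(Z) / (2 * sum(pq[poly]))
  dimnames(G) <- list(dataset$samples$sample_id, dataset$samples$sample_id)
  G
}

#' REML fit of the null polygenic model
#'
#' Fits y = mu + g + e with g ~ N(0, sigma2_g G) and e ~ N(0, sigma2_e I)
#' by restricted maximum likelihood: after an eigendecomposition of the
#' (ridged) GRM the likelihood is profiled over the variance ratio
#' delta = sigma2_g / sigma2_e and maximized by one-dimensional search on
#' the log scale. Deterministic. A near-constant phenotype is flagged
#' degenerate with both components ~ 0.
#'
#' @param y numeric phenotype vector, one value per individual.
#' @param grm genomic relationship matrix from [grm_vanraden()].
#' @param ridge diagonal ridge added to the GRM (default 1e-6).
#' @return list with `sigma2_g`, `sigma2_e`, `h2`, `logREML`, `degenerate`
#'   and the eigendecomposition reused by [single_snp_scan()].
#' @export
fit_null_mixed <- function(y, grm, ridge = 1e-6) {
  n <- length(y)
  stopifnot(nrow(grm) == n)
  eig <- eigen(grm + diag(ridge, n), symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- crossprod(U, y)
  xs <- crossprod(U, rep(1, n))
  if (stats::var(y) < .Machine$double.eps * 100)
    return(list(sigma2_g = 0, sigma2_e = 0, h2 = NA_real_,
                logREML = NA_real_, degenerate = TRUE,
                lambda = lambda, U = U))
  reml_ll <- function(log_delta) {
    delta <- exp(log_delta)
    v <- delta * lambda + 1            # V / sigma2_e
    xv <- sum(xs^2 / v)
    beta <- sum(xs * ys / v) / xv
    r <- ys - xs * beta
    rss <- sum(r^2 / v)
    s2e <- rss / (n - 1)
    -0.5 * ((n - 1) * log(2 * pi * s2e) + sum(log(v)) + log(xv) +
              rss / s2e)
  }
  opt <- stats::optimize(reml_ll, interval = c(-12, 12), maximum = TRUE,
                         tol = 1e-8)
  if (!is.finite(opt$objective)) stop("non-finite REML likelihood")
  delta <- exp(opt$maximum)
  v <- delta * lambda + 1
  xv <- sum(xs^2 / v)
  beta <- sum(xs * ys / v) / xv
  s2e <- sum((ys - xs * beta)^2 / v) / (n - 1)
  list(sigma2_g = delta * s2e, sigma2_e = s2e,
       h2 = delta / (delta + 1),
       logREML = opt$objective, degenerate = FALSE,
       lambda = lambda, U = U)
}

#' Single-SNP mixed-model association scan
#'
#' Generalized least squares per SNP with the covariance fixed at the null
#' REML fit (the P3D/EMMAX approximation): the phenotype, intercept and
#' each imputed dosage vector are whitened by V^(-1/2) and an ordinary
#' regression gives the SNP effect, its standard error and a two-sided
#' t-test p-value. Missing dosages are imputed to twice the allele
#' frequency; SNPs with zero dosage variance are reported with effect 0
#' and p = 1. Benjamini-Hochberg q-values are appended.
#'
#' @param dataset a post-QC [genotype_dataset()].
#' @param y numeric phenotype vector.
#' @param null_fit result of [fit_null_mixed()].
#' @return data.frame per SNP: `marker_id`, `chromosome`, `position_bp`,
#'   `beta`, `se`, `p`, `q`.
#' @export
single_snp_scan <- function(dataset, y, null_fit) {
  n <- length(y)
  v <- null_fit$sigma2_g * null_fit$lambda + null_fit$sigma2_e
  if (any(v <= 0)) v <- pmax(v, .Machine$double.eps)
  W <- sweep(t(null_fit$U), 1, sqrt(v), "/")    # V^(-1/2) rotation
  p_all <- allele_freq(dataset)
  Z <- dataset$dosages
  imp <- matrix(2 * p_all, n, ncol(Z), byrow = TRUE)
  Z[is.na(Z)] <- imp[is.na(Z)]
  yt <- as.vector(W %*% y)
  x0 <- as.vector(W %*% rep(1, n))
  Gt <- W %*% Z
  a11 <- sum(x0^2)
  a12 <- colSums(x0 * Gt)
  a22 <- colSums(Gt^2)
  b1 <- sum(x0 * yt)
  b2 <- colSums(Gt * yt)
  det <- a11 * a22 - a12^2
  ok <- det > 1e-12 * a11 * pmax(a22, .Machine$double.eps)
  beta0 <- (a22 * b1 - a12 * b2) / det
  beta1 <- (a11 * b2 - a12 * b1) / det
  yy <- sum(yt^2)
  rss <- yy - (beta0 * b1 + beta1 * b2)
  rss <- pmax(rss, 0)
  df <- n - 2
  s2 <- rss / df
  se <- sqrt(s2 * a11 / det)
  tstat <- beta1 / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  beta1[!ok] <- 0; se[!ok] <- NA_real_; pval[!ok] <- 1
  data.frame(marker_id = dataset$map$marker_id,
             chromosome = dataset$map$chromosome,
             position_bp = dataset$map$position_bp,
             beta = beta1, se = se, p = pval,
             q = stats::p.adjust(pval, method = "BH"),
             row.names = NULL)
}

#' Benjamini-Hochberg FDR adjustment with significance sets
#'
#' @param pvalues numeric p-values in (0, 1].
#' @param levels FDR levels to report significant sets at.
#' @return list with `q` (q-values in input order) and `significant`, a
#'   named list of index vectors per level.
#' @export
fdr_adjust <- function(pvalues, levels = c(0.01, 0.05)) {
  q <- stats::p.adjust(pvalues, method = "BH")
  sig <- lapply(levels, function(a) which(q <= a))
  names(sig) <- paste0("fdr_", levels)
  list(q = q, significant = sig)
}
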