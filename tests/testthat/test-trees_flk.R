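test_that("Reynolds distance matches per-locus hand evaluation", {
  pa <- c(0.2, 0.5, 0.9)
  pb <- c(0.4, 0.5, 0.1)
  num <- (0.2 - 0.4)^2 + 0 + (0.9 - 0.1)^2
  den <- (0.2 + 0.4 - 2 * 0.2 * 0.4) + (1 - 2 * 0.25) +
    (0.9 + 0.1 - 2 * 0.09)
  D <- reynolds_distance(rbind(a = pa, b = pb))
  expect_equal(D["a", "b"], num / den, tolerance = 1e-12)
  expect_equal(D["a", "b"], o_reynolds(pa, pb), tolerance = 1e-12)
  same <- reynolds_distance(rbind(a = pa, b = pa))
  expect_equal(same["a", "b"], 0)
  opp <- reynolds_distance(rbind(a = c(1, 0, 1), b = c(0, 1, 0)))
  expect_equal(opp["a", "b"], 1)
})

test_that("neighbour joining recovers the worked additive four-taxon tree", {
  labs <- c("a", "b", "c", "d")
  D <- matrix(0, 4, 4, dimnames = list(labs, labs))
  D["a", "b"] <- 3; D["a", "c"] <- 5; D["a", "d"] <- 6
  D["b", "c"] <- 6; D["b", "d"] <- 7; D["c", "d"] <- 7
  D <- D + t(D)
  tree <- nj_tree(D)
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tree))[labs, labs]),
               unname(D), tolerance = 1e-9)
  # ab|cd split with internal branch 1
  internal <- tree$edge.length[tree$edge[, 2] > 4]
  expect_equal(sort(internal), 1, tolerance = 1e-9)
  tip_len <- tree$edge.length[match(1:4, tree$edge[, 2])]
  expect_equal(sort(tip_len), c(1, 2, 3, 4), tolerance = 1e-9)
})

test_that("a star metric collapses the internal branch to zero", {
  labs <- letters[1:4]
  D <- matrix(2, 4, 4, dimnames = list(labs, labs)); diag(D) <- 0
  tree <- nj_tree(D)
  internal <- tree$edge.length[tree$edge[, 2] > 4]
  expect_true(all(abs(internal) < 1e-12))
  expect_true(all(tree$edge.length >= 0))
})

test_that("random additive metrics are reconstructed exactly", {
  for (seed in 1:20) {
    set.seed(seed)
    gen <- ape::rtree(8, br = function(n) runif(n, 0.5, 2))
    D <- ape::cophenetic.phylo(gen)
    rec <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(gen), ape::unroot(rec)), 0,
                 ignore_attr = TRUE)
    expect_equal(
      as.matrix(ape::cophenetic.phylo(rec))[rownames(D), colnames(D)],
      D, tolerance = 1e-9)
  }
})

test_that("local trees equal genome trees when given the whole genome", {
  ds <- rand_dataset(40, 60, seed = 61, miss_rate = 0.02, n_breeds = 4,
                     n_chrom = 1)
  whole <- local_tree(ds, 1, 1, 1e9)
  genome <- nj_tree(reynolds_distance(allele_freq(ds, per_breed = TRUE)))
  expect_equal(ape::dist.topo(whole, genome), 0, ignore_attr = TRUE)
  expect_error(local_tree(ds, 2, 1, 1e9), "fewer than 2")
})

test_that("tree kinship is shared root-path length and PSD", {
  tr <- read_newick(text = "(a:1,b:1);")
  K <- kinship_from_tree(tr)
  expect_equal(K["a", "b"], 0)
  expect_equal(K["a", "a"], 1)
  # sister pair sharing a stem of length s
  tr2 <- read_newick(text = "((a:1,b:1):0.5,c:2);")
  K2 <- kinship_from_tree(tr2)
  expect_equal(K2["a", "b"], K2["a", "a"] - 1)
  expect_true(K2["a", "b"] > 0)
  for (seed in 1:25) {
    set.seed(seed)
    K3 <- kinship_from_tree(ape::rtree(sample(4:10, 1)))
    expect_true(isSymmetric(K3, tol = 1e-10))
    expect_gt(min(eigen(K3, symmetric = TRUE)$values), -1e-8)
  }
})

test_that("the FLK statistic has its two-population closed form", {
  K <- diag(2); dimnames(K) <- list(c("a", "b"), c("a", "b"))
  fr <- rbind(a = c(0.3, 0.5, 0.9), b = c(0.7, 0.5, 0.2))
  flk <- flk_statistic(fr, K)
  p0 <- (fr[1, ] + fr[2, ]) / 2
  hand <- (fr[1, ] - fr[2, ])^2 / (2 * p0 * (1 - p0))
  expect_equal(flk, unname(hand), tolerance = 1e-6)
  expect_equal(flk[2], 0)          # equal frequencies
  mono <- flk_statistic(rbind(a = c(0, 1), b = c(0, 1)), K)
  expect_equal(mono, c(0, 0))
})

test_that("neutral drift gives FLK a chi-square scale and calibrated tails", {
  set.seed(71)
  npop <- 5; m <- 20000
  Fd <- c(0.05, 0.08, 0.1, 0.12, 0.15)
  p0 <- runif(m, 0.15, 0.85)
  fr <- t(vapply(Fd, function(f)
    rbeta(m, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f), numeric(m)))
  rownames(fr) <- paste0("P", 1:npop)
  K <- diag(Fd); dimnames(K) <- list(rownames(fr), rownames(fr))
  flk <- flk_statistic(fr, K)
  expect_lt(abs(mean(flk) - (npop - 1)) / (npop - 1), 0.1)
  pv <- pvalues_by_standardization(flk)
  frac <- mean(pv$p < 0.05)
  expect_gt(frac, 0.02); expect_lt(frac, 0.09)
})

test_that("standardized p-values match the normal tail exactly", {
  set.seed(72)
  x <- rnorm(5000, 3, 2)
  pv <- pvalues_by_standardization(x)
  z <- (x - mean(x)) / sd(x)
  expect_equal(pv$p, pnorm(z, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(pv$neglog10p, -log10(pv$p), tolerance = 1e-12)
  at_mean <- pvalues_by_standardization(c(mean(x), x))$p[1]
  expect_equal(at_mean, 0.5, tolerance = 1e-3)
  p1645 <- pvalues_by_standardization(c(mean(x) + 1.645 * sd(x), x))$p[1]
  expect_equal(p1645, 0.05, tolerance = 1e-3)
  expect_error(pvalues_by_standardization(rep(1, 5)), "zero variance")
})

test_that("Newick round trips preserve topology and branch lengths", {
  t2 <- read_newick(text = "(a:1,b:2);")
  expect_equal(sort(t2$tip.label), c("a", "b"))
  expect_error(read_newick(text = "((a:1,b:2;"), "")
  for (seed in 1:25) {
    set.seed(seed)
    tr <- ape::rtree(sample(3:12, 1))
    back <- read_newick(text = write_newick(tr))
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
                 ignore_attr = TRUE)
    D1 <- ape::cophenetic.phylo(tr)
    expect_equal(as.matrix(ape::cophenetic.phylo(back))[rownames(D1),
                                                        colnames(D1)],
                 D1, tolerance = 1e-9)
  }
})
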