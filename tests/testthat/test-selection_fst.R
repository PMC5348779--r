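test_that("group frequencies pool calls and flag empty groups", {
  ds <- rand_dataset(6, 20, seed = 3, miss_rate = 0, n_breeds = 1)
  scheme <- setNames(c("g1", "g1", "g1", "g2", "g2", "g2"),
                     ds$samples$sample_id)
  gf <- group_allele_frequencies(ds, scheme)
  expect_equal(unname(gf["g1", ]),
               o_freq(ds$dosages[1:3, , drop = FALSE]), tolerance = 1e-12)
  one <- setNames(c("g1", "g2"), ds$samples$sample_id[1:2])
  ds$dosages[1, 1] <- 2L
  gf1 <- group_allele_frequencies(ds, one)
  expect_equal(unname(gf1["g1", 1]), 1)
  expect_error(group_allele_frequencies(ds, setNames("g1", "zzz")),
               "unknown sample")
})

test_that("per-SNP FST follows the group-deviation definition", {
  f <- fst_per_snp(rbind(g1 = 1, g2 = 0))
  expect_equal(unname(f[, 1]), c(1, 1))
  expect_equal(unname(fst_per_snp(rbind(a = 0.3, b = 0.3, c = 0.3))[, 1]),
               c(0, 0, 0))
  f3 <- fst_per_snp(rbind(a = 0.2, b = 0.2, c = 0.8))
  expect_equal(unname(f3[, 1]), c(1, 1, 4) / 6, tolerance = 1e-10)
  # matches the loop oracle on random frequencies with gaps
  set.seed(8)
  fr <- matrix(runif(5 * 40), 5, 40, dimnames = list(paste0("g", 1:5)))
  fr[sample(200, 20)] <- NA
  expect_equal(fst_per_snp(fr), o_fst(fr), tolerance = 1e-12)
})

test_that("scenario 1 averages pairwise FST over the other breeds", {
  ds <- rand_dataset(40, 60, seed = 51, miss_rate = 0.05, n_breeds = 4)
  f1 <- fst_scenario1(ds)
  pf <- allele_freq(ds, per_breed = TRUE)
  # loop-over-pairs oracle
  K <- nrow(pf)
  for (a in seq_len(K)) {
    acc <- rep(0, ncol(pf)); cnt <- rep(0, ncol(pf))
    for (b in setdiff(seq_len(K), a)) {
      v <- o_fst(pf[c(a, b), ])[1, ]
      ok <- !is.na(v)
      acc[ok] <- acc[ok] + v[ok]; cnt[ok] <- cnt[ok] + 1
    }
    expect_equal(unname(f1[a, ]), ifelse(cnt > 0, acc / cnt, NA),
                 tolerance = 1e-12)
  }
  # two breeds: equals the plain pairwise value
  ds2 <- rand_dataset(20, 30, seed = 52, n_breeds = 2)
  pf2 <- allele_freq(ds2, per_breed = TRUE)
  expect_equal(fst_scenario1(ds2), fst_per_snp(pf2), tolerance = 1e-12)
})

test_that("grouped scenarios reduce to per-SNP FST on pooled groups", {
  ds <- rand_dataset(30, 50, seed = 53, miss_rate = 0.05, n_breeds = 3)
  singleton <- c(B1 = "B1", B2 = "B2", B3 = "B3")
  expect_equal(unname(fst_scenarios_grouped(ds, singleton)),
               unname(fst_per_snp(allele_freq(ds, per_breed = TRUE))),
               tolerance = 1e-12)
  # a swept group shows the maximal track in the sweep region
  cfg <- sim_config(n_breeds = 4, n_per_breed = 40, n_snps = 2000,
                    n_chromosomes = 2, drift_F = 0.08, seed = 54)
  swept <- inject_sweep(simulate_breeds(cfg),
                        sweep_spec("B1", 1, 10e6, 12e6, s = 0.95),
                        seed = 9)
  tr <- fst_scenarios_grouped(swept, c(B1 = "meat", B2 = "milk",
                                       B3 = "milk", B4 = "fiber"))
  cols <- swept$map$chromosome == 1 & swept$map$position_bp >= 10e6 &
    swept$map$position_bp <= 12e6
  expect_gt(mean(tr["meat", cols], na.rm = TRUE),
            3 * mean(tr["meat", !cols], na.rm = TRUE))
})

test_that("moving-average smoothing behaves at spikes, ends, constants", {
  map <- rand_map(21, n_chrom = 1)
  const <- rep(0.3, 21)
  expect_equal(smooth_track(const, map, 5), const)
  x <- rep(0, 21); x[11] <- 1
  expect_equal(smooth_track(x, map, 1), x)
  sm <- smooth_track(x, map, 5)
  expect_equal(sm[11], 0.2)
  expect_equal(sm[9], 0.2)
  expect_equal(sm[8], 0)
  # truncation at ends: first value averages positions 1..3
  y <- seq(0, 1, length.out = 21)
  expect_equal(smooth_track(y, map, 5)[1], mean(y[1:3]))
  # windows never cross chromosomes
  map2 <- rand_map(20, n_chrom = 2)
  z <- c(rep(0, 10), rep(1, 10))
  expect_equal(smooth_track(z, map2, 5), z)
  # mean approximately preserved
  set.seed(6)
  r <- runif(200)
  expect_lt(abs(mean(smooth_track(r, rand_map(200, 1), 5)) - mean(r)),
            0.01)
})

test_that("region calling thresholds at mean plus k standard deviations", {
  map <- rand_map(300, n_chrom = 1)
  expect_equal(nrow(call_regions(rep(0.2, 300), map, 3)), 0)
  set.seed(10)
  x <- abs(rnorm(300, 0.02, 0.005))
  x[100:120] <- 0.5
  reg <- call_regions(x, map, 3, "grp")
  expect_equal(nrow(reg), 1)
  expect_equal(reg$threshold_class, "3SD")
  pk <- match(reg$peak_marker_id, map$marker_id)
  expect_true(pk >= 100 && pk <= 120)
  thr <- mean(x) + 3 * sd(x)
  inside <- map$position_bp >= reg$start_bp & map$position_bp <= reg$end_bp
  expect_true(all(x[inside] > thr))
  reg2 <- call_regions(x, map, 2, "grp")
  expect_true(all(reg2$peak_value >= reg$peak_value[1] |
                    reg2$threshold_class == "2SD"))
})

test_that("region sharing is symmetric bp-overlap on one chromosome", {
  regs <- data.frame(group = c("a", "b", "c"),
                     chromosome = c(1, 1, 1),
                     start_bp = c(100, 150, 301),
                     end_bp = c(200, 300, 400))
  sh <- shared_regions(regs)
  expect_equal(sh$shared_with, c("b", "a", ""))
  # randomized regions vs brute-force interval intersection
  set.seed(12)
  rr <- data.frame(group = sample(letters[1:4], 30, replace = TRUE),
                   chromosome = sample(1:3, 30, replace = TRUE),
                   start_bp = sample(1e6, 30))
  rr$end_bp <- rr$start_bp + sample(2e5, 30)
  sh2 <- shared_regions(rr)
  for (i in seq_len(30)) {
    expected <- sort(unique(rr$group[
      rr$group != rr$group[i] & rr$chromosome == rr$chromosome[i] &
        pmax(rr$start_bp, rr$start_bp[i]) <=
          pmin(rr$end_bp, rr$end_bp[i])]))
    expect_equal(sh2$shared_with[i], paste(expected, collapse = ","))
  }
})

test_that("FST value bins are proportions summing to one", {
  expect_equal(unname(fst_distribution_bins(rep(0, 50))[1]), 1)
  set.seed(14)
  v <- runif(500, 0, 0.6)
  pr <- fst_distribution_bins(v)
  expect_equal(sum(pr), 1)
  expect_equal(unname(pr[1]), mean(v <= 0.05))
  expect_equal(unname(pr["0.1-0.15"]), mean(v > 0.1 & v <= 0.15))
})

test_that("regional LD matches a direct correlation oracle", {
  ds <- rand_dataset(60, 40, seed = 55, miss_rate = 0.05, n_breeds = 2)
  ld <- regional_ld(ds, 1, 1, 1e9, maf_min = 0.05)
  for (b in c("B1", "B2")) {
    rows <- ds$samples$breed == b
    cols <- which(ds$map$chromosome == 1)
    db <- ds$dosages[rows, cols, drop = FALSE]
    p <- o_freq(db)
    keep <- which(!is.na(p) & pmin(p, 1 - p) >= 0.05)
    adj <- vapply(seq_len(length(keep) - 1), function(k)
      o_r2(db[, keep[k]], db[, keep[k + 1]]), numeric(1))
    row <- ld[ld$breed == b, ]
    expect_equal(row$n_snps, length(keep))
    expect_equal(row$adjacent_r2_mean, mean(adj), tolerance = 1e-12)
  }
  # duplicated SNP column has r2 = 1 with itself's copy
  d <- rand_dataset(30, 2, seed = 56, miss_rate = 0)$dosages
  d[, 2] <- d[, 1]
  dup <- toy_dataset(d)
  expect_equal(regional_ld(dup, 1, 1, 1e9, maf_min = 0)$adjacent_r2_mean,
               1, tolerance = 1e-12)
})

test_that("independent SNPs show near-zero LD at large n", {
  ds <- rand_dataset(500, 60, seed = 57, miss_rate = 0, n_breeds = 1)
  ld <- regional_ld(ds, 1, 1, 1e9, maf_min = 0.05)
  expect_lt(ld$syntenic_r2_mean, 0.02)
})

test_that("FST tracks are invariant to allele-orientation flips", {
  ds <- rand_dataset(40, 80, seed = 58, miss_rate = 0.05, n_breeds = 3)
  flipped <- flip_alleles(ds, seq(2, 80, by = 2))
  expect_equal(fst_scenario1(ds), fst_scenario1(flipped),
               tolerance = 1e-12)
})
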