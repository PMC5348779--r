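test_that("the minimum-SNP bound evaluates and is monotone", {
  r <- lencz_min_snps(50000, 1000, alpha = 0.05, het = 0.37)
  expect_equal(r$l_real, log(0.05 / (50000 * 1000)) / log(1 - 0.37),
               tolerance = 1e-12)
  expect_equal(r$l_real, 44.85, tolerance = 0.01)
  expect_equal(r$l, 45L)
  expect_lt(lencz_min_snps(50000, 1000, 0.05, 0.6)$l_real, r$l_real)
  expect_gt(lencz_min_snps(50000, 1000, 0.005, 0.37)$l_real, r$l_real)
  expect_error(lencz_min_snps(100, 10, 0.05, het = 0), "het")
})

test_that("an all-homozygous chromosome yields one full-span segment", {
  set.seed(4)
  g <- matrix(sample(c(0L, 2L), 200, replace = TRUE), 1)
  ds <- toy_dataset(g)
  seg <- detect_roh(ds, roh_params(min_snps = 10, min_length_kb = 100))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start_bp, min(ds$map$position_bp))
  expect_equal(seg$end_bp, max(ds$map$position_bp))
  expect_equal(seg$n_snps, 200L)
})

test_that("regular heterozygosity suppresses all segments", {
  g <- rep(c(rep(0L, 9), 1L), 20)       # a het every 10 SNPs
  ds <- toy_dataset(matrix(g, 1))
  seg <- detect_roh(ds, roh_params(min_snps = 20, window_snps = 20,
                                   min_length_kb = 100))
  expect_equal(nrow(seg), 0)
})

test_that("a planted homozygous run is recovered with tight boundaries", {
  cfg <- sim_config(n_breeds = 1, n_per_breed = 20, n_snps = 3000,
                    n_chromosomes = 2, drift_F = 0.05, seed = 44)
  ds <- simulate_breeds(cfg)
  plan <- data.frame(sample_id = "B1_0005", chromosome = 1,
                     start_bp = 20e6, end_bp = 30e6)
  planted <- plant_roh(ds, plan, seed = 7)
  seg <- detect_roh(planted)
  hits <- seg[seg$sample_id == "B1_0005" & seg$chromosome == 1 &
                seg$end_bp >= 20e6 & seg$start_bp <= 30e6, ]
  expect_equal(nrow(hits), 1)
  w <- roh_params()$window_snps * cfg$spacing_bp
  expect_lt(abs(hits$start_bp - 20e6), w)
  expect_lt(abs(hits$end_bp - 30e6), w)
})

test_that("reported segments satisfy every detection constraint", {
  cfg <- sim_config(n_breeds = 2, n_per_breed = 15, n_snps = 4000,
                    n_chromosomes = 3, drift_F = 0.1, seed = 45)
  ds <- simulate_breeds(cfg)
  plan <- data.frame(sample_id = c("B1_0002", "B2_0004", "B2_0004"),
                     chromosome = c(1, 2, 3),
                     start_bp = c(10e6, 5e6, 30e6),
                     end_bp = c(18e6, 14e6, 45e6))
  params <- roh_params(min_snps = 30)
  seg <- detect_roh(plant_roh(ds, plan, seed = 2), params)
  expect_gt(nrow(seg), 0)
  expect_true(all(seg$n_snps >= 30))
  expect_true(all(seg$length_kb >= params$min_length_kb))
  expect_true(all(seg$length_kb / seg$n_snps <= params$max_kb_per_snp))
  # non-overlap within individual x chromosome
  key <- paste(seg$sample_id, seg$chromosome)
  for (k in unique(key)) {
    s <- seg[key == k, ]
    if (nrow(s) > 1) {
      s <- s[order(s$start_bp), ]
      expect_true(all(s$start_bp[-1] > s$end_bp[-nrow(s)]))
    }
  }
  # detection is orientation-invariant
  flip <- flip_alleles(plant_roh(ds, plan, seed = 2), seq(1, 4000, 2))
  expect_equal(detect_roh(flip, params), seg)
})

test_that("per-breed summaries agree with a direct recount", {
  cfg <- sim_config(n_breeds = 2, n_per_breed = 10, n_snps = 2000,
                    n_chromosomes = 2, seed = 46)
  ds <- simulate_breeds(cfg)
  plan <- data.frame(sample_id = c("B1_0001", "B1_0001", "B2_0002"),
                     chromosome = c(1, 2, 1),
                     start_bp = c(5e6, 10e6, 1e6),
                     end_bp = c(15e6, 22e6, 9e6))
  planted <- plant_roh(ds, plan, seed = 5)
  seg <- detect_roh(planted, roh_params(min_snps = 30))
  sm <- summarize_roh(seg, planted)
  for (b in c("B1", "B2")) {
    ids <- planted$samples$sample_id[planted$samples$breed == b]
    counts <- vapply(ids, function(i) sum(seg$sample_id == i), numeric(1))
    kbs <- vapply(ids, function(i) sum(seg$length_kb[seg$sample_id == i]),
                  numeric(1))
    row <- sm[sm$breed == b, ]
    expect_equal(row$nseg_mean, mean(counts))
    expect_equal(row$nseg_max, max(counts))
    expect_equal(row$kb_mean, mean(kbs))
  }
  # individuals without segments count as zero
  expect_true(any(sm$nseg_min == 0))
  # PHOM of an all-homozygous individual is 1
  allhom <- toy_dataset(matrix(rep(c(0L, 2L), 50), 1))
  sm2 <- summarize_roh(detect_roh(allhom, roh_params(min_snps = 5,
                                                     min_length_kb = 100)),
                       allhom)
  expect_equal(sm2$phom, 1)
})

test_that("length categories bin proportions that sum to one", {
  seg <- data.frame(breed = c("X", "X", "X", "Y"),
                    length_kb = c(2000, 7000, 20000, 1000))
  pr <- roh_length_categories(seg)
  expect_equal(unname(pr["X", ]), c(1, 1, 1) / 3)
  expect_equal(unname(pr["Y", ]), c(1, 0, 0))
  expect_equal(unname(rowSums(pr)), c(1, 1))
})
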