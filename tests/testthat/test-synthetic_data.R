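test_that("the generator is a pure function of its seed", {
  cfg <- sim_config(n_breeds = 3, n_per_breed = 15, n_snps = 400, seed = 5)
  d1 <- simulate_breeds(cfg)
  d2 <- simulate_breeds(cfg)
  expect_identical(d1$dosages, d2$dosages)
  expect_identical(d1$map, d2$map)
})

test_that("zero drift keeps breed frequencies at the ancestral values", {
  cfg <- sim_config(n_breeds = 2, n_per_breed = 500, n_snps = 1500,
                    drift_F = 0, missing_rate = 0, seed = 3)
  ds <- simulate_breeds(cfg)
  fst <- fst_scenario1(ds)
  # only binomial sampling noise separates the breeds: E[FST] ~ 1/(2n)
  expect_lt(mean(fst, na.rm = TRUE), 0.005)
  expect_error(sim_config(n_breeds = 2, n_per_breed = 5, n_snps = 100,
                          drift_F = 1), "drift_F")
})

test_that("mean pairwise FST matches a Monte-Carlo oracle of the model", {
  cfg <- sim_config(n_breeds = 2, n_per_breed = 200, n_snps = 20000,
                    drift_F = 0.1, ancestral_freq_range = c(0.15, 0.85),
                    missing_rate = 0, seed = 41)
  ds <- simulate_breeds(cfg)
  observed <- mean(fst_scenario1(ds), na.rm = TRUE)
  # oracle: 1e6 frequency-level replicates of the same generative model,
  # with binomial sampling at the same breed size
  set.seed(99)
  R <- 1e6; Fd <- 0.1; n <- 200
  p0 <- runif(R, 0.15, 0.85)
  pa <- rbeta(R, p0 * (1 - Fd) / Fd, (1 - p0) * (1 - Fd) / Fd)
  pb <- rbeta(R, p0 * (1 - Fd) / Fd, (1 - p0) * (1 - Fd) / Fd)
  pha <- rbinom(R, 2 * n, pa) / (2 * n)
  phb <- rbinom(R, 2 * n, pb) / (2 * n)
  pbar <- (pha + phb) / 2
  den <- pbar * (1 - pbar)
  v <- ifelse(den > 0, ((pha - pbar)^2) / den, 0)
  expect_lt(abs(observed - mean(v)) / mean(v), 0.20)
})

test_that("expected heterozygosity sits in the realistic array band", {
  for (seed in 1:5) {
    cfg <- sim_config(n_breeds = 2, n_per_breed = 60, n_snps = 2000,
                      drift_F = 0.1, ancestral_freq_range = c(0.05, 0.95),
                      seed = seed)
    he <- expected_heterozygosity(simulate_breeds(cfg))
    expect_true(all(he > 0.25 & he < 0.45))
  }
})

test_that("sweep injection moves the target breed's frequencies as specified", {
  cfg <- sim_config(n_breeds = 3, n_per_breed = 40, n_snps = 900,
                    missing_rate = 0.01, seed = 8)
  ds <- simulate_breeds(cfg)
  spec0 <- sweep_spec("B2", 2, 1, 3e6, s = 0)
  expect_identical(inject_sweep(ds, spec0, seed = 1)$dosages, ds$dosages)

  spec1 <- sweep_spec("B2", 2, 1, 3e6, s = 1)
  swept <- inject_sweep(ds, spec1, seed = 1)
  cols <- which(swept$map$chromosome == 2 & swept$map$position_bp <= 3e6)
  rows <- swept$samples$breed == "B2"
  block <- swept$dosages[rows, cols]
  expect_true(all(block[!is.na(block)] == 2))
  # missingness preserved
  expect_identical(is.na(swept$dosages), is.na(ds$dosages))

  spec9 <- sweep_spec("B2", 2, 1, 3e6, s = 0.9)
  swept9 <- inject_sweep(ds, spec9, seed = 2)
  pin <- colMeans(swept9$dosages[rows, cols], na.rm = TRUE) / 2
  pout <- colMeans(swept9$dosages[!rows, cols], na.rm = TRUE) / 2
  expect_gt(mean(pin), mean(pout))
  expect_error(inject_sweep(ds, sweep_spec("nope", 2, 1, 3e6, 0.5)),
               "breed not found")
})

test_that("planted homozygous segments have no heterozygote and no gap", {
  cfg <- sim_config(n_breeds = 2, n_per_breed = 10, n_snps = 600,
                    n_chromosomes = 2, missing_rate = 0.05, seed = 12)
  ds <- simulate_breeds(cfg)
  plan <- data.frame(sample_id = c("B1_0001", "B2_0003"),
                     chromosome = c(1, 2), start_bp = c(1e6, 2e6),
                     end_bp = c(6e6, 8e6))
  planted <- plant_roh(ds, plan, seed = 3)
  for (r in 1:2) {
    i <- match(plan$sample_id[r], planted$samples$sample_id)
    cols <- which(planted$map$chromosome == plan$chromosome[r] &
                  planted$map$position_bp >= plan$start_bp[r] &
                  planted$map$position_bp <= plan$end_bp[r])
    g <- planted$dosages[i, cols]
    expect_false(anyNA(g))
    expect_true(all(g %in% c(0L, 2L)))
  }
  expect_identical(plant_roh(ds, plan[0, ], seed = 1)$dosages, ds$dosages)
  bad <- data.frame(sample_id = "B1_0001", chromosome = 1,
                    start_bp = c(1e6, 4e6), end_bp = c(5e6, 9e6))
  expect_error(plant_roh(ds, bad), "overlapping")
})

test_that("pedigrees are acyclic with inbred full-sib offspring", {
  ped <- simulate_pedigree(20, 4, full_sib_mating_rate = 0.5, seed = 6)
  f <- f_pedigree(ped)           # would error on a cycle
  founders <- ped$sire == 0 & ped$dam == 0
  expect_true(all(f[founders] == 0))
  expect_gt(max(f), 0.2)         # full-sib matings create F >= 0.25
  expect_identical(simulate_pedigree(10, 3, 0.2, seed = 4),
                   simulate_pedigree(10, 3, 0.2, seed = 4))
})

test_that("ear phenotype is the breed code plus an optional dosage effect", {
  ds <- rand_dataset(20, 50, seed = 9, miss_rate = 0, n_breeds = 2)
  y0 <- assign_ear_phenotype(ds, c(B1 = 1, B2 = 1))
  expect_equal(y0, rep(1, 20))
  expect_error(assign_ear_phenotype(ds, c(B1 = 1)), "B2")
  y1 <- assign_ear_phenotype(ds, c(B1 = 0, B2 = 2),
                             qtl = list(marker_id = "m0007", effect = 1))
  base <- ifelse(ds$samples$breed == "B1", 0, 2)
  expect_equal(y1 - base, as.numeric(ds$dosages[, 7]))
  expect_equal(assign_ear_phenotype(ds, c(B1 = 0, B2 = 2),
                                    qtl = list(marker_id = "m0007",
                                               effect = 0)),
               base)
})
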