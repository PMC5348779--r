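#' Default breed design of the simulator
#'
#' Nine breeds emulating a multi-country goat panel: sample sizes 403, 61,
#' 67, 48, 81, 54, 66, 318 and 53 (total 1151), four selection purposes
#' (milk, meat, fiber, dual) and an ear-size code (0 short, 1 average,
#' 2 long) determined by breed.
#'
#' @return data.frame with columns `breed`, `n`, `purpose`, `ear_code`.
#' @export
default_breed_design <- function() {
  data.frame(
    breed = c("AL", "BA", "BC", "CA", "LA", "NU", "RA", "SA", "TO"),
    n = c(403L, 61L, 67L, 48L, 81L, 54L, 66L, 318L, 53L),
    purpose = c("milk", "meat", "meat", "fiber", "milk", "dual",
                "meat", "milk", "milk"),
    ear_code = c(1L, 1L, 1L, 1L, 0L, 2L, 1L, 1L, 1L))
}

#' Simulation configuration
#'
#' Defaults emulate a 50K-array, nine-breed design: 52,088 biallelic SNPs
#' spread over 29 autosomes at 50 kb spacing, per-breed drift F spread over
#' 0.05-0.15 (the observed range of between-breed differentiation on such
#' panels), ancestral frequencies Uniform(0.15, 0.85) -- array SNPs are
#' ascertained toward intermediate frequencies, which puts expected
#' per-breed heterozygosity in the 0.33-0.41 band typical of goat 50K
#' data -- and 1% missing calls.
#'
#' @param n_breeds number of breeds.
#' @param n_per_breed integer vector of breed sizes (recycled if length 1).
#' @param n_snps total SNP count, divided across chromosomes as evenly as
#'   possible (earlier chromosomes take the remainder).
#' @param n_chromosomes number of autosomes (default 29).
#' @param spacing_bp distance between adjacent SNPs (default 50,000).
#' @param drift_F per-breed Balding-Nichols drift parameter in (0,1);
#'   0 means no drift (breed frequencies equal ancestral).
#' @param ancestral_freq_range range of the Uniform ancestral frequency.
#' @param missing_rate probability a call is missing, independently.
#' @param breed_labels optional character vector of breed names.
#' @param seed integer RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_breeds = 9,
                       n_per_breed = default_breed_design()$n,
                       n_snps = 52088,
                       n_chromosomes = 29,
                       spacing_bp = 50000,
                       drift_F = seq(0.05, 0.15, length.out = n_breeds),
                       ancestral_freq_range = c(0.15, 0.85),
                       missing_rate = 0.01,
                       breed_labels = NULL,
                       seed = 1) {
  n_per_breed <- rep_len(as.integer(n_per_breed), n_breeds)
  drift_F <- rep_len(drift_F, n_breeds)
  if (is.null(breed_labels)) {
    breed_labels <- if (n_breeds == 9 &&
                        identical(n_per_breed, default_breed_design()$n))
      default_breed_design()$breed else paste0("B", seq_len(n_breeds))
  }
  stopifnot(length(breed_labels) == n_breeds,
            all(drift_F >= 0), missing_rate >= 0, missing_rate < 1,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
            ancestral_freq_range[1] < ancestral_freq_range[2],
            n_snps >= n_chromosomes)
  if (any(drift_F >= 1)) stop("drift_F must be < 1")
  structure(list(n_breeds = n_breeds, n_per_breed = n_per_breed,
                 n_snps = as.integer(n_snps),
                 n_chromosomes = as.integer(n_chromosomes),
                 spacing_bp = as.integer(spacing_bp),
                 drift_F = drift_F,
                 ancestral_freq_range = ancestral_freq_range,
                 missing_rate = missing_rate,
                 breed_labels = breed_labels, seed = seed),
            class = "sim_config")
}

sim_marker_map <- function(config) {
  base <- config$n_snps %/% config$n_chromosomes
  extra <- config$n_snps %% config$n_chromosomes
  per_chrom <- rep(base, config$n_chromosomes) +
    c(rep(1L, extra), rep(0L, config$n_chromosomes - extra))
  chrom <- rep(seq_len(config$n_chromosomes), per_chrom)
  pos <- unlist(lapply(per_chrom, function(k) seq_len(k) * config$spacing_bp))
  data.frame(marker_id = sprintf("snp%06d", seq_len(config$n_snps)),
             chromosome = chrom, position_bp = as.integer(pos),
             allele_a = "A", allele_b = "B", row.names = NULL)
}

#' Simulate a multi-breed genotype dataset (Balding-Nichols model)
#'
#' Ancestral frequencies are drawn Uniform over `ancestral_freq_range`;
#' each breed's frequency at SNP j is Beta with mean p0_j and variance
#' F * p0_j * (1 - p0_j) (the Balding-Nichols drift model; F = 0 keeps the
#' ancestral frequency exactly); genotypes are Binomial(2, p) under
#' Hardy-Weinberg within breed; calls go missing independently at
#' `missing_rate`. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a [genotype_dataset()].
#' @export
simulate_breeds <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_snps
  map <- sim_marker_map(config)
  p0 <- stats::runif(m, config$ancestral_freq_range[1],
                     config$ancestral_freq_range[2])
  n_total <- sum(config$n_per_breed)
  d <- matrix(NA_integer_, n_total, m)
  row0 <- 0L
  for (b in seq_len(config$n_breeds)) {
    Fb <- config$drift_F[b]
    pb <- if (Fb == 0) p0 else
      stats::rbeta(m, p0 * (1 - Fb) / Fb, (1 - p0) * (1 - Fb) / Fb)
    nb <- config$n_per_breed[b]
    d[row0 + seq_len(nb), ] <-
      matrix(stats::rbinom(nb * m, 2L, rep(pb, each = nb)), nb, m)
    row0 <- row0 + nb
  }
  if (config$missing_rate > 0) {
    miss <- stats::runif(length(d)) < config$missing_rate
    d[miss] <- NA_integer_
  }
  samples <- data.frame(
    sample_id = sprintf("%s_%04d",
                        rep(config$breed_labels, config$n_per_breed),
                        unlist(lapply(config$n_per_breed, seq_len))),
    breed = rep(config$breed_labels, config$n_per_breed),
    row.names = NULL)
  genotype_dataset(d, map, samples)
}

#' Specify a selective sweep to plant
#'
#' @param breed_label breed under selection.
#' @param chromosome,start_bp,end_bp swept interval (1-based, inclusive).
#' @param s selection strength in `[0,1]`: within the region the favoured
#'   allele's frequency p moves to p + s(1-p).
#' @param target_allele `"a"` or `"b"`: which allele is favoured.
#' @return list of class `sweep_spec`.
#' @export
sweep_spec <- function(breed_label, chromosome, start_bp, end_bp,
                       s, target_allele = "b") {
  stopifnot(s >= 0, s <= 1, end_bp >= start_bp,
            target_allele %in% c("a", "b"))
  structure(list(breed_label = breed_label, chromosome = chromosome,
                 start_bp = start_bp, end_bp = end_bp, s = s,
                 target_allele = target_allele), class = "sweep_spec")
}

#' Plant a selective sweep in one breed
#'
#' Within the specified region, the target breed's allele frequencies are
#' pushed toward the favoured allele (p to p + s(1-p)) and the breed's
#' genotypes in the region are re-drawn Binomial(2, p'), so Hardy-Weinberg
#' structure within breed is preserved. The missingness pattern and all
#' other breeds are untouched.
#'
#' @param dataset a [genotype_dataset()].
#' @param spec a [sweep_spec()].
#' @param seed integer RNG seed.
#' @return a [genotype_dataset()].
#' @export
inject_sweep <- function(dataset, spec, seed = 1) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- which(dataset$samples$breed == spec$breed_label)
  if (!length(rows)) stop("breed not found: ", spec$breed_label)
  cols <- which(dataset$map$chromosome == spec$chromosome &
                dataset$map$position_bp >= spec$start_bp &
                dataset$map$position_bp <= spec$end_bp)
  if (!length(cols)) stop("sweep region contains no SNPs")
  if (spec$s == 0) return(dataset)
  set.seed(seed)
  d <- dataset$dosages
  block <- d[rows, cols, drop = FALSE]
  p <- colMeans(block, na.rm = TRUE) / 2       # breed frequency of allele B
  p[!is.finite(p)] <- 0.5
  pb <- if (spec$target_allele == "b") p + spec$s * (1 - p)
        else p * (1 - spec$s)
  redraw <- matrix(stats::rbinom(length(block), 2L,
                                 rep(pb, each = nrow(block))),
                   nrow(block), ncol(block))
  redraw[is.na(block)] <- NA_integer_
  d[rows, cols] <- redraw
  genotype_dataset(d, dataset$map, dataset$samples)
}

#' Plant homozygous segments (ground-truth ROH)
#'
#' For each planned segment the individual is made homozygous at every SNP
#' in the region for a single haplotype drawn from its breed's allele
#' frequencies; missing calls inside the region are cleared (the segment is
#' fully observed), and calls outside are untouched.
#'
#' @param dataset a [genotype_dataset()].
#' @param plan data.frame with columns `sample_id`, `chromosome`,
#'   `start_bp`, `end_bp`.
#' @param seed integer RNG seed.
#' @return a [genotype_dataset()].
#' @export
plant_roh <- function(dataset, plan, seed = 1) {
  if (nrow(plan) == 0) return(dataset)
  key <- paste(plan$sample_id, plan$chromosome)
  for (k in unique(key)) {
    rows <- plan[key == k, , drop = FALSE]
    if (nrow(rows) > 1) {
      o <- order(rows$start_bp)
      if (any(rows$start_bp[o][-1] <= rows$end_bp[o][-nrow(rows)]))
        stop("overlapping planted segments for ", k)
    }
  }
  set.seed(seed)
  d <- dataset$dosages
  pf <- allele_freq(dataset, per_breed = TRUE)
  idx <- match(plan$sample_id, dataset$samples$sample_id)
  if (anyNA(idx)) stop("unknown sample in plan")
  for (r in seq_len(nrow(plan))) {
    i <- idx[r]
    cols <- which(dataset$map$chromosome == plan$chromosome[r] &
                  dataset$map$position_bp >= plan$start_bp[r] &
                  dataset$map$position_bp <= plan$end_bp[r])
    if (length(cols) < 2) stop("planted region must contain >= 2 SNPs")
    p <- pf[dataset$samples$breed[i], cols]
    p[!is.finite(p)] <- 0.5
    hap <- stats::rbinom(length(cols), 1L, p)
    d[i, cols] <- 2L * hap
  }
  genotype_dataset(d, dataset$map, dataset$samples)
}

#' Simulate a discrete-generation pedigree
#'
#' Founders (generation 0) have unknown parents. Each later generation has
#' as many individuals as the founder generation; each offspring's sire and
#' dam are drawn from the previous generation, and a stated fraction of
#' matings is between full sibs (when a full-sib male/female pair exists),
#' creating inbreeding loops. Sexes alternate within each generation.
#'
#' @param n_founders number of founders (>= 2).
#' @param n_generations number of offspring generations.
#' @param full_sib_mating_rate fraction of matings between full sibs.
#' @param seed integer RNG seed.
#' @return data.frame with columns `id`, `sire`, `dam` (0 = unknown),
#'   parents always listed before offspring.
#' @export
simulate_pedigree <- function(n_founders, n_generations,
                              full_sib_mating_rate = 0, seed = 1) {
  stopifnot(n_founders >= 2, n_generations >= 0,
            full_sib_mating_rate >= 0, full_sib_mating_rate <= 1)
  set.seed(seed)
  id <- seq_len(n_founders)
  sire <- dam <- rep(0L, n_founders)
  sex <- rep_len(c("M", "F"), n_founders)
  prev <- data.frame(id = id, sire = sire, dam = dam, sex = sex)
  all_rows <- prev
  next_id <- n_founders + 1L
  for (g in seq_len(n_generations)) {
    males <- prev$id[prev$sex == "M"]
    females <- prev$id[prev$sex == "F"]
    kids <- vector("list", n_founders)
    for (k in seq_len(n_founders)) {
      use_fs <- stats::runif(1) < full_sib_mating_rate
      pair <- NULL
      if (use_fs && nrow(prev) && any(prev$sire > 0)) {
        fam <- paste(prev$sire, prev$dam)
        for (f in sample(unique(fam[prev$sire > 0]))) {
          ms <- prev$id[fam == f & prev$sex == "M"]
          fs <- prev$id[fam == f & prev$sex == "F"]
          if (length(ms) && length(fs)) {
            pair <- c(ms[sample.int(length(ms), 1)],
                      fs[sample.int(length(fs), 1)])
            break
          }
        }
      }
      if (is.null(pair))
        pair <- c(males[sample.int(length(males), 1)],
                  females[sample.int(length(females), 1)])
      kids[[k]] <- data.frame(id = next_id, sire = pair[1], dam = pair[2],
                              sex = c("M", "F")[1 + (k %% 2)])
      next_id <- next_id + 1L
    }
    prev <- do.call(rbind, kids)
    all_rows <- rbind(all_rows, prev)
  }
  data.frame(id = all_rows$id, sire = as.integer(all_rows$sire),
             dam = as.integer(all_rows$dam), row.names = NULL)
}

#' Breed-coded ear phenotype, optionally with a planted QTL
#'
#' The base phenotype is the breed's ear code (0 short, 1 average, 2 long).
#' If a QTL is supplied, `effect` times the individual's dosage at that
#' marker is added and the result kept as a real number (for power
#' studies); missing dosages at the QTL contribute the breed-frequency
#' expectation 2p.
#'
#' @param dataset a [genotype_dataset()].
#' @param breed_codes named vector/list mapping every breed to a code.
#' @param qtl optional list `(marker_id =, effect =)`.
#' @return numeric phenotype vector, one value per individual.
#' @export
assign_ear_phenotype <- function(dataset, breed_codes, qtl = NULL) {
  breeds <- unique(dataset$samples$breed)
  miss <- setdiff(breeds, names(breed_codes))
  if (length(miss))
    stop("breed(s) without ear code: ", paste(miss, collapse = ", "))
  y <- as.numeric(unlist(breed_codes)[dataset$samples$breed])
  if (!is.null(qtl)) {
    j <- match(qtl$marker_id, dataset$map$marker_id)
    if (is.na(j)) stop("QTL marker not found: ", qtl$marker_id)
    g <- dataset$dosages[, j]
    if (anyNA(g)) {
      pf <- allele_freq(dataset, per_breed = TRUE)
      g[is.na(g)] <- 2 * pf[cbind(dataset$samples$breed[is.na(g)],
                                  dataset$map$marker_id[j])]
    }
    y <- y + qtl$effect * g
  }
  unname(y)
}
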