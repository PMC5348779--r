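#' Pipeline configuration
#'
#' Bundles every stage's settings with their standard defaults: MAF 0.01
#' and call rate 0.95 for QC, a five-SNP smoothing window, 2 and 3 SD
#' region thresholds, ROH false-positive tolerance 0.05 and FDR levels 1%
#' and 5%. Exactly one of `sim` (a [sim_config()]) or `ped_path`/
#' `map_path` must be given.
#'
#' @param sim a [sim_config()] for simulation mode.
#' @param ped_path,map_path PLINK text input files (file mode).
#' @param pedigree optional pedigree data.frame (`id`, `sire`, `dam`).
#' @param ear_codes optional named breed-to-code map for the GWAS
#'   phenotype; default codes breed labels `LA` = 0, `NU` = 2, others 1.
#' @param scenarios named list of breed-to-group maps for grouped FST
#'   scenarios (defaults mirror the milk/meat/fiber/dual groupings of the
#'   nine-breed design when its labels are present).
#' @param maf_min,call_rate_min QC thresholds.
#' @param smooth_window smoothing window in SNPs.
#' @param k_sd SD multipliers for region calling.
#' @param roh a [roh_params()].
#' @param fdr_levels FDR levels for the GWAS.
#' @param out_dir output directory.
#' @param seed integer seed governing all randomness.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, ped_path = NULL, map_path = NULL,
                            pedigree = NULL, ear_codes = NULL,
                            scenarios = NULL,
                            maf_min = 0.01, call_rate_min = 0.95,
                            smooth_window = 5, k_sd = c(2, 3),
                            roh = roh_params(),
                            fdr_levels = c(0.01, 0.05),
                            out_dir = "results", seed = 1) {
  if (is.null(sim) == (is.null(ped_path) || is.null(map_path)))
    stop("give exactly one of `sim` or `ped_path`+`map_path`")
  structure(list(sim = sim, ped_path = ped_path, map_path = map_path,
                 pedigree = pedigree, ear_codes = ear_codes,
                 scenarios = scenarios, maf_min = maf_min,
                 call_rate_min = call_rate_min,
                 smooth_window = smooth_window, k_sd = k_sd, roh = roh,
                 fdr_levels = fdr_levels, out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

default_scenarios <- function(breeds) {
  sc <- list()
  if (all(c("AL", "SA", "CA", "BA", "BC") %in% breeds)) {
    sc$FST2 <- c(AL = "milk", SA = "milk", BA = "meat", BC = "meat",
                 CA = "fiber")
    sc$FST3 <- c(AL = "milk", LA = "milk", SA = "milk", TO = "milk",
                 BA = "meat", BC = "meat", RA = "meat",
                 NU = "dual", CA = "fiber")
  }
  sc
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Simulates or loads genotypes, applies QC, and produces: the QC report,
#' the per-breed diversity table, the per-individual inbreeding table and
#' its correlation matrix, ROH segments and per-breed summaries, raw and
#' smoothed FST tracks with called regions for the individual-breed
#' scenario and any grouped scenarios, the Reynolds/NJ genome tree, FLK
#' statistics with standardized p-values, and a mixed-model GWAS of the
#' ear phenotype. All tables are written as TSV under `config$out_dir`
#' together with a run manifest; outputs are deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  message("seed: ", config$seed)
  dataset <- if (!is.null(config$sim)) simulate_breeds(config$sim)
             else read_plink_text(config$ped_path, config$map_path)
  qc <- qc_filter(dataset, config$maf_min, config$call_rate_min)
  dataset <- qc$dataset
  write_tsv(qc$report, file.path(config$out_dir, "qc_report.tsv"))

  div <- breed_diversity_table(dataset)
  write_tsv(div, file.path(config$out_dir, "diversity.tsv"))

  segments <- detect_roh(dataset, config$roh)
  write_tsv(segments, file.path(config$out_dir, "roh_segments.tsv"))
  write_tsv(summarize_roh(segments, dataset),
            file.path(config$out_dir, "roh_summary.tsv"))

  ftab <- data.frame(sample_id = dataset$samples$sample_id,
                     breed = dataset$samples$breed,
                     F_EH = f_excess_homozygosity(dataset, per_breed = TRUE),
                     F_VR = f_vanraden(dataset, per_breed = TRUE),
                     F_LEUT = f_leutenegger(dataset, per_breed = TRUE),
                     F_ROH = f_roh(dataset, segments), row.names = NULL)
  if (!is.null(config$pedigree)) {
    fp <- f_pedigree(config$pedigree)
    ftab$F_PED <- unname(fp[match(ftab$sample_id, names(fp))])
  } else {
    message("no pedigree supplied: skipping pedigree inbreeding")
  }
  write_tsv(ftab, file.path(config$out_dir, "inbreeding.tsv"))
  fcor <- inbreeding_correlations(ftab[, -(1:2), drop = FALSE])
  utils::write.table(fcor, file.path(config$out_dir,
                                     "inbreeding_correlations.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)

  breeds <- sort(unique(dataset$samples$breed))
  scen <- config$scenarios
  if (is.null(scen)) scen <- default_scenarios(breeds)
  tracks <- list(FST1 = fst_scenario1(dataset))
  for (nm in names(scen))
    tracks[[nm]] <- fst_scenarios_grouped(dataset, scen[[nm]])
  regions <- list()
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    for (g in rownames(tr)) {
      sm <- smooth_track(tr[g, ], dataset$map, config$smooth_window)
      reg <- call_regions(sm, dataset$map, k_sd = min(config$k_sd),
                          group_label = paste(nm, g, sep = ":"))
      if (nrow(reg)) regions[[length(regions) + 1]] <- reg
    }
  }
  regions <- if (length(regions)) shared_regions(do.call(rbind, regions))
             else data.frame()
  write_tsv(regions, file.path(config$out_dir, "selection_regions.tsv"))

  pf <- allele_freq(dataset, per_breed = TRUE)
  if (length(breeds) >= 3) {
    tree <- nj_tree(reynolds_distance(pf))
    write_newick(tree, file.path(config$out_dir, "genome_tree.nwk"))
    flk <- flk_statistic(pf, kinship_from_tree(tree))
    flk_p <- pvalues_by_standardization(flk)
    write_tsv(cbind(dataset$map[c("marker_id", "chromosome",
                                  "position_bp")],
                    flk = flk, flk_p),
              file.path(config$out_dir, "flk.tsv"))
  } else tree <- NULL

  codes <- config$ear_codes
  if (is.null(codes)) {
    codes <- stats::setNames(rep(1, length(breeds)), breeds)
    codes[names(codes) == "LA"] <- 0
    codes[names(codes) == "NU"] <- 2
  }
  y <- assign_ear_phenotype(dataset, codes)
  grm <- grm_vanraden(dataset)
  gw <- single_snp_scan(dataset, y, fit_null_mixed(y, grm))
  write_tsv(gw, file.path(config$out_dir, "gwas.tsv"))

  manifest <- data.frame(
    key = c("seed", "n_individuals", "n_snps_post_qc", "maf_min",
            "call_rate_min", "smooth_window", "roh_alpha",
            "package_version"),
    value = c(config$seed, n_individuals(dataset), n_markers(dataset),
              config$maf_min, config$call_rate_min, config$smooth_window,
              config$roh$alpha,
              as.character(utils::packageVersion("capripop"))))
  write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  invisible(list(dataset = dataset, qc_report = qc$report,
                 diversity = div, inbreeding = ftab,
                 inbreeding_correlations = fcor, roh_segments = segments,
                 fst_tracks = tracks, selection_regions = regions,
                 genome_tree = tree, gwas = gw))
}
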