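#' Read PLINK text genotypes (.ped/.map)
#'
#' Parses the whitespace-delimited PLINK text format. Each .ped row carries
#' six header columns (family, individual, sire, dam, sex, phenotype)
#' followed by two allele columns per marker; the family ID is taken as the
#' breed label. For each marker, allele A is the first non-missing allele
#' encountered in file order and allele B the second; dosage counts copies
#' of allele B. A `0 0` pair is a missing call; a half-missing pair such as
#' `A 0` is a format error.
#'
#' @param ped_path path to the .ped file.
#' @param map_path path to the .map file (chromosome, marker id, cM,
#'   position in bp).
#' @return a [genotype_dataset()].
#' @export
read_plink_text <- function(ped_path, map_path) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map_raw <- utils::read.table(map_path, header = FALSE,
                               col.names = c("chromosome", "marker_id",
                                             "cm", "position_bp"),
                               colClasses = c("integer", "character",
                                              "numeric", "integer"))
  m <- nrow(map_raw)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0) {
    return(genotype_dataset(
      matrix(integer(0), 0, m),
      data.frame(marker_id = map_raw$marker_id,
                 chromosome = map_raw$chromosome,
                 position_bp = map_raw$position_bp,
                 allele_a = rep(NA_character_, m),
                 allele_b = rep(NA_character_, m)),
      data.frame(sample_id = character(0), breed = character(0))))
  }
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  lens <- lengths(toks)
  if (any(lens != want))
    stop("ragged .ped row at line ", which(lens != want)[1], ": expected ",
         want, " fields, found ", lens[lens != want][1])
  tok_mat <- matrix(unlist(toks), nrow = n, byrow = TRUE)
  valid <- c("A", "C", "G", "T", "1", "2", "0")
  a1 <- tok_mat[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- tok_mat[, 6L + 2L * seq_len(m), drop = FALSE]
  if (any(!(a1 %in% valid)) || any(!(a2 %in% valid)))
    stop("invalid allele code in .ped (allowed: A C G T 1 2 0)")
  half <- xor(a1 == "0", a2 == "0")
  if (any(half)) {
    idx <- which(half, arr.ind = TRUE)[1, ]
    stop("half-missing genotype at line ", idx[1], ", marker ",
         map_raw$marker_id[idx[2]])
  }
  dosages <- matrix(NA_integer_, n, m)
  allele_a <- rep(NA_character_, m)
  allele_b <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    obs <- c(rbind(a1[, j], a2[, j]))      # file order within each sample
    obs <- obs[obs != "0"]
    seen <- unique(obs)
    if (length(seen) > 2)
      stop("marker ", map_raw$marker_id[j], " has >2 alleles")
    if (length(seen) >= 1) allele_a[j] <- seen[1]
    if (length(seen) == 2) allele_b[j] <- seen[2]
    miss <- a1[, j] == "0"
    d <- (a1[, j] == allele_b[j]) + (a2[, j] == allele_b[j])
    d[is.na(d)] <- 0L                      # monomorphic: no allele B seen
    d[miss] <- NA_integer_
    dosages[, j] <- as.integer(d)
  }
  genotype_dataset(
    dosages,
    data.frame(marker_id = map_raw$marker_id,
               chromosome = map_raw$chromosome,
               position_bp = map_raw$position_bp,
               allele_a = allele_a, allele_b = allele_b,
               row.names = NULL),
    data.frame(sample_id = tok_mat[, 2], breed = tok_mat[, 1],
               row.names = NULL))
}

#' Write PLINK text genotypes (.ped/.map)
#'
#' Inverse of [read_plink_text()]: the breed label is written as the family
#' ID, missing dosages as `0 0`. Markers where allele B was never observed
#' are written with the `0` placeholder for the B allele (they are
#' monomorphic, so the placeholder is never emitted in a genotype).
#'
#' @param dataset a [genotype_dataset()].
#' @param ped_path,map_path output paths.
#' @return invisibly, the two paths.
#' @export
write_plink_text <- function(dataset, ped_path, map_path) {
  map <- dataset$map
  utils::write.table(
    data.frame(map$chromosome, map$marker_id, 0, map$position_bp),
    map_path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  d <- dataset$dosages
  n <- nrow(d); m <- ncol(d)
  if (n == 0) {
    writeLines(character(0), ped_path)
    return(invisible(c(ped_path, map_path)))
  }
  aa <- ifelse(is.na(map$allele_a), "0", map$allele_a)
  ab <- ifelse(is.na(map$allele_b), "0", map$allele_b)
  first <- second <- matrix("0", n, m)
  for (j in seq_len(m)) {
    dj <- d[, j]
    first[, j] <- ifelse(is.na(dj), "0", ifelse(dj == 2, ab[j], aa[j]))
    second[, j] <- ifelse(is.na(dj), "0", ifelse(dj >= 1, ab[j], aa[j]))
  }
  geno <- matrix("", n, 2L * m)
  geno[, seq(1, 2 * m, 2)] <- first
  geno[, seq(2, 2 * m, 2)] <- second
  rows <- cbind(dataset$samples$breed, dataset$samples$sample_id,
                "0", "0", "0", "-9", geno)
  writeLines(apply(rows, 1, paste, collapse = " "), ped_path)
  invisible(c(ped_path, map_path))
}
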