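#' Read PLINK text PED/MAP files into a genotype panel
#'
#' Parses the classical PLINK text dialect: the MAP file has one row per SNP
#' (chromosome, SNP id, genetic position, base-pair position); the PED file
#' has one row per individual (family, individual, sire, dam, sex, phenotype,
#' then two allele columns per SNP). Allele symbols may be A/C/G/T or 1/2;
#' `0` codes a missing allele. A half-missing genotype (one `0` allele) is
#' treated as fully missing, following the PLINK convention.
#'
#' After loading, allele 2 of every SNP is set to the panel-wide minor allele
#' (ties at frequency 0.5 broken lexicographically, the alphabetically first
#' symbol becoming allele 2), and each genotype cell stores the count of
#' allele-2 copies.
#'
#' @param ped_path Path to the PED file.
#' @param map_path Path to the MAP file.
#' @param pop Optional character vector of population labels, one per PED
#'   row; defaults to the PED family column.
#' @param exclude_chrom Chromosome labels to drop (e.g. sex chromosomes, so
#'   that only autosomal SNPs remain). Default none.
#' @return A [gene_panel()]. The PED sire/dam/sex columns are kept in the
#'   individual table (`sire`, `dam`, `sex`).
#' @export
read_ped_map <- function(ped_path, map_path, pop = NULL, exclude_chrom = character()) {
  map <- utils::read.table(map_path,
    header = FALSE, colClasses = "character",
    col.names = c("chrom", "snp_id", "cm", "pos")
  )
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * nrow(map)
  nt <- lengths(toks)
  if (any(nt != want)) {
    stop(sprintf(
      "ragged PED row(s): line %d has %d fields, expected %d",
      which(nt != want)[1], nt[nt != want][1], want
    ), call. = FALSE)
  }
  ped <- do.call(rbind, toks)
  fam <- ped[, 1]
  ids <- ped[, 2]
  a1 <- ped[, 6L + 2L * seq_len(nrow(map)) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(nrow(map)), drop = FALSE]

  ok <- c("A", "C", "G", "T", "1", "2", "0")
  bad <- !(a1 %in% ok & a2 %in% ok)
  if (any(bad)) stop("unrecognized allele symbol in PED file", call. = FALSE)

  geno <- matrix(NA_integer_, nrow = nrow(ped), ncol = nrow(map))
  allele1 <- allele2 <- character(nrow(map))
  for (j in seq_len(nrow(map))) {
    x1 <- a1[, j]
    x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    obs <- c(x1[!miss], x2[!miss])
    sym <- sort(unique(obs))
    if (length(sym) > 2L) {
      stop(sprintf("SNP %s has >2 observed alleles", map$snp_id[j]), call. = FALSE)
    }
    if (length(sym) == 0L) sym <- c("0", "0")
    # monomorphic: the unseen allele (symbol unknown, coded 0) is the minor
    if (length(sym) == 1L) sym <- c(sym, "0")
    if (length(sym) == 2L && all(sym != "0")) {
      # minor allele becomes allele2; at an exact 0.5 tie the
      # lexicographically first symbol (sym is sorted) is taken
      n2 <- sum(obs == sym[2])
      if (n2 * 2L >= length(obs)) sym <- rev(sym)
    }
    allele1[j] <- sym[1]
    allele2[j] <- sym[2]
    g <- (x1 == sym[2]) + (x2 == sym[2])
    g[miss] <- NA_integer_
    geno[, j] <- as.integer(g)
  }

  keep <- !(map$chrom %in% exclude_chrom)
  panel <- gene_panel(
    geno[, keep, drop = FALSE],
    tibble::tibble(
      snp_id = map$snp_id, chrom = map$chrom,
      pos = as.integer(map$pos),
      allele1 = allele1, allele2 = allele2
    )[keep, ],
    tibble::tibble(
      ind_id = ids,
      pop = if (is.null(pop)) fam else as.character(pop),
      sire = ped[, 3], dam = ped[, 4], sex = ped[, 5]
    )
  )
  panel
}

#' Write a genotype panel as PLINK text PED/MAP
#'
#' Inverse of [read_ped_map()]: genotype cells become pairs of allele
#' symbols, missing cells become `0 0`.
#'
#' @param panel A [gene_panel()].
#' @param ped_path,map_path Output paths.
#' @return Invisibly, `c(ped_path, map_path)`.
#' @export
write_ped_map <- function(panel, ped_path, map_path) {
  s <- panel$snps
  utils::write.table(
    data.frame(s$chrom, s$snp_id, 0, s$pos),
    map_path,
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  g <- panel$geno
  n <- nrow(g)
  m <- ncol(g)
  out <- matrix("0", nrow = n, ncol = 2L * m)
  for (j in seq_len(m)) {
    x1 <- ifelse(is.na(g[, j]), "0", ifelse(g[, j] >= 1L, s$allele2[j], s$allele1[j]))
    x2 <- ifelse(is.na(g[, j]), "0", ifelse(g[, j] == 2L, s$allele2[j], s$allele1[j]))
    out[, 2L * j - 1L] <- x1
    out[, 2L * j] <- x2
  }
  ind <- panel$inds
  sire <- if ("sire" %in% names(ind)) ind$sire else "0"
  dam <- if ("dam" %in% names(ind)) ind$dam else "0"
  sex <- ifelse(is.na(ind$sex), "0", ind$sex)
  lead <- cbind(ind$pop, ind$ind_id, sire, dam, sex, "-9")
  writeLines(apply(cbind(lead, out), 1, paste, collapse = " "), ped_path)
  invisible(c(ped_path, map_path))
}

#' Read a VCF file into a genotype panel
#'
#' Optional VCF ingestion mapping diploid GT fields onto the same 0/1/2
#' allele-2 dosage encoding as [read_ped_map()] (ALT is allele 2; the
#' minor-allele reorientation of the PED reader is *not* applied here, the
#' REF/ALT orientation of the file is kept). Requires the vcfR package.
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @param pop Optional population labels, one per sample; default `"pop1"`.
#' @return A [gene_panel()].
#' @export
read_vcf <- function(path, pop = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf() requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt))
  clean <- gsub("\\|", "/", gt)
  dos_t <- ifelse(clean %in% c("0/0"), 0L,
    ifelse(clean %in% c("0/1", "1/0"), 1L,
      ifelse(clean %in% c("1/1"), 2L, NA_integer_)
    )
  )
  dos <- t(matrix(dos_t, nrow = nrow(gt), ncol = ncol(gt)))
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  gene_panel(
    dos,
    tibble::tibble(
      snp_id = ids, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
      allele1 = fix[, "REF"], allele2 = fix[, "ALT"]
    ),
    tibble::tibble(
      ind_id = colnames(gt),
      pop = if (is.null(pop)) "pop1" else as.character(pop)
    )
  )
}
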