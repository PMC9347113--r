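#' Construct a genotype panel
#'
#' A `gene_panel` bundles a biallelic SNP genotype matrix with its marker map
#' and sample sheet. Genotypes are stored as counts of allele 2 (0, 1, 2) with
#' `NA` for missing calls; by convention allele 2 is the panel-wide minor
#' allele when the panel comes from [read_ped_map()] or the simulator.
#'
#' @param geno Integer matrix, individuals in rows and SNPs in columns, cells
#'   in `{0, 1, 2, NA}`. Row and column names are ignored; identities come
#'   from `inds` and `snps`.
#' @param snps Data frame with one row per SNP: `snp_id`, `chrom` (opaque
#'   chromosome label), `pos` (1-based base-pair position), and optionally
#'   `allele1`, `allele2` (the symbols counted as 0 and 2 copies).
#' @param inds Data frame with one row per individual: `ind_id`, `pop`
#'   (population label, non-empty), and optionally `flock` and `sex`.
#'
#' @return An object of class `gene_panel` with elements `geno`, `snps`,
#'   `inds`. SNPs are sorted canonically by chromosome then position.
#' @export
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 2L, 1L, 0L), nrow = 3)
#' gene_panel(g,
#'   snps = data.frame(snp_id = c("s1", "s2"), chrom = "1", pos = c(100, 200)),
#'   inds = data.frame(ind_id = c("a", "b", "c"), pop = "P1")
#' )
gene_panel <- function(geno, snps, inds) {
  snps <- tibble::as_tibble(snps)
  inds <- tibble::as_tibble(inds)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(nrow(geno) == nrow(inds), ncol(geno) == nrow(snps))
  if (!all(c("snp_id", "chrom", "pos") %in% names(snps))) {
    stop("`snps` needs columns snp_id, chrom, pos", call. = FALSE)
  }
  if (!all(c("ind_id", "pop") %in% names(inds))) {
    stop("`inds` needs columns ind_id, pop", call. = FALSE)
  }
  if (!("allele1" %in% names(snps))) snps$allele1 <- "1"
  if (!("allele2" %in% names(snps))) snps$allele2 <- "2"
  if (!("flock" %in% names(inds))) inds$flock <- NA_character_
  if (!("sex" %in% names(inds))) inds$sex <- NA_character_
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  inds$ind_id <- as.character(inds$ind_id)
  inds$pop <- as.character(inds$pop)

  if (anyDuplicated(inds$ind_id)) {
    stop("duplicated individual identifiers: ",
      paste(unique(inds$ind_id[duplicated(inds$ind_id)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(snps$snp_id)) {
    stop("duplicated SNP identifiers", call. = FALSE)
  }
  if (any(is.na(inds$pop) | inds$pop == "")) {
    stop("population labels must be non-empty", call. = FALSE)
  }
  bad <- !(geno %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("genotype cells must be 0, 1, 2 or NA", call. = FALSE)
  if (any(!is.na(snps$pos) & snps$pos <= 0L)) {
    stop("positions must be positive integers", call. = FALSE)
  }

  ord <- order(snps$chrom, snps$pos)
  snps <- snps[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  dup <- duplicated(snps[, c("chrom", "pos")])
  if (any(dup)) {
    stop("positions must be strictly increasing within a chromosome", call. = FALSE)
  }
  dimnames(geno) <- list(inds$ind_id, snps$snp_id)
  structure(list(geno = geno, snps = snps, inds = inds), class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf(
    "<gene_panel> %d individuals x %d SNPs on %d chromosome(s)\n",
    nrow(x$geno), ncol(x$geno), length(unique(x$snps$chrom))
  ))
  cat(
    "populations:",
    paste(sprintf("%s (%d)", names(table(x$inds$pop)), table(x$inds$pop)),
      collapse = ", "
    ), "\n"
  )
  miss <- mean(is.na(x$geno))
  cat(sprintf("call rate: %.2f%%\n", 100 * (1 - miss)))
  invisible(x)
}

#' Number of individuals / SNPs in a panel
#' @param panel A [gene_panel()].
#' @return Integer count.
#' @export
n_ind <- function(panel) nrow(panel$geno)

#' @rdname n_ind
#' @export
n_snp <- function(panel) ncol(panel$geno)

#' Subset a genotype panel
#'
#' @param panel A [gene_panel()].
#' @param ind Individual ids, logical mask or integer indices (default all).
#' @param snp SNP ids, logical mask or integer indices (default all).
#' @return A new `gene_panel`.
#' @export
panel_subset <- function(panel, ind = NULL, snp = NULL) {
  ii <- resolve_idx(ind, panel$inds$ind_id, "individual")
  jj <- resolve_idx(snp, panel$snps$snp_id, "SNP")
  gene_panel(
    panel$geno[ii, jj, drop = FALSE],
    panel$snps[jj, , drop = FALSE],
    panel$inds[ii, , drop = FALSE]
  )
}

resolve_idx <- function(sel, ids, what) {
  if (is.null(sel)) return(seq_along(ids))
  if (is.logical(sel)) {
    stopifnot(length(sel) == length(ids))
    return(which(sel))
  }
  if (is.numeric(sel)) return(as.integer(sel))
  idx <- match(sel, ids)
  if (anyNA(idx)) {
    stop("unknown ", what, " id(s): ",
      paste(utils::head(sel[is.na(idx)], 5), collapse = ", "),
      call. = FALSE
    )
  }
  idx
}

#' Individuals belonging to a population or flock
#' @param panel A [gene_panel()].
#' @param pop Population label(s); `NULL` keeps all.
#' @param flock Flock label(s); `NULL` keeps all.
#' @return A `gene_panel` restricted to the matching individuals.
#' @export
panel_pop <- function(panel, pop = NULL, flock = NULL) {
  keep <- rep(TRUE, n_ind(panel))
  if (!is.null(pop)) {
    if (!all(pop %in% panel$inds$pop)) {
      stop("unknown population label(s): ",
        paste(setdiff(pop, panel$inds$pop), collapse = ", "),
        call. = FALSE
      )
    }
    keep <- keep & panel$inds$pop %in% pop
  }
  if (!is.null(flock)) keep <- keep & panel$inds$flock %in% flock
  panel_subset(panel, ind = keep)
}

#' Tidy a panel into long genotype records
#'
#' @param x A [gene_panel()].
#' @param ... Unused.
#' @return A tibble with columns `ind_id`, `pop`, `snp_id`, `chrom`, `pos`,
#'   `dosage` (allele-2 count, `NA` when missing).
#' @method tidy gene_panel
#' @export
tidy.gene_panel <- function(x, ...) {
  tibble::tibble(
    ind_id = rep(x$inds$ind_id, times = n_snp(x)),
    pop = rep(x$inds$pop, times = n_snp(x)),
    snp_id = rep(x$snps$snp_id, each = n_ind(x)),
    chrom = rep(x$snps$chrom, each = n_ind(x)),
    pos = rep(x$snps$pos, each = n_ind(x)),
    dosage = as.integer(x$geno)
  )
}

#' One-line panel summary
#' @param x A [gene_panel()].
#' @param ... Unused.
#' @return A one-row tibble: counts, chromosomes, call rate.
#' @method glance gene_panel
#' @export
glance.gene_panel <- function(x, ...) {
  tibble::tibble(
    n_ind = n_ind(x),
    n_snp = n_snp(x),
    n_chrom = length(unique(x$snps$chrom)),
    n_pop = length(unique(x$inds$pop)),
    call_rate = 1 - mean(is.na(x$geno))
  )
}
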