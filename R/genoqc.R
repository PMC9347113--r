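#' Panel-wide allele-2 frequencies (internal helper shared with divstats)
#' @noRd
panel_freq <- function(panel, rows = seq_len(n_ind(panel))) {
  g <- panel$geno[rows, , drop = FALSE]
  colMeans(g, na.rm = TRUE) / 2
}

#' Quality-control filters for a genotype panel
#'
#' Applies, in a fixed logged order, (1) an individual missingness filter,
#' (2) a SNP missingness filter, then (3) a minor-allele-frequency filter on
#' the retained individuals. The MAF filter keeps SNPs whose panel-wide MAF
#' is strictly greater than `maf_min`.
#'
#' @param panel A [gene_panel()].
#' @param maf_min MAF threshold (strict `>`), default 0.001.
#' @param max_missing_snp Maximum fraction of missing calls per SNP, default
#'   0.05 (call rate >= 95%).
#' @param max_missing_ind Maximum fraction of missing calls per individual,
#'   default 0.05.
#' @param quiet Suppress the per-stage log lines on stderr.
#' @return A list with `panel` (the filtered panel) and `report`, a tibble
#'   with one row per filter stage (counts before/after, removed ids) plus
#'   the overall call rate of the retained panel.
#' @export
filter_panel <- function(panel, maf_min = 0.001, max_missing_snp = 0.05,
                         max_missing_ind = 0.05, quiet = FALSE) {
  stopifnot(
    maf_min >= 0, maf_min <= 1,
    max_missing_snp >= 0, max_missing_snp <= 1,
    max_missing_ind >= 0, max_missing_ind <= 1
  )
  stages <- list()
  log_stage <- function(stage, before, after, removed) {
    if (!quiet) {
      message(sprintf(
        "[qc] %-18s %d -> %d (-%d)", stage, before, after, length(removed)
      ))
    }
    tibble::tibble(
      stage = stage, unit = if (grepl("individual", stage)) "individual" else "snp",
      n_before = before, n_after = after, removed = list(removed)
    )
  }

  miss_ind <- rowMeans(is.na(panel$geno))
  keep_i <- miss_ind <= max_missing_ind
  stages[[1]] <- log_stage(
    "individual-miss", n_ind(panel), sum(keep_i),
    panel$inds$ind_id[!keep_i]
  )
  panel <- panel_subset(panel, ind = keep_i)
  if (n_ind(panel) == 0L) stop("all individuals removed by QC", call. = FALSE)

  miss_snp <- colMeans(is.na(panel$geno))
  keep_s <- miss_snp <= max_missing_snp
  stages[[2]] <- log_stage(
    "snp-miss", n_snp(panel), sum(keep_s),
    panel$snps$snp_id[!keep_s]
  )
  panel <- panel_subset(panel, snp = keep_s)

  p <- panel_freq(panel)
  maf <- pmin(p, 1 - p)
  keep_m <- !is.na(maf) & maf > maf_min
  stages[[3]] <- log_stage(
    "maf", n_snp(panel), sum(keep_m),
    panel$snps$snp_id[!keep_m]
  )
  panel <- panel_subset(panel, snp = keep_m)
  if (n_snp(panel) == 0L) stop("all SNPs removed by QC", call. = FALSE)

  report <- dplyr::bind_rows(stages)
  report$call_rate_after <- 1 - mean(is.na(panel$geno))
  list(panel = panel, report = report)
}

#' Squared genotype correlation between two SNPs
#'
#' Composite linkage disequilibrium r-squared: the squared Pearson
#' correlation of unphased allele-count vectors over pairwise-complete
#' observations. Returns `NA` (not prunable against) when either vector has
#' zero variance or fewer than two complete pairs.
#'
#' @param g1,g2 Integer dosage vectors of equal length (0/1/2/NA).
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
genotype_r2 <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2L) return(NA_real_)
  x <- g1[ok]
  y <- g2[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Windowed LD pruning of a genotype panel
#'
#' Greedy within-window pruning in the indep-pairwise style: per chromosome,
#' a window of `window_snps` markers slides by `step_snps`; within each
#' window, while any pair of retained markers has r-squared above `r2_max`,
#' one member of the offending pair is removed -- the one with the lower
#' panel-wide MAF, ties going to the later position. Removed markers stay
#' removed in later windows.
#'
#' @param panel A [gene_panel()] (markers sorted by chromosome and position,
#'   which `gene_panel()` guarantees).
#' @param window_snps Window size in SNPs, default 30.
#' @param step_snps Step size in SNPs, default 10.
#' @param r2_max r-squared threshold above which a pair is in high LD,
#'   default 0.8.
#' @return Character vector of kept SNP ids, in panel order. Use
#'   [panel_subset()] to materialize the pruned panel.
#' @export
prune_ld <- function(panel, window_snps = 30, step_snps = 10, r2_max = 0.8) {
  if (window_snps < 2) stop("window_snps must be >= 2", call. = FALSE)
  if (step_snps < 1) stop("step_snps must be >= 1", call. = FALSE)
  p <- panel_freq(panel)
  maf <- pmin(p, 1 - p)
  keep <- rep(TRUE, n_snp(panel))
  for (chr in unique(panel$snps$chrom)) {
    idx <- which(panel$snps$chrom == chr)
    L <- length(idx)
    starts <- seq(1L, max(1L, L), by = step_snps)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1L, L)]
      repeat {
        live <- win[keep[win]]
        if (length(live) < 2L) break
        drop <- find_ld_victim(panel$geno, live, maf, r2_max)
        if (is.na(drop)) break
        keep[drop] <- FALSE
      }
      if (s + window_snps - 1L >= L) break
    }
  }
  panel$snps$snp_id[keep]
}

# First pair in index order with r2 > threshold decides the victim:
# lower panel-wide MAF loses, tie -> the later position.
find_ld_victim <- function(geno, live, maf, r2_max) {
  for (a in seq_len(length(live) - 1L)) {
    for (b in (a + 1L):length(live)) {
      i <- live[a]
      j <- live[b]
      r2 <- genotype_r2(geno[, i], geno[, j])
      if (!is.na(r2) && r2 > r2_max) {
        if (maf[i] < maf[j]) return(i)
        if (maf[j] < maf[i]) return(j)
        return(j) # equal MAF: remove the later position
      }
    }
  }
  NA_integer_
}
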