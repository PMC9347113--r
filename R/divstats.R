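#' Allele frequencies within a scope
#'
#' Frequency of allele 2 at every SNP, computed either panel-wide
#' (`scope = "global"`) or within one population.
#'
#' @param panel A [gene_panel()].
#' @param scope `"global"` or a population label present in the panel.
#' @return A tibble `snp_id`, `freq` (NaN when no call in scope), `n_obs`
#'   (number of non-missing *allele* observations, i.e. 2 x individuals).
#' @export
allele_frequencies <- function(panel, scope = "global") {
  rows <- if (identical(scope, "global")) {
    seq_len(n_ind(panel))
  } else {
    if (!scope %in% panel$inds$pop) {
      stop("unknown scope label: ", scope, call. = FALSE)
    }
    which(panel$inds$pop == scope)
  }
  g <- panel$geno[rows, , drop = FALSE]
  n_called <- colSums(!is.na(g))
  tibble::tibble(
    snp_id = panel$snps$snp_id,
    freq = unname(colSums(g, na.rm = TRUE) / (2 * n_called)),
    n_obs = unname(2L * n_called)
  )
}

#' Method-of-moments inbreeding coefficient of one individual
#'
#' `F = (Hom_obs - Hom_exp) / (n_loci - Hom_exp)` where `Hom_obs` is the
#' observed number of homozygous loci, `Hom_exp = sum(1 - 2 p (1-p) * N/(N-1))`
#' the expected number under Hardy-Weinberg at the reference allele
#' frequencies `p`, and `N/(N-1)` a small-sample correction with `N` the
#' number of allele observations behind each frequency. Loci with a missing
#' genotype, an unavailable frequency, or `p` outside `(0, 1)` are excluded.
#'
#' @param g Integer dosage vector for one individual (0/1/2/NA).
#' @param p Reference allele-2 frequencies, same length.
#' @param n_obs Allele observation counts behind `p` (same length or scalar);
#'   only used when `correct = TRUE`.
#' @param correct Apply the `N/(N-1)` small-sample correction (default TRUE).
#' @return F (numeric), or `NA` when the denominator is not positive.
#' @export
mom_inbreeding <- function(g, p, n_obs = NULL, correct = TRUE) {
  stopifnot(length(g) == length(p))
  if (correct) {
    if (is.null(n_obs)) stop("n_obs required when correct = TRUE", call. = FALSE)
    n_obs <- rep_len(n_obs, length(p))
  }
  use <- !is.na(g) & !is.na(p) & p > 0 & p < 1
  if (correct) use <- use & n_obs > 1
  if (!any(use)) return(NA_real_)
  p <- p[use]
  het_exp <- 2 * p * (1 - p)
  if (correct) het_exp <- het_exp * n_obs[use] / (n_obs[use] - 1)
  hom_exp <- sum(1 - het_exp)
  hom_obs <- sum(g[use] != 1L)
  denom <- sum(use) - hom_exp
  if (denom <= 0) return(NA_real_)
  (hom_obs - hom_exp) / denom
}

#' Per-individual Fit and Fis for a panel
#'
#' Fit uses allele frequencies estimated across the whole panel (all
#' populations); Fis uses each individual's own-population frequencies. Both
#' are method-of-moments coefficients (see [mom_inbreeding()]).
#'
#' @param panel A [gene_panel()].
#' @param correct Small-sample correction toggle, default TRUE.
#' @return A tibble `ind_id`, `pop`, `fit`, `fis`.
#' @export
inbreeding_fit_fis <- function(panel, correct = TRUE) {
  glob <- allele_frequencies(panel, "global")
  out <- tibble::tibble(
    ind_id = panel$inds$ind_id, pop = panel$inds$pop,
    fit = NA_real_, fis = NA_real_
  )
  for (pp in unique(out$pop)) {
    rows <- which(out$pop == pp)
    loc <- allele_frequencies(panel, pp)
    for (i in rows) {
      g <- panel$geno[i, ]
      out$fit[i] <- mom_inbreeding(g, glob$freq, glob$n_obs, correct)
      out$fis[i] <- mom_inbreeding(g, loc$freq, loc$n_obs, correct)
    }
  }
  out
}

#' Observed and expected heterozygosity of a population
#'
#' `Ho` is the mean over SNPs of the heterozygote fraction among non-missing
#' calls; `He` is the mean over SNPs of `2 p (1 - p)` with `p` the
#' within-population frequency. SNPs with no call in the population are
#' dropped from both means.
#'
#' @param panel A [gene_panel()].
#' @param pop Population label.
#' @return A one-row tibble `pop`, `ho`, `he`, `ho_se`, `he_se` (standard
#'   errors across SNPs), `n_snp_used`.
#' @export
heterozygosity <- function(panel, pop) {
  sub <- panel_pop(panel, pop)
  if (n_ind(sub) == 0L) stop("empty population: ", pop, call. = FALSE)
  g <- sub$geno
  called <- colSums(!is.na(g))
  use <- called > 0L
  ho_snp <- colSums(g == 1L, na.rm = TRUE)[use] / called[use]
  p <- (colSums(g, na.rm = TRUE) / (2 * called))[use]
  he_snp <- 2 * p * (1 - p)
  tibble::tibble(
    pop = pop,
    ho = mean(ho_snp), he = mean(he_snp),
    ho_se = stats::sd(ho_snp) / sqrt(length(ho_snp)),
    he_se = stats::sd(he_snp) / sqrt(length(he_snp)),
    n_snp_used = sum(use)
  )
}

#' Mean MAF and fixed-allele proportion of a population
#'
#' Per SNP with at least one call in the population, the local MAF is
#' `min(p, 1 - p)`; the fixed proportion is the share of such SNPs that are
#' monomorphic (MAF = 0), and the mean MAF averages over all of them (fixed
#' SNPs contributing 0).
#'
#' @inheritParams heterozygosity
#' @return A one-row tibble `pop`, `maf`, `fixed`, `maf_se`, `n_snp_used`.
#' @export
maf_and_fixed <- function(panel, pop) {
  sub <- panel_pop(panel, pop)
  if (n_ind(sub) == 0L) stop("empty population: ", pop, call. = FALSE)
  fr <- allele_frequencies(sub, "global")
  ok <- fr$n_obs > 0L
  maf_snp <- pmin(fr$freq[ok], 1 - fr$freq[ok])
  tibble::tibble(
    pop = pop,
    maf = mean(maf_snp),
    fixed = mean(maf_snp == 0),
    maf_se = stats::sd(maf_snp) / sqrt(length(maf_snp)),
    n_snp_used = sum(ok)
  )
}

#' Per-population diversity summary
#'
#' One row per population with the six classical indices: mean Fit, mean
#' Fis (method-of-moments, with standard errors across individuals),
#' observed and expected heterozygosity, mean MAF and the proportion of
#' fixed alleles.
#'
#' @param panel A [gene_panel()].
#' @param correct Small-sample correction for Fit/Fis, default TRUE.
#' @return A tibble of class `diversity_summary`.
#' @export
diversity_summary <- function(panel, correct = TRUE) {
  ff <- inbreeding_fit_fis(panel, correct)
  by_pop <- dplyr::summarise(
    dplyr::group_by(ff, .data$pop),
    fit_se = stats::sd(.data$fit, na.rm = TRUE) / sqrt(sum(!is.na(.data$fit))),
    fis_se = stats::sd(.data$fis, na.rm = TRUE) / sqrt(sum(!is.na(.data$fis))),
    fit = mean(.data$fit, na.rm = TRUE),
    fis = mean(.data$fis, na.rm = TRUE),
    n_ind = dplyr::n(),
    .groups = "drop"
  )
  pops <- by_pop$pop
  het <- dplyr::bind_rows(lapply(pops, function(p) heterozygosity(panel, p)))
  mf <- dplyr::bind_rows(lapply(pops, function(p) maf_and_fixed(panel, p)))
  out <- dplyr::left_join(by_pop, het, by = "pop")
  out <- dplyr::left_join(out, dplyr::select(mf, -"n_snp_used"), by = "pop")
  class(out) <- c("diversity_summary", class(out))
  out
}

#' Weir-Cockerham Fst
#'
#' Per-SNP variance components (a: among populations, b: among individuals
#' within populations, c: within individuals) of the Weir-Cockerham (1984)
#' theta estimator for biallelic markers and unequal sample sizes, the
#' ratio-of-sums weighted global theta, and the pairwise population matrix.
#' SNPs monomorphic across the involved populations, or observed in fewer
#' than two of them, are excluded from the sums; negative per-SNP components
#' are retained (not truncated).
#'
#' @param panel A [gene_panel()].
#' @param pops Population labels to include (default: all in the panel).
#' @param pairwise Also compute the matrix of pairwise weighted thetas
#'   (default TRUE).
#' @return An object of class `fst_result`: list with `theta` (weighted
#'   global), `per_snp` (tibble `snp_id`, `a`, `b`, `c`, `theta`), `pairwise`
#'   (symmetric matrix or NULL), `pops`.
#' @export
wc_fst <- function(panel, pops = NULL, pairwise = TRUE) {
  if (is.null(pops)) pops <- unique(panel$inds$pop)
  if (length(pops) < 2L) stop("need at least two populations", call. = FALSE)
  comp <- wc_components(panel, pops)
  theta <- sum(comp$a) / sum(comp$a + comp$b + comp$c)
  pw <- NULL
  if (pairwise && length(pops) >= 2L) {
    pw <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
    for (i in seq_len(length(pops) - 1L)) {
      for (j in (i + 1L):length(pops)) {
        cij <- wc_components(panel, pops[c(i, j)])
        pw[i, j] <- pw[j, i] <- sum(cij$a) / sum(cij$a + cij$b + cij$c)
      }
    }
  }
  structure(
    list(theta = theta, per_snp = comp, pairwise = pw, pops = pops),
    class = "fst_result"
  )
}

# Weir & Cockerham 1984 components for every usable SNP.
wc_components <- function(panel, pops) {
  idx <- lapply(pops, function(p) which(panel$inds$pop == p))
  m <- n_snp(panel)
  r_pops <- length(pops)
  n_mat <- p_mat <- h_mat <- matrix(0, r_pops, m)
  for (k in seq_len(r_pops)) {
    g <- panel$geno[idx[[k]], , drop = FALSE]
    n_mat[k, ] <- colSums(!is.na(g))
    p_mat[k, ] <- colSums(g, na.rm = TRUE) / (2 * pmax(n_mat[k, ], 1))
    h_mat[k, ] <- colSums(g == 1L, na.rm = TRUE) / pmax(n_mat[k, ], 1)
  }
  has <- n_mat > 0
  r <- colSums(has)
  n_tot <- colSums(n_mat)
  nbar <- n_tot / pmax(r, 1)
  pbar <- colSums(n_mat * p_mat) / pmax(n_tot, 1)
  hbar <- colSums(n_mat * h_mat) / pmax(n_tot, 1)
  s2 <- colSums(n_mat * (p_mat - rep(pbar, each = r_pops))^2) /
    (pmax(r - 1, 1) * pmax(nbar, 1))
  nc <- (n_tot - colSums(n_mat^2) / pmax(n_tot, 1)) / pmax(r - 1, 1)
  usable <- r >= 2 & pbar > 0 & pbar < 1 & nbar > 1 & nc > 0
  a <- b <- cc <- rep(NA_real_, m)
  i <- usable
  a[i] <- nbar[i] / nc[i] * (s2[i] -
    (pbar[i] * (1 - pbar[i]) - (r[i] - 1) / r[i] * s2[i] - hbar[i] / 4) /
      (nbar[i] - 1))
  b[i] <- nbar[i] / (nbar[i] - 1) * (pbar[i] * (1 - pbar[i]) -
    (r[i] - 1) / r[i] * s2[i] - (2 * nbar[i] - 1) / (4 * nbar[i]) * hbar[i])
  cc[i] <- hbar[i] / 2
  out <- tibble::tibble(
    snp_id = panel$snps$snp_id, a = a, b = b, c = cc,
    theta = a / (a + b + cc)
  )
  out[usable, , drop = FALSE]
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf(
    "<fst_result> weighted global theta = %.4f over %d SNPs, %d populations\n",
    x$theta, nrow(x$per_snp), length(x$pops)
  ))
  invisible(x)
}

#' @method tidy fst_result
#' @export
tidy.fst_result <- function(x, ...) {
  if (is.null(x$pairwise)) {
    return(x$per_snp)
  }
  m <- x$pairwise
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(
    pop_a = rownames(m)[idx[, 1]], pop_b = colnames(m)[idx[, 2]],
    fst = m[idx]
  )
}

#' @method glance fst_result
#' @export
glance.fst_result <- function(x, ...) {
  tibble::tibble(
    theta = x$theta, n_snp = nrow(x$per_snp), n_pop = length(x$pops)
  )
}

#' Nei's standard genetic distance D (1972)
#'
#' `D = -ln( J_AB / sqrt(J_A * J_B) )` where, for biallelic markers with
#' allele-2 frequencies `pA`, `pB`, the identities averaged over loci are
#' `J_A = mean(pA^2 + (1-pA)^2)`, `J_B` likewise, and
#' `J_AB = mean(pA*pB + (1-pA)*(1-pB))`. Loci with a missing frequency in
#' either population are dropped; `Inf` is returned when no alleles are
#' shared anywhere (`J_AB = 0`).
#'
#' @param freqs_a,freqs_b Allele-2 frequency vectors over shared SNPs.
#' @return Nei's D (non-negative, possibly `Inf`).
#' @export
nei_distance <- function(freqs_a, freqs_b) {
  stopifnot(length(freqs_a) == length(freqs_b))
  ok <- !is.na(freqs_a) & !is.na(freqs_b)
  pa <- freqs_a[ok]
  pb <- freqs_b[ok]
  if (!length(pa)) stop("no shared loci with data", call. = FALSE)
  jaa <- mean(pa^2 + (1 - pa)^2)
  jbb <- mean(pb^2 + (1 - pb)^2)
  jab <- mean(pa * pb + (1 - pa) * (1 - pb))
  if (jab == 0) return(Inf)
  -log(jab / sqrt(jaa * jbb))
}

#' Pairwise Nei distance matrix between populations
#' @param panel A [gene_panel()].
#' @param pops Populations to include (default all).
#' @return A symmetric matrix of Nei's D with zero diagonal.
#' @export
nei_distance_matrix <- function(panel, pops = NULL) {
  if (is.null(pops)) pops <- unique(panel$inds$pop)
  fr <- lapply(pops, function(p) {
    f <- allele_frequencies(panel, p)
    f$freq[f$n_obs == 0L] <- NA_real_
    f$freq
  })
  d <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_len(length(pops) - 1L)) {
    for (j in (i + 1L):length(pops)) {
      d[i, j] <- d[j, i] <- nei_distance(fr[[i]], fr[[j]])
    }
  }
  d
}
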