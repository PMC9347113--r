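#' Founder-based effective population size
#'
#' Classical sex-ratio corrected effective size of a founder group,
#' `Ne = 4 * Nm * Nf / (Nm + Nf)`, with `Nm` sires and `Nf` dams. This is
#' the "initial founder-based Ne" of a management program.
#'
#' @param n_males,n_females Positive founder counts by sex (vectorized).
#' @return Effective size (positive numeric).
#' @export
#' @examples
#' founder_effective_size(5, 5) # 10
#' founder_effective_size(20, 33) # 49.8
founder_effective_size <- function(n_males, n_females) {
  if (any(n_males < 1 | n_females < 1)) {
    stop("founder counts must be >= 1", call. = FALSE)
  }
  4 * n_males * n_females / (n_males + n_females)
}

#' Per-generation inbreeding rate from mean inbreeding
#'
#' Inverts the classical recurrence `F_n = 1 - (1 - dF)^n`:
#' `dF = 1 - (1 - mean_F)^(1/n)` over `n` generations, assuming inbreeding
#' and coancestry were zero at the start of the pedigree.
#'
#' @param mean_F Mean inbreeding coefficient, a fraction in `[0, 1)`.
#' @param n_generations Number of generations in the pedigree (>= 1).
#' @return The per-generation rate as a fraction (multiply by 100 for the
#'   percent scale used in reports).
#' @export
#' @examples
#' inbreeding_rate(0.072, 4) # ~0.0185
inbreeding_rate <- function(mean_F, n_generations) {
  if (any(mean_F < 0 | mean_F >= 1)) {
    stop("mean_F must be a fraction in [0, 1)", call. = FALSE)
  }
  if (any(n_generations < 1)) stop("n_generations must be >= 1", call. = FALSE)
  1 - (1 - mean_F)^(1 / n_generations)
}

# Dense kinship matrix over a topologically sorted pedigree (tabular method).
# K[i, i] = (1 + F_i) / 2; unknown parents contribute zero kinship.
kinship_matrix <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]
    d <- di[i]
    f_i <- if (!is.na(s) && !is.na(d)) K[s, d] else 0
    if (i > 1L) {
      js <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + K[s, js]
      if (!is.na(d)) row <- row + K[d, js]
      K[i, js] <- row / 2
      K[js, i] <- row / 2
    }
    K[i, i] <- (1 + f_i) / 2
  }
  K
}

ensure_sorted_ped <- function(ped) {
  ped <- tibble::as_tibble(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  ok <- all(is.na(si) | si < seq_len(nrow(ped))) &&
    all(is.na(di) | di < seq_len(nrow(ped)))
  if (!ok) ped <- read_pedigree(ped) # resort, never return wrong values
  if (!("generation" %in% names(ped))) {
    ped$generation <- pedigree_toposort(ped$id, ped$sire, ped$dam)$depth
  }
  ped
}

#' Pedigree inbreeding coefficients
#'
#' Computes each individual's inbreeding coefficient F as the kinship of its
#' parents, by the exact tabular (recursive) method. Founders and individuals
#' with any unknown parent get F = 0.
#'
#' @param ped Pedigree tibble (see [read_pedigree()]); resorted internally if
#'   parents do not precede offspring.
#' @return A tibble `id`, `F` in pedigree order.
#' @export
#' @examples
#' ped <- read_pedigree(data.frame(
#'   id = c("A", "B", "X", "Y", "Z"),
#'   sire = c(0, 0, "A", "A", "X"),
#'   dam = c(0, 0, "B", "B", "Y")
#' ))
#' pedigree_inbreeding(ped) # Z is full-sib offspring: F = 0.25
pedigree_inbreeding <- function(ped) {
  ped <- ensure_sorted_ped(ped)
  K <- kinship_matrix(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  f <- ifelse(!is.na(si) & !is.na(di), K[cbind(si, di)], 0)
  tibble::tibble(id = ped$id, F = as.numeric(f))
}

#' Equivalent complete generations
#'
#' Pedigree-completeness measure: `EqG_i` is the sum over known ancestors of
#' `(1/2)^depth`, computed by the recurrence
#' `EqG_i = sum over known parents of (1 + EqG_parent) / 2`. Founders have
#' `EqG = 0`.
#'
#' @inheritParams pedigree_inbreeding
#' @return A tibble `id`, `eqg`.
#' @export
equivalent_generations <- function(ped) {
  ped <- ensure_sorted_ped(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  n <- nrow(ped)
  eqg <- numeric(n)
  for (i in seq_len(n)) {
    e <- 0
    if (!is.na(si[i])) e <- e + (1 + eqg[si[i]]) / 2
    if (!is.na(di[i])) e <- e + (1 + eqg[di[i]]) / 2
    eqg[i] <- e
  }
  tibble::tibble(id = ped$id, eqg = eqg)
}

#' Realized effective population size from individual inbreeding increases
#'
#' The individual-increase-in-inbreeding method: for each individual in the
#' reference cohort with equivalent generations `EqG > 1`,
#' `dF_i = 1 - (1 - F_i)^(1 / (EqG_i - 1))`, and
#' `Ne = 1 / (2 * mean(dF_i))`. Individuals with `EqG <= 1` fall outside the
#' method's domain and are excluded.
#'
#' @inheritParams pedigree_inbreeding
#' @param cohort Which individuals form the reference cohort: `"last"`
#'   (default) takes the latest birth cohort (maximum `birth_year` if
#'   present, else maximum generation index), `"all"` uses every eligible
#'   individual, or a character vector of ids.
#' @return A one-row tibble: `ne` (NA when not estimable), `mean_delta_f`,
#'   `n_used`, `mean_F`, `mean_eqg`.
#' @export
realized_effective_size <- function(ped, cohort = "last") {
  ped <- ensure_sorted_ped(ped)
  fi <- pedigree_inbreeding(ped)$F
  eqg <- equivalent_generations(ped)$eqg
  in_cohort <- if (identical(cohort, "all")) {
    rep(TRUE, nrow(ped))
  } else if (identical(cohort, "last")) {
    if ("birth_year" %in% names(ped) && !all(is.na(ped$birth_year))) {
      by <- suppressWarnings(as.numeric(ped$birth_year))
      !is.na(by) & by == max(by, na.rm = TRUE)
    } else {
      ped$generation == max(ped$generation)
    }
  } else {
    ped$id %in% cohort
  }
  use <- in_cohort & eqg > 1
  if (!any(use)) {
    return(tibble::tibble(
      ne = NA_real_, mean_delta_f = NA_real_, n_used = 0L,
      mean_F = NA_real_, mean_eqg = NA_real_
    ))
  }
  dfi <- 1 - (1 - fi[use])^(1 / (eqg[use] - 1))
  mdf <- mean(dfi)
  tibble::tibble(
    ne = if (mdf > 0) 1 / (2 * mdf) else NA_real_,
    mean_delta_f = mdf,
    n_used = sum(use),
    mean_F = mean(fi[in_cohort]),
    mean_eqg = mean(eqg[in_cohort])
  )
}

#' Demographic summary of one or many managed populations
#'
#' Mirrors the layout of a management-program report: founder counts and
#' founder Ne, generation count, mean pedigree inbreeding (percent), realized
#' Ne and per-generation inbreeding rate (percent).
#'
#' @param management Data frame with columns `pop`, `n_male_founders`,
#'   `n_female_founders`, `n_generations`, and either `mean_F_pct` (percent)
#'   or a `pedigree` list-column of pedigree tibbles from which mean F of the
#'   latest cohort is computed.
#' @return A tibble with one row per population: inputs plus `ne_founders`,
#'   `delta_f_pct`, and (when pedigrees are supplied) `ne_demo`.
#' @export
pedigree_stats <- function(management) {
  df <- tibble::as_tibble(management)
  stopifnot(all(c("pop", "n_male_founders", "n_female_founders", "n_generations")
  %in% names(df)))
  df$ne_founders <- founder_effective_size(df$n_male_founders, df$n_female_founders)
  if (!("mean_F_pct" %in% names(df)) && "pedigree" %in% names(df)) {
    stats <- purrr::map(df$pedigree, realized_effective_size)
    df$mean_F_pct <- purrr::map_dbl(stats, ~ 100 * .x$mean_F)
    df$ne_demo <- purrr::map_dbl(stats, "ne")
  }
  df$delta_f_pct <- NA_real_
  ok <- !is.na(df$mean_F_pct) & !is.na(df$n_generations)
  if (any(ok)) {
    df$delta_f_pct[ok] <-
      100 * inbreeding_rate(df$mean_F_pct[ok] / 100, df$n_generations[ok])
  }
  dplyr::relocate(
    df, "pop", "n_male_founders", "n_female_founders",
    "n_generations", "ne_founders", "mean_F_pct", "delta_f_pct"
  )
}
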