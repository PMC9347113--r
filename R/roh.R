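#' Parameters for runs-of-homozygosity detection
#'
#' Defaults follow the classical 50K-chip scanning convention: a segment must
#' span at least 500 kb, contain at least 30 SNPs at a density of one SNP per
#' 50 kb or better, and the scanning window is 50 SNPs wide allowing one
#' heterozygous and one missing call. The window hit-fraction threshold
#' (0.05) and the maximum gap between consecutive SNPs inside a segment
#' (1 Mb) are the scanning tool defaults the panel-specific parameters are
#' usually combined with; both are exposed here.
#'
#' @param min_length_bp Minimum segment length in bp (default 500,000).
#' @param min_snps Minimum number of SNPs in a segment (default 30).
#' @param max_bp_per_snp Density bound: a segment needs at least one SNP per
#'   this many bp (default 50,000).
#' @param scan_window_snps Scanning window size in SNPs (default 50).
#' @param max_het_per_window Heterozygous calls allowed per window (default 1).
#' @param max_missing_per_window Missing calls allowed per window (default 1).
#' @param window_hit_fraction Minimum fraction of qualifying windows covering
#'   a SNP for it to be ROH-eligible (default 0.05, compared with `>=`).
#' @param max_gap_bp Maximum bp gap between consecutive SNPs in a segment
#'   (default 1,000,000).
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(min_length_bp = 500000, min_snps = 30,
                       max_bp_per_snp = 50000, scan_window_snps = 50,
                       max_het_per_window = 1, max_missing_per_window = 1,
                       window_hit_fraction = 0.05, max_gap_bp = 1000000) {
  p <- list(
    min_length_bp = min_length_bp, min_snps = min_snps,
    max_bp_per_snp = max_bp_per_snp, scan_window_snps = scan_window_snps,
    max_het_per_window = max_het_per_window,
    max_missing_per_window = max_missing_per_window,
    window_hit_fraction = window_hit_fraction, max_gap_bp = max_gap_bp
  )
  stopifnot(
    all(unlist(p[c(1:4, 8)]) > 0),
    window_hit_fraction > 0, window_hit_fraction <= 1,
    max_het_per_window >= 0, max_missing_per_window >= 0
  )
  structure(p, class = "roh_params")
}

# Eligibility of each SNP on one chromosome track (positions sorted).
# Windows slide one SNP at a time; with fewer SNPs than the window size a
# single truncated window is used, keeping the same absolute allowances.
roh_eligible <- function(calls, params) {
  L <- length(calls)
  w <- params$scan_window_snps
  is_het <- !is.na(calls) & calls == 1L
  is_mis <- is.na(calls)
  if (L <= w) {
    ok <- sum(is_het) <= params$max_het_per_window &&
      sum(is_mis) <= params$max_missing_per_window
    return(rep(ok && 1 >= params$window_hit_fraction, L))
  }
  n_win <- L - w + 1L
  ch <- cumsum(is_het)
  cm <- cumsum(is_mis)
  het_in <- ch[w:L] - c(0, ch[seq_len(n_win - 1L)])
  mis_in <- cm[w:L] - c(0, cm[seq_len(n_win - 1L)])
  qual <- het_in <= params$max_het_per_window &
    mis_in <= params$max_missing_per_window
  # windows covering SNP i: starts max(1, i-w+1) .. min(i, n_win)
  cq <- c(0, cumsum(qual))
  i <- seq_len(L)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, n_win)
  cover <- hi - lo + 1L
  hits <- cq[hi + 1L] - cq[lo]
  hits / cover >= params$window_hit_fraction
}

# Split a run of SNP indices at gaps, trim ends to homozygous calls, apply
# the length / count / density filters, and emit segments.
finalize_runs <- function(run, calls, pos, params) {
  if (!length(run)) return(NULL)
  gaps <- diff(pos[run])
  pieces <- split(run, cumsum(c(0, gaps > params$max_gap_bp)))
  segs <- lapply(pieces, function(ix) {
    hom <- which(!is.na(calls[ix]) & calls[ix] != 1L)
    if (!length(hom)) return(NULL)
    ix <- ix[hom[1]:hom[length(hom)]]
    len <- pos[ix[length(ix)]] - pos[ix[1]] + 1L
    n <- length(ix)
    if (len < params$min_length_bp) return(NULL)
    if (n < params$min_snps) return(NULL)
    if (n * params$max_bp_per_snp < len) return(NULL)
    data.frame(
      start = pos[ix[1]], end = pos[ix[length(ix)]], n_snps = n,
      n_het_inside = sum(calls[ix] == 1L, na.rm = TRUE),
      n_missing_inside = sum(is.na(calls[ix]))
    )
  })
  do.call(rbind, segs)
}

#' Detect runs of homozygosity for every individual in a panel
#'
#' Two-phase sliding-window scan per individual and chromosome: (1) a window
#' of `scan_window_snps` markers slides one SNP at a time and qualifies when
#' it contains at most the allowed heterozygous and missing calls; each
#' SNP's hit fraction is the share of qualifying windows among the windows
#' covering it, and SNPs at or above `window_hit_fraction` are ROH-eligible.
#' (2) Maximal runs of consecutive eligible SNPs are split at inter-SNP gaps
#' above `max_gap_bp`, trimmed so they start and end at homozygous calls,
#' and kept when they satisfy the minimum length, SNP count and density
#' constraints.
#'
#' @param panel A [gene_panel()].
#' @param params A [roh_params()] list.
#' @return A tibble of segments: `ind_id`, `pop`, `chrom`, `start`, `end`,
#'   `length_bp`, `n_snps`, `n_het_inside`, `n_missing_inside`.
#' @export
detect_roh <- function(panel, params = roh_params()) {
  chroms <- split(seq_len(n_snp(panel)), panel$snps$chrom)
  out <- list()
  for (i in seq_len(n_ind(panel))) {
    for (chr in names(chroms)) {
      jj <- chroms[[chr]]
      segs <- detect_roh_track(
        panel$geno[i, jj], panel$snps$pos[jj], params
      )
      if (!is.null(segs) && nrow(segs)) {
        segs$ind_id <- panel$inds$ind_id[i]
        segs$pop <- panel$inds$pop[i]
        segs$chrom <- chr
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(
      ind_id = character(), pop = character(), chrom = character(),
      start = integer(), end = integer(), length_bp = integer(),
      n_snps = integer(), n_het_inside = integer(), n_missing_inside = integer()
    ))
  }
  res <- tibble::as_tibble(do.call(rbind, out))
  res$length_bp <- res$end - res$start + 1L
  dplyr::select(
    res, "ind_id", "pop", "chrom", "start", "end", "length_bp",
    "n_snps", "n_het_inside", "n_missing_inside"
  )
}

#' ROH scan of a single chromosome track
#'
#' Low-level worker behind [detect_roh()], exposed for testing and custom
#' tracks.
#'
#' @param calls Integer dosage vector (0/1/2/NA) along one chromosome.
#' @param pos Strictly increasing bp positions, same length.
#' @param params A [roh_params()] list.
#' @return A data.frame of segments (`start`, `end`, `n_snps`,
#'   `n_het_inside`, `n_missing_inside`), or NULL when none.
#' @export
detect_roh_track <- function(calls, pos, params = roh_params()) {
  stopifnot(length(calls) == length(pos))
  if (length(pos) > 1L && any(diff(pos) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  if (!length(calls)) return(NULL)
  elig <- roh_eligible(calls, params)
  runs <- split(which(elig), cumsum(!elig)[elig])
  segs <- lapply(runs, finalize_runs, calls = calls, pos = pos, params = params)
  out <- do.call(rbind, segs)
  if (!is.null(out)) rownames(out) <- NULL
  out
}

#' Genomic inbreeding coefficient from ROH
#'
#' `F_ROH` is the summed length of an individual's ROH segments divided by
#' the SNP-covered autosomal span (sum over chromosomes of last minus first
#' SNP position + 1).
#'
#' @param segments Segment tibble from [detect_roh()] (any subset of its
#'   rows; may be empty).
#' @param genome_span_bp Total SNP-covered length in bp; use
#'   [genome_span()] to compute it from a panel.
#' @return A tibble `ind_id`, `f_roh`. Individuals absent from `segments`
#'   are absent here (their F_ROH is 0); use a join to recover them.
#' @export
f_roh <- function(segments, genome_span_bp) {
  stopifnot(genome_span_bp > 0)
  if (nrow(segments)) {
    chk <- dplyr::group_by(segments, .data$ind_id, .data$chrom)
    bad <- dplyr::summarise(chk,
      ov = any(diff(.data$start[order(.data$start)]) <
        .data$length_bp[order(.data$start)][-dplyr::n()]),
      .groups = "drop"
    )
    if (any(bad$ov, na.rm = TRUE)) {
      stop("overlapping segments within an individual/chromosome", call. = FALSE)
    }
  }
  dplyr::summarise(
    dplyr::group_by(segments, .data$ind_id),
    f_roh = sum(.data$length_bp) / genome_span_bp,
    .groups = "drop"
  )
}

#' SNP-covered genome span of a panel
#' @param panel A [gene_panel()].
#' @return Total bp covered (sum over chromosomes of max - min position + 1).
#' @export
genome_span <- function(panel) {
  spans <- dplyr::summarise(
    dplyr::group_by(panel$snps, .data$chrom),
    span = max(.data$pos) - min(.data$pos) + 1L, .groups = "drop"
  )
  sum(spans$span)
}

#' Per-population ROH summary
#'
#' Mean F_ROH, mean number of segments per individual, and mean segment
#' length, with standard errors across individuals. Individuals with zero
#' segments contribute a count of 0 and an F_ROH of 0 but are excluded from
#' the mean-length average (which is `NA` if nobody has a segment).
#'
#' @param segments Segment tibble from [detect_roh()].
#' @param panel The panel the segments came from (supplies the population of
#'   every individual, including segment-free ones, and the genome span).
#' @param params The [roh_params()] used (recorded in the output attributes).
#' @return A tibble of class `roh_summary`: one row per population.
#' @export
roh_summary <- function(segments, panel, params = roh_params()) {
  span <- genome_span(panel)
  base <- tibble::tibble(ind_id = panel$inds$ind_id, pop = panel$inds$pop)
  per_ind <- dplyr::summarise(
    dplyr::group_by(segments, .data$ind_id),
    n_seg = dplyr::n(), sum_len = sum(.data$length_bp),
    mean_len = mean(.data$length_bp), .groups = "drop"
  )
  per_ind <- dplyr::left_join(base, per_ind, by = "ind_id")
  per_ind$n_seg[is.na(per_ind$n_seg)] <- 0L
  per_ind$sum_len[is.na(per_ind$sum_len)] <- 0
  per_ind$f_roh <- per_ind$sum_len / span
  se <- function(x) if (sum(!is.na(x)) > 1) {
    stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  } else {
    NA_real_
  }
  out <- dplyr::summarise(
    dplyr::group_by(per_ind, .data$pop),
    mean_f_roh = mean(.data$f_roh),
    f_roh_se = se(.data$f_roh),
    mean_n_seg = mean(.data$n_seg),
    n_seg_se = se(.data$n_seg),
    mean_seg_length = if (all(is.na(.data$mean_len))) NA_real_ else
      mean(.data$mean_len, na.rm = TRUE),
    seg_length_se = se(.data$mean_len),
    n_ind = dplyr::n(),
    .groups = "drop"
  )
  attr(out, "params") <- params
  attr(out, "per_ind") <- per_ind
  class(out) <- c("roh_summary", class(out))
  out
}
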