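# Independent oracles used across test files. These deliberately re-derive
# quantities by brute force (path enumeration, exhaustive scans, scalar
# arithmetic) and share no code with the implementation they check.

# --- Wright's path-counting inbreeding oracle -------------------------------

# All ancestor paths starting at `i` (each path a vector of ids, first = i).
.ancestor_paths <- function(i, sire, dam, id) {
  out <- list(i)
  for (p in c(sire[match(i, id)], dam[match(i, id)])) {
    if (!is.na(p)) {
      for (sub in .ancestor_paths(p, sire, dam, id)) {
        out[[length(out) + 1]] <- c(i, sub)
      }
    }
  }
  out
}

# F by summing (1/2)^(n1+n2+1) (1 + F_A) over common ancestors A and pairs of
# ancestor paths that share no node but A.
path_inbreeding_oracle <- function(ped) {
  id <- ped$id
  sire <- ped$sire
  dam <- ped$dam
  f <- stats::setNames(numeric(length(id)), id)
  for (k in seq_along(id)) {
    s <- sire[k]
    d <- dam[k]
    if (is.na(s) || is.na(d)) next
    ps <- .ancestor_paths(s, sire, dam, id)
    pd <- .ancestor_paths(d, sire, dam, id)
    acc <- 0
    for (a in ps) {
      for (b in pd) {
        anc <- a[length(a)]
        if (anc != b[length(b)]) next
        if (length(intersect(a[-length(a)], b[-length(b)])) > 0) next
        if (anc %in% a[-length(a)] || anc %in% b[-length(b)]) next
        acc <- acc + 0.5^((length(a) - 1) + (length(b) - 1) + 1) * (1 + f[anc])
      }
    }
    f[k] <- acc
  }
  f
}

# Random small pedigree generator for oracle comparisons.
random_pedigree <- function(n, n_founders = 6, seed = 1) {
  set.seed(seed)
  id <- paste0("i", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  sex <- c(
    rep(c("M", "F"), length.out = n_founders),
    sample(c("M", "F"), n - n_founders, replace = TRUE)
  )
  for (k in (n_founders + 1):n) {
    prev_m <- which(sex[seq_len(k - 1)] == "M")
    prev_f <- which(sex[seq_len(k - 1)] == "F")
    if (length(prev_m) && length(prev_f) && stats::runif(1) < 0.9) {
      sire[k] <- id[sample(prev_m, 1)]
      dam[k] <- id[sample(prev_f, 1)]
    }
  }
  tibble::tibble(id = id, sire = sire, dam = dam, sex = sex)
}

# --- exhaustive ROH oracle ---------------------------------------------------

roh_oracle <- function(calls, pos, params) {
  L <- length(calls)
  w <- params$scan_window_snps
  if (L == 0) return(NULL)
  if (L <= w) {
    starts <- 1L
    ends <- L
  } else {
    starts <- 1:(L - w + 1)
    ends <- starts + w - 1
  }
  win_ok <- logical(length(starts))
  for (s in seq_along(starts)) {
    win <- calls[starts[s]:ends[s]]
    win_ok[s] <- sum(win == 1L, na.rm = TRUE) <= params$max_het_per_window &&
      sum(is.na(win)) <= params$max_missing_per_window
  }
  elig <- logical(L)
  for (i in seq_len(L)) {
    cov <- which(starts <= i & ends >= i)
    elig[i] <- mean(win_ok[cov]) >= params$window_hit_fraction
  }
  segs <- list()
  add_piece <- function(ix) {
    # trim to homozygous endpoints, then filter
    while (length(ix) && (is.na(calls[ix[1]]) || calls[ix[1]] == 1L)) ix <- ix[-1]
    while (length(ix) && (is.na(calls[ix[length(ix)]]) ||
      calls[ix[length(ix)]] == 1L)) {
      ix <- ix[-length(ix)]
    }
    if (!length(ix)) return()
    len <- pos[ix[length(ix)]] - pos[ix[1]] + 1
    if (len < params$min_length_bp) return()
    if (length(ix) < params$min_snps) return()
    if (length(ix) * params$max_bp_per_snp < len) return()
    segs[[length(segs) + 1]] <<- data.frame(
      start = pos[ix[1]], end = pos[ix[length(ix)]], n_snps = length(ix),
      n_het_inside = sum(calls[ix] == 1L, na.rm = TRUE),
      n_missing_inside = sum(is.na(calls[ix]))
    )
  }
  i <- 1L
  while (i <= L) {
    if (!elig[i]) {
      i <- i + 1L
      next
    }
    j <- i
    while (j < L && elig[j + 1L]) j <- j + 1L
    run <- i:j
    # split at large gaps
    piece <- run[1]
    for (k in run[-1]) {
      if (pos[k] - pos[piece[length(piece)]] > params$max_gap_bp) {
        add_piece(piece)
        piece <- k
      } else {
        piece <- c(piece, k)
      }
    }
    add_piece(piece)
    i <- j + 1L
  }
  if (!length(segs)) return(NULL)
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

# Random genotype track with planted homozygous blocks.
random_track <- function(n_snps, seed, spacing = 50000L) {
  set.seed(seed)
  pos <- cumsum(sample(seq(spacing / 5, spacing * 2), n_snps, replace = TRUE))
  calls <- sample(c(0L, 1L, 2L, NA), n_snps, replace = TRUE,
    prob = c(0.35, 0.35, 0.25, 0.05)
  )
  # plant 0-3 homozygous stretches
  for (b in seq_len(sample(0:3, 1))) {
    at <- sample(n_snps, 1)
    len <- sample(10:80, 1)
    ix <- at:min(at + len, n_snps)
    calls[ix] <- sample(c(0L, 2L), length(ix), replace = TRUE)
  }
  list(calls = as.integer(calls), pos = as.integer(pos))
}

# --- scalar Weir-Cockerham oracle (one SNP) ---------------------------------

wc_oracle_snp <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  pbar <- sum(n_i * p_i) / sum(n_i)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / sum(n_i)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
    (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# --- misc helpers ------------------------------------------------------------

# Minimal regex-based Newick leaf extractor (independent of ape).
newick_leaves <- function(s) {
  s <- gsub(";\\s*$", "", s)
  toks <- regmatches(s, gregexpr("[(,]([^(),:]+)", s))[[1]]
  sort(sub("^[(,]", "", toks))
}

small_test_panel <- function() {
  # 6 individuals x 5 SNPs, two populations, planted missingness
  geno <- rbind(
    c(0L, 1L, 2L, 0L, 1L),
    c(0L, 1L, 2L, 1L, NA),
    c(1L, 0L, 2L, 2L, 0L),
    c(2L, 0L, 1L, 0L, 0L),
    c(2L, 1L, 0L, 0L, 1L),
    c(1L, 2L, 0L, NA, 2L)
  )
  gene_panel(
    geno,
    snps = tibble::tibble(
      snp_id = paste0("s", 1:5), chrom = "1",
      pos = c(100L, 200L, 300L, 400L, 500L)
    ),
    inds = tibble::tibble(
      ind_id = paste0("i", 1:6),
      pop = rep(c("P1", "P2"), each = 3)
    )
  )
}

binom_panel <- function(n, freqs, pop = "pop1", seed = 1, chrom_size = 100L) {
  set.seed(seed)
  m <- length(freqs)
  geno <- matrix(
    stats::rbinom(n * m, 2L, rep(freqs, each = n)),
    nrow = n, ncol = m
  )
  nchr <- ceiling(m / chrom_size)
  gene_panel(
    geno,
    snps = tibble::tibble(
      snp_id = paste0("s", seq_len(m)),
      chrom = as.character(rep(seq_len(nchr), each = chrom_size)[seq_len(m)]),
      pos = rep(seq_len(chrom_size) * 50000L, nchr)[seq_len(m)]
    ),
    inds = tibble::tibble(
      ind_id = paste0(pop, "_", seq_len(n)),
      pop = rep_len(pop, n)
    )
  )
}
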