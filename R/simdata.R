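#' Mating-design configuration for pedigree simulation
#'
#' Describes a closed breeding nucleus. The default emulates the hierarchical
#' design of small conservation flocks: each breeding unit is one sire mated
#' with three to four unrelated hens, and the program tries to keep every
#' sire family represented across generations.
#'
#' @param n_sires Breeding sires per generation.
#' @param dams_per_sire Integer range (length-2 vector, or scalar) of dams
#'   mated to each sire; default `c(3, 4)`, must lie within `[1, 20]`.
#' @param offspring_per_dam Offspring produced per dam, default 4.
#' @param n_generations Number of discrete generations after the founders.
#' @param n_male_founders,n_female_founders Founder counts by sex; default
#'   `n_sires` males and enough females for the first round of matings.
#' @param mating One of `"hierarchical-random"` (random sires, dams nested
#'   within sires), `"full-sib-line"` (repeated brother-sister matings), or
#'   `"random"` (each offspring draws a random sire and dam; constant census).
#' @param family_conservation For the hierarchical design, guarantee that
#'   every sire family contributes at least one male to the next generation
#'   when possible (default TRUE).
#' @return A list of class `design_config`.
#' @export
design_config <- function(n_sires = 10, dams_per_sire = c(3, 4),
                          offspring_per_dam = 4, n_generations = 5,
                          n_male_founders = n_sires,
                          n_female_founders = n_sires * max(dams_per_sire),
                          mating = c("hierarchical-random", "full-sib-line", "random"),
                          family_conservation = TRUE) {
  mating <- match.arg(mating)
  dams_per_sire <- sort(rep_len(as.integer(dams_per_sire), 2))
  stopifnot(
    n_sires >= 1, offspring_per_dam >= 1, n_generations >= 1,
    n_male_founders >= 1, n_female_founders >= 1,
    dams_per_sire[1] >= 1, dams_per_sire[2] <= 20
  )
  structure(
    list(
      n_sires = n_sires, dams_per_sire = dams_per_sire,
      offspring_per_dam = offspring_per_dam, n_generations = n_generations,
      n_male_founders = n_male_founders, n_female_founders = n_female_founders,
      mating = mating, family_conservation = family_conservation
    ),
    class = "design_config"
  )
}

#' Genome configuration for genotype simulation
#'
#' A reduced-scale biallelic autosomal SNP panel: evenly spaced markers on
#' equally long chromosomes with a uniform genetic map (1 cM/Mb by default)
#' and founder allele frequencies drawn from a configurable distribution
#' (uniform on `[0.05, 0.5]` by default), in linkage equilibrium.
#'
#' @param n_chrom Number of chromosomes, default 10.
#' @param chrom_length_bp Physical length per chromosome in bp (recycled),
#'   default 10 Mb.
#' @param snps_per_chrom Markers per chromosome (recycled), default 200.
#' @param cm_per_mb Uniform recombination rate, default 1 cM/Mb.
#' @param freq_fn Function `n -> n` founder allele-2 frequencies; default
#'   `runif(n, 0.05, 0.5)`.
#' @return A list of class `genome_config` with a precomputed `snps` tibble
#'   (`snp_id`, `chrom`, `pos`, `cm`).
#' @export
genome_config <- function(n_chrom = 10, chrom_length_bp = 1e7,
                          snps_per_chrom = 200, cm_per_mb = 1,
                          freq_fn = function(n) stats::runif(n, 0.05, 0.5)) {
  stopifnot(n_chrom >= 1, all(chrom_length_bp > 0), all(snps_per_chrom >= 1))
  len <- rep_len(chrom_length_bp, n_chrom)
  nsp <- rep_len(as.integer(snps_per_chrom), n_chrom)
  snps <- dplyr::bind_rows(lapply(seq_len(n_chrom), function(c) {
    pos <- as.integer(round(seq_len(nsp[c]) * (len[c] / nsp[c])))
    tibble::tibble(
      snp_id = sprintf("c%d_s%d", c, seq_len(nsp[c])),
      chrom = as.character(c), pos = pos,
      cm = pos / 1e6 * cm_per_mb
    )
  }))
  structure(
    list(
      n_chrom = n_chrom, chrom_length_bp = len, snps_per_chrom = nsp,
      cm_per_mb = cm_per_mb, freq_fn = freq_fn, snps = snps
    ),
    class = "genome_config"
  )
}

#' Simulate a pedigree under a mating design
#'
#' Founders form generation 0; each later generation is produced by the
#' configured mating rule. Deterministic under a fixed seed.
#'
#' @param config A [design_config()].
#' @param seed Random seed.
#' @return A pedigree tibble (`id`, `sire`, `dam`, `sex`, `generation`,
#'   `founder`), topologically sorted.
#' @export
build_pedigree <- function(config, seed = 1) {
  stopifnot(inherits(config, "design_config"))
  set.seed(seed)
  ped <- tibble::tibble(
    id = c(
      sprintf("g0_m%d", seq_len(config$n_male_founders)),
      sprintf("g0_f%d", seq_len(config$n_female_founders))
    ),
    sire = NA_character_, dam = NA_character_,
    sex = rep(c("M", "F"), c(config$n_male_founders, config$n_female_founders)),
    generation = 0L
  )
  for (g in seq_len(config$n_generations)) {
    prev <- ped[ped$generation == g - 1L, ]
    males <- prev$id[prev$sex == "M"]
    females <- prev$id[prev$sex == "F"]
    if (!length(males) || !length(females)) {
      stop("generation ", g - 1L, " lacks one sex; design infeasible", call. = FALSE)
    }
    kids <- switch(config$mating,
      "hierarchical-random" = mate_hierarchical(
        males, females, config, g,
        last = g == config$n_generations
      ),
      "full-sib-line" = mate_fullsib(males, females, config, g),
      "random" = mate_random(males, females, config, g)
    )
    ped <- dplyr::bind_rows(ped, kids)
  }
  ped$founder <- is.na(ped$sire) & is.na(ped$dam)
  ped
}

mate_hierarchical <- function(males, females, config, g, last = FALSE) {
  ns <- min(config$n_sires, length(males))
  sires <- sample(males, ns)
  pool <- sample(females)
  if (length(pool) < ns) {
    stop("not enough dams for ", ns, " sire families; design infeasible",
      call. = FALSE
    )
  }
  rng <- seq(config$dams_per_sire[1], config$dams_per_sire[2])
  want <- rng[sample.int(length(rng), ns, replace = TRUE)]
  rec <- list()
  used <- 0L
  for (s in seq_len(ns)) {
    k <- min(want[s], length(pool) - used)
    if (k < 1L) k <- 1L
    if (used + k > length(pool)) {
      stop("not enough dams; design infeasible", call. = FALSE)
    }
    dams <- pool[used + seq_len(k)]
    used <- used + k
    rec[[s]] <- tibble::tibble(
      sire = sires[s],
      dam = rep(dams, each = config$offspring_per_dam)
    )
  }
  kids <- dplyr::bind_rows(rec)
  kids$id <- sprintf("g%d_i%d", g, seq_len(nrow(kids)))
  kids$generation <- g
  kids$sex <- assign_sex(
    kids$sire,
    # the final generation feeds no further matings
    n_males_needed = if (last) 0L else config$n_sires,
    n_females_needed = if (last) 0L else config$n_sires * config$dams_per_sire[1],
    conserve_families = config$family_conservation
  )
  kids[, c("id", "sire", "dam", "sex", "generation")]
}

# Fair-coin sexes, then deterministic fixes: with family conservation the
# first offspring of each sire family is made male; any deficit in either
# required sex is then filled by birth order from the excess sex.
assign_sex <- function(sire_of, n_males_needed, n_females_needed,
                       conserve_families) {
  n <- length(sire_of)
  if (n_males_needed + n_females_needed > n) {
    stop("design infeasible: ", n, " offspring cannot supply ",
      n_males_needed, " sires and ", n_females_needed, " dams",
      call. = FALSE
    )
  }
  sex <- sample(c("M", "F"), n, replace = TRUE)
  if (conserve_families) {
    first_of_family <- !duplicated(sire_of)
    sex[first_of_family] <- "M"
  }
  deficit_m <- n_males_needed - sum(sex == "M")
  if (deficit_m > 0) {
    cand <- which(sex == "F")
    sex[cand[seq_len(min(deficit_m, length(cand)))]] <- "M"
  }
  deficit_f <- n_females_needed - sum(sex == "F")
  if (deficit_f > 0) {
    cand <- which(sex == "M" & duplicated(sire_of))
    if (length(cand) < deficit_f) cand <- which(sex == "M")
    sex[cand[seq_len(min(deficit_f, length(cand)))]] <- "F"
  }
  sex
}

mate_fullsib <- function(males, females, config, g) {
  n_off <- max(2L, config$offspring_per_dam)
  kids <- tibble::tibble(
    id = sprintf("g%d_i%d", g, seq_len(n_off)),
    sire = males[1], dam = females[1],
    sex = c("M", "F", sample(c("M", "F"), n_off - 2L, replace = TRUE)),
    generation = g
  )
  kids
}

mate_random <- function(males, females, config, g) {
  nm <- config$n_male_founders
  nf <- config$n_female_founders
  n_off <- nm + nf
  kids <- tibble::tibble(
    id = sprintf("g%d_i%d", g, seq_len(n_off)),
    sire = sample(males, n_off, replace = TRUE),
    dam = sample(females, n_off, replace = TRUE),
    sex = sample(rep(c("M", "F"), c(nm, nf))),
    generation = g
  )
  kids
}

#' Simulate founder haplotypes
#'
#' Per-SNP allele-2 frequencies are drawn from the genome's configured
#' distribution; haplotypes are i.i.d. Bernoulli draws at those frequencies
#' (linkage equilibrium among founders).
#'
#' @param genome A [genome_config()].
#' @param n_founders Number of founder individuals (two haplotypes each).
#' @param seed Random seed.
#' @return A list of class `founder_pool`: `haplotypes` (2 x n_founders rows
#'   by n_snp 0/1 matrix), `freqs`, `genome`.
#' @export
simulate_founders <- function(genome, n_founders, seed = 1) {
  stopifnot(inherits(genome, "genome_config"), n_founders >= 2)
  set.seed(seed)
  m <- nrow(genome$snps)
  freqs <- genome$freq_fn(m)
  hap <- matrix(
    stats::rbinom(2L * n_founders * m, 1L, rep(freqs, each = 2L * n_founders)),
    nrow = 2L * n_founders, ncol = m
  )
  structure(
    list(haplotypes = hap, freqs = freqs, genome = genome),
    class = "founder_pool"
  )
}

# One gamete from a parent's two haplotype rows: Poisson crossovers on the
# cM scale (Haldane, no interference), fair-coin starting strand.
make_gamete <- function(h1, h2, snp_chrom, snp_cm, chrom_cm_len) {
  out <- integer(length(h1))
  for (c in seq_along(chrom_cm_len)) {
    jj <- which(snp_chrom == c)
    ncx <- stats::rpois(1, chrom_cm_len[c] / 100)
    strand <- stats::rbinom(1, 1, 0.5)
    if (ncx == 0L) {
      out[jj] <- if (strand == 0L) h1[jj] else h2[jj]
    } else {
      cx <- sort(stats::runif(ncx, 0, chrom_cm_len[c]))
      seg <- (strand + findInterval(snp_cm[jj], cx)) %% 2L
      out[jj] <- ifelse(seg == 0L, h1[jj], h2[jj])
    }
  }
  out
}

#' Drop founder haplotypes through a pedigree
#'
#' Standard gene dropping: every non-founder receives one recombined gamete
#' from each parent (Poisson crossover counts with mean equal to the map
#' length in Morgans, uniformly placed, starting strand by fair coin);
#' genotypes are the sum of the two transmitted haplotypes.
#'
#' @param ped Pedigree tibble (topologically sorted, e.g. from
#'   [build_pedigree()]).
#' @param founders A `founder_pool` from [simulate_founders()] with at least
#'   as many founders as the pedigree has.
#' @param seed Random seed.
#' @param pop Population label for the emitted panel (default `"pop1"`), or
#'   a vector/function mapping pedigree rows to labels.
#' @return A list of class `gene_drop`: `panel` (a [gene_panel()] covering
#'   every pedigree member, with `generation` carried in the individual
#'   table), `truth` (haplotype matrix, founder frequencies, pedigree,
#'   genome).
#' @export
gene_drop <- function(ped, founders, seed = 1, pop = "pop1") {
  stopifnot(inherits(founders, "founder_pool"))
  ped <- ensure_sorted_ped(ped)
  set.seed(seed)
  genome <- founders$genome
  m <- nrow(genome$snps)
  n <- nrow(ped)
  founder_rows <- which(is.na(ped$sire) & is.na(ped$dam))
  if (2L * length(founder_rows) > nrow(founders$haplotypes)) {
    stop("pedigree has more founders than the founder pool supplies", call. = FALSE)
  }
  miss_par <- xor(is.na(ped$sire), is.na(ped$dam))
  if (any(miss_par)) {
    stop("gene_drop needs both parents known or both unknown", call. = FALSE)
  }
  snp_chrom <- as.integer(genome$snps$chrom)
  snp_cm <- genome$snps$cm
  chrom_cm_len <- genome$chrom_length_bp / 1e6 * genome$cm_per_mb
  hap <- matrix(0L, nrow = 2L * n, ncol = m)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  fcount <- 0L
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      fcount <- fcount + 1L
      hap[2L * i - 1L, ] <- founders$haplotypes[2L * fcount - 1L, ]
      hap[2L * i, ] <- founders$haplotypes[2L * fcount, ]
    } else {
      hap[2L * i - 1L, ] <- make_gamete(
        hap[2L * si[i] - 1L, ], hap[2L * si[i], ], snp_chrom, snp_cm, chrom_cm_len
      )
      hap[2L * i, ] <- make_gamete(
        hap[2L * di[i] - 1L, ], hap[2L * di[i], ], snp_chrom, snp_cm, chrom_cm_len
      )
    }
  }
  geno <- hap[2L * seq_len(n) - 1L, , drop = FALSE] + hap[2L * seq_len(n), , drop = FALSE]
  pop_lab <- if (is.function(pop)) pop(ped) else rep_len(pop, n)
  inds <- tibble::tibble(
    ind_id = ped$id, pop = pop_lab,
    flock = if ("flock" %in% names(ped)) ped$flock else NA_character_,
    sex = if ("sex" %in% names(ped)) ped$sex else NA_character_,
    generation = ped$generation
  )
  panel <- gene_panel(geno, genome$snps[, c("snp_id", "chrom", "pos")], inds)
  structure(
    list(
      panel = panel,
      truth = list(
        haplotypes = hap, founder_freqs = founders$freqs,
        pedigree = ped, genome = genome
      )
    ),
    class = "gene_drop"
  )
}

#' Simulate a complete population (pedigree + genotypes)
#'
#' Convenience wrapper: [build_pedigree()], [simulate_founders()],
#' [gene_drop()] with one seed.
#'
#' @param design A [design_config()].
#' @param genome A [genome_config()].
#' @param seed Random seed (substreams are derived for each phase).
#' @param pop Population label.
#' @return A `gene_drop` list (`panel`, `truth`).
#' @export
simulate_panel <- function(design, genome, seed = 1, pop = "pop1") {
  ped <- build_pedigree(design, seed = seed)
  founders <- simulate_founders(
    genome, design$n_male_founders + design$n_female_founders,
    seed = seed + 1L
  )
  gene_drop(ped, founders, seed = seed + 2L, pop = pop)
}

#' Simulate subdivided flocks from one founder pool
#'
#' One panmictic founder pool is split into `k_flocks` flocks that then
#' evolve in (near-)isolation: each offspring draws its sire and dam from
#' its own flock's previous generation with probability `1 - migration_rate`
#' and from a random other flock otherwise. Emits the final generation with
#' flock labels (as both `pop` and `flock`), plus the realized
#' between-flock Fst in the truth record -- the raw material for Wahlund
#' effect demonstrations.
#'
#' @param genome A [genome_config()].
#' @param k_flocks Number of flocks (>= 2).
#' @param flock_size Individuals per flock per generation.
#' @param generations_isolated Generations of subdivided evolution.
#' @param migration_rate Per-parent probability of drawing from another
#'   flock, in `[0, 1]`; 1 is complete mixing.
#' @param seed Random seed.
#' @return A list: `panel` (final generation, flock-labeled), `truth`
#'   (`realized_fst`, full `pedigree`, `founder_freqs`).
#' @export
simulate_subdivided <- function(genome, k_flocks = 2, flock_size = 25,
                                generations_isolated = 10, migration_rate = 0,
                                seed = 1) {
  stopifnot(k_flocks >= 2, flock_size >= 2)
  set.seed(seed)
  n0 <- k_flocks * flock_size
  ped <- tibble::tibble(
    id = sprintf("g0_i%d", seq_len(n0)),
    sire = NA_character_, dam = NA_character_,
    sex = rep_len(c("M", "F"), n0),
    generation = 0L,
    flock = rep(seq_len(k_flocks), each = flock_size)
  )
  for (g in seq_len(generations_isolated)) {
    prev <- ped[ped$generation == g - 1L, ]
    rows <- list()
    for (f in seq_len(k_flocks)) {
      src <- function() {
        if (k_flocks > 1L && stats::runif(1) < migration_rate) {
          sample(setdiff(seq_len(k_flocks), f), 1)
        } else {
          f
        }
      }
      sire <- dam <- character(flock_size)
      for (i in seq_len(flock_size)) {
        fs <- src()
        fd <- src()
        sire[i] <- sample(prev$id[prev$flock == fs & prev$sex == "M"], 1)
        dam[i] <- sample(prev$id[prev$flock == fd & prev$sex == "F"], 1)
      }
      rows[[f]] <- tibble::tibble(
        id = sprintf("g%d_f%d_i%d", g, f, seq_len(flock_size)),
        sire = sire, dam = dam,
        sex = rep_len(c("M", "F"), flock_size),
        generation = g, flock = f
      )
    }
    ped <- dplyr::bind_rows(ped, rows)
  }
  founders <- simulate_founders(genome, n0, seed = seed + 1L)
  gd <- gene_drop(ped, founders,
    seed = seed + 2L,
    pop = function(p) paste0("flock", p$flock)
  )
  last <- panel_subset(gd$panel, ind = gd$panel$inds$generation == generations_isolated)
  last$inds$flock <- sub("^flock", "", last$inds$pop)
  fst <- wc_fst(last, pairwise = FALSE)
  list(
    panel = last,
    truth = list(
      realized_fst = fst$theta, pedigree = ped,
      founder_freqs = founders$freqs, genome = genome
    )
  )
}

#' Admix two panels sharing a SNP table
#'
#' Replaces a fraction of panel A's individuals by F1 (or backcross)
#' offspring of cross-panel parents; gametes are drawn allele-wise from the
#' parents' genotypes.
#'
#' @param panel_a,panel_b Two [gene_panel()]s with identical SNP tables.
#' @param fraction Fraction of A individuals to replace, in `[0, 1]`.
#' @param seed Random seed.
#' @param type `"F1"` (default) or `"backcross"` (F1 x A).
#' @return A `gene_panel` like A, with the replaced individuals relabelled
#'   `admx_*` and flagged by `flock = "admixed"`.
#' @export
simulate_admixture <- function(panel_a, panel_b, fraction, seed = 1,
                               type = c("F1", "backcross")) {
  type <- match.arg(type)
  if (!identical(
    panel_a$snps[, c("snp_id", "chrom", "pos")],
    panel_b$snps[, c("snp_id", "chrom", "pos")]
  )) {
    stop("panels do not share a SNP table", call. = FALSE)
  }
  stopifnot(fraction >= 0, fraction <= 1)
  set.seed(seed)
  n_rep <- round(fraction * n_ind(panel_a))
  if (n_rep == 0L) return(panel_a)
  who <- sample(n_ind(panel_a), n_rep)
  gam <- function(g) {
    a <- stats::rbinom(length(g), 1L, g / 2)
    a[is.na(g)] <- stats::rbinom(sum(is.na(g)), 1L, 0.5)
    a
  }
  geno <- panel_a$geno
  for (i in seq_len(n_rep)) {
    pa <- panel_a$geno[sample(n_ind(panel_a), 1), ]
    pb <- panel_b$geno[sample(n_ind(panel_b), 1), ]
    f1 <- gam(pa) + gam(pb)
    if (type == "backcross") {
      pa2 <- panel_a$geno[sample(n_ind(panel_a), 1), ]
      f1 <- gam(f1) + gam(pa2)
    }
    geno[who[i], ] <- f1
  }
  inds <- panel_a$inds
  inds$ind_id[who] <- sprintf("admx_%d", seq_len(n_rep))
  inds$flock[who] <- "admixed"
  gene_panel(geno, panel_a$snps, inds)
}
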