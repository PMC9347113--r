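test_that("allele frequencies count alleles within the requested scope", {
  panel <- small_test_panel()
  fr <- allele_frequencies(panel, "global")
  # s1 dosages: 0,0,1,2,2,1 over 6 individuals -> 6/12
  expect_equal(fr$freq[fr$snp_id == "s1"], 0.5)
  p1 <- allele_frequencies(panel, "P1")
  expect_equal(p1$freq[p1$snp_id == "s1"], (0 + 0 + 1) / 6)
  expect_equal(p1$n_obs[p1$snp_id == "s5"], 4L) # one missing call in P1
  expect_error(allele_frequencies(panel, "nope"), "unknown scope")
  # all-missing SNP in scope is flagged unavailable
  g <- rbind(c(0L, NA), c(1L, NA))
  pan <- gene_panel(
    g, tibble::tibble(snp_id = c("a", "b"), chrom = "1", pos = c(1L, 2L)),
    tibble::tibble(ind_id = c("x", "y"), pop = "P")
  )
  expect_true(is.nan(allele_frequencies(pan)$freq[2]))
})

test_that("method-of-moments F hits its fixed points", {
  p <- c(0.2, 0.4, 0.5)
  n_obs <- 40
  # all-homozygous individual: F = 1 regardless of frequencies
  expect_equal(mom_inbreeding(c(0L, 2L, 2L), p, n_obs), 1)
  # observed homozygosity equal to expectation: F = 0 (no correction)
  p2 <- 0.5
  g <- c(0L, 1L, 1L, 2L) # 2 hom out of 4, expectation 4*(1-0.5) = 2
  expect_equal(mom_inbreeding(g, rep(p2, 4), correct = FALSE), 0)
})

test_that("method-of-moments F equals hand arithmetic on a worked fixture", {
  p <- c(0.25, 0.4, 0.1)
  n_obs <- c(20, 20, 10)
  geno <- rbind(
    c(0L, 1L, 0L),
    c(2L, 2L, 0L),
    c(1L, 1L, NA),
    c(0L, 0L, 2L)
  )
  for (i in 1:4) {
    g <- geno[i, ]
    use <- !is.na(g)
    hexp <- sum((2 * p * (1 - p) * n_obs / (n_obs - 1))[use])
    hom_exp <- sum(use) - hexp
    hom_obs <- sum(g[use] != 1L)
    want <- (hom_obs - hom_exp) / (sum(use) - hom_exp)
    expect_equal(mom_inbreeding(g, p, n_obs), want)
  }
  # no usable locus (p outside (0,1)) is flagged undefined
  expect_true(is.na(mom_inbreeding(c(1L, 2L), c(1, 0), 20)))
})

test_that("Fis centers on zero in a random-mating population", {
  d <- design_config(
    mating = "random", n_male_founders = 25, n_female_founders = 25,
    n_generations = 2, n_sires = 25
  )
  g <- genome_config(n_chrom = 10, snps_per_chrom = 200)
  sim <- simulate_panel(d, g, seed = 21)
  last <- panel_subset(sim$panel, ind = sim$panel$inds$generation == 2)
  ff <- inbreeding_fit_fis(last)
  expect_lt(abs(mean(ff$fis)), 0.02)
})

test_that("heterozygosity and MAF summaries match direct counting", {
  panel <- small_test_panel()
  het <- heterozygosity(panel, "P1")
  g <- panel$geno[1:3, ]
  called <- colSums(!is.na(g))
  expect_equal(het$ho, mean(colSums(g == 1L, na.rm = TRUE) / called))
  p <- colSums(g, na.rm = TRUE) / (2 * called)
  expect_equal(het$he, mean(2 * p * (1 - p)))
  mf <- maf_and_fixed(panel, "P1")
  expect_equal(mf$maf, mean(pmin(p, 1 - p)))
  expect_equal(mf$fixed, mean(pmin(p, 1 - p) == 0))
  # trivial bounds
  hom <- gene_panel(
    matrix(2L, 3, 4),
    tibble::tibble(snp_id = paste0("s", 1:4), chrom = "1", pos = 1:4 * 10L),
    tibble::tibble(ind_id = paste0("i", 1:3), pop = "P")
  )
  expect_equal(heterozygosity(hom, "P")$ho, 0)
  expect_equal(maf_and_fixed(hom, "P")$fixed, 1)
  expect_equal(maf_and_fixed(hom, "P")$maf, 0)
  allhet <- gene_panel(
    matrix(1L, 3, 4),
    tibble::tibble(snp_id = paste0("s", 1:4), chrom = "1", pos = 1:4 * 10L),
    tibble::tibble(ind_id = paste0("i", 1:3), pop = "P")
  )
  expect_equal(heterozygosity(allhet, "P")$ho, 1)
  expect_error(heterozygosity(panel, "P9"), "unknown population")
})

test_that("Weir-Cockerham theta is 1 under complete fixation", {
  g <- rbind(
    matrix(0L, 10, 20),
    matrix(2L, 10, 20)
  )
  panel <- gene_panel(
    g,
    tibble::tibble(snp_id = paste0("s", 1:20), chrom = "1", pos = 1:20 * 10L),
    tibble::tibble(
      ind_id = paste0("i", 1:20),
      pop = rep(c("A", "B"), each = 10)
    )
  )
  fst <- wc_fst(panel)
  expect_equal(fst$theta, 1)
  expect_equal(fst$pairwise["A", "B"], 1)
  expect_true(isSymmetric(fst$pairwise))
})

test_that("Weir-Cockerham theta is near zero under the null", {
  set.seed(31)
  freqs <- runif(500, 0.1, 0.9)
  g <- matrix(rbinom(200 * 500, 2, rep(freqs, each = 200)), 200, 500)
  panel <- gene_panel(
    g,
    tibble::tibble(
      snp_id = paste0("s", 1:500), chrom = "1", pos = 1:500 * 100L
    ),
    tibble::tibble(
      ind_id = paste0("i", 1:200),
      pop = rep(c("A", "B"), each = 100)
    )
  )
  fst <- wc_fst(panel, pairwise = FALSE)
  expect_lt(abs(fst$theta), 0.02)
})

test_that("Weir-Cockerham components equal scalar hand evaluation", {
  # pop A: 10 hom(2) + 10 het -> 30/10 allele-2/allele-1; pop B mirrored
  g <- rbind(
    matrix(rep(c(2L, 1L), each = 10), ncol = 1),
    matrix(rep(c(0L, 1L), each = 10), ncol = 1)
  )
  panel <- gene_panel(
    g,
    tibble::tibble(snp_id = "s1", chrom = "1", pos = 100L),
    tibble::tibble(
      ind_id = paste0("i", 1:40), pop = rep(c("A", "B"), each = 20)
    )
  )
  fst <- wc_fst(panel, pairwise = FALSE)
  want <- wc_oracle_snp(
    n_i = c(20, 20), p_i = c(0.75, 0.25), h_i = c(0.5, 0.5)
  )
  expect_equal(fst$per_snp$a, unname(want["a"]))
  expect_equal(fst$per_snp$b, unname(want["b"]))
  expect_equal(fst$per_snp$c, unname(want["c"]))
  expect_equal(fst$theta, unname(want["theta"]))
})

test_that("a split-half population has theta about zero", {
  set.seed(41)
  freqs <- runif(300, 0.2, 0.8)
  g <- matrix(rbinom(100 * 300, 2, rep(freqs, each = 100)), 100, 300)
  panel <- gene_panel(
    g,
    tibble::tibble(snp_id = paste0("s", 1:300), chrom = "1", pos = 1:300 * 10L),
    tibble::tibble(
      ind_id = paste0("i", 1:100), pop = rep(c("H1", "H2"), 50)
    )
  )
  expect_lt(abs(wc_fst(panel, pairwise = FALSE)$theta), 0.03)
})

test_that("pooling differentiated flocks induces the Wahlund Fis deficit", {
  sub <- simulate_subdivided(
    genome_config(n_chrom = 5, snps_per_chrom = 100),
    k_flocks = 2, flock_size = 100, generations_isolated = 21, seed = 5
  )
  theta <- sub$truth$realized_fst
  expect_gt(theta, 0.05)
  pool <- sub$panel
  pool$inds$pop <- "pooled"
  fis <- mean(inbreeding_fit_fis(pool)$fis)
  expect_gt(fis, 0)
  # for k equally pooled flocks the deficit is (k-1)/k of theta
  expect_lt(abs(fis - theta / 2) / (theta / 2), 0.35)
})

test_that("Fit exceeds Fis on average when populations are differentiated", {
  sub <- simulate_subdivided(
    genome_config(n_chrom = 4, snps_per_chrom = 100),
    k_flocks = 2, flock_size = 50, generations_isolated = 10, seed = 13
  )
  ff <- inbreeding_fit_fis(sub$panel)
  expect_gt(mean(ff$fit), mean(ff$fis))
})

test_that("Nei's distance matches direct evaluation and its fixed points", {
  expect_equal(nei_distance(c(0.2, 0.5), c(0.2, 0.5)), 0)
  expect_equal(nei_distance(c(1, 1), c(0, 0)), Inf)
  pa <- c(0.2, 0.6, 0.9)
  pb <- c(0.3, 0.5, 0.4)
  jaa <- mean(pa^2 + (1 - pa)^2)
  jbb <- mean(pb^2 + (1 - pb)^2)
  jab <- mean(pa * pb + (1 - pa) * (1 - pb))
  expect_equal(nei_distance(pa, pb), -log(jab / sqrt(jaa * jbb)))
  # panel-level matrix is symmetric, zero diagonal
  panel <- small_test_panel()
  d <- nei_distance_matrix(panel)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), c(P1 = 0, P2 = 0))
})
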