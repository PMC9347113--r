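test_that("pedigree builder honors the design constraints", {
  d1 <- design_config(
    n_sires = 1, dams_per_sire = c(1, 1), offspring_per_dam = 1,
    n_generations = 1, n_male_founders = 1, n_female_founders = 1
  )
  ped <- build_pedigree(d1, seed = 1)
  expect_equal(nrow(ped), 3)
  expect_equal(sum(ped$founder), 2)
  # hierarchical: every dam mated to exactly one sire
  dh <- design_config(
    n_sires = 10, dams_per_sire = c(3, 3), offspring_per_dam = 2,
    n_generations = 3
  )
  ph <- build_pedigree(dh, seed = 2)
  per_dam <- tapply(ph$sire[!ph$founder], ph$dam[!ph$founder], function(s) {
    length(unique(s))
  })
  expect_true(all(per_dam == 1))
  # determinism
  expect_identical(build_pedigree(dh, seed = 2), ph)
  expect_error(
    build_pedigree(design_config(
      n_sires = 5, dams_per_sire = c(3, 3), offspring_per_dam = 1,
      n_generations = 2, n_male_founders = 5, n_female_founders = 15
    ), seed = 1),
    "infeasible"
  )
})

test_that("full-sib lines follow the classical inbreeding series", {
  d <- design_config(
    mating = "full-sib-line", n_sires = 1, n_male_founders = 1,
    n_female_founders = 1, offspring_per_dam = 4, n_generations = 5
  )
  ped <- build_pedigree(d, seed = 3)
  f <- pedigree_inbreeding(ped)
  by_gen <- tapply(f$F, ped$generation, mean)
  expect_equal(
    as.numeric(by_gen[as.character(1:5)]),
    c(0, 0.25, 0.375, 0.5, 0.59375)
  )
})

test_that("founder haplotypes are Bernoulli draws at the configured frequencies", {
  g <- genome_config(
    n_chrom = 2, snps_per_chrom = 250,
    freq_fn = function(n) rep(0.5, n)
  )
  fd <- simulate_founders(g, n_founders = 40, seed = 4)
  expect_equal(dim(fd$haplotypes), c(80, 500))
  rate <- mean(fd$haplotypes)
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / (80 * 500)))
  fd2 <- simulate_founders(g, n_founders = 2, seed = 9)
  expect_equal(nrow(fd2$haplotypes), 4)
  expect_identical(fd2$haplotypes, simulate_founders(g, 2, seed = 9)$haplotypes)
})

test_that("gene dropping transmits intact strands on a zero-length map", {
  g <- genome_config(n_chrom = 2, snps_per_chrom = 50, cm_per_mb = 0)
  d <- design_config(
    n_sires = 2, dams_per_sire = c(2, 2), offspring_per_dam = 2,
    n_generations = 1, n_male_founders = 2, n_female_founders = 4
  )
  ped <- build_pedigree(d, seed = 5)
  fd <- simulate_founders(g, sum(ped$founder), seed = 5)
  gd <- gene_drop(ped, fd, seed = 5)
  hap <- gd$truth$haplotypes
  si <- match(ped$sire, ped$id)
  chroms <- split(seq_len(nrow(g$snps)), g$snps$chrom)
  for (i in which(!ped$founder)) {
    s <- si[i]
    for (jj in chroms) {
      child_paternal <- hap[2 * i - 1, jj]
      expect_true(
        identical(child_paternal, hap[2 * s - 1, jj]) ||
          identical(child_paternal, hap[2 * s, jj])
      )
    }
  }
})

test_that("gene dropping is Mendelian-consistent", {
  g <- genome_config(n_chrom = 3, snps_per_chrom = 60)
  d <- design_config(n_sires = 3, n_generations = 2)
  sim <- simulate_panel(d, g, seed = 6)
  ped <- sim$truth$pedigree
  geno <- sim$panel$geno
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  for (i in which(!ped$founder)) {
    for (p in c(si[i], di[i])) {
      # child and parent share at least one allele at every SNP
      incompatible <- abs(geno[i, ] - geno[p, ]) == 2L
      expect_false(any(incompatible))
    }
  }
})

test_that("one generation of drift has Wright-Fisher variance", {
  g <- genome_config(
    n_chrom = 5, snps_per_chrom = 100,
    freq_fn = function(n) rep(0.5, n)
  )
  n <- 20
  ratios <- vapply(1:30, function(s) {
    d <- design_config(
      mating = "random", n_male_founders = n / 2, n_female_founders = n / 2,
      n_sires = n / 2, n_generations = 1
    )
    sim <- simulate_panel(d, g, seed = 500 + s)
    founder_rows <- sim$panel$inds$generation == 0
    p0 <- colMeans(sim$panel$geno[founder_rows, ]) / 2
    p1 <- colMeans(sim$panel$geno[!founder_rows, ]) / 2
    mean((p1 - p0)^2) / mean(p0 * (1 - p0) / (2 * n))
  }, 0)
  expect_equal(mean(ratios), 1, tolerance = 0.15)
})

test_that("subdivision scenarios span panmixia to isolation", {
  g <- genome_config(n_chrom = 3, snps_per_chrom = 100)
  mixed <- simulate_subdivided(g,
    k_flocks = 2, flock_size = 30,
    generations_isolated = 6, migration_rate = 1, seed = 7
  )
  expect_lt(abs(mixed$truth$realized_fst), 0.03)
  iso_short <- simulate_subdivided(g,
    k_flocks = 2, flock_size = 30,
    generations_isolated = 3, migration_rate = 0, seed = 8
  )
  iso_long <- simulate_subdivided(g,
    k_flocks = 2, flock_size = 30,
    generations_isolated = 18, migration_rate = 0, seed = 8
  )
  expect_gt(iso_long$truth$realized_fst, iso_short$truth$realized_fst)
  expect_equal(sort(unique(iso_long$panel$inds$pop)), c("flock1", "flock2"))
})

test_that("admixture produces heterozygous F1s between fixed panels", {
  snps <- tibble::tibble(
    snp_id = paste0("s", 1:40), chrom = "1", pos = 1:40 * 1000L
  )
  pa <- gene_panel(
    matrix(0L, 10, 40), snps,
    tibble::tibble(ind_id = paste0("a", 1:10), pop = "A")
  )
  pb <- gene_panel(
    matrix(2L, 10, 40), snps,
    tibble::tibble(ind_id = paste0("b", 1:10), pop = "B")
  )
  expect_identical(simulate_admixture(pa, pb, fraction = 0), pa)
  mixed <- simulate_admixture(pa, pb, fraction = 0.5, seed = 9)
  adm <- mixed$inds$flock %in% "admixed"
  expect_equal(sum(adm), 5)
  expect_true(all(mixed$geno[adm, ] == 1L))
  expect_true(all(mixed$geno[!adm, ] == 0L))
  bad <- pb
  bad$snps$pos <- bad$snps$pos + 5L
  expect_error(simulate_admixture(pa, bad, 0.5), "share a SNP table")
})

test_that("admixed individuals sit between the source clusters on the tree", {
  set.seed(10)
  fa <- runif(200, 0, 0.2)
  fb <- runif(200, 0.8, 1)
  pa <- binom_panel(12, fa, pop = "A", seed = 11)
  pb <- binom_panel(12, fb, pop = "B", seed = 12)
  pb$inds$ind_id <- paste0("B", 1:12)
  mixed <- simulate_admixture(pa, pb, fraction = 0.25, seed = 13)
  both <- gene_panel(
    rbind(mixed$geno, pb$geno),
    mixed$snps,
    dplyr::bind_rows(mixed$inds, pb$inds)
  )
  d <- ibs_distance(both)
  adm <- grep("admx", rownames(d), value = TRUE)
  pure_a <- setdiff(mixed$inds$ind_id[mixed$inds$pop == "A"], adm)
  pure_b <- pb$inds$ind_id
  for (x in adm) {
    da <- mean(d[x, pure_a])
    db <- mean(d[x, pure_b])
    dab <- mean(d[pure_a, pure_b])
    # roughly midway: closer to each source than the sources are to each other
    expect_lt(da, dab)
    expect_lt(db, dab)
  }
})

test_that("pedigree and molecular inbreeding agree on replicate gene drops", {
  g <- genome_config(n_chrom = 5, snps_per_chrom = 100)
  d <- design_config(
    n_sires = 3, dams_per_sire = c(3, 3), offspring_per_dam = 3,
    n_generations = 5, n_male_founders = 3, n_female_founders = 9
  )
  ped <- build_pedigree(d, seed = 20)
  fi <- pedigree_inbreeding(ped)
  last <- ped$generation == 5
  fped <- mean(fi$F[last])
  fmol <- vapply(1:12, function(s) {
    fd <- simulate_founders(g, sum(ped$founder), seed = 600 + s)
    gd <- gene_drop(ped, fd, seed = 700 + s)
    glast <- gd$panel$geno[last, , drop = FALSE]
    f <- vapply(seq_len(nrow(glast)), function(i) {
      mom_inbreeding(glast[i, ], fd$freqs, correct = FALSE)
    }, 0)
    mean(f, na.rm = TRUE)
  }, 0)
  se <- sd(fmol) / sqrt(length(fmol))
  expect_lt(abs(mean(fmol) - fped), 3 * se + 0.01)
})
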