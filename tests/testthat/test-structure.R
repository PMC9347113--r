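test_that("IBS distance counts shared alleles", {
  g <- rbind(
    c(0L, 2L, 1L, 0L),
    c(0L, 2L, 1L, 0L), # identical to i1
    c(2L, 0L, 1L, 2L), # opposite homozygote at 1,2,4
    c(1L, 1L, 0L, 1L) # het against i1's homozygotes
  )
  panel <- gene_panel(
    g,
    tibble::tibble(snp_id = paste0("s", 1:4), chrom = "1", pos = 1:4 * 10L),
    tibble::tibble(ind_id = paste0("i", 1:4), pop = "P")
  )
  d <- ibs_distance(panel)
  expect_equal(d["i1", "i2"], 0)
  expect_equal(mean(abs(g[1, ] - g[3, ])) / 2, d["i1", "i3"])
  het_only <- panel_subset(panel, ind = c(1, 4), snp = c(1, 2, 4))
  expect_equal(ibs_distance(het_only)["i1", "i4"], 0.5)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), setNames(rep(0, 4), paste0("i", 1:4)))
  # a pair with zero overlap is an error naming the pair
  g2 <- rbind(c(1L, NA), c(NA, 1L))
  p2 <- gene_panel(
    g2, tibble::tibble(snp_id = c("a", "b"), chrom = "1", pos = c(1L, 2L)),
    tibble::tibble(ind_id = c("x", "y"), pop = "P")
  )
  expect_error(ibs_distance(p2), "x / y")
})

test_that("neighbor joining recovers additive trees exactly", {
  # ((A,B),(C,D)) with all five branches length 1
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 2
  d["C", "D"] <- d["D", "C"] <- 2
  for (x in c("A", "B")) {
    for (y in c("C", "D")) d[x, y] <- d[y, x] <- 3
  }
  tr <- neighbor_joining(d)
  dd <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(dd, d, tolerance = 1e-9)
  # AB|CD split present
  expect_true(ape::is.monophyletic(ape::root(tr, "C"), c("A", "B")))
  # three leaves: closed-form star
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
    dimnames = list(c("x", "y", "z"), c("x", "y", "z"))
  )
  tr3 <- neighbor_joining(d3)
  dd3 <- ape::cophenetic.phylo(tr3)[rownames(d3), colnames(d3)]
  expect_equal(dd3, d3, tolerance = 1e-9)
  expect_error(neighbor_joining(d3[1:2, 1:2]), "3 leaves")
  dbad <- d
  dbad[1, 2] <- 9
  expect_error(neighbor_joining(dbad), "symmetric")
})

test_that("neighbor joining round-trips random tree metrics", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(4:12, 1)
    tr0 <- ape::rtree(n)
    d0 <- ape::cophenetic.phylo(tr0)
    tr <- neighbor_joining(d0)
    d1 <- ape::cophenetic.phylo(tr)[rownames(d0), colnames(d0)]
    expect_lt(max(abs(d1 - d0)), 1e-9)
    # independent cross-check: same unrooted topology as ape's NJ
    expect_equal(
      as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(ape::nj(d0)))), 0
    )
  }
})

test_that("DAPC separates diverged populations and is exchangeable on clones", {
  sub <- simulate_subdivided(
    genome_config(n_chrom = 5, snps_per_chrom = 200),
    k_flocks = 2, flock_size = 50, generations_isolated = 21, seed = 9
  )
  expect_gt(sub$truth$realized_fst, 0.1)
  da <- dapc(sub$panel, k = 2, seed = 3)
  memb <- da$membership
  expect_equal(rowSums(as.matrix(memb[, c("p_1", "p_2")])), rep(1, nrow(memb)),
    tolerance = 1e-9
  )
  tab <- table(memb$pop, memb$cluster)
  agree <- max(sum(diag(tab)), tab[1, 2] + tab[2, 1]) / sum(tab)
  expect_gte(agree, 0.95)
  # duplicated panel: clusters cut across the two copies, means near 0.5
  set.seed(77)
  freqs <- runif(300, 0.2, 0.8)
  g <- matrix(rbinom(40 * 300, 2, rep(freqs, each = 40)), 40, 300)
  clone <- gene_panel(
    rbind(g, g),
    tibble::tibble(snp_id = paste0("s", 1:300), chrom = "1", pos = 1:300 * 10L),
    tibble::tibble(
      ind_id = paste0("i", 1:80), pop = rep(c("C1", "C2"), each = 40)
    )
  )
  dc <- dapc(clone, k = 2, seed = 5)
  pm <- as.matrix(dc$pop_membership[, c("p_1", "p_2")])
  expect_lt(max(abs(pm - 0.5)), 0.15)
  expect_error(dapc(sub$panel, k = 1), "k must be")
})

test_that("mantel p-values match exhaustive enumeration on small matrices", {
  set.seed(8)
  n <- 5
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- runif(10)
  a <- a + t(a)
  b <- matrix(0, n, n)
  b[upper.tri(b)] <- runif(10)
  b <- b + t(b)
  got <- mantel_test(a, b,
    transform_a = identity, transform_b = identity,
    exact = TRUE
  )
  # oracle: enumerate the 120 permutations directly
  perms <- as.matrix(expand.grid(rep(list(1:n), n)))
  perms <- perms[apply(perms, 1, function(x) length(unique(x)) == n), ]
  ut <- upper.tri(a)
  r_obs <- cor(a[ut], b[ut])
  rs <- apply(perms, 1, function(pm) cor(a[ut], b[pm, pm][ut]))
  expect_equal(got$r, r_obs)
  expect_equal(got$n_perm, 120)
  expect_equal(got$p, mean(rs >= r_obs - 1e-12))
  # self-correlation: r = 1 at the smallest achievable p
  self <- mantel_test(a, a,
    transform_a = identity, transform_b = identity,
    n_perm = 199, seed = 1
  )
  expect_equal(self$r, 1)
  # smallest achievable p given that sampled permutations can also reach r = 1
  expect_lte(self$p, 0.05)
})

test_that("mantel test is calibrated under the null", {
  rej <- 0L
  for (s in 1:100) {
    set.seed(1000 + s)
    n <- 8
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- runif(choose(n, 2))
    a <- a + t(a)
    b <- matrix(0, n, n)
    b[upper.tri(b)] <- runif(choose(n, 2))
    b <- b + t(b)
    p <- mantel_test(a, b,
      n_perm = 199, transform_a = identity,
      transform_b = identity, seed = s
    )$p
    if (p <= 0.05) rej <- rej + 1L
  }
  # 3 binomial SDs around the nominal 5/100
  expect_lte(abs(rej - 5), 3 * sqrt(100 * 0.05 * 0.95))
})

test_that("mantel agrees with an independent implementation on r", {
  skip_if_not_installed("vegan")
  set.seed(17)
  n <- 7
  a <- as.matrix(dist(matrix(runif(n * 2), n)))
  b <- as.matrix(dist(matrix(runif(n * 2), n)))
  got <- mantel_test(a, b,
    transform_a = identity, transform_b = identity,
    n_perm = 999, seed = 2
  )
  ref <- vegan::mantel(as.dist(a), as.dist(b), permutations = 999)
  expect_equal(got$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("partial correlation reduces to Pearson and to residual correlation", {
  set.seed(23)
  x <- rnorm(30)
  y <- 0.5 * x + rnorm(30)
  expect_equal(partial_correlation(x, y)$r, cor(x, y))
  expect_equal(partial_correlation(x, x + 0 * y, z = rnorm(30))$r, 1)
  # 10-row fixture with one covariate: equals correlation of residuals
  z <- rnorm(10)
  x10 <- 0.8 * z + rnorm(10)
  y10 <- -0.5 * z + rnorm(10)
  pc <- partial_correlation(x10, y10, z)
  rx <- resid(lm(x10 ~ z))
  ry <- resid(lm(y10 ~ z))
  expect_equal(pc$r, cor(rx, ry))
  expect_equal(pc$df, 10 - 3)
  # p matches the t distribution arithmetic
  tstat <- pc$r * sqrt(pc$df / (1 - pc$r^2))
  expect_equal(pc$p, 2 * pt(-abs(tstat), pc$df))
  expect_error(partial_correlation(x10, y10, cbind(z, z)), "singular")
})

test_that("great-circle distances match the haversine closed form", {
  co <- data.frame(pop = c("a", "b"), lat = c(10, 10), lon = c(20, 20))
  expect_equal(geographic_distance(co)["a", "b"], 0)
  anti <- data.frame(pop = c("a", "b"), lat = c(0, 0), lon = c(0, 180))
  expect_equal(geographic_distance(anti)["a", "b"], pi * 6371, tolerance = 1e-9)
  expect_error(
    geographic_distance(data.frame(pop = "x", lat = 95, lon = 0)),
    "out of range"
  )
  skip_if_not_installed("geosphere")
  tab <- breed_coordinates()
  d <- geographic_distance(tab)
  i <- match("GAT", tab$pop)
  j <- match("HOU", tab$pop) # two breeds near Paris
  ref <- geosphere::distHaversine(
    c(tab$lon[i], tab$lat[i]), c(tab$lon[j], tab$lat[j]), r = 6371000
  ) / 1000
  expect_equal(d["GAT", "HOU"], ref, tolerance = 1e-6)
})

test_that("management partial correlations reproduce the published signs", {
  pc <- management_partial_correlations(breed_management())
  r_gen <- pc$r[pc$x == "n_generations" & pc$y == "ne_demo"]
  r_nef <- pc$r[pc$x == "ne_founders" & pc$y == "delta_f_pct"]
  expect_gt(r_gen, 0)
  expect_lt(r_nef, 0)
})
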