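#' Identity-by-state distance matrix between individuals
#'
#' For each pair, similarity is the mean shared-allele count over mutually
#' non-missing SNPs (2 for identical genotypes, 1 for one shared allele, 0
#' for opposite homozygotes) divided by 2; the distance is 1 minus that,
#' i.e. `mean(|g_i - g_j|) / 2`.
#'
#' @param panel A [gene_panel()] with at least two individuals.
#' @return A symmetric matrix with zero diagonal, individual ids as
#'   dimnames.
#' @export
ibs_distance <- function(panel) {
  if (n_ind(panel) < 2L) stop("need at least two individuals", call. = FALSE)
  g <- panel$geno
  m0 <- (!is.na(g) & g == 0L) * 1
  m1 <- (!is.na(g) & g == 1L) * 1
  m2 <- (!is.na(g) & g == 2L) * 1
  called <- (!is.na(g)) * 1
  overlap <- tcrossprod(called)
  absdiff <- tcrossprod(m0, m1) + tcrossprod(m1, m0) +
    tcrossprod(m1, m2) + tcrossprod(m2, m1) +
    2 * (tcrossprod(m0, m2) + tcrossprod(m2, m0))
  if (any(overlap[upper.tri(overlap)] == 0)) {
    idx <- which(overlap == 0 & upper.tri(overlap), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "no overlapping SNPs for pair %s / %s",
      panel$inds$ind_id[idx[1]], panel$inds$ind_id[idx[2]]
    ), call. = FALSE)
  }
  d <- absdiff / (2 * overlap)
  diag(d) <- 0
  dimnames(d) <- list(panel$inds$ind_id, panel$inds$ind_id)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q criterion, written here so
#' the tie-breaking and negative-branch policy are explicit and
#' deterministic: among tied minimal-Q pairs the lexicographically smallest
#' (sorted) label pair is joined; a negative estimated branch length is
#' clamped to zero and the deficit transferred to its sister branch. The
#' result is an unrooted ape `phylo` object, serializable with
#' [write_newick()].
#'
#' @param d Symmetric distance matrix (zero diagonal, dimension >= 3) with
#'   unique dimnames, or a `dist` object.
#' @param tol Symmetry tolerance, default 1e-8.
#' @return An ape `phylo` tree whose tip labels are the matrix labels.
#' @export
neighbor_joining <- function(d, tol = 1e-8) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (nrow(d) < 3L) stop("need at least 3 leaves", call. = FALSE)
  if (max(abs(d - t(d))) > tol) stop("matrix is not symmetric", call. = FALSE)
  labels <- rownames(d)
  frag <- labels # newick fragment per active node
  first <- labels # lexicographic representative for tie-breaking
  act <- d
  while (nrow(act) > 3L) {
    n <- nrow(act)
    r <- rowSums(act)
    q <- (n - 2) * act - outer(r, r, "+")
    diag(q) <- Inf
    mn <- min(q)
    cand <- which(q - mn <= tol * max(1, abs(mn)) & upper.tri(q), arr.ind = TRUE)
    pick <- pick_pair(cand, first)
    i <- pick[1]
    j <- pick[2]
    vi <- act[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- act[i, j] - vi
    if (vi < 0) {
      vj <- vj + vi
      vi <- 0
    }
    if (vj < 0) {
      vi <- vi + vj
      vj <- 0
    }
    vi <- max(vi, 0)
    vj <- max(vj, 0)
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], vi, frag[j], vj)
    newfirst <- min(first[i], first[j])
    dnew <- (act[i, ] + act[j, ] - act[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    act <- rbind(cbind(act[keep, keep, drop = FALSE], dnew[keep]), c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    first <- c(first[keep], newfirst)
  }
  # final three-point star
  v1 <- (act[1, 2] + act[1, 3] - act[2, 3]) / 2
  v2 <- (act[1, 2] + act[2, 3] - act[1, 3]) / 2
  v3 <- (act[1, 3] + act[2, 3] - act[1, 2]) / 2
  v <- pmax(c(v1, v2, v3), 0)
  nwk <- sprintf(
    "(%s:%.10g,%s:%.10g,%s:%.10g);", frag[1], v[1], frag[2], v[2], frag[3], v[3]
  )
  ape::read.tree(text = nwk)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

pick_pair <- function(cand, first) {
  if (nrow(cand) == 1L) return(cand[1, ])
  keys <- apply(cand, 1, function(ij) {
    s <- sort(c(first[ij[1]], first[ij[2]]))
    paste(s, collapse = "\r")
  })
  cand[order(keys)[1], ]
}

#' Discriminant analysis of principal components
#'
#' The classical DAPC pipeline: the genotype matrix is column-centered
#' (missing cells mean-imputed per SNP), rotated onto its leading principal
#' components, clustered by K-means on the retained axes, and a linear
#' discriminant analysis of the clusters on those axes yields per-individual
#' posterior membership probabilities.
#'
#' @param panel A [gene_panel()].
#' @param k Number of clusters (>= 2), default 2.
#' @param n_pc Number of retained principal components; default the smallest
#'   count explaining at least 80% of the variance (capped below the number
#'   of individuals).
#' @param n_da Number of discriminant axes, default `k - 1`.
#' @param n_start K-means restarts, default 20.
#' @param seed Random seed for the K-means initialization.
#' @return An object of class `dapc_result`: `membership` tibble (`ind_id`,
#'   `pop`, `cluster`, one `p_<cluster>` column per cluster), `pop_membership`
#'   (per-population mean membership), `n_pc`, `k`, `var_explained`.
#' @export
dapc <- function(panel, k = 2, n_pc = NULL, n_da = k - 1, n_start = 20,
                 seed = 1) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > n_ind(panel)) stop("k exceeds the number of individuals", call. = FALSE)
  g <- panel$geno
  cm <- colMeans(g, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  x <- sweep(g, 2, cm)
  x[is.na(x)] <- 0 # mean imputation after centering
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  var_frac <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  if (is.null(n_pc)) n_pc <- which(var_frac >= 0.8)[1]
  n_pc <- min(n_pc, n_ind(panel) - 1L, sum(pc$sdev > 1e-10))
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  set.seed(seed)
  km <- stats::kmeans(scores, centers = k, nstart = n_start)
  fit <- tryCatch(
    MASS::lda(scores, grouping = factor(km$cluster)),
    error = function(e) {
      # ridge-regularize a singular within-cluster scatter by jittering
      message("[dapc] singular scatter; ridge epsilon 1e-8 applied")
      MASS::lda(scores + matrix(
        stats::rnorm(length(scores), sd = 1e-8),
        nrow(scores)
      ), grouping = factor(km$cluster))
    }
  )
  post <- stats::predict(fit, scores)$posterior
  nd <- min(n_da, ncol(fit$scaling))
  memb <- tibble::as_tibble(post, .name_repair = ~ paste0("p_", .x))
  memb <- dplyr::bind_cols(
    tibble::tibble(
      ind_id = panel$inds$ind_id, pop = panel$inds$pop,
      cluster = as.integer(colnames(post)[max.col(post)])
    ),
    memb
  )
  pop_memb <- dplyr::summarise(
    dplyr::group_by(memb, .data$pop),
    dplyr::across(dplyr::starts_with("p_"), mean),
    .groups = "drop"
  )
  structure(
    list(
      membership = memb, pop_membership = pop_memb, n_pc = n_pc, k = k,
      n_da = nd, var_explained = var_frac[n_pc]
    ),
    class = "dapc_result"
  )
}

#' @export
print.dapc_result <- function(x, ...) {
  cat(sprintf(
    "<dapc_result> K = %d clusters, %d PCs (%.1f%% variance), %d individuals\n",
    x$k, x$n_pc, 100 * x$var_explained, nrow(x$membership)
  ))
  invisible(x)
}

#' @method tidy dapc_result
#' @export
tidy.dapc_result <- function(x, ...) x$membership

#' @method glance dapc_result
#' @export
glance.dapc_result <- function(x, ...) {
  tibble::tibble(
    k = x$k, n_pc = x$n_pc, n_da = x$n_da,
    var_explained = x$var_explained, n_ind = nrow(x$membership)
  )
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal upper triangles after elementwise
#' transforms, with a one-sided permutation p-value: rows/columns of the
#' second matrix are permuted jointly and
#' `p = (1 + #(r_perm >= r_obs)) / (1 + n_perm)`.
#'
#' @param a,b Symmetric matrices with identical labels in identical order.
#' @param n_perm Number of permutations (>= 99), default 999.
#' @param transform_a,transform_b Elementwise transforms applied before the
#'   correlation. Defaults follow the isolation-by-distance convention for a
#'   genetic-differentiation matrix against geographic distance:
#'   `a -> 1 / (1 - a)` (for Fst) and `b -> log(b)`. Pass `identity` for raw
#'   matrices.
#' @param seed Random seed for the permutations.
#' @param exact Enumerate all `n!` label permutations instead of sampling
#'   (feasible for small matrices, say `n <= 8`); the p-value is then the
#'   exact fraction of permutations with `r >= r_obs` (the identity
#'   permutation included, so `p > 0`).
#' @return A one-row tibble `r`, `p`, `n_perm`, `n` (labels). `r` is `NA`
#'   when a transform leaves zero variance.
#' @export
mantel_test <- function(a, b, n_perm = 999,
                        transform_a = function(x) 1 / (1 - x),
                        transform_b = log, seed = 1, exact = FALSE) {
  stopifnot(nrow(a) == ncol(a), nrow(b) == ncol(b), nrow(a) == nrow(b))
  if (!exact && n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
    !identical(rownames(a), rownames(b))) {
    stop("matrices must share labels in the same order", call. = FALSE)
  }
  ta <- transform_a(a)
  tb <- transform_b(b)
  ut <- upper.tri(ta)
  x <- ta[ut]
  if (stats::sd(x) == 0 || stats::sd(tb[ut]) == 0) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, n_perm = n_perm, n = nrow(a)))
  }
  r_obs <- stats::cor(x, tb[ut])
  n <- nrow(a)
  if (exact) {
    perms <- all_permutations(n)
    rs <- vapply(perms, function(pm) stats::cor(x, tb[pm, pm][ut]), 0)
    return(tibble::tibble(
      r = r_obs, p = mean(rs >= r_obs - 1e-12), n_perm = length(perms), n = n
    ))
  }
  set.seed(seed)
  hits <- 0L
  for (k in seq_len(n_perm)) {
    pm <- sample.int(n)
    rp <- stats::cor(x, tb[pm, pm][ut])
    if (rp >= r_obs) hits <- hits + 1L
  }
  tibble::tibble(
    r = r_obs, p = (1 + hits) / (1 + n_perm), n_perm = n_perm, n = n
  )
}

#' Partial correlation between two variables given covariates
#'
#' Computed from the inverse of the correlation matrix of `(x, y, Z)`:
#' `r = -Omega_xy / sqrt(Omega_xx * Omega_yy)`; the two-sided p-value uses
#' `t = r * sqrt((n - 2 - k) / (1 - r^2))` on `n - 2 - k` degrees of
#' freedom, `k` the number of covariates. Complete cases only.
#'
#' @param x,y Numeric vectors.
#' @param z Optional covariates: a numeric vector, matrix or data frame.
#' @return A one-row tibble `r`, `p`, `n`, `df`.
#' @export
partial_correlation <- function(x, y, z = NULL) {
  z <- if (is.null(z)) {
    matrix(numeric(0), nrow = length(x), ncol = 0)
  } else {
    as.matrix(as.data.frame(z))
  }
  stopifnot(length(x) == length(y), nrow(z) == length(x))
  cc <- stats::complete.cases(x, y, z)
  x <- x[cc]
  y <- y[cc]
  z <- z[cc, , drop = FALSE]
  n <- length(x)
  k <- ncol(z)
  if (n <= k + 2) stop("not enough complete cases", call. = FALSE)
  zz <- cbind(`(intercept)` = 1, z)
  qz <- qr(zz)
  if (qz$rank < ncol(zz)) {
    bad <- colnames(zz)[-seq_len(qz$rank)]
    stop("singular correlation matrix; collinear or constant columns among: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  # residual form of the inverse-correlation-matrix partial correlation
  rx <- stats::lm.fit(zz, x)$residuals
  ry <- stats::lm.fit(zz, y)$residuals
  if (stats::sd(rx) < 1e-14 || stats::sd(ry) < 1e-14) {
    stop("singular correlation matrix; collinear or constant columns among: x, y",
      call. = FALSE
    )
  }
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  tibble::tibble(
    r = r, p = 2 * stats::pt(-abs(tstat), df), n = n, df = df
  )
}

#' Great-circle distance matrix from decimal-degree coordinates
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param coords Data frame with columns `lat`, `lon` in decimal degrees and
#'   optionally a label column (`pop` or the first character column).
#' @return A symmetric matrix of distances in km.
#' @export
geographic_distance <- function(coords) {
  coords <- as.data.frame(coords)
  lat <- coords$lat
  lon <- coords$lon
  if (any(abs(lat) > 90) || any(abs(lon) > 180)) {
    stop("coordinates out of range", call. = FALSE)
  }
  labs <- if ("pop" %in% names(coords)) {
    coords$pop
  } else {
    chr <- which(vapply(coords, is.character, logical(1)))
    if (length(chr)) coords[[chr[1]]] else as.character(seq_along(lat))
  }
  rad <- pi / 180
  phi <- lat * rad
  lam <- lon * rad
  n <- length(lat)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    h <- sin((phi[j] - phi[i]) / 2)^2 +
      cos(phi[i]) * cos(phi[j]) * sin((lam[j] - lam[i]) / 2)^2
    dd <- 2 * 6371 * asin(pmin(1, sqrt(h)))
    d[i, j] <- d[j, i] <- dd
  }
  d
}
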