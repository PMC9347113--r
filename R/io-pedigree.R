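#' Read a pedigree table
#'
#' Reads a delimited file (or coerces a data frame) with columns `id`,
#' `sire`, `dam` and optionally `sex` and `birth_year`. Unknown parents are
#' coded `0`, empty, or `NA`. The result is topologically sorted so that
#' parents precede their offspring, founders (both parents unknown) are
#' flagged, and a generation index (longest ancestor path, founders = 0) is
#' attached.
#'
#' @param x Path to a CSV/TSV file (delimiter sniffed from the header), or a
#'   data frame with the same columns.
#' @return A tibble with columns `id`, `sire`, `dam` (`NA` = unknown),
#'   optional `sex`/`birth_year`, `founder` (logical) and `generation`
#'   (integer birth-order proxy), topologically sorted.
#' @export
#' @examples
#' ped <- read_pedigree(data.frame(
#'   id = c("C", "A", "B"), sire = c("A", 0, 0), dam = c("B", 0, 0)
#' ))
#' ped$founder
read_pedigree <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    hdr <- readLines(x, n = 1)
    sep <- if (grepl("\t", hdr)) "\t" else if (grepl(";", hdr)) ";" else ","
    x <- utils::read.table(x,
      header = TRUE, sep = sep, colClasses = "character",
      stringsAsFactors = FALSE
    )
  }
  df <- tibble::as_tibble(x)
  names(df) <- tolower(names(df))
  names(df)[names(df) == "individual"] <- "id"
  if (!all(c("id", "sire", "dam") %in% names(df))) {
    stop("pedigree needs columns id (or individual), sire, dam", call. = FALSE)
  }
  df$id <- as.character(df$id)
  df$sire <- clean_parent(df$sire)
  df$dam <- clean_parent(df$dam)
  if (anyDuplicated(df$id)) {
    stop("duplicated individual id(s): ",
      paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
      call. = FALSE
    )
  }
  # parents referenced but absent from the id column are implicit founders
  ghosts <- setdiff(c(df$sire, df$dam), c(df$id, NA))
  if (length(ghosts)) {
    pad <- df[rep(NA_integer_, length(ghosts)), ]
    pad$id <- ghosts
    pad$sire <- NA_character_
    pad$dam <- NA_character_
    df <- dplyr::bind_rows(pad, df)
  }
  ord <- pedigree_toposort(df$id, df$sire, df$dam)
  df <- df[ord$order, , drop = FALSE]
  df$generation <- ord$depth[ord$order]
  df$founder <- is.na(df$sire) & is.na(df$dam)
  df
}

clean_parent <- function(p) {
  p <- as.character(p)
  p[is.na(p) | p %in% c("0", "", "NA", ".")] <- NA_character_
  p
}

# Kahn topological sort over the parent -> offspring DAG.
# Returns the visit order and the generation depth (longest path from a
# founder); reports one cycle on failure.
pedigree_toposort <- function(id, sire, dam) {
  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
  indeg <- (!is.na(si)) + (!is.na(di))
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) kids[[p]] <- c(kids[[p]], i)
    }
  }
  depth <- integer(n)
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    out <- c(out, v)
    for (k in kids[[v]]) {
      depth[k] <- max(depth[k], depth[v] + 1L)
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) < n) {
    left <- setdiff(seq_len(n), out)
    cyc <- find_cycle(left, si, di)
    stop(
      "cyclic parentage involving: ", paste(id[cyc], collapse = " -> "),
      call. = FALSE
    )
  }
  list(order = out, depth = depth)
}

find_cycle <- function(left, si, di) {
  # walk parent pointers inside the unresolved set until a repeat
  seen <- integer(0)
  v <- left[1]
  while (!(v %in% seen)) {
    seen <- c(seen, v)
    p <- c(si[v], di[v])
    p <- p[!is.na(p) & p %in% left]
    v <- p[1]
  }
  c(seen[which(seen == v):length(seen)], v)
}

#' Write a pedigree table to CSV
#' @param ped A pedigree tibble as returned by [read_pedigree()] or
#'   [build_pedigree()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a phylogenetic tree in Newick format
#'
#' Thin serialization wrapper around the ape `phylo` machinery; trees built
#' by [neighbor_joining()] are `phylo` objects and round-trip through this
#' writer to 1e-9 in branch length.
#'
#' @param tree A `phylo` object (connected, finite branch lengths).
#' @param path Optional output file; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$edge.length) && any(!is.finite(tree$edge.length))) {
    stop("branch lengths must be finite", call. = FALSE)
  }
  # a phylo with fewer edges than needed to connect all tips is disconnected
  if (nrow(tree$edge) < length(tree$tip.label) + tree$Nnode - 1L) {
    stop("tree is not connected", call. = FALSE)
  }
  s <- ape::write.tree(tree)
  if (is.null(path)) {
    return(s)
  }
  writeLines(s, path)
  invisible(s)
}

#' Read a Newick tree
#' @param x Path to a Newick file, or a Newick string.
#' @return An ape `phylo` object.
#' @export
read_newick <- function(x) {
  if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
}
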