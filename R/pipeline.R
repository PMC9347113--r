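#' Configuration for an end-to-end analysis run
#'
#' Bundles the inputs and every stage parameter with the defaults of a
#' standard 50K-chip conservation-genetics workflow: MAF > 0.001,
#' per-marker and per-individual missingness <= 0.05, LD pruning in 30-SNP
#' windows stepping by 10 at r-squared 0.8, the [roh_params()] defaults, and
#' DAPC with K = 2.
#'
#' @param panel A [gene_panel()], or NULL to read from `ped_path`/`map_path`.
#' @param ped_path,map_path PLINK text input (used when `panel` is NULL).
#' @param pedigree Optional pedigree (path or tibble) for `pedstats`.
#' @param management Optional management table (see [breed_management()]) for
#'   `pedstats` and `pcor`.
#' @param coords Optional coordinates table (see [breed_coordinates()]) for
#'   the Mantel stage.
#' @param stages Stages to run, a subset of
#'   `c("qc", "prune", "divstats", "fst", "roh", "pedstats", "tree", "dapc",
#'   "mantel", "pcor")`; executed in that fixed order.
#' @param maf_min,max_missing_snp,max_missing_ind QC thresholds.
#' @param prune_window,prune_step,prune_r2 LD pruning parameters.
#' @param roh A [roh_params()] list.
#' @param dapc_k DAPC cluster count.
#' @param mantel_n_perm Mantel permutations.
#' @param seed Top-level seed; stage substreams are derived from it.
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(panel = NULL, ped_path = NULL, map_path = NULL,
                       pedigree = NULL, management = NULL, coords = NULL,
                       stages = c(
                         "qc", "prune", "divstats", "fst", "roh",
                         "pedstats", "tree", "dapc", "mantel", "pcor"
                       ),
                       maf_min = 0.001, max_missing_snp = 0.05,
                       max_missing_ind = 0.05,
                       prune_window = 30, prune_step = 10, prune_r2 = 0.8,
                       roh = roh_params(), dapc_k = 2, mantel_n_perm = 999,
                       seed = 1, out_dir = tempfile("flockdiv_run_"),
                       quiet = FALSE) {
  order_all <- c(
    "qc", "prune", "divstats", "fst", "roh", "pedstats", "tree",
    "dapc", "mantel", "pcor"
  )
  stages <- order_all[order_all %in% stages]
  structure(
    list(
      panel = panel, ped_path = ped_path, map_path = map_path,
      pedigree = pedigree, management = management, coords = coords,
      stages = stages, maf_min = maf_min, max_missing_snp = max_missing_snp,
      max_missing_ind = max_missing_ind, prune_window = prune_window,
      prune_step = prune_step, prune_r2 = prune_r2, roh = roh,
      dapc_k = dapc_k, mantel_n_perm = mantel_n_perm, seed = seed,
      out_dir = out_dir, quiet = quiet
    ),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in fixed order -- QC, LD pruning, diversity
#' indices, Fst, ROH, pedigree demography, NJ tree, DAPC, Mantel test,
#' partial correlations -- writing one TSV (or Newick) artifact per stage
#' into `config$out_dir`, plus a resolved-config copy and a manifest listing
#' every artifact with the MD5 hashes of the inputs that produced it. All
#' randomness is derived from the single top-level seed, so a rerun with an
#' identical config writes byte-identical artifacts; outputs that already
#' match on hash are left untouched.
#'
#' A stage failure aborts with the stage name; artifacts already written are
#' preserved.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  manifest <- list()
  say <- function(...) if (!config$quiet) message("[pipeline] ", sprintf(...))

  input_hashes <- character()
  panel <- config$panel
  if (is.null(panel) && !is.null(config$ped_path)) {
    input_hashes <- tools::md5sum(c(config$ped_path, config$map_path))
    panel <- read_ped_map(config$ped_path, config$map_path)
  }

  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    tmp <- paste0(path, ".tmp")
    writer(tmp)
    if (file.exists(path) &&
      identical(unname(tools::md5sum(tmp)), unname(tools::md5sum(path)))) {
      unlink(tmp) # unchanged: reuse the existing artifact
    } else {
      file.rename(tmp, path)
    }
    manifest[[length(manifest) + 1L]] <<- tibble::tibble(
      artifact = name, md5 = unname(tools::md5sum(path)),
      inputs = paste(sprintf("%s=%s", names(input_hashes), input_hashes),
        collapse = ";"
      )
    )
    path
  }
  run_stage <- function(stage, fn) {
    say("stage %s", stage)
    tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
        call. = FALSE
      )
    })
  }

  cfg_lines <- resolved_config_lines(config)
  writeLines(cfg_lines, file.path(config$out_dir, "resolved_config.txt"))

  pruned <- panel
  for (stage in config$stages) {
    if (stage == "qc") {
      run_stage("qc", function() {
        qc <- filter_panel(panel,
          maf_min = config$maf_min,
          max_missing_snp = config$max_missing_snp,
          max_missing_ind = config$max_missing_ind, quiet = config$quiet
        )
        panel <<- qc$panel
        pruned <<- qc$panel
        rep <- dplyr::mutate(qc$report,
          n_removed = lengths(.data$removed), removed = NULL
        )
        emit("qc_report.tsv", function(p) readr::write_tsv(rep, p))
        res$qc <<- qc
      })
    } else if (stage == "prune") {
      run_stage("prune", function() {
        kept <- prune_ld(panel,
          window_snps = config$prune_window,
          step_snps = config$prune_step, r2_max = config$prune_r2
        )
        pruned <<- panel_subset(panel, snp = kept)
        emit("pruned_snps.txt", function(p) writeLines(kept, p))
        res$prune <<- kept
      })
    } else if (stage == "divstats") {
      run_stage("divstats", function() {
        ds <- diversity_summary(pruned)
        emit("diversity.tsv", function(p) readr::write_tsv(tibble::as_tibble(ds), p))
        res$divstats <<- ds
      })
    } else if (stage == "fst") {
      run_stage("fst", function() {
        if (length(unique(pruned$inds$pop)) < 2) {
          say("fst skipped: single population")
          return(invisible())
        }
        fst <- wc_fst(pruned)
        emit("fst_global.tsv", function(p) readr::write_tsv(glance(fst), p))
        emit("fst_pairwise.tsv", function(p) readr::write_tsv(tidy(fst), p))
        res$fst <<- fst
      })
    } else if (stage == "roh") {
      run_stage("roh", function() {
        segs <- detect_roh(panel, config$roh)
        smry <- roh_summary(segs, panel, config$roh)
        hdr <- sprintf(
          "# window_hit_fraction=%g max_gap_bp=%d (scanner defaults; panel-specific parameters in resolved_config.txt)",
          config$roh$window_hit_fraction, config$roh$max_gap_bp
        )
        emit("roh_segments.tsv", function(p) {
          writeLines(hdr, p)
          readr::write_tsv(segs, p, append = TRUE, col_names = TRUE)
        })
        emit("roh_summary.tsv", function(p) {
          readr::write_tsv(tibble::as_tibble(smry), p)
        })
        res$roh <<- list(segments = segs, summary = smry)
      })
    } else if (stage == "pedstats") {
      run_stage("pedstats", function() {
        if (is.null(config$management) && is.null(config$pedigree)) {
          say("pedstats skipped: no pedigree or management input")
          return(invisible())
        }
        if (!is.null(config$management)) {
          ps <- pedigree_stats(config$management)
        } else {
          ped <- read_pedigree(config$pedigree)
          ne <- realized_effective_size(ped)
          ps <- dplyr::mutate(ne, pop = "pedigree", .before = 1)
        }
        emit("pedigree_stats.tsv", function(p) readr::write_tsv(ps, p))
        res$pedstats <<- ps
      })
    } else if (stage == "tree") {
      run_stage("tree", function() {
        d <- ibs_distance(pruned)
        tree <- neighbor_joining(d)
        emit("nj_tree.nwk", function(p) write_newick(tree, p))
        res$tree <<- tree
      })
    } else if (stage == "dapc") {
      run_stage("dapc", function() {
        da <- dapc(pruned, k = config$dapc_k, seed = config$seed + 101L)
        emit("dapc_membership.tsv", function(p) readr::write_tsv(da$membership, p))
        emit("dapc_pop_membership.tsv", function(p) {
          readr::write_tsv(da$pop_membership, p)
        })
        res$dapc <<- da
      })
    } else if (stage == "mantel") {
      run_stage("mantel", function() {
        if (is.null(config$coords) || is.null(res$fst)) {
          say("mantel skipped: needs coords and the fst stage")
          return(invisible())
        }
        pops <- intersect(rownames(res$fst$pairwise), config$coords$pop)
        if (length(pops) < 4) {
          say("mantel skipped: fewer than 4 populations with coordinates")
          return(invisible())
        }
        geo <- geographic_distance(
          config$coords[match(pops, config$coords$pop), ]
        )
        mt <- mantel_test(
          res$fst$pairwise[pops, pops], geo[pops, pops],
          n_perm = config$mantel_n_perm, seed = config$seed + 202L
        )
        emit("mantel.tsv", function(p) readr::write_tsv(mt, p))
        res$mantel <<- mt
      })
    } else if (stage == "pcor") {
      run_stage("pcor", function() {
        if (is.null(config$management)) {
          say("pcor skipped: no management table")
          return(invisible())
        }
        pc <- management_partial_correlations(config$management)
        emit("partial_correlations.tsv", function(p) readr::write_tsv(pc, p))
        res$pcor <<- pc
      })
    }
  }
  readr::write_tsv(dplyr::bind_rows(manifest), file.path(config$out_dir, "manifest.tsv"))
  invisible(res)
}

resolved_config_lines <- function(config) {
  flat <- c(
    config[c(
      "maf_min", "max_missing_snp", "max_missing_ind", "prune_window",
      "prune_step", "prune_r2", "dapc_k", "mantel_n_perm", "seed"
    )],
    unclass(config$roh)
  )
  c(
    sprintf("stages=%s", paste(config$stages, collapse = ",")),
    sprintf("%s=%s", names(flat), vapply(flat, format, "")),
    sprintf("flockdiv_version=%s", as.character(utils::packageVersion("flockdiv")))
  )
}

#' Partial correlations between demography and management features
#'
#' For the feature pairs of a management-program evaluation, computes
#' partial Pearson correlations over complete-case rows of a management
#' table: every pair among `n_generations`, `n_male_founders`,
#' `n_female_founders`, `ne_demo`, `ne_founders` and `delta_f_pct` is
#' corrected for the remaining management features, except that pairs
#' involving `ne_founders` are corrected for `n_generations` only
#' (`ne_founders` being a function of the founder counts).
#'
#' @param management A management tibble (see [breed_management()]);
#'   `ne_founders` is recomputed from the founder counts if absent.
#' @return A tibble `x`, `y`, `r`, `p`, `n` of class `pcor_result`.
#' @export
management_partial_correlations <- function(management) {
  df <- tibble::as_tibble(management)
  if (!("ne_founders" %in% names(df))) {
    df$ne_founders <- founder_effective_size(
      df$n_male_founders, df$n_female_founders
    )
  }
  feats <- c("n_generations", "n_male_founders", "n_female_founders", "ne_founders")
  resp <- intersect(c("ne_demo", "delta_f_pct", "mean_F_pct"), names(df))
  out <- list()
  for (y in resp) {
    for (x in feats) {
      zc <- if (x == "ne_founders") {
        "n_generations"
      } else {
        setdiff(feats, c(x, "ne_founders"))
      }
      sub <- df[, c(x, y, zc)]
      sub <- sub[stats::complete.cases(sub), ]
      if (nrow(sub) <= length(zc) + 2) next
      pc <- partial_correlation(sub[[x]], sub[[y]], sub[, zc, drop = FALSE])
      out[[length(out) + 1L]] <- tibble::tibble(
        x = x, y = y, r = pc$r, p = pc$p, n = pc$n
      )
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("pcor_result", class(res))
  res
}
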