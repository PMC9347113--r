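#' Plot per-population diversity indices
#'
#' Faceted dot-and-error-bar panel of the six indices (Fit, Fis, Ho, He,
#' MAF, fixed proportion), populations sorted by Fit.
#'
#' @param object A `diversity_summary` from [diversity_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diversity_summary
#' @export
autoplot.diversity_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("fit", "fis", "ho", "he", "maf", "fixed"),
    names_to = "index", values_to = "value"
  )
  se_map <- c(fit = "fit_se", fis = "fis_se", ho = "ho_se", he = "he_se", maf = "maf_se")
  long$se <- purrr::map2_dbl(long$index, seq_len(nrow(long)), function(ix, i) {
    col <- se_map[ix]
    if (is.na(col)) NA_real_ else long[[col]][i]
  })
  long$index <- factor(long$index, levels = c("fit", "fis", "ho", "he", "maf", "fixed"))
  ord <- object$pop[order(-object$fit)]
  long$pop <- factor(long$pop, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pop, y = .data$value)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$value - .data$se,
        ymax = .data$value + .data$se
      ),
      width = 0.3, na.rm = TRUE
    ) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$index), scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot per-population ROH summaries
#'
#' Bars of mean F_ROH, mean segment count per individual, and mean segment
#' length (Mb), with standard-error bars.
#'
#' @param object A `roh_summary` from [roh_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roh_summary
#' @export
autoplot.roh_summary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- dplyr::bind_rows(
    tibble::tibble(
      pop = df$pop, stat = "F_ROH",
      value = df$mean_f_roh, se = df$f_roh_se
    ),
    tibble::tibble(
      pop = df$pop, stat = "segments / individual",
      value = df$mean_n_seg, se = df$n_seg_se
    ),
    tibble::tibble(
      pop = df$pop, stat = "segment length (Mb)",
      value = df$mean_seg_length / 1e6, se = df$seg_length_se / 1e6
    )
  )
  ord <- df$pop[order(-df$mean_f_roh)]
  long$pop <- factor(long$pop, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pop, y = .data$value)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$value - .data$se,
        ymax = .data$value + .data$se
      ),
      width = 0.3, na.rm = TRUE
    ) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$stat), scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot DAPC cluster memberships
#'
#' Stacked per-individual posterior membership bars grouped by population.
#'
#' @param object A `dapc_result` from [dapc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dapc_result
#' @export
autoplot.dapc_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$membership,
    cols = dplyr::starts_with("p_"),
    names_to = "cluster_p", values_to = "membership"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$ind_id, y = .data$membership, fill = .data$cluster_p
  )) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$pop), scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_brewer(palette = "Set1", name = "cluster") +
    ggplot2::labs(x = NULL, y = "posterior membership") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank()
    )
}

#' Plot an unrooted neighbor-joining tree
#'
#' @param tree A `phylo` object, e.g. from [neighbor_joining()].
#' @param tip_groups Optional named vector mapping tip labels to groups
#'   (colors).
#' @param ... Passed to [ape::plot.phylo()].
#' @return Invisibly, the tree.
#' @export
plot_nj_tree <- function(tree, tip_groups = NULL, ...) {
  if (is.null(tip_groups)) {
    ape::plot.phylo(tree, type = "unrooted", ...)
  } else {
    grp <- factor(tip_groups[tree$tip.label])
    pal <- grDevices::hcl.colors(max(2L, nlevels(grp)), "Dark 3")
    ape::plot.phylo(tree,
      type = "unrooted",
      tip.color = pal[as.integer(grp)], ...
    )
  }
  invisible(tree)
}
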