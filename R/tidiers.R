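#' Tidy a venom-specificity call set
#'
#' @param x a `venom_calls` object from [call_venom_specific()].
#' @param ... unused.
#' @return the underlying tibble, one row per gene.
#' @export
tidy.venom_calls <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a venom-specificity call set
#'
#' @inheritParams tidy.venom_calls
#' @return a one-row tibble: gene counts, pass count and the thresholds
#'   applied.
#' @export
glance.venom_calls <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble::tibble(
    n_genes = nrow(x),
    n_pass = sum(x$pass),
    alpha = th$alpha,
    min_log2_ratio = th$min_log2_ratio,
    min_fpkm_vg = th$min_fpkm_vg
  )
}

#' Volcano-style plot of venom-specificity calls
#'
#' Log2 venom-gland/carcass ratio against -log10 adjusted p, colored by
#' the three-part pass flag, with the two threshold lines drawn.
#'
#' @param object a `venom_calls` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.venom_calls <- function(object, ...) {
  th <- attr(object, "thresholds")
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$log2_ratio,
    y = -log10(pmax(.data$p_adj, 1e-300)),
    colour = .data$pass
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = th$min_log2_ratio, linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(th$alpha), linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#c0392b", `FALSE` = "grey55"),
      name = "venom-specific"
    ) +
    ggplot2::labs(
      x = "log2 (FPKM VG + 1) / (FPKM carcass + 1)",
      y = "-log10 adjusted p"
    ) +
    ggplot2::theme_minimal()
}

#' Expression-profile heatmap
#'
#' Tile heatmap of log2(FPKM + 1) across samples, the usual way
#' stage/tissue SPI expression panels are displayed.
#'
#' @param mat FPKM tibble (see [read_fpkm()]).
#' @param pseudocount passed to [log2_profile()].
#' @return a ggplot object.
#' @export
plot_expression_profile <- function(mat, pseudocount = 1) {
  prof <- log2_profile(mat, pseudocount)
  long <- tidyr::pivot_longer(
    prof, -"gene",
    names_to = "sample", values_to = "log2_fpkm"
  )
  long$sample <- factor(long$sample, levels = setdiff(names(prof), "gene"))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$sample, y = .data$gene, fill = .data$log2_fpkm
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#1a9850", mid = "grey95", high = "#d73027",
      midpoint = stats::median(long$log2_fpkm), name = "log2 FPKM"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)
    )
}

#' Bar plot of relative expression folds
#'
#' @param folds a tibble from [ddct()].
#' @return a ggplot object.
#' @export
plot_ddct <- function(folds) {
  folds$sample <- factor(folds$sample, levels = folds$sample)
  ggplot2::ggplot(folds, ggplot2::aes(x = .data$sample, y = .data$fold)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "relative expression (2^-ddCt)") +
    ggplot2::theme_minimal()
}
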