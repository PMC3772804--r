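#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' QC waterfall plot
#'
#' Items remaining after each successive filter of a QC report.
#'
#' @param object a `qc_report` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot qc_report
#' @export
autoplot.qc_report <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$stage <- factor(seq_len(nrow(d)),
                    labels = paste0(seq_len(nrow(d)), ": ", d$filter))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$n_after,
                                  fill = .data$unit)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = paste0("-", .data$n_excluded)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "items remaining",
                  title = "QC exclusion chain") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Scan overview plot
#'
#' Heritability estimates against LRT evidence for the heritability scan of
#' a [run_study()] report, colored by FDR tier.
#'
#' @param object a `scan_report`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot scan_report
#' @export
autoplot.scan_report <- function(object, ...) {
  d <- object$heritability
  d$tier <- dplyr::case_when(
    d$p < object$corrections$threshold[
      object$corrections$scan == "heritability"][1] ~ "bonferroni",
    d$q < 0.05 ~ "fdr5",
    d$p < 0.05 ~ "nominal",
    TRUE ~ "ns")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$h2, y = -log10(.data$p),
                                  color = .data$tier)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = expression(hat(h)^2),
                  y = expression(-log[10](p)),
                  title = "Heritability scan") +
    ggplot2::theme_minimal()
}

#' Heatmap of an additive relationship matrix
#'
#' @param rm a `relmat` or relationship matrix.
#' @param ids optional subset / ordering of individuals.
#' @return a ggplot.
#' @export
plot_relationship <- function(rm, ids = NULL) {
  A <- as.matrix(rm)
  if (!is.null(ids)) A <- A[ids, ids]
  d <- tibble::as_tibble(A, rownames = "i") |>
    tidyr::pivot_longer(-"i", names_to = "j", values_to = "a")
  d$i <- factor(d$i, levels = rownames(A))
  d$j <- factor(d$j, levels = rownames(A))
  ggplot2::ggplot(d, ggplot2::aes(.data$i, .data$j, fill = .data$a)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 limits = c(0, max(d$a))) +
    ggplot2::labs(x = NULL, y = NULL, fill = "A") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
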