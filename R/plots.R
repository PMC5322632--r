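#' Plot methods for test results and summaries
#'
#' `autoplot()` on a permutation or simulation result draws per-gene
#' one-sided P-values on a log scale with the 0.05 line; on a gene summary
#' it draws the per-gene total/rare/specific counts for both cohorts.
#' `plot_spectrum()` is the function form of the summary plot.
#'
#' @param object A `vs_perm_test`, `vs_sim_test` or `vs_gene_summary`.
#' @param alpha Reference significance level drawn as a horizontal line.
#' @param ... Unused.
#' @return A ggplot object.
#' @name varspectrum-plots
NULL

pvals_plot <- function(d, alpha, title) {
  d <- d |> mutate(scope = factor(.data$scope, levels = unique(.data$scope)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$scope, y = pmax(.data$p_value, 1e-6))) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$scope == "ALL"), size = 2.5,
                        show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = alpha, linetype = 2, colour = "grey40") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "one-sided P", title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname varspectrum-plots
#' @method autoplot vs_perm_test
#' @export
autoplot.vs_perm_test <- function(object, alpha = 0.05, ...) {
  pvals_plot(strip_tbl(object), alpha,
             paste0("Allele-permutation test: ", attr(object, "statistic"),
                    " statistic"))
}

#' @rdname varspectrum-plots
#' @method autoplot vs_sim_test
#' @export
autoplot.vs_sim_test <- function(object, alpha = 0.05, ...) {
  pvals_plot(strip_tbl(object), alpha,
             "Rare-variant excess vs aggregate reference")
}

#' @rdname varspectrum-plots
#' @method autoplot vs_gene_summary
#' @export
autoplot.vs_gene_summary <- function(object, ...) plot_spectrum(object)

#' @rdname varspectrum-plots
#' @param summary A `vs_gene_summary`.
#' @export
plot_spectrum <- function(summary) {
  d <- strip_tbl(summary) |>
    filter(.data$gene != "Total") |>
    select("gene", dplyr::matches("^(case|ctrl)_(total|rare|specific)$")) |>
    tidyr::pivot_longer(-"gene", names_to = c("cohort", "count"),
                        names_sep = "_", values_to = "n") |>
    mutate(gene = factor(.data$gene, levels = unique(.data$gene)),
           cohort = dplyr::recode(.data$cohort, case = "cases", ctrl = "controls"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene, y = .data$n, fill = .data$cohort)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~count, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "variant sites",
                  title = paste0("Variant spectrum (", attr(summary, "region"),
                                 " regions)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
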