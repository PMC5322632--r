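#' Broom-style accessors for varspectrum results
#'
#' `tidy()` returns the result rows as a plain tibble; `glance()` returns a
#' one-row tibble of the run's settings (replicate counts, seed, modes), so
#' pipelines can collate many runs with `purrr::map_df()`.
#'
#' @param x A `vs_perm_test`, `vs_sim_test`, `vs_snp_tests`, `vs_hwe` or
#'   `vs_gene_summary` object.
#' @param ... Unused.
#' @return A tibble.
#' @name varspectrum-tidiers
NULL

strip_tbl <- function(x) as_tibble(as.data.frame(x))

#' @rdname varspectrum-tidiers
#' @method tidy vs_perm_test
#' @export
tidy.vs_perm_test <- function(x, ...) strip_tbl(x)

#' @rdname varspectrum-tidiers
#' @method tidy vs_sim_test
#' @export
tidy.vs_sim_test <- function(x, ...) strip_tbl(x)

#' @rdname varspectrum-tidiers
#' @method tidy vs_snp_tests
#' @export
tidy.vs_snp_tests <- function(x, ...) strip_tbl(x)

#' @rdname varspectrum-tidiers
#' @method tidy vs_hwe
#' @export
tidy.vs_hwe <- function(x, ...) strip_tbl(x)

#' @rdname varspectrum-tidiers
#' @method tidy vs_gene_summary
#' @export
tidy.vs_gene_summary <- function(x, ...) strip_tbl(x)

#' @rdname varspectrum-tidiers
#' @method glance vs_perm_test
#' @export
glance.vs_perm_test <- function(x, ...) {
  tibble(statistic = attr(x, "statistic"), mode = attr(x, "mode"),
         threshold = attr(x, "threshold"), n_perm = attr(x, "n_perm"),
         seed = attr(x, "seed"), n_scopes = sum(x$scope != "ALL"))
}

#' @rdname varspectrum-tidiers
#' @method glance vs_sim_test
#' @export
glance.vs_sim_test <- function(x, ...) {
  tibble(mode = attr(x, "mode"), model = attr(x, "model"),
         rarity = attr(x, "rarity"), threshold = attr(x, "threshold"),
         n_sim = attr(x, "n_sim"), seed = attr(x, "seed"),
         n_scopes = sum(x$scope != "ALL"))
}

#' @rdname varspectrum-tidiers
#' @method glance vs_gene_summary
#' @export
glance.vs_gene_summary <- function(x, ...) {
  tibble(region = attr(x, "region"), threshold = attr(x, "threshold"),
         case_population = attr(x, "case_population"),
         ctrl_population = attr(x, "ctrl_population"),
         n_genes = sum(x$gene != "Total"),
         totals_correlation = suppressWarnings(totals_correlation(x)))
}

#' @export
print.vs_perm_test <- function(x, ...) {
  cat("One-sided allele-permutation test (", attr(x, "statistic"),
      " statistic, ", attr(x, "n_perm"), " replicates, mode=",
      attr(x, "mode"), ")\n", sep = "")
  NextMethod()
}

#' @export
print.vs_sim_test <- function(x, ...) {
  cat("One-sided reference-simulation test (", attr(x, "model"),
      " sampling, ", attr(x, "n_sim"), " replicates)\n", sep = "")
  NextMethod()
}
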