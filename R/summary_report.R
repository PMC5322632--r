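#' Per-gene variant-spectrum summary table
#'
#' Builds the per-gene summary of detected polymorphisms for one region class
#' (promoter or coding): for each cohort the total number of detected sites,
#' the rare count (within-cohort MAF at or below `threshold`), the
#' population-specific count, the count of sites absent from dbSNP ("new"),
#' the functional-class breakdown (missense / nonsense / synonymous) and the
#' concordantly damaging count. A `Total` row sums the gene rows. Every cell
#' is produced by the spectrum-statistic classifiers, so regenerating the
#' table from the same data is bit-identical.
#'
#' @inheritParams spectrum_stats
#' @param region `"promoter"` or `"coding"`; sites are filtered on their
#'   `region_class` column.
#' @return A `vs_gene_summary` tibble with one row per panel gene plus
#'   `Total`; case columns are prefixed `case_`, control columns `ctrl_`.
#' @export
gene_summary <- function(case, control, sites, panel = NULL,
                         region = c("coding", "promoter"), threshold = 0.01) {
  region <- match.arg(region)
  s <- sites[sites$region_class == region, , drop = FALSE]
  genes <- if (!is.null(panel)) panel_genes(panel)$gene else unique(sites$gene)
  ca <- cohort_at_sites(case, s, panel)
  co <- cohort_at_sites(control, s, panel)
  dmg <- damaging_flags(s)
  fc <- s$functional_class %||% rep("unknown", nrow(s))
  new_site <- !(s$in_dbsnp %||% rep(TRUE, nrow(s)))
  block <- function(present, other_present, aligned) {
    tibble(
      gene = s$gene,
      total = present,
      rare = is_rare(aligned$alt_count, aligned$chrom_count, threshold),
      specific = present & !other_present,
      new = present & new_site,
      missense = present & fc == "missense",
      nonsense = present & fc == "nonsense",
      synonymous = present & fc == "synonymous",
      damaging = present & dmg
    )
  }
  sum_block <- function(b, prefix) {
    b |>
      group_by(.data$gene) |>
      summarise(across(dplyr::everything(), sum), .groups = "drop") |>
      (\(d) {
        full <- tibble(gene = genes) |> left_join(d, by = "gene")
        full[is.na(full)] <- 0L
        full
      })() |>
      rename_with(\(nm) paste0(prefix, nm), -"gene")
  }
  pa <- is_present(ca$alt_count); po <- is_present(co$alt_count)
  out <- left_join(sum_block(block(pa, po, ca), "case_"),
                   sum_block(block(po, pa, co), "ctrl_"), by = "gene")
  total <- out |> summarise(across(-"gene", sum)) |> mutate(gene = "Total", .before = 1)
  new_tibble(bind_rows(out, total), class = "vs_gene_summary",
             region = region, threshold = threshold,
             case_population = cohort_population(case),
             ctrl_population = cohort_population(control))
}

#' Correlation of per-gene totals between two populations
#'
#' Pearson correlation of the per-gene total variant counts of the two
#' cohorts in a [gene_summary()] table (the `Total` row is excluded). With
#' fewer than 3 genes, or zero variance in either vector, the correlation is
#' undefined and `NA` is returned with a warning.
#'
#' @param summary A `vs_gene_summary`, or any tibble with `gene`,
#'   `case_total`, `ctrl_total`.
#' @return Single numeric correlation (possibly `NA`).
#' @examples
#' totals_correlation(tibble::tibble(
#'   gene = letters[1:10],
#'   case_total = c(5, 3, 4, 0, 2, 5, 1, 2, 2, 13),
#'   ctrl_total = c(4, 6, 1, 2, 4, 9, 2, 3, 2, 7)
#' )) # ~0.59
#' @export
totals_correlation <- function(summary) {
  d <- summary |> filter(.data$gene != "Total")
  if (nrow(d) < 3) {
    warn("fewer than 3 genes: correlation undefined")
    return(NA_real_)
  }
  if (stats::sd(d$case_total) == 0 || stats::sd(d$ctrl_total) == 0) {
    warn("zero variance in per-gene totals: correlation undefined")
    return(NA_real_)
  }
  cor(d$case_total, d$ctrl_total)
}

#' Render a gene summary
#'
#' `write_summary_tsv()` writes the table as TSV; `summary_markdown()`
#' returns a Markdown table mirroring the published column order.
#'
#' @param summary A `vs_gene_summary`.
#' @param path Output file.
#' @export
write_summary_tsv <- function(summary, path) {
  readr::write_tsv(as_tibble(summary), path)
  invisible(path)
}

#' @rdname write_summary_tsv
#' @export
summary_markdown <- function(summary) {
  d <- as_tibble(summary)
  hdr <- paste0("| ", paste(names(d), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(d)), collapse = "|"), "|")
  rows <- apply(d, 1, \(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(hdr, sep, rows)
}
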