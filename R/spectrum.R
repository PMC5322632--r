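#' Spectrum-of-variation statistics
#'
#' Three per-gene statistics summarise how the spectrum of detected variants
#' differs between a case cohort and a control cohort:
#' \describe{
#'   \item{rare}{number of sites detected in the cohort with within-cohort
#'     MAF at or below the rarity threshold (default 1%);}
#'   \item{specific}{number of sites detected in one cohort and absent
#'     (zero alternate alleles) from the other;}
#'   \item{damaging}{number of sites detected in the cohort whose missense
#'     annotation is concordantly damaging under both SIFT and PolyPhen-2.}
#' }
#' `spectrum_stats()` computes all three for both cohorts, per gene and for
#' the sum over genes (`scope == "ALL"`). The `stat_*` functions compute a
#' single statistic for one scope and return a one-row tibble
#' (`kind`, `scope`, `value`).
#'
#' @param case,control,cohort `vs_cohort` objects (see [cohort_counts()]).
#' @param sites Site annotation tibble with columns `chrom`, `pos`, `ref`,
#'   `alt`, `gene`, and for the damaging statistic `sift`, `polyphen`.
#' @param scope A gene name, or `"ALL"` for the sum over all genes in `sites`.
#' @param threshold Within-cohort MAF threshold defining "rare".
#' @param panel Optional panel tibble, used to pad sites absent from a cohort
#'   with the right chromosome total (X-linkage aware).
#' @return A tibble; see Details.
#' @examples
#' d <- sim_cohort_pair(sim_config(n_genes = 3), seed = 1)
#' spectrum_stats(d$case, d$control, d$sites, panel = d$panel)
#' @export
spectrum_stats <- function(case, control, sites, threshold = 0.01, panel = NULL) {
  ca <- cohort_at_sites(case, sites, panel)
  co <- cohort_at_sites(control, sites, panel)
  dmg <- damaging_flags(sites)
  per_site <- tibble(
    gene = ca$gene,
    rare_case = is_rare(ca$alt_count, ca$chrom_count, threshold),
    rare_control = is_rare(co$alt_count, co$chrom_count, threshold),
    specific_case = is_present(ca$alt_count) & co$alt_count == 0L,
    specific_control = is_present(co$alt_count) & ca$alt_count == 0L,
    damaging_case = is_present(ca$alt_count) & dmg,
    damaging_control = is_present(co$alt_count) & dmg
  )
  by_gene <- per_site |>
    group_by(.data$gene) |>
    summarise(across(dplyr::everything(), \(v) sum(v)), .groups = "drop")
  all_row <- by_gene |>
    summarise(across(-"gene", sum)) |>
    mutate(gene = "ALL", .before = 1)
  out <- bind_rows(by_gene, all_row) |>
    tidyr::pivot_longer(-"gene", names_to = c("kind", "cohort"), names_sep = "_",
                        values_to = "value") |>
    tidyr::pivot_wider(names_from = "cohort", values_from = "value") |>
    rename(scope = "gene")
  out
}

damaging_flags <- function(sites) {
  sift <- tolower(as.character(sites$sift %||% rep(NA, nrow(sites))))
  poly <- tolower(as.character(sites$polyphen %||% rep(NA, nrow(sites))))
  missing_ann <- is.na(sift) | is.na(poly) | sift == "missing" | poly == "missing"
  n_missing_missense <- sum(missing_ann &
                              (sites$functional_class %||% "") == "missense")
  if (n_missing_missense > 0) {
    inform(paste0(n_missing_missense,
                  " missense site(s) lack SIFT/PolyPhen-2 calls; excluded from the damaging statistic"))
  }
  !missing_ann & sift == "damaging" & poly == "damaging"
}

scope_sites <- function(sites, scope) {
  if (identical(scope, "ALL")) return(sites)
  if (!scope %in% sites$gene) {
    return(sites[0, , drop = FALSE])
  }
  sites[sites$gene == scope, , drop = FALSE]
}

#' @rdname spectrum_stats
#' @export
stat_rare_count <- function(cohort, sites, scope = "ALL", threshold = 0.01,
                            panel = NULL) {
  s <- scope_sites(sites, scope)
  x <- cohort_at_sites(cohort, s, panel)
  tibble(kind = "rare", scope = scope,
         value = sum(is_rare(x$alt_count, x$chrom_count, threshold)))
}

#' @rdname spectrum_stats
#' @export
stat_case_specific <- function(case, control, sites, scope = "ALL", panel = NULL) {
  s <- scope_sites(sites, scope)
  ca <- cohort_at_sites(case, s, panel)
  co <- cohort_at_sites(control, s, panel)
  tibble(kind = "specific", scope = scope,
         value = sum(is_present(ca$alt_count) & co$alt_count == 0L))
}

#' @rdname spectrum_stats
#' @export
stat_damaging_count <- function(cohort, sites, scope = "ALL", panel = NULL) {
  s <- scope_sites(sites, scope)
  x <- cohort_at_sites(cohort, s, panel)
  tibble(kind = "damaging", scope = scope,
         value = sum(is_present(x$alt_count) & damaging_flags(s)))
}
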