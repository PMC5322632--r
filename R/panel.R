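#' Gene panel definitions
#'
#' A gene panel is a tibble with one row per (gene, region) interval and
#' columns `gene`, `chrom`, `x_linked`, `region_class` (`"promoter"` or
#' `"coding"`), `start`, `end` (1-based inclusive), `strand` (`"+"`/`"-"`).
#' Intervals must not overlap within a gene; the coding length of a gene is
#' the summed length of its coding intervals.
#'
#' `tlr_panel()` returns the default ten-gene Toll-like receptor panel:
#' coding lengths 2358 (TLR1), 2352 (TLR2), 2712 (TLR3), 2517 (TLR4),
#' 2574 (TLR5), 2388 (TLR6), 3147 (TLR7), 3123 (TLR8), 3096 (TLR9),
#' 2433 (TLR10) bp, with TLR7 and TLR8 X-linked. Genomic coordinates are
#' schematic (single-exon geometry anchored near each gene's GRCh37 locus);
#' the analysis only uses gene membership, X-linkage and interval lengths.
#'
#' @return A panel tibble as described above.
#' @examples
#' tlr_panel()
#' @export
tlr_panel <- function() {
  def <- tibble(
    gene   = paste0("TLR", 1:10),
    chrom  = c("4", "4", "4", "9", "1", "4", "X", "X", "3", "4"),
    x_linked = c(rep(FALSE, 6), TRUE, TRUE, FALSE, FALSE),
    strand = c("-", "+", "-", "+", "-", "-", "+", "+", "-", "-"),
    tss    = c(38798089L, 154605441L, 186990309L, 120466452L, 223283622L,
               38823592L, 12867030L, 12924324L, 52255096L, 38772238L),
    coding_length = c(2358L, 2352L, 2712L, 2517L, 2574L,
                      2388L, 3147L, 3123L, 3096L, 2433L)
  )
  rows <- purrr::pmap(def, function(gene, chrom, x_linked, strand, tss,
                                    coding_length) {
    prom <- promoter_interval(tss, strand)
    if (strand == "+") {
      cod <- c(tss + 101L, tss + 100L + coding_length)
    } else {
      cod <- c(tss - 100L - coding_length, tss - 101L)
    }
    tibble(
      gene = gene, chrom = chrom, x_linked = x_linked,
      region_class = c("promoter", "coding"),
      start = c(prom[1], cod[1]), end = c(prom[2], cod[2]),
      strand = strand
    )
  })
  validate_panel(bind_rows(rows))
}

#' Strand-aware promoter interval around the start of exon 1
#'
#' The promoter region is defined as 500 bp upstream to 50 bp downstream of
#' the start of exon 1, in transcription direction; coordinates are 1-based
#' inclusive.
#'
#' @param exon1_start Genomic coordinate of the first base of exon 1.
#' @param strand `"+"` or `"-"`.
#' @return Integer vector `c(start, end)` in genomic coordinates.
#' @examples
#' promoter_interval(1000L, "+") # 500..1050
#' promoter_interval(1000L, "-") # 950..1500
#' @export
promoter_interval <- function(exon1_start, strand = c("+", "-")) {
  strand <- match.arg(strand)
  if (strand == "+") {
    c(exon1_start - 500L, exon1_start + 50L)
  } else {
    c(exon1_start - 50L, exon1_start + 500L)
  }
}

#' @rdname tlr_panel
#' @param panel A panel tibble to validate.
#' @export
validate_panel <- function(panel) {
  need <- c("gene", "chrom", "x_linked", "region_class", "start", "end", "strand")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop_input("panel is missing columns: ", paste(miss, collapse = ", "))
  if (any(panel$start > panel$end)) stop_input("panel has intervals with start > end")
  if (!all(panel$region_class %in% c("promoter", "coding"))) {
    stop_input("panel region_class must be 'promoter' or 'coding'")
  }
  overl <- panel |>
    group_by(.data$gene) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(bad = any(.data$start[-1] <= head(.data$end, -1)), .groups = "drop")
  if (any(overl$bad)) {
    stop_input("panel has overlapping intervals within gene(s): ",
               paste(overl$gene[overl$bad], collapse = ", "))
  }
  as_tibble(panel)
}

#' Per-gene coding lengths and X-linkage of a panel
#'
#' @param panel A panel tibble (see [tlr_panel()]).
#' @return Tibble with `gene`, `chrom`, `x_linked`, `coding_length_bp`.
#' @export
panel_genes <- function(panel) {
  panel |>
    group_by(.data$gene, .data$chrom, .data$x_linked) |>
    summarise(
      coding_length_bp = sum((.data$end - .data$start + 1L) *
                               (.data$region_class == "coding")),
      .groups = "drop"
    ) |>
    arrange(match(.data$gene, unique(panel$gene)))
}

#' Read / write a panel TSV
#'
#' Columns: gene, chrom, x_linked, region_class, start, end, strand.
#'
#' @param path File path.
#' @return `read_panel_tsv()` returns a validated panel tibble.
#' @export
read_panel_tsv <- function(path) {
  if (!file.exists(path)) stop_input("panel file not found: ", path)
  p <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         chrom = readr::col_character(),
                         x_linked = readr::col_logical(),
                         start = readr::col_integer(),
                         end = readr::col_integer()
                       ))
  validate_panel(p)
}

#' @rdname read_panel_tsv
#' @param panel Panel tibble to write.
#' @export
write_panel_tsv <- function(panel, path) {
  readr::write_tsv(validate_panel(panel), path)
  invisible(path)
}
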