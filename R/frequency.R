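#' Allele frequencies and rarity classification
#'
#' `alt_frequency()` is the alternate-allele frequency `alt_count /
#' chrom_count`, using the same reference allele for every population so
#' frequencies are comparable across cohorts. `maf()` folds it to the minor
#' allele: `min(f, 1 - f)`, in `[0, 0.5]`. `is_present()` asks whether a site
#' was detected at all; `is_rare()` classifies a detected site as rare when
#' its within-cohort MAF is at or below `threshold` (default 1%). A site with
#' no alternate alleles has MAF 0 but is *not* rare: rarity is a statement
#' about detected variants.
#'
#' The MAF-threshold comparison is done on integer counts
#' (`minor_count <= threshold * chrom_count`), so the `<=` boundary is exact:
#' 5 copies in 576 chromosomes (MAF 0.0087) is rare at 1%, 6 copies
#' (MAF 0.0104) is not.
#'
#' @param alt_count,chrom_count Integer allele / chromosome counts (vectorised).
#' @param threshold MAF threshold in (0, 0.5].
#' @return Numeric frequencies, or logical classifications.
#' @examples
#' alt_frequency(5, 576)  # 0.00868...
#' maf(571, 576)          # folds to the same 0.00868...
#' is_rare(5, 576)        # TRUE
#' is_rare(6, 576)        # FALSE
#' @export
alt_frequency <- function(alt_count, chrom_count) {
  if (any(chrom_count <= 0)) stop_input("chrom_count must be positive to define a frequency")
  if (any(alt_count < 0 | alt_count > chrom_count)) {
    stop_input("alt_count outside [0, chrom_count]")
  }
  alt_count / chrom_count
}

#' @rdname alt_frequency
#' @export
maf <- function(alt_count, chrom_count) {
  f <- alt_frequency(alt_count, chrom_count)
  pmin(f, 1 - f)
}

#' @rdname alt_frequency
#' @export
is_present <- function(alt_count) alt_count >= 1L

#' @rdname alt_frequency
#' @export
is_rare <- function(alt_count, chrom_count, threshold = 0.01) {
  check_threshold(threshold)
  minor <- pmin(alt_count, chrom_count - alt_count)
  # tiny relative slack keeps the inclusive boundary exact under binary
  # floating point (e.g. minor/chrom == threshold precisely)
  is_present(alt_count) & minor <= threshold * chrom_count * (1 + 1e-12)
}

check_threshold <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 0.5) {
    stop_input("threshold must be a single value in (0, 0.5]")
  }
  invisible(threshold)
}
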