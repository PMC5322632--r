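#' Two-proportion normal-approximation association test
#'
#' Compares the alternate-allele frequency of a site between two cohorts with
#' the classical two-sample z-test on proportions: with pooled frequency
#' `p = (a1 + a2) / (n1 + n2)`,
#' `z = (f1 - f2) / sqrt(p (1 - p) (1/n1 + 1/n2))` and a two-sided normal
#' P-value. No continuity correction is applied by default (set
#' `continuity = TRUE` for the Yates-corrected variant). A site monomorphic
#' in the pooled sample has no defined z; it is flagged degenerate with
#' `p_value = 1`.
#'
#' @param case_alt,case_n,ctrl_alt,ctrl_n Allele / chromosome counts
#'   (vectorised).
#' @param continuity Apply a continuity correction of `0.5 * (1/n1 + 1/n2)`
#'   to the frequency difference.
#' @return Tibble: `case_freq`, `ctrl_freq`, `freq_diff`, `z`, `p_value`,
#'   `degenerate`.
#' @examples
#' two_prop_test(100, 576, 60, 758)
#' @export
two_prop_test <- function(case_alt, case_n, ctrl_alt, ctrl_n,
                          continuity = FALSE) {
  f1 <- alt_frequency(case_alt, case_n)
  f2 <- alt_frequency(ctrl_alt, ctrl_n)
  pbar <- (case_alt + ctrl_alt) / (case_n + ctrl_n)
  se <- sqrt(pbar * (1 - pbar) * (1 / case_n + 1 / ctrl_n))
  diff <- f1 - f2
  adj <- if (continuity) pmin(abs(diff), 0.5 * (1 / case_n + 1 / ctrl_n)) else 0
  z <- ifelse(se > 0, (diff - sign(diff) * adj) / se, NA_real_)
  degenerate <- pbar <= 0 | pbar >= 1
  tibble(
    case_freq = f1, ctrl_freq = f2, freq_diff = diff,
    z = ifelse(degenerate, NA_real_, z),
    p_value = ifelse(degenerate, 1, 2 * pnorm(-abs(z))),
    degenerate = degenerate
  )
}

#' MAF eligibility for single-SNP testing
#'
#' A site is tested individually only when at least one of the two cohorts
#' shows a minor-allele frequency at or above `threshold` (default 5%,
#' inclusive).
#'
#' @inheritParams spectrum_stats
#' @param threshold MAF eligibility threshold.
#' @return Logical vector along the rows of `sites`.
#' @export
snp_eligible <- function(case, control, sites, threshold = 0.05, panel = NULL) {
  check_threshold(threshold)
  ca <- cohort_at_sites(case, sites, panel)
  co <- cohort_at_sites(control, sites, panel)
  m1 <- maf(ca$alt_count, ca$chrom_count)
  m2 <- maf(co$alt_count, co$chrom_count)
  pmax(m1, m2) >= threshold * (1 - 1e-12)
}

#' Single-SNP association scan over common variants
#'
#' Runs [two_prop_test()] at every site where at least one cohort has MAF at
#' or above `maf_threshold` ([snp_eligible()]).
#'
#' @inheritParams spectrum_stats
#' @param maf_threshold Eligibility threshold (default 0.05).
#' @param continuity Passed to [two_prop_test()].
#' @return A `vs_snp_tests` tibble: site key columns, gene, eligibility,
#'   frequencies, `z`, `p_value`.
#' @export
snp_assoc_test <- function(case, control, sites, maf_threshold = 0.05,
                           continuity = FALSE, panel = NULL) {
  elig <- snp_eligible(case, control, sites, maf_threshold, panel)
  ca <- cohort_at_sites(case, sites, panel)
  co <- cohort_at_sites(control, sites, panel)
  res <- two_prop_test(ca$alt_count, ca$chrom_count,
                       co$alt_count, co$chrom_count, continuity)
  out <- bind_rows(tibble(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    gene = sites$gene, eligible = elig
  )) |> dplyr::bind_cols(res) |> filter(.data$eligible)
  new_tibble(out, class = "vs_snp_tests", maf_threshold = maf_threshold)
}

#' Hardy-Weinberg equilibrium screen
#'
#' One-degree-of-freedom chi-square comparing observed genotype counts to the
#' `p^2 : 2pq : q^2` expectation (default), or the exact conditional test
#' enumerating heterozygote counts given the allele counts
#' (`method = "exact"`). Requires genotype-level data; for X-linked genes the
#' diploid genotype tallies are female-only by construction, so males never
#' enter the test. Monomorphic sites are returned with `tested = FALSE`.
#'
#' @param cohort A `vs_cohort` with `hom_ref`, `het`, `hom_alt` columns.
#' @param sites Site annotation tibble; tested sites are those with
#'   within-cohort MAF at or above `maf_threshold`.
#' @param maf_threshold Minimum MAF for testing (default 0.05).
#' @param method `"chisq"` (default) or `"exact"`.
#' @param panel Optional panel tibble.
#' @return A `vs_hwe` tibble: site key columns, genotype counts,
#'   `chi_square`, `p_value`, `tested`.
#' @export
hwe_test <- function(cohort, sites = NULL, maf_threshold = 0.05,
                     method = c("chisq", "exact"), panel = NULL) {
  method <- match.arg(method)
  x <- as_tibble(cohort)
  if (!all(c("hom_ref", "het", "hom_alt") %in% names(x))) {
    stop_input("Hardy-Weinberg screening needs genotype-level data (hom_ref/het/hom_alt)")
  }
  if (!is.null(sites)) {
    keep <- site_key(x$chrom, x$pos, x$ref, x$alt) %in%
      site_key(sites$chrom, sites$pos, sites$ref, sites$alt)
    x <- x[keep, , drop = FALSE]
  }
  res <- purrr::pmap(list(x$hom_ref, x$het, x$hom_alt),
                     function(rr, rh, aa) hwe_site(rr, rh, aa, method))
  out <- dplyr::bind_cols(
    x |> select("chrom", "pos", "ref", "alt", "hom_ref", "het", "hom_alt"),
    bind_rows(res)
  ) |> mutate(tested = .data$tested & .data$maf_diploid >= maf_threshold * (1 - 1e-12)) |>
    mutate(chi_square = ifelse(.data$tested, .data$chi_square, NA_real_),
           p_value = ifelse(.data$tested, .data$p_value, NA_real_)) |>
    select(-"maf_diploid")
  new_tibble(out, class = "vs_hwe", method = method,
             maf_threshold = maf_threshold)
}

hwe_site <- function(hom_ref, het, hom_alt, method) {
  n <- hom_ref + het + hom_alt
  if (n == 0) return(tibble(chi_square = NA_real_, p_value = NA_real_,
                            tested = FALSE, maf_diploid = 0))
  a <- 2 * hom_alt + het
  p <- a / (2 * n)
  mafd <- min(p, 1 - p)
  if (p == 0 || p == 1) {
    return(tibble(chi_square = NA_real_, p_value = NA_real_,
                  tested = FALSE, maf_diploid = mafd))
  }
  if (method == "chisq") {
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    chi <- sum((c(hom_ref, het, hom_alt) - e)^2 / e)
    tibble(chi_square = chi, p_value = pchisq(chi, df = 1, lower.tail = FALSE),
           tested = TRUE, maf_diploid = mafd)
  } else {
    tibble(chi_square = NA_real_, p_value = hwe_exact_p(hom_ref, het, hom_alt),
           tested = TRUE, maf_diploid = mafd)
  }
}

# exact conditional HWE test: enumerate all heterozygote counts compatible
# with the observed minor-allele count, probability mass per Levene/Haldane,
# two-sided by summing outcomes no more probable than the observed one
hwe_exact_p <- function(hom_ref, het, hom_alt) {
  n <- hom_ref + het + hom_alt
  minor <- min(2 * hom_alt + het, 2 * hom_ref + het)
  hets <- seq(minor %% 2, minor, by = 2)
  log_prob <- vapply(hets, function(h) {
    na <- (minor - h) / 2       # minor-allele homozygotes
    nb <- n - na - h            # major-allele homozygotes
    lgamma(n + 1) - lgamma(na + 1) - lgamma(h + 1) - lgamma(nb + 1) +
      h * log(2) + lgamma(minor + 1) + lgamma(2 * n - minor + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(log_prob - max(log_prob))
  prob <- prob / sum(prob)
  obs <- prob[match(het, hets)]
  min(1, sum(prob[prob <= obs * (1 + 1e-9)]))
}
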