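#' Randomize the alleles at one site between two cohorts
#'
#' Pools the `case_alt + ctrl_alt` alternate alleles carried by the
#' `case_n + ctrl_n` chromosomes at a site and deals `case_n` chromosomes
#' back to the case side without replacement, so the permuted case count is
#' hypergeometric and per-site totals are conserved. Vectorised over sites.
#'
#' @param case_alt,case_n,ctrl_alt,ctrl_n Integer counts per site.
#' @return Tibble with permuted `case_alt` and `ctrl_alt`.
#' @examples
#' withr::with_seed(1, permute_site(1, 4, 0, 4))
#' @export
permute_site <- function(case_alt, case_n, ctrl_alt, ctrl_n) {
  total_alt <- case_alt + ctrl_alt
  total_ref <- (case_n + ctrl_n) - total_alt
  if (any(total_ref < 0)) stop_input("alt alleles exceed pooled chromosomes")
  new_case <- rhyper(length(total_alt), total_alt, total_ref, case_n)
  tibble(case_alt = as.integer(new_case),
         ctrl_alt = as.integer(total_alt - new_case))
}

# permuted-case-count replicate matrix for one scope: n_sites x n_perm,
# chunked so no more than ~2e7 cells are held at once
perm_stat_replicates <- function(alt_case, n_case, alt_ctrl, n_ctrl,
                                 n_perm, stat_fun) {
  n_sites <- length(alt_case)
  if (n_sites == 0L) return(numeric(n_perm))
  total_alt <- alt_case + alt_ctrl
  total_ref <- (n_case + n_ctrl) - total_alt
  chunk <- max(1L, min(n_perm, as.integer(2e7 / n_sites)))
  out <- numeric(n_perm)
  done <- 0L
  while (done < n_perm) {
    k <- min(chunk, n_perm - done)
    d <- matrix(rhyper(n_sites * k, total_alt, total_ref, n_case), nrow = n_sites)
    out[(done + 1L):(done + k)] <- stat_fun(d)
    done <- done + k
  }
  out
}

stat_fun_for <- function(statistic, n_case, total_alt, threshold, dmg) {
  switch(statistic,
    rare = function(d) {
      cap <- threshold * n_case * (1 + 1e-12)
      colSums(d >= 1L & pmin(d, n_case - d) <= cap)
    },
    specific = function(d) colSums(d == total_alt & total_alt >= 1L),
    damaging = function(d) colSums(d[dmg, , drop = FALSE] >= 1L)
  )
}

observed_stat <- function(statistic, alt_case, n_case, alt_ctrl, threshold, dmg) {
  switch(statistic,
    rare = sum(is_rare(alt_case, n_case, threshold)),
    specific = sum(is_present(alt_case) & alt_ctrl == 0L),
    damaging = sum(is_present(alt_case) & dmg)
  )
}

#' One-sided per-site allele-randomization permutation test
#'
#' Tests whether the case cohort carries an excess of rare,
#' population-specific, or concordantly damaging variants relative to the
#' control cohort. Each replicate randomizes the alleles between the two
#' cohorts independently at every variable site (holding per-site allele
#' totals and per-cohort chromosome counts fixed), recomputes the spectrum
#' statistic on the permuted case side — rarity and specificity are
#' re-classified from the permuted counts — and the one-sided P-value is the
#' proportion of replicates whose permuted value exceeds the observed value.
#'
#' Results are reported per gene and for the sum over genes (`scope "ALL"`).
#' Each gene's sites are permuted under an RNG substream derived from the
#' master `seed` and the gene name, so per-gene results do not depend on
#' gene order, and the global statistic sums the same per-gene replicate
#' streams, so per-gene and global results are mutually consistent.
#'
#' Two tie-handling modes are available: `"strict"` counts only replicates
#' strictly above the observed value (`p = n_exceeding / n_perm`, matching
#' the published description of the test), and `"ge"` counts ties and applies
#' the add-one correction (`p = (n_ge + 1) / (n_perm + 1)`), which cannot be
#' anti-conservative at p = 0. Both proportions are returned; `p_value`
#' follows `mode`.
#'
#' @inheritParams spectrum_stats
#' @param statistic `"rare"`, `"specific"` or `"damaging"`.
#' @param n_perm Number of permutation replicates (default 100000).
#' @param seed Master RNG seed.
#' @param mode Tie handling, `"strict"` (default) or `"ge"`.
#' @param genes Optional subset of genes to test (default: all in `sites`).
#' @return A `vs_perm_test` tibble with one row per gene plus an `"ALL"` row:
#'   `statistic`, `scope`, `observed`, `n_perm`, `n_exceeding`, `p_value`,
#'   `p_strict`, `p_ge`, `degenerate`, `seed`.
#' @examples
#' d <- sim_cohort_pair(sim_config(n_genes = 2), seed = 7)
#' perm_test(d$case, d$control, d$sites, "specific", n_perm = 500, seed = 7)
#' @export
perm_test <- function(case, control, sites,
                      statistic = c("rare", "specific", "damaging"),
                      n_perm = 100000L, seed = 1L,
                      mode = c("strict", "ge"),
                      threshold = 0.01, panel = NULL, genes = NULL) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  check_threshold(threshold)
  if (n_perm < 1L) stop_input("n_perm must be >= 1")
  genes <- genes %||% unique(sites$gene)

  per_gene <- purrr::map(genes, function(g) {
    s <- scope_sites(sites, g)
    ca <- cohort_at_sites(case, s, panel)
    co <- cohort_at_sites(control, s, panel)
    dmg <- if (nrow(s)) damaging_flags(s) else logical(0)
    obs <- observed_stat(statistic, ca$alt_count, ca$chrom_count,
                         co$alt_count, threshold, dmg)
    total_alt <- ca$alt_count + co$alt_count
    # a site fixed in the pooled sample (all-ref or all-alt) cannot be
    # randomized; a scope with only such sites has no permutation null
    all_fixed <- nrow(s) > 0L &&
      all(total_alt == 0L | total_alt == ca$chrom_count + co$chrom_count)
    if (nrow(s) == 0L || all_fixed ||
        (statistic == "damaging" && !any(dmg))) {
      return(list(observed = obs, reps = rep(obs, n_perm), degenerate = TRUE))
    }
    sf <- stat_fun_for(statistic, ca$chrom_count, ca$alt_count + co$alt_count,
                       threshold, dmg)
    reps <- withr::with_seed(substream_seed(seed, g),
      perm_stat_replicates(ca$alt_count, ca$chrom_count,
                           co$alt_count, co$chrom_count, n_perm, sf))
    list(observed = obs, reps = reps, degenerate = FALSE)
  })
  names(per_gene) <- genes

  all_obs <- sum(purrr::map_dbl(per_gene, "observed"))
  all_reps <- Reduce(`+`, purrr::map(per_gene, "reps"))
  rows <- c(per_gene, list(ALL = list(
    observed = all_obs, reps = all_reps,
    degenerate = all(purrr::map_lgl(per_gene, "degenerate"))
  )))

  out <- purrr::imap(rows, function(r, scope) {
    n_gt <- sum(r$reps > r$observed)
    n_ge <- sum(r$reps >= r$observed)
    p_strict <- if (r$degenerate) 1 else n_gt / n_perm
    p_ge <- if (r$degenerate) 1 else (n_ge + 1) / (n_perm + 1)
    tibble(statistic = statistic, scope = scope, observed = r$observed,
           n_perm = as.integer(n_perm),
           n_exceeding = if (mode == "strict") n_gt else n_ge,
           p_value = if (mode == "strict") p_strict else p_ge,
           p_strict = p_strict, p_ge = p_ge,
           degenerate = r$degenerate, seed = as.integer(seed))
  }) |> bind_rows()

  new_tibble(out, class = "vs_perm_test", statistic = statistic,
             mode = mode, threshold = threshold, n_perm = as.integer(n_perm),
             seed = as.integer(seed))
}

#' Bonferroni adjustment with a caller-supplied test count
#'
#' `min(1, m * p)` per value; `m` defaults to the number of p-values, but can
#' be set to the full family size (e.g. 20 when ten genes are each tested
#' with two overlapping statistics, a deliberately conservative family).
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param m Family size.
#' @return Adjusted p-values.
#' @examples
#' bonferroni_adjust(0.00009, m = 20) # 0.0018
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) stop_input("p-values must lie in [0, 1]")
  if (m < 1) stop_input("m must be >= 1")
  pmin(1, m * p)
}
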