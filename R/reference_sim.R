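#' Simulate a case-sized cohort from an aggregate reference
#'
#' Draws, for every reference site, a simulated alternate-allele count for a
#' cohort of `n_chrom` chromosomes. The default `"binomial"` model samples
#' each chromosome independently at the reference frequency
#' `alt_count / chrom_count`; the `"hypergeometric"` model deals `n_chrom`
#' chromosomes out of the finite reference pool without replacement. The two
#' agree closely whenever the reference pool is much larger than the cohort.
#'
#' @param reference Tibble of aggregate per-site counts: `chrom`, `pos`,
#'   `ref`, `alt`, `alt_count`, `chrom_count` (no individual-level data).
#' @param n_chrom Number of chromosomes in the simulated cohort.
#' @param model `"binomial"` (default) or `"hypergeometric"`.
#' @return Tibble with the reference site keys and simulated `alt_count`,
#'   `chrom_count = n_chrom`. Sites with reference `chrom_count` 0 are
#'   skipped with a message.
#' @export
simulate_cohort_from_reference <- function(reference, n_chrom,
                                           model = c("binomial", "hypergeometric")) {
  model <- match.arg(model)
  if (any(n_chrom < 1)) stop_input("n_chrom must be >= 1")
  bad <- reference$chrom_count == 0
  if (any(bad)) {
    inform(paste0(sum(bad), " reference site(s) with chrom_count 0 skipped"))
    reference <- reference[!bad, , drop = FALSE]
  }
  sim_alt <- sim_alt_counts(reference$alt_count, reference$chrom_count,
                            n_chrom, model)
  tibble(chrom = reference$chrom, pos = reference$pos,
         ref = reference$ref, alt = reference$alt,
         alt_count = sim_alt,
         chrom_count = as.integer(rep_len(n_chrom, nrow(reference))))
}

sim_alt_counts <- function(ref_alt, ref_n, n_chrom, model) {
  if (model == "binomial") {
    as.integer(rbinom(length(ref_alt), rep_len(n_chrom, length(ref_alt)),
                      ref_alt / ref_n))
  } else {
    if (any(ref_n < n_chrom)) {
      stop_input("hypergeometric model needs reference chrom_count >= n_chrom at every site")
    }
    as.integer(rhyper(length(ref_alt), ref_alt, ref_n - ref_alt,
                      rep_len(n_chrom, length(ref_alt))))
  }
}

#' One-sided simulation test for rare-variant excess against a reference
#'
#' Asks whether the case cohort carries more rare variants (within-cohort MAF
#' at or below `threshold`) than expected for a cohort of its size drawn from
#' an aggregate reference population known only through per-site allele
#' counts (an ExAC/gnomAD-style extract). Each replicate simulates a
#' case-sized chromosome set from the reference frequencies
#' ([simulate_cohort_from_reference()]) and recomputes the rare-variant count
#' with rarity judged inside the simulated cohort (or, with
#' `rarity = "reference"`, at the fixed reference frequencies); the one-sided
#' P-value is the proportion of replicates exceeding the observed count.
#'
#' The site universe is the union of case and reference sites: a case-private
#' site has reference frequency 0 and can never appear in a simulated
#' cohort, which is exactly why its observed presence is evidence of excess.
#'
#' @inheritParams perm_test
#' @param reference Aggregate reference count tibble (see
#'   [simulate_cohort_from_reference()]).
#' @param n_sim Number of simulation replicates (default 100000).
#' @param model Sampling model for simulated cohorts.
#' @param rarity Judge rarity within each `"simulated"` cohort (default) or
#'   at the `"reference"` frequencies.
#' @return A `vs_sim_test` tibble with one row per gene plus `"ALL"`:
#'   `scope`, `observed`, `n_sim`, `n_exceeding`, `p_value`, `p_strict`,
#'   `p_ge`, `degenerate`, `seed`, `model`.
#' @examples
#' d <- sim_cohort_pair(sim_config(n_genes = 2), seed = 3)
#' ref <- sim_reference(d$manifest, n_individuals = 5000, seed = 4)
#' ref_sim_test(d$case, ref, d$sites, n_sim = 500, seed = 5)
#' @export
ref_sim_test <- function(case, reference, sites, n_sim = 100000L, seed = 1L,
                         mode = c("strict", "ge"),
                         model = c("binomial", "hypergeometric"),
                         rarity = c("simulated", "reference"),
                         threshold = 0.01, panel = NULL, genes = NULL) {
  mode <- match.arg(mode)
  model <- match.arg(model)
  rarity <- match.arg(rarity)
  check_threshold(threshold)
  if (n_sim < 1L) stop_input("n_sim must be >= 1")
  genes <- genes %||% unique(sites$gene)
  ref_key <- site_key(reference$chrom, reference$pos, reference$ref, reference$alt)

  per_gene <- purrr::map(genes, function(g) {
    s <- scope_sites(sites, g)
    if (nrow(s) == 0L) {
      return(list(observed = 0L, reps = numeric(n_sim), degenerate = TRUE))
    }
    ca <- cohort_at_sites(case, s, panel)
    idx <- match(ca$site, ref_key)
    ref_alt <- ifelse(is.na(idx), 0L, reference$alt_count[idx])
    ref_n <- ifelse(is.na(idx), 1L, reference$chrom_count[idx]) # freq 0 when absent
    keep <- ref_n > 0
    if (any(!keep)) inform(paste0(sum(!keep), " reference site(s) with chrom_count 0 skipped"))
    obs <- sum(is_rare(ca$alt_count, ca$chrom_count, threshold))
    n_chrom <- ca$chrom_count[keep]
    ra <- ref_alt[keep]; rn <- ref_n[keep]
    if (rarity == "reference") {
      rare_ref <- is_rare(ra, rn, threshold)
    }
    reps <- withr::with_seed(substream_seed(seed, g), {
      n_sites <- length(ra)
      chunk <- max(1L, min(n_sim, as.integer(2e7 / max(1L, n_sites))))
      out <- numeric(n_sim); done <- 0L
      while (done < n_sim) {
        k <- min(chunk, n_sim - done)
        d <- matrix(sim_alt_counts(rep(ra, k), rep(rn, k), rep(n_chrom, k), model),
                    nrow = n_sites)
        out[(done + 1L):(done + k)] <- if (rarity == "simulated") {
          cap <- threshold * n_chrom * (1 + 1e-12)
          colSums(d >= 1L & pmin(d, n_chrom - d) <= cap)
        } else {
          colSums(d >= 1L & rare_ref)
        }
        done <- done + k
      }
      out
    })
    list(observed = obs, reps = reps, degenerate = FALSE)
  })
  names(per_gene) <- genes

  rows <- c(per_gene, list(ALL = list(
    observed = sum(purrr::map_dbl(per_gene, "observed")),
    reps = Reduce(`+`, purrr::map(per_gene, "reps")),
    degenerate = all(purrr::map_lgl(per_gene, "degenerate"))
  )))
  out <- purrr::imap(rows, function(r, scope) {
    n_gt <- sum(r$reps > r$observed)
    n_ge <- sum(r$reps >= r$observed)
    p_strict <- if (r$degenerate) 1 else n_gt / n_sim
    p_ge <- if (r$degenerate) 1 else (n_ge + 1) / (n_sim + 1)
    tibble(scope = scope, observed = r$observed, n_sim = as.integer(n_sim),
           n_exceeding = if (mode == "strict") n_gt else n_ge,
           p_value = if (mode == "strict") p_strict else p_ge,
           p_strict = p_strict, p_ge = p_ge,
           degenerate = r$degenerate, seed = as.integer(seed), model = model)
  }) |> bind_rows()

  new_tibble(out, class = "vs_sim_test", mode = mode, model = model,
             rarity = rarity, threshold = threshold,
             n_sim = as.integer(n_sim), seed = as.integer(seed))
}
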