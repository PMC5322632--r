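ref_tbl <- function(sites, ac, an) {
  tibble::tibble(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
                 alt = sites$alt, alt_count = as.integer(ac),
                 chrom_count = as.integer(an))
}

test_that("simulated cohorts follow the reference frequencies", {
  s <- tiny_sites(3, 0)
  ref <- ref_tbl(s, c(0, 66616, 66), 66616)
  sim <- withr::with_seed(2, simulate_cohort_from_reference(ref, n_chrom = 576))
  expect_identical(sim$alt_count[1], 0L)        # frequency 0 never appears
  expect_identical(sim$alt_count[2], 576L)      # frequency 1 always fixed
  expect_true(all(sim$chrom_count == 576L))

  # binomial mean: freq 0.001 on 576 chromosomes -> 0.576 expected copies;
  # 1e5 iid sites with the same reference frequency act as replicates
  many <- tibble::tibble(chrom = "1", pos = seq_len(1e5), ref = "A", alt = "G",
                         alt_count = 1L, chrom_count = 1000L)
  got <- withr::with_seed(8, simulate_cohort_from_reference(many, 576)$alt_count)
  se <- stats::sd(got) / sqrt(length(got))
  expect_lt(abs(mean(got) - 0.576), 3 * se)

  zero_an <- ref_tbl(s[1:2, ], c(0, 1), c(0, 100))
  expect_message(out <- simulate_cohort_from_reference(zero_an, 10), "skipped")
  expect_identical(nrow(out), 1L)
})

test_that("rare-excess test: case-private rare sites can never be matched by a monomorphic reference", {
  s <- tiny_sites(3, 0)
  case <- make_cohort(s, c(1, 1, 1), 576, n_female = 288, n_male = 0)
  ref <- ref_tbl(s, c(0, 0, 0), 66616)
  res <- ref_sim_test(case, ref, s, n_sim = 500, seed = 5)
  all_row <- res[res$scope == "ALL", ]
  expect_identical(all_row$observed, 3)
  expect_identical(all_row$p_strict, 0)

  # a case with nothing detected cannot show excess
  none <- make_cohort(s, c(0, 0, 0), 576, n_female = 288, n_male = 0)
  common_ref <- ref_tbl(s, c(600, 600, 600), 66616) # ~1% in the reference
  res0 <- ref_sim_test(none, common_ref, s, n_sim = 500, seed = 5)
  expect_identical(res0$observed[res0$scope == "ALL"], 0)
  expect_gt(res0$p_value[res0$scope == "ALL"], 0.5)
})

test_that("binomial and hypergeometric sampling agree for a deep reference", {
  d <- sim_cohort_pair(sim_config(n_genes = 2), seed = 41)
  ref <- sim_reference(d$manifest, n_individuals = 33000, seed = 42)
  n_sim <- 4000
  pb <- ref_sim_test(d$case, ref, d$sites, n_sim = n_sim, seed = 6,
                     model = "binomial")
  ph <- ref_sim_test(d$case, ref, d$sites, n_sim = n_sim, seed = 6,
                     model = "hypergeometric")
  for (sc in pb$scope) {
    p1 <- pb$p_ge[pb$scope == sc]; p2 <- ph$p_ge[ph$scope == sc]
    se <- sqrt(p1 * (1 - p1) / n_sim + p2 * (1 - p2) / n_sim)
    expect_lt(abs(p1 - p2), 3 * se + 2 / n_sim)
  }
})

test_that("adding case-private rare sites never weakens the evidence", {
  base_sites <- tiny_sites(3, 0)
  ref <- ref_tbl(base_sites, c(50, 30, 10), 66616)
  p_prev <- Inf
  for (extra in 0:3) {
    s <- tiny_sites(3 + extra, 0)
    alt <- c(2, 1, 1, rep(1, extra))
    case <- make_cohort(s, alt, 576, n_female = 288, n_male = 0)
    res <- ref_sim_test(case, ref, s, n_sim = 3000, seed = 13)
    p <- res$p_ge[res$scope == "ALL"]
    expect_lte(p, p_prev + 1e-12)
    p_prev <- p
  }
})

test_that("reference simulation is reproducible and X-aware", {
  d <- sim_cohort_pair(sim_config(n_genes = 8), seed = 43)
  ref <- sim_reference(d$manifest, n_individuals = 5000, seed = 44)
  r1 <- ref_sim_test(d$case, ref, d$sites, n_sim = 1000, seed = 9)
  r2 <- ref_sim_test(d$case, ref, d$sites, n_sim = 1000, seed = 9)
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(sim_reference(d$manifest, 5000, seed = 44),
                   sim_reference(d$manifest, 5000, seed = 44))
})
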