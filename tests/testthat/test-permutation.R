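test_that("per-site randomization conserves totals and has the hypergeometric law", {
  # one alt among 8 pooled chromosomes, 4 dealt to the case side: P(case) = 1/2
  draws <- withr::with_seed(9, purrr::map_int(1:4000, \(i)
    permute_site(1L, 4L, 0L, 4L)$case_alt))
  expect_true(all(draws %in% c(0L, 1L)))
  expect_lt(abs(mean(draws) - 0.5), 3 * sqrt(0.25 / 4000))

  expect_identical(permute_site(0L, 5L, 0L, 7L)$case_alt, 0L)
  fixed <- permute_site(4L, 4L, 4L, 4L)
  expect_identical(fixed$case_alt, 4L)
  expect_identical(fixed$ctrl_alt, 4L)

  multi <- withr::with_seed(1, permute_site(c(3L, 10L), c(10L, 20L),
                                            c(5L, 0L), c(12L, 30L)))
  expect_identical(multi$case_alt + multi$ctrl_alt, c(8L, 10L))
})

test_that("two case-private singletons on 2+2 chromosomes give the enumerated p", {
  s <- tiny_sites(2, 0)
  case <- make_cohort(s, c(1, 1), 2, n_female = 1, n_male = 0)
  ctrl <- make_cohort(s, c(0, 0), 2, "CTRL", n_female = 1, n_male = 0)
  res <- perm_test(case, ctrl, s, "specific", n_perm = 4000, seed = 3)
  all_row <- res[res$scope == "ALL", ]
  expect_identical(all_row$observed, 2)
  # observed is the maximum attainable: strictly-greater replicates impossible
  expect_identical(all_row$p_strict, 0)
  # P(both singletons land in the case half) = 1/4
  expect_lt(abs(all_row$p_ge - 0.25), 3 * sqrt(0.25 * 0.75 / 4000) + 1 / 4000)
})

test_that("Monte-Carlo p-values match exhaustive enumeration on tiny panels", {
  cases <- list(
    list(ca = c(1L, 2L), cn = c(4L, 4L), oa = c(1L, 0L), on = c(6L, 6L),
         stat = "specific"),
    list(ca = c(2L, 1L, 1L), cn = c(6L, 6L, 6L), oa = c(0L, 1L, 3L),
         on = c(6L, 6L, 6L), stat = "rare"),
    list(ca = c(1L, 0L), cn = c(5L, 5L), oa = c(1L, 2L), on = c(7L, 7L),
         stat = "damaging")
  )
  n_perm <- 20000
  for (cc in cases) {
    s <- tiny_sites(length(cc$ca), 0)
    s$sift <- "damaging"; s$polyphen <- "damaging"
    case <- make_cohort(s, cc$ca, cc$cn, n_female = cc$cn[1] / 2, n_male = 0)
    ctrl <- make_cohort(s, cc$oa, cc$on, "CTRL", n_female = cc$on[1] / 2,
                        n_male = 0)
    # rarity at these cohort sizes reduces to presence of the minor allele;
    # the enumeration oracle applies the same MAF rule independently
    res <- perm_test(case, ctrl, s, cc$stat, n_perm = n_perm, seed = 17,
                     threshold = 0.25)
    oracle <- enum_perm_null(cc$ca, cc$cn, cc$oa, cc$on, cc$stat,
                             threshold = 0.25)
    all_row <- res[res$scope == "ALL", ]
    expect_identical(all_row$observed, as.numeric(oracle$observed))
    se <- sqrt(oracle$p_gt * (1 - oracle$p_gt) / n_perm)
    expect_lt(abs(all_row$p_strict - oracle$p_gt), 3 * se + 1e-9)
    se_ge <- sqrt(oracle$p_ge * (1 - oracle$p_ge) / n_perm)
    expect_lt(abs(all_row$p_ge - oracle$p_ge), 3 * se_ge + 2 / n_perm)
  }
})

test_that("per-gene results are independent of gene order and share the ALL stream", {
  d <- sim_cohort_pair(sim_config(n_genes = 4), seed = 31)
  r1 <- perm_test(d$case, d$control, d$sites, "rare", n_perm = 2000, seed = 11)
  r2 <- perm_test(d$case, d$control, d$sites, "rare", n_perm = 2000, seed = 11,
                  genes = rev(unique(d$sites$gene)))
  m1 <- r1[order(r1$scope), c("scope", "observed", "p_strict", "p_ge")]
  m2 <- r2[order(r2$scope), c("scope", "observed", "p_strict", "p_ge")]
  expect_equal(as.data.frame(m1), as.data.frame(m2))
  # ALL observed is the sum of per-gene observed
  expect_equal(r1$observed[r1$scope == "ALL"],
               sum(r1$observed[r1$scope != "ALL"]))
  # bit-reproducible under the same seed
  r3 <- perm_test(d$case, d$control, d$sites, "rare", n_perm = 2000, seed = 11)
  expect_identical(r1$p_value, r3$p_value)
})

test_that("degenerate scopes are flagged with p = 1", {
  s <- tiny_sites(2, 0)
  case <- make_cohort(s, c(10, 10), 10, n_female = 5, n_male = 0)
  ctrl <- make_cohort(s, c(8, 8), 8, "CTRL", n_female = 4, n_male = 0)
  res <- perm_test(case, ctrl, s, "rare", n_perm = 100, seed = 1)
  expect_true(all(res$degenerate))
  expect_true(all(res$p_value == 1))

  empty <- perm_test(case, ctrl, s[0, ], "rare", n_perm = 100, seed = 1,
                     genes = "ghost")
  expect_true(all(empty$degenerate))
  expect_true(all(empty$p_value == 1))
  expect_identical(empty$observed, c(0, 0))
})

test_that("Bonferroni adjustment uses the caller-supplied family size", {
  expect_equal(bonferroni_adjust(0.00009, m = 20), 0.0018)
  expect_equal(bonferroni_adjust(0.03, m = 20), 0.6)
  expect_equal(bonferroni_adjust(1.0, m = 50), 1.0)
  expect_equal(bonferroni_adjust(c(0.01, 0.2)), c(0.02, 0.4))
  expect_error(bonferroni_adjust(1.5), "\\[0, 1\\]")
})
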