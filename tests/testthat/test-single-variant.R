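test_that("two-proportion z-test: null, symmetry and degenerate behaviour", {
  eq <- two_prop_test(50, 500, 75, 750)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)

  a <- two_prop_test(100, 576, 60, 758)
  b <- two_prop_test(60, 758, 100, 576)
  expect_equal(a$z, -b$z)
  expect_equal(a$p_value, b$p_value)
  expect_identical(sign(a$z), sign(a$freq_diff))

  mono <- two_prop_test(0, 100, 0, 200)
  expect_true(mono$degenerate)
  expect_equal(mono$p_value, 1)
  fixed <- two_prop_test(100, 100, 200, 200)
  expect_true(fixed$degenerate)
})

test_that("normal-approximation p agrees with an exact binomial Monte-Carlo oracle", {
  res <- two_prop_test(100, 576, 100, 758)
  p_mc <- two_prop_mc_oracle(100, 576, 100, 758, n_draws = 1e6)
  # normal approximation vs exact resampling: agree to ~1 percentage point
  expect_lt(abs(res$p_value - p_mc), 0.01)
  res2 <- two_prop_test(150, 576, 120, 758)
  p_mc2 <- two_prop_mc_oracle(150, 576, 120, 758, n_draws = 1e6)
  expect_lt(abs(res2$p_value - p_mc2), 0.01)
})

test_that("MAF eligibility takes the max over cohorts, inclusive at 5%", {
  s <- tiny_sites(3, 0)
  # site MAFs: case 0.02/0.01/0.05, control 0.06/0.01/0.04
  case <- make_cohort(s, c(4, 2, 10), 200, n_female = 100, n_male = 0)
  ctrl <- make_cohort(s, c(12, 2, 8), 200, "CTRL", n_female = 100, n_male = 0)
  expect_identical(snp_eligible(case, ctrl, s), c(TRUE, FALSE, TRUE))
  scan <- snp_assoc_test(case, ctrl, s)
  expect_identical(nrow(scan), 2L)
  expect_true(all(scan$p_value > 0 & scan$p_value <= 1))
})

test_that("HWE chi-square matches closed forms and the first-principles oracle", {
  r <- hwe_test(make_cohort(tiny_sites(1, 0), 200, 400,
                            hom_ref = 100L, het = 0L, hom_alt = 100L))
  expect_equal(r$chi_square, 200) # maximal disequilibrium: chi^2 = n
  expect_lt(r$p_value, 1e-10)

  at_hwe <- hwe_test(make_cohort(tiny_sites(1, 0), 100, 200,
                                 hom_ref = 25L, het = 50L, hom_alt = 25L))
  expect_equal(at_hwe$chi_square, 0)
  expect_equal(at_hwe$p_value, 1)

  r3 <- hwe_test(make_cohort(tiny_sites(1, 0), 96, 576,
                             hom_ref = 200L, het = 80L, hom_alt = 8L))
  expect_equal(r3$chi_square, hwe_chi_oracle(200, 80, 8), tolerance = 1e-12)
  expect_equal(r3$p_value,
               pchisq(hwe_chi_oracle(200, 80, 8), 1, lower.tail = FALSE))
})

test_that("HWE screen skips monomorphic and low-MAF sites; exact test enumerates", {
  s2 <- tiny_sites(2, 0)
  co <- make_cohort(s2, c(0, 2), 400,
                    hom_ref = c(200L, 198L), het = c(0L, 2L), hom_alt = c(0L, 0L))
  r <- hwe_test(co, maf_threshold = 0.05)
  expect_identical(r$tested, c(FALSE, FALSE)) # monomorphic; MAF 0.5% < 5%
  r_low <- hwe_test(co, maf_threshold = 0.004)
  expect_identical(r_low$tested, c(FALSE, TRUE))

  # exact conditional test, n = 2 with both alleles at frequency 1/2:
  # het counts 0 and 2 have probabilities 1/3 and 2/3, so observing
  # zero heterozygotes gives p = 1/3
  ex <- hwe_test(make_cohort(tiny_sites(1, 0), 2, 4,
                             hom_ref = 1L, het = 0L, hom_alt = 1L),
                 maf_threshold = 0.05, method = "exact")
  expect_equal(ex$p_value, 1 / 3, tolerance = 1e-12)
})

test_that("X-linked HWE uses female genotypes only by construction", {
  cfg <- sim_config(n_genes = 8, genotype_level = TRUE)
  d <- sim_cohort_pair(cfg, seed = 77)
  xs <- d$sites$x_linked
  x <- tibble::as_tibble(d$case)[xs, ]
  expect_true(all(x$hom_ref + x$het + x$hom_alt == 140))
  expect_true(all(x$hemi_ref + x$hemi_alt == 148))
  r <- hwe_test(d$case, d$sites)
  expect_identical(nrow(r), nrow(d$sites))
})
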