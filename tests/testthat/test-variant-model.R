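test_that("chromosome counts respect ploidy and X-linkage", {
  expect_identical(chromosome_count(140, 148, FALSE), 576L)
  expect_identical(chromosome_count(140, 148, TRUE), 428L)
  expect_identical(chromosome_count(0, 0, FALSE), 0L)
  expect_identical(chromosome_count(0, 0, TRUE), 0L)
  expect_error(chromosome_count(-1, 0, FALSE), "negative")
})

test_that("cohort constructor enforces count and genotype invariants", {
  s <- tiny_sites()
  expect_s3_class(make_cohort(s, c(5, 0, 2, 1, 0), 10), "vs_cohort")
  expect_error(make_cohort(s, c(11, 0, 0, 0, 0), 10), "outside")
  expect_error(make_cohort(s[c(1, 1, 2, 3, 4), ], rep(1, 5), 10), "duplicate")
  # genotype tallies must reproduce the allele counts: 2*1 + 3 = 5 != 4
  expect_error(
    make_cohort(s[1, ], 4, 10, hom_ref = 1L, het = 3L, hom_alt = 1L),
    "genotype"
  )
  expect_s3_class(
    make_cohort(s[1, ], 5, 10, hom_ref = 1L, het = 3L, hom_alt = 1L),
    "vs_cohort"
  )
})

test_that("validate_cohort reports problems instead of raising", {
  s <- tiny_sites()
  clean <- make_cohort(s, c(1, 2, 0, 1, 1), c(20, 20, 20, 15, 15))
  expect_identical(nrow(validate_cohort(clean, tiny_panel())), 0L)

  off_panel <- make_cohort(
    tibble::tibble(chrom = "1", pos = 5000L, ref = "A", alt = "G",
                   gene = "geneA"), 1, 20)
  rep <- validate_cohort(off_panel, tiny_panel())
  expect_true(any(grepl("outside all panel intervals", rep$issue)))

  # X-linked site claiming more chromosomes than 2*nf + nm
  x_over <- make_cohort(s[4, ], 1, 30, n_female = 5, n_male = 5)
  rep <- validate_cohort(x_over, tiny_panel())
  expect_true(any(grepl("exceeds cohort chromosome total", rep$issue)))
})

test_that("variant TSV round-trips sites, counts and sex metadata", {
  d <- sim_cohort_pair(sim_config(n_genes = 3, genotype_level = TRUE), seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_tsv(d$sites, list(CASE = d$case, CTRL = d$control), path)
  back <- read_variant_tsv(path)
  expect_identical(back$sites$pos, d$sites$pos)
  expect_identical(back$cohorts$CASE$alt_count, d$case$alt_count)
  expect_identical(back$cohorts$CTRL$chrom_count, d$control$chrom_count)
  expect_identical(back$cohorts$CASE$het, d$case$het)
  expect_identical(cohort_sexes(back$cohorts$CASE), cohort_sexes(d$case))
  expect_identical(cohort_population(back$cohorts$CTRL), "CTRL")
})

test_that("variant TSV reader drops indels and rejects bad counts", {
  hdr <- "chrom\tpos\tref\talt\tgene\tAR_alt_count\tAR_chrom_count"
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hdr,
               "1\t100\tA\tG\tgeneA\t5\t576",
               "1\t101\tA\tAT\tgeneA\t1\t576",
               "1\t102\tCT\tC\tgeneA\t1\t576"), path)
  expect_message(tab <- read_variant_tsv(path), "2 indel")
  expect_identical(nrow(tab$sites), 1L)
  expect_identical(tab$cohorts$AR$alt_count, 5L)

  writeLines(c(hdr, "1\t100\tA\tG\tgeneA\t600\t576"), path)
  expect_error(read_variant_tsv(path), "outside")
  writeLines(c(hdr, "1\t100\tA\tG\tgeneA\t5\t576",
               "1\t100\tA\tG\tgeneA\t4\t576"), path)
  expect_error(read_variant_tsv(path), "duplicate")
})

vcf_fixture <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AC_AR,Number=A,Type=Integer,Description=\"AR alt allele count\">",
    "##INFO=<ID=AN_AR,Number=1,Type=Integer,Description=\"AR chromosome count\">",
    "##INFO=<ID=AC_EUR,Number=A,Type=Integer,Description=\"EUR alt allele count\">",
    "##INFO=<ID=AN_EUR,Number=1,Type=Integer,Description=\"EUR chromosome count\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "1\t1001\t.\tA\tG,T\t.\tPASS\tAC_AR=5,2;AN_AR=576;AC_EUR=3,0;AN_EUR=758",
    "1\t1050\t.\tA\tAT\t.\tPASS\tAC_AR=4;AN_AR=576;AC_EUR=1;AN_EUR=758",
    "X\t1100\t.\tC\tG\t.\tPASS\tAC_AR=1;AN_AR=428;AC_EUR=0;AN_EUR=569"
  ), path)
  path
}

test_that("VCF input splits multiallelics, conserves alt copies, drops indels", {
  path <- vcf_fixture(withr::local_tempfile(fileext = ".vcf"))
  expect_message(
    tab <- read_variant_vcf(path, populations = list(AR = c(140, 148),
                                                     EUR = c(190, 189))),
    "1 indel")
  expect_identical(nrow(tab$sites), 3L)
  split_recs <- tab$sites$pos == 1001L
  expect_identical(sum(split_recs), 2L)
  expect_setequal(tab$sites$alt[split_recs], c("G", "T"))
  # multiallelic split conserves total alt copies at the site
  expect_identical(sum(tab$cohorts$AR$alt_count[split_recs]), 7L)
  expect_identical(sum(tab$cohorts$EUR$alt_count[split_recs]), 3L)
  expect_identical(tab$cohorts$AR$chrom_count[tab$sites$chrom == "X"], 428L)
})

test_that("VCF genotype mode counts alleles and missing data per population", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3\ts4",
    "1\t1001\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1\t0/0\t./.",
    "1\t1002\t.\tT\tC\t.\tPASS\t.\tGT\t0/0\t0/1\t0/1\t0/0"
  ), path)
  map <- data.frame(sample = c("s1", "s2", "s3", "s4"),
                    population = c("CASE", "CASE", "CTRL", "CTRL"))
  tab <- read_variant_vcf(path, sample_map = map)
  expect_identical(tab$cohorts$CASE$alt_count, c(3L, 1L))
  expect_identical(tab$cohorts$CASE$chrom_count, c(4L, 4L))
  # missing genotype ./. reduces the control chromosome count at site 1
  expect_identical(tab$cohorts$CTRL$chrom_count, c(2L, 4L))
  expect_identical(tab$cohorts$CTRL$alt_count, c(0L, 1L))
})

test_that("panel validation catches overlap and the promoter helper is strand-aware", {
  expect_identical(promoter_interval(1000L, "+"), c(500L, 1050L))
  expect_identical(promoter_interval(1000L, "-"), c(950L, 1500L))
  bad <- tiny_panel()
  bad$end[1] <- 1500L # promoter now overlaps coding
  expect_error(validate_panel(bad), "overlapping")
  expect_identical(panel_genes(tlr_panel())$coding_length_bp,
                   c(2358L, 2352L, 2712L, 2517L, 2574L, 2388L, 3147L, 3123L,
                     3096L, 2433L))
})
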