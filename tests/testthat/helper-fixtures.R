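# small deterministic fixtures built in code

tiny_panel <- function() {
  validate_panel(tibble::tribble(
    ~gene,   ~chrom, ~x_linked, ~region_class, ~start, ~end,  ~strand,
    "geneA", "1",    FALSE,     "promoter",    401L,   951L,  "+",
    "geneA", "1",    FALSE,     "coding",      1001L,  2000L, "+",
    "geneB", "X",    TRUE,      "promoter",    401L,   951L,  "+",
    "geneB", "X",    TRUE,      "coding",      1001L,  2000L, "+"
  ))
}

tiny_sites <- function(n_a = 3, n_b = 2) {
  tibble::tibble(
    chrom = c(rep("1", n_a), rep("X", n_b)),
    pos = c(seq(1001L, length.out = n_a), seq(1001L, length.out = n_b)),
    ref = "A", alt = "G",
    gene = c(rep("geneA", n_a), rep("geneB", n_b)),
    x_linked = c(rep(FALSE, n_a), rep(TRUE, n_b)),
    region_class = "coding",
    functional_class = "missense",
    sift = "tolerated", polyphen = "benign",
    in_dbsnp = TRUE
  )
}

make_cohort <- function(sites, alt_counts, chrom_counts, population = "POP",
                        n_female = 5, n_male = 5, ...) {
  cohort_counts(
    tibble::tibble(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
                   alt = sites$alt, alt_count = as.integer(alt_counts),
                   chrom_count = as.integer(chrom_counts), ...),
    population, n_female, n_male
  )
}
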