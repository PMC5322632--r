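#' Diploid chromosome count of a cohort for a locus
#'
#' Autosomal loci contribute two chromosomes per individual; X-linked loci
#' contribute two per female and one per (hemizygous) male.
#'
#' @param n_female,n_male Non-negative individual counts.
#' @param x_linked Logical (vectorised).
#' @return Integer chromosome count.
#' @examples
#' chromosome_count(140, 148, x_linked = FALSE) # 576
#' chromosome_count(140, 148, x_linked = TRUE)  # 428
#' @export
chromosome_count <- function(n_female, n_male, x_linked) {
  if (any(n_female < 0) || any(n_male < 0)) stop_input("negative individual counts")
  as.integer(ifelse(x_linked, 2L * n_female + n_male, 2L * (n_female + n_male)))
}

#' Construct a per-site allele-count cohort
#'
#' A cohort is a tibble with one row per variant site: `chrom`, `pos`, `ref`,
#' `alt`, `alt_count`, `chrom_count`, and optionally genotype tallies
#' `hom_ref`, `het`, `hom_alt` (diploid individuals; females only for
#' X-linked loci) and `hemi_ref`, `hemi_alt` (hemizygous males). Cohort-level
#' metadata (population label and sex split) is carried in attributes.
#' Sites absent from the table are taken to have `alt_count` 0.
#'
#' @param data Tibble/data frame of per-site records.
#' @param population Population label.
#' @param n_female,n_male Individuals of each sex (`n_individuals` is their sum).
#' @return A `vs_cohort` tibble.
#' @export
cohort_counts <- function(data, population, n_female, n_male) {
  x <- as_tibble(data)
  need <- c("chrom", "pos", "ref", "alt", "alt_count", "chrom_count")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop_input("cohort is missing columns: ", paste(miss, collapse = ", "))
  x$chrom <- as.character(x$chrom)
  key <- site_key(x$chrom, x$pos, x$ref, x$alt)
  if (anyDuplicated(key)) {
    stop_input("duplicate site key(s): ",
               paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  if (any(x$alt_count < 0) || any(x$alt_count > x$chrom_count)) {
    bad <- key[x$alt_count < 0 | x$alt_count > x$chrom_count]
    stop_input("alt_count outside [0, chrom_count] at: ", paste(bad, collapse = ", "))
  }
  if (any(nchar(x$ref) != 1L | nchar(x$alt) != 1L)) {
    stop_input("cohort contains non-SNV alleles; indels are not supported")
  }
  if (any(x$ref == x$alt)) stop_input("ref and alt alleles identical at some site")
  gt <- all(c("hom_ref", "het", "hom_alt") %in% names(x))
  if (gt) {
    hemi_alt <- if ("hemi_alt" %in% names(x)) x$hemi_alt else 0L
    hemi_ref <- if ("hemi_ref" %in% names(x)) x$hemi_ref else 0L
    implied_alt <- 2L * x$hom_alt + x$het + hemi_alt
    implied_n <- 2L * (x$hom_ref + x$het + x$hom_alt) + hemi_ref + hemi_alt
    if (any(implied_alt != x$alt_count) || any(implied_n != x$chrom_count)) {
      stop_input("genotype tallies inconsistent with allele counts at: ",
                 paste(key[implied_alt != x$alt_count | implied_n != x$chrom_count],
                       collapse = ", "))
    }
  }
  new_tibble(x, class = "vs_cohort",
             population = as.character(population),
             n_female = as.integer(n_female), n_male = as.integer(n_male))
}

#' @rdname cohort_counts
#' @param x A `vs_cohort`.
#' @export
cohort_population <- function(x) attr(x, "population") %||% "unknown"

#' @rdname cohort_counts
#' @export
cohort_sexes <- function(x) {
  c(n_female = attr(x, "n_female") %||% NA_integer_,
    n_male = attr(x, "n_male") %||% NA_integer_)
}

#' Validate a cohort against a gene panel
#'
#' Report-based validation: returns a tibble of issues (empty when clean)
#' rather than raising. Checks per-site count bounds, genotype/allele-count
#' consistency, heterozygous hemizygote calls, chromosome totals exceeding
#' what the sex split allows, and sites falling outside every panel interval.
#'
#' @param cohort A `vs_cohort`.
#' @param panel A panel tibble (see [tlr_panel()]); optional.
#' @return Tibble with columns `site`, `issue`.
#' @export
validate_cohort <- function(cohort, panel = NULL) {
  x <- as_tibble(cohort)
  key <- site_key(x$chrom, x$pos, x$ref, x$alt)
  issues <- list()
  flag <- function(i, what) tibble(site = key[i], issue = what)

  bad <- which(x$alt_count < 0 | x$alt_count > x$chrom_count)
  if (length(bad)) issues <- c(issues, list(flag(bad, "alt_count outside [0, chrom_count]")))

  if (all(c("hom_ref", "het", "hom_alt") %in% names(x))) {
    hemi_alt <- if ("hemi_alt" %in% names(x)) x$hemi_alt else rep(0L, nrow(x))
    hemi_ref <- if ("hemi_ref" %in% names(x)) x$hemi_ref else rep(0L, nrow(x))
    bad <- which(2L * x$hom_alt + x$het + hemi_alt != x$alt_count)
    if (length(bad)) issues <- c(issues, list(flag(bad, "genotype tallies disagree with alt_count")))
    bad <- which(2L * (x$hom_ref + x$het + x$hom_alt) + hemi_ref + hemi_alt != x$chrom_count)
    if (length(bad)) issues <- c(issues, list(flag(bad, "genotype tallies disagree with chrom_count")))
  }

  sexes <- cohort_sexes(cohort)
  if (!is.null(panel) && !anyNA(sexes)) {
    gmap <- panel_genes(panel)
    in_gene <- purrr::map_chr(seq_len(nrow(x)), function(i) {
      hit <- panel$chrom == x$chrom[i] & panel$start <= x$pos[i] & panel$end >= x$pos[i]
      if (any(hit)) panel$gene[which(hit)[1]] else NA_character_
    })
    out <- which(is.na(in_gene))
    if (length(out)) issues <- c(issues, list(flag(out, "site outside all panel intervals")))
    xl <- gmap$x_linked[match(in_gene, gmap$gene)]
    cap <- chromosome_count(sexes[["n_female"]], sexes[["n_male"]], ifelse(is.na(xl), FALSE, xl))
    bad <- which(!is.na(xl) & x$chrom_count > cap)
    if (length(bad)) issues <- c(issues, list(flag(bad, "chrom_count exceeds cohort chromosome total")))
    if (all(c("het", "hemi_ref", "hemi_alt") %in% names(x))) {
      # X-linked males are hemizygous: diploid tallies there are female-only,
      # so a site whose diploid + hemizygous totals exceed the sex split is bad
      bad <- which(!is.na(xl) & xl &
                     2L * (x$hom_ref + x$het + x$hom_alt) > 2L * sexes[["n_female"]])
      if (length(bad)) issues <- c(issues, list(flag(bad, "more diploid X genotypes than females")))
    }
  }
  if (!length(issues)) return(tibble(site = character(), issue = character()))
  bind_rows(issues)
}

# Align a cohort to an arbitrary site table: absent sites get alt_count 0 and
# the cohort's full chromosome complement for that gene's linkage.
cohort_at_sites <- function(cohort, sites, panel = NULL) {
  sexes <- cohort_sexes(cohort)
  x <- as_tibble(cohort)
  key_c <- site_key(x$chrom, x$pos, x$ref, x$alt)
  key_s <- site_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  idx <- match(key_s, key_c)
  alt <- ifelse(is.na(idx), 0L, x$alt_count[idx])
  n <- x$chrom_count[idx]
  if (anyNA(n)) {
    xl <- if ("x_linked" %in% names(sites)) {
      sites$x_linked
    } else if (!is.null(panel)) {
      gmap <- panel_genes(panel)
      gmap$x_linked[match(sites$gene, gmap$gene)]
    } else {
      rep(FALSE, nrow(sites))
    }
    if (anyNA(sexes)) stop_input("cohort lacks sex metadata needed to pad absent sites")
    fill <- chromosome_count(sexes[["n_female"]], sexes[["n_male"]], xl)
    n[is.na(n)] <- fill[is.na(n)]
  }
  tibble(site = key_s, gene = sites$gene,
         alt_count = as.integer(alt), chrom_count = as.integer(n))
}
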