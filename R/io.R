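#' Read and write the flat variant table
#'
#' The TSV dialect carries one row per biallelic SNV with annotation columns
#' `chrom, pos, ref, alt, gene, region_class, functional_class, sift,
#' polyphen, in_dbsnp` followed by one `<POP>_alt_count` / `<POP>_chrom_count`
#' pair per population (and optional `<POP>_hom_ref`, `<POP>_het`,
#' `<POP>_hom_alt`, `<POP>_hemi_ref`, `<POP>_hemi_alt` genotype tallies).
#' Cohort sex splits travel in header lines of the form
#' `##population <POP> n_female=140 n_male=148` (tab-separated), so a write
#' followed by a read reproduces site keys, counts and metadata exactly.
#' Indel rows (multi-base alleles) are dropped with a message; duplicate site
#' keys and counts outside `[0, chrom_count]` are errors naming the row.
#'
#' @param path File path.
#' @return `read_variant_tsv()`: a list with `sites` (annotation tibble) and
#'   `cohorts` (named list of [cohort_counts()] objects).
#' @export
read_variant_tsv <- function(path) {
  if (!file.exists(path)) stop_input("variant table not found: ", path)
  hdr <- readLines(path, n = 50L)
  meta <- grep("^##population\t", hdr, value = TRUE)
  pops <- list()
  for (m in meta) {
    f <- strsplit(m, "\t")[[1]]
    nf <- as.integer(sub("n_female=", "", f[3]))
    nm <- as.integer(sub("n_male=", "", f[4]))
    pops[[f[2]]] <- c(n_female = nf, n_male = nm)
  }
  d <- readr::read_tsv(path, comment = "##", show_col_types = FALSE,
                       col_types = readr::cols(chrom = readr::col_character(),
                                               ref = readr::col_character(),
                                               alt = readr::col_character()))
  count_like <- grepl("^pos$|_alt_count$|_chrom_count$|_hom_ref$|_het$|_hom_alt$|_hemi_ref$|_hemi_alt$",
                      names(d))
  d[count_like] <- lapply(d[count_like], as.integer)
  prob <- readr::problems(d)
  if (nrow(prob)) {
    stop_input("malformed variant table row(s) at line(s): ",
               paste(unique(prob$row), collapse = ", "))
  }
  need <- c("chrom", "pos", "ref", "alt", "gene")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop_input("variant table missing columns: ", paste(miss, collapse = ", "))

  indel <- nchar(d$ref) != 1L | nchar(d$alt) != 1L
  if (any(indel)) {
    inform(paste0(sum(indel), " indel record(s) dropped (SNVs only)"))
    d <- d[!indel, , drop = FALSE]
  }
  key <- site_key(d$chrom, d$pos, d$ref, d$alt)
  if (anyDuplicated(key)) {
    stop_input("duplicate site key(s): ", paste(unique(key[duplicated(key)]), collapse = ", "))
  }

  pop_names <- unique(sub("_alt_count$", "",
                          grep("_alt_count$", names(d), value = TRUE)))
  if (!length(pop_names)) stop_input("no <POP>_alt_count columns found")
  cohorts <- purrr::map(pop_names, function(p) {
    cols <- paste0(p, c("_alt_count", "_chrom_count"))
    if (!all(cols %in% names(d))) {
      stop_input("population ", p, " lacks a chrom_count column")
    }
    cc <- tibble(chrom = d$chrom, pos = d$pos, ref = d$ref, alt = d$alt,
                 alt_count = d[[cols[1]]], chrom_count = d[[cols[2]]])
    for (g in c("hom_ref", "het", "hom_alt", "hemi_ref", "hemi_alt")) {
      gc <- paste0(p, "_", g)
      if (gc %in% names(d)) cc[[g]] <- d[[gc]]
    }
    sx <- pops[[p]] %||% c(n_female = NA_integer_, n_male = NA_integer_)
    bad <- which(cc$alt_count > cc$chrom_count | cc$alt_count < 0)
    if (length(bad)) {
      stop_input("alt_count outside [0, chrom_count] for ", p, " at: ",
                 paste(key[bad], collapse = ", "))
    }
    cohort_counts(cc, p, sx[["n_female"]], sx[["n_male"]])
  })
  names(cohorts) <- pop_names

  ann_cols <- intersect(c("chrom", "pos", "ref", "alt", "gene", "x_linked",
                          "region_class", "functional_class", "sift",
                          "polyphen", "in_dbsnp"), names(d))
  list(sites = d[, ann_cols, drop = FALSE], cohorts = cohorts)
}

#' @rdname read_variant_tsv
#' @param sites Site annotation tibble.
#' @param cohorts Named list of [cohort_counts()] objects covering `sites`.
#' @export
write_variant_tsv <- function(sites, cohorts, path) {
  d <- as_tibble(sites)
  meta <- character()
  for (p in names(cohorts)) {
    co <- cohorts[[p]]
    at <- cohort_at_sites(co, d)
    d[[paste0(p, "_alt_count")]] <- at$alt_count
    d[[paste0(p, "_chrom_count")]] <- at$chrom_count
    x <- as_tibble(co)
    if (all(c("hom_ref", "het", "hom_alt") %in% names(x))) {
      idx <- match(site_key(d$chrom, d$pos, d$ref, d$alt),
                   site_key(x$chrom, x$pos, x$ref, x$alt))
      for (g in c("hom_ref", "het", "hom_alt", "hemi_ref", "hemi_alt")) {
        if (g %in% names(x)) d[[paste0(p, "_", g)]] <- x[[g]][idx]
      }
    }
    sx <- cohort_sexes(co)
    meta <- c(meta, paste("##population", p,
                          paste0("n_female=", sx[["n_female"]]),
                          paste0("n_male=", sx[["n_male"]]), sep = "\t"))
  }
  writeLines(meta, path)
  readr::write_tsv(d, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read variant sites and cohort counts from a VCF
#'
#' Supports VCF v4.2 input in two shapes: per-population allele counts in
#' INFO fields `AC_<POP>` / `AN_<POP>`, or per-sample `GT` genotypes with a
#' `sample_map` assigning samples to populations. Multiallelic records are
#' split into one biallelic record per alternate allele (conserving alt
#' copies); indel alleles are dropped with a message. Gene and region
#' assignment comes from `panel` interval overlap when given.
#'
#' @param path VCF path (plain or bgzipped).
#' @param populations Named list `pop -> c(n_female, n_male)` metadata.
#' @param sample_map For GT mode: data frame with `sample`, `population`.
#' @param panel Optional panel tibble for gene/region assignment.
#' @return As [read_variant_tsv()].
#' @export
read_variant_vcf <- function(path, populations = NULL, sample_map = NULL,
                             panel = NULL) {
  if (!file.exists(path)) stop_input("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  alts <- strsplit(fix$ALT %||% character(), ",", fixed = TRUE)

  rows <- list(); n_indel <- 0L
  pop_names <- names(populations) %||% unique(sample_map$population)
  ac_mode <- is.null(sample_map)
  info_get <- function(el) vcfR::extract.info(v, element = el)
  ac_info <- if (ac_mode) {
    purrr::map(pop_names, \(p) strsplit(info_get(paste0("AC_", p)), ","))
  }
  an_info <- if (ac_mode) purrr::map(pop_names, \(p) as.integer(info_get(paste0("AN_", p))))
  gt <- if (!ac_mode) vcfR::extract.gt(v)

  for (i in seq_along(alts)) {
    for (j in seq_along(alts[[i]])) {
      a <- alts[[i]][j]
      if (nchar(fix$REF[i]) != 1L || nchar(a) != 1L || a == "*") {
        n_indel <- n_indel + 1L
        next
      }
      counts <- purrr::map(seq_along(pop_names), function(k) {
        if (ac_mode) {
          ac <- suppressWarnings(as.integer(ac_info[[k]][[i]][j]))
          c(alt = ac, n = an_info[[k]][i])
        } else {
          smp <- sample_map$sample[sample_map$population == pop_names[k]]
          g <- gt[i, intersect(smp, colnames(gt))]
          al <- unlist(strsplit(g[!is.na(g)], "[/|]"))
          al <- al[al != "."]
          c(alt = sum(al == as.character(j)), n = length(al))
        }
      })
      rows[[length(rows) + 1L]] <- tibble(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = a,
        !!!stats::setNames(purrr::map_int(counts, \(x) as.integer(x[["alt"]])),
                           paste0(pop_names, "_alt_count")),
        !!!stats::setNames(purrr::map_int(counts, \(x) as.integer(x[["n"]])),
                           paste0(pop_names, "_chrom_count"))
      )
    }
  }
  if (n_indel > 0) inform(paste0(n_indel, " indel/symbolic allele record(s) dropped (SNVs only)"))
  d <- bind_rows(rows)
  if (nrow(d) == 0) stop_input("no biallelic SNV records in VCF")
  key <- site_key(d$chrom, d$pos, d$ref, d$alt)
  if (anyDuplicated(key)) {
    stop_input("duplicate site key(s) in VCF: ",
               paste(unique(key[duplicated(key)]), collapse = ", "))
  }

  d$gene <- NA_character_; d$region_class <- NA_character_
  if (!is.null(panel)) {
    for (i in seq_len(nrow(d))) {
      hit <- which(panel$chrom == d$chrom[i] & panel$start <= d$pos[i] &
                     panel$end >= d$pos[i])
      if (length(hit)) {
        d$gene[i] <- panel$gene[hit[1]]
        d$region_class[i] <- panel$region_class[hit[1]]
      }
    }
  }
  cohorts <- purrr::map(pop_names, function(p) {
    sx <- populations[[p]] %||% c(NA_integer_, NA_integer_)
    cohort_counts(
      tibble(chrom = d$chrom, pos = d$pos, ref = d$ref, alt = d$alt,
             alt_count = d[[paste0(p, "_alt_count")]],
             chrom_count = d[[paste0(p, "_chrom_count")]]),
      p, sx[[1]], sx[[2]])
  })
  names(cohorts) <- pop_names
  list(sites = d[, c("chrom", "pos", "ref", "alt", "gene", "region_class")],
       cohorts = cohorts)
}
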