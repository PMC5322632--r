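#' Synthetic-data generator configuration
#'
#' Defines the study geometry the generator emulates: a ten-gene candidate
#' panel re-sequenced in a case cohort of 288 individuals (140 female / 148
#' male), compared against a 379-individual control population and a large
#' aggregate reference. Two X-linked genes (TLR7/TLR8) exercise sex-dependent
#' chromosome counts. Variable sites come in two layers: a *common* layer of
#' shared polymorphisms with population frequencies drawn from a neutral-like
#' site-frequency spectrum, and a *rare* layer of low-frequency sites whose
#' case-side occurrence probability is multiplied by the enrichment factor
#' `rho` in designated genes. Both cohorts sample every site binomially from
#' its population frequency, so at `rho = 1` case and control are
#' exchangeable given per-site allele totals — exactly the null the
#' permutation test conditions on.
#'
#' @param n_genes Number of panel genes (first `n_genes` of [tlr_panel()]).
#' @param region `"coding"` or `"promoter"` — which intervals carry sites.
#' @param n_case_female,n_case_male,n_control_female,n_control_male Cohort
#'   sex splits (defaults 140/148 cases, 190/189 controls).
#' @param n_reference Individuals behind the aggregate reference.
#' @param shared_per_kb,rare_per_kb Candidate site densities per kb for the
#'   common and rare layers.
#' @param rho Rare-layer case enrichment factor (>= 1).
#' @param enriched_genes Genes whose rare layer is enriched (default none).
#' @param sfs_model,sfs_classes,pool_size Common-layer frequency model; see
#'   [sample_sfs()].
#' @param rare_freq_shape Beta shape parameters for rare-layer frequencies
#'   (default Beta(0.5, 400), mean ~0.00125).
#' @param p_missense,p_nonsense,p_synonymous Functional-class probabilities
#'   for coding sites (must sum to 1).
#' @param p_damaging Probability a missense site is concordantly damaging
#'   (SIFT and PolyPhen-2 agree); `p_discordant` the probability the two
#'   predictors disagree.
#' @param p_discordant See `p_damaging`.
#' @param p_dbsnp_common,p_dbsnp_rare dbSNP membership probabilities per layer.
#' @param genotype_level Emit genotype tallies (diploid females + hemizygous
#'   males for X-linked genes) instead of bare allele counts.
#' @return A `vs_sim_config` list.
#' @export
sim_config <- function(n_genes = 10,
                       region = c("coding", "promoter"),
                       n_case_female = 140, n_case_male = 148,
                       n_control_female = 190, n_control_male = 189,
                       n_reference = 33000,
                       shared_per_kb = 3, rare_per_kb = 1.2,
                       rho = 1, enriched_genes = character(),
                       sfs_model = c("neutral", "beta"),
                       sfs_classes = NULL, pool_size = 758,
                       rare_freq_shape = c(0.5, 400),
                       p_missense = 0.55, p_nonsense = 0.03, p_synonymous = 0.42,
                       p_damaging = 0.35, p_discordant = 0.15,
                       p_dbsnp_common = 0.95, p_dbsnp_rare = 0.15,
                       genotype_level = FALSE) {
  region <- match.arg(region)
  sfs_model <- match.arg(sfs_model)
  if (rho < 1) stop_input("rho must be >= 1")
  if (n_genes < 1 || n_genes > 10) stop_input("n_genes must be in 1..10")
  pfc <- c(p_missense, p_nonsense, p_synonymous)
  if (abs(sum(pfc) - 1) > 1e-8 || any(pfc < 0)) {
    stop_input("functional-class probabilities must be non-negative and sum to 1")
  }
  cfg <- as.list(environment())
  panel <- tlr_panel()
  cfg$panel <- panel[panel$gene %in% paste0("TLR", seq_len(n_genes)), , drop = FALSE]
  structure(cfg, class = "vs_sim_config")
}

#' Sample population frequencies from a site-frequency spectrum
#'
#' `"neutral"` draws an allele-count class `i` in `1..n_classes` with
#' probability proportional to `1/i` (the standard-neutral expectation) and
#' returns frequency `i / pool_size`; `"beta"` draws from
#' `Beta(shape1, shape2)`.
#'
#' @param n_sites Number of frequencies to draw.
#' @param model `"neutral"` or `"beta"`.
#' @param n_classes Number of allele-count classes (default `pool_size - 1`).
#' @param pool_size Chromosome pool defining the class-to-frequency scale.
#' @param shape1,shape2 Beta parameters.
#' @return Numeric frequencies in (0, 1).
#' @examples
#' withr::with_seed(1, sample_sfs(5, "neutral", n_classes = 10))
#' @export
sample_sfs <- function(n_sites, model = c("neutral", "beta"),
                       n_classes = NULL, pool_size = 758,
                       shape1 = 0.5, shape2 = 5) {
  model <- match.arg(model)
  if (n_sites == 0) return(numeric(0))
  if (model == "neutral") {
    n_classes <- n_classes %||% (pool_size - 1L)
    cls <- sample.int(n_classes, n_sites, replace = TRUE,
                      prob = 1 / seq_len(n_classes))
    cls / pool_size
  } else {
    stats::rbeta(n_sites, shape1, shape2)
  }
}

#' Generate a synthetic case/control cohort pair
#'
#' Draws the panel's variable sites and samples both cohorts from their
#' population frequencies (see [sim_config()] for the model). Sites detected
#' in neither cohort are dropped, mirroring what a re-sequencing study can
#' observe.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed; the whole draw is deterministic given `(config, seed)`.
#' @return A list (class `vs_sim_data`) with elements `case` and `control`
#'   ([cohort_counts()] objects), `sites` (annotation tibble), `panel`,
#'   `manifest` (true per-site frequencies and layers, for
#'   parameter-recovery checks) and `config`.
#' @export
sim_cohort_pair <- function(config, seed) {
  stopifnot(inherits(config, "vs_sim_config"))
  withr::with_seed(as.integer(seed), sim_cohort_pair_impl(config, seed))
}

sim_cohort_pair_impl <- function(cfg, seed) {
  panel <- cfg$panel
  gmap <- panel_genes(panel)
  intervals <- panel[panel$region_class == cfg$region, , drop = FALSE]
  case_nf <- cfg$n_case_female; case_nm <- cfg$n_case_male
  ctrl_nf <- cfg$n_control_female; ctrl_nm <- cfg$n_control_male

  per_gene <- purrr::pmap(intervals, function(gene, chrom, x_linked, region_class,
                                              start, end, strand) {
    kb <- (end - start + 1) / 1000
    n_common <- rpois(1, cfg$shared_per_kb * kb)
    n_rare <- rpois(1, cfg$rare_per_kb * kb)
    # rho > 1 adds case-only rare sites so the case cohort's rare-site
    # occurrence rate in enriched genes is rho times the base rate; at
    # rho = 1 both cohorts sample every site from the same frequency and
    # are exchangeable given the per-site allele totals
    n_enr <- if (gene %in% cfg$enriched_genes && cfg$rho > 1) {
      rpois(1, (cfg$rho - 1) * cfg$rare_per_kb * kb)
    } else 0L
    n_tot <- n_common + n_rare + n_enr
    if (n_tot == 0) return(NULL)
    f <- c(sample_sfs(n_common, cfg$sfs_model, cfg$sfs_classes, cfg$pool_size),
           stats::rbeta(n_rare + n_enr, cfg$rare_freq_shape[1],
                        cfg$rare_freq_shape[2]))
    layer <- rep(c("common", "rare", "case_private"),
                 c(n_common, n_rare, n_enr))
    pos <- sort(sample(start:end, n_tot))
    tibble(gene = gene, chrom = chrom, x_linked = x_linked,
           region_class = region_class, pos = pos, layer = layer,
           # case-private sites are absent from the background population
           true_freq = ifelse(layer == "case_private", 0, f),
           case_freq = f)
  }) |> bind_rows()

  if (nrow(per_gene) == 0) stop_input("generator produced no sites; increase densities")

  bases <- c("A", "C", "G", "T")
  per_gene$ref <- sample(bases, nrow(per_gene), replace = TRUE)
  per_gene$alt <- purrr::map_chr(per_gene$ref, \(r) sample(setdiff(bases, r), 1))

  draw_cohort <- function(freqs, nf, nm, genotype_level) {
    n_dip_auto <- nf + nm
    res <- purrr::pmap(
      list(freqs, per_gene$x_linked),
      function(f, xl) {
        if (!genotype_level) {
          nchr <- chromosome_count(nf, nm, xl)
          c(alt = rbinom(1, nchr, f), nchr = nchr,
            hom_ref = NA, het = NA, hom_alt = NA, hemi_ref = NA, hemi_alt = NA)
        } else {
          n_dip <- if (xl) nf else n_dip_auto
          g <- rmultinom(1, n_dip, c((1 - f)^2, 2 * f * (1 - f), f^2))[, 1]
          hemi_alt <- if (xl) rbinom(1, nm, f) else 0L
          hemi_ref <- if (xl) nm - hemi_alt else 0L
          alt <- 2L * g[3] + g[2] + hemi_alt
          c(alt = alt, nchr = 2L * n_dip + hemi_ref + hemi_alt,
            hom_ref = g[1], het = g[2], hom_alt = g[3],
            hemi_ref = hemi_ref, hemi_alt = hemi_alt)
        }
      })
    do.call(rbind, res)
  }
  ca <- draw_cohort(per_gene$case_freq, case_nf, case_nm, cfg$genotype_level)
  co <- draw_cohort(per_gene$true_freq, ctrl_nf, ctrl_nm, cfg$genotype_level)

  detected <- ca[, "alt"] >= 1 | co[, "alt"] >= 1
  per_gene <- per_gene[detected, , drop = FALSE]
  ca <- ca[detected, , drop = FALSE]; co <- co[detected, , drop = FALSE]

  n <- nrow(per_gene)
  fc <- if (cfg$region == "coding") {
    sample(c("missense", "nonsense", "synonymous"), n, replace = TRUE,
           prob = c(cfg$p_missense, cfg$p_nonsense, cfg$p_synonymous))
  } else rep("noncoding", n)
  sift <- poly <- rep("missing", n)
  mis <- which(fc == "missense")
  for (i in mis) {
    u <- runif(1)
    if (u < cfg$p_damaging) {
      sift[i] <- "damaging"; poly[i] <- "damaging"
    } else if (u < cfg$p_damaging + cfg$p_discordant) {
      if (runif(1) < 0.5) { sift[i] <- "damaging"; poly[i] <- "benign" }
      else { sift[i] <- "tolerated"; poly[i] <- "damaging" }
    } else {
      sift[i] <- "tolerated"; poly[i] <- "benign"
    }
  }
  in_db <- runif(n) < ifelse(per_gene$layer == "common",
                             cfg$p_dbsnp_common, cfg$p_dbsnp_rare)

  sites <- tibble(
    chrom = per_gene$chrom, pos = per_gene$pos,
    ref = per_gene$ref, alt = per_gene$alt,
    gene = per_gene$gene, x_linked = per_gene$x_linked,
    region_class = per_gene$region_class,
    functional_class = fc, sift = sift, polyphen = poly, in_dbsnp = in_db
  )
  mk_cohort <- function(m, label, nf, nm) {
    d <- tibble(chrom = sites$chrom, pos = sites$pos,
                ref = sites$ref, alt = sites$alt,
                alt_count = as.integer(m[, "alt"]),
                chrom_count = as.integer(m[, "nchr"]))
    if (cfg$genotype_level) {
      d$hom_ref <- as.integer(m[, "hom_ref"]); d$het <- as.integer(m[, "het"])
      d$hom_alt <- as.integer(m[, "hom_alt"])
      d$hemi_ref <- as.integer(m[, "hemi_ref"]); d$hemi_alt <- as.integer(m[, "hemi_alt"])
    }
    cohort_counts(d, label, nf, nm)
  }
  manifest <- tibble(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    gene = sites$gene, layer = per_gene$layer,
    freq = per_gene$true_freq, case_freq = per_gene$case_freq
  )
  structure(list(
    case = mk_cohort(ca, "CASE", case_nf, case_nm),
    control = mk_cohort(co, "CTRL", ctrl_nf, ctrl_nm),
    sites = sites, panel = panel, manifest = manifest,
    config = cfg, seed = as.integer(seed)
  ), class = "vs_sim_data")
}

#' Generate an aggregate reference from per-site population frequencies
#'
#' Per-site allele counts `AC ~ Binomial(2 * n_individuals, freq)`; the
#' per-site chromosome total can be jittered downwards (binomial call rate
#' `1 - an_jitter`) to emulate variable per-site call rates.
#'
#' @param freqs Tibble with `chrom`, `pos`, `ref`, `alt` and a `freq` column
#'   (a `vs_sim_data$manifest` works directly).
#' @param n_individuals Reference cohort size (default 33000).
#' @param seed RNG seed.
#' @param an_jitter Per-chromosome dropout probability in `[0, 1)`.
#' @return Reference count tibble (`alt_count`, `chrom_count` per site).
#' @export
sim_reference <- function(freqs, n_individuals = 33000, seed = 1L,
                          an_jitter = 0) {
  if (!"freq" %in% names(freqs)) stop_input("freqs needs a 'freq' column")
  if (an_jitter < 0 || an_jitter >= 1) stop_input("an_jitter must be in [0, 1)")
  withr::with_seed(as.integer(seed), {
    an_full <- 2L * n_individuals
    an <- if (an_jitter > 0) {
      rbinom(nrow(freqs), an_full, 1 - an_jitter)
    } else rep(an_full, nrow(freqs))
    tibble(chrom = freqs$chrom, pos = freqs$pos,
           ref = freqs$ref, alt = freqs$alt,
           alt_count = as.integer(rbinom(nrow(freqs), an, freqs$freq)),
           chrom_count = as.integer(an))
  })
}
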