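# independent oracles, written from first principles and kept free of the
# package's permutation/statistic code paths

# exhaustive permutation null for tiny panels: enumerate every combination of
# per-site hypergeometric outcomes, weight by the product of dhyper masses,
# and accumulate exact P(stat > obs) and P(stat >= obs)
enum_perm_null <- function(case_alt, case_n, ctrl_alt, ctrl_n,
                           stat = c("specific", "rare", "damaging"),
                           threshold = 0.01, damaging = NULL) {
  stat <- match.arg(stat)
  n_sites <- length(case_alt)
  damaging <- damaging %||% rep(TRUE, n_sites)
  total_alt <- case_alt + ctrl_alt
  total_n <- case_n + ctrl_n
  site_stat <- function(a, i) {
    switch(stat,
      specific = as.integer(a >= 1 && (total_alt[i] - a) == 0),
      rare = as.integer(a >= 1 && min(a, case_n[i] - a) / case_n[i] <= threshold + 1e-12),
      damaging = as.integer(a >= 1 && damaging[i]))
  }
  supports <- lapply(seq_len(n_sites), function(i) {
    lo <- max(0L, total_alt[i] - ctrl_n[i])
    hi <- min(case_n[i], total_alt[i])
    a <- lo:hi
    list(a = a,
         p = dhyper(a, total_alt[i], total_n[i] - total_alt[i], case_n[i]),
         s = vapply(a, site_stat, integer(1), i = i))
  })
  grid <- expand.grid(lapply(supports, function(x) seq_along(x$a)))
  probs <- apply(grid, 1, function(idx)
    prod(vapply(seq_len(n_sites), function(i) supports[[i]]$p[idx[i]], numeric(1))))
  stats <- apply(grid, 1, function(idx)
    sum(vapply(seq_len(n_sites), function(i) supports[[i]]$s[idx[i]], integer(1))))
  observed <- sum(vapply(seq_len(n_sites),
                         function(i) site_stat(case_alt[i], i), integer(1)))
  list(observed = observed,
       p_gt = sum(probs[stats > observed]),
       p_ge = sum(probs[stats >= observed]))
}

# chi-square HWE statistic straight from the textbook definition
hwe_chi_oracle <- function(hom_ref, het, hom_alt) {
  n <- hom_ref + het + hom_alt
  p <- (2 * hom_ref + het) / (2 * n)  # major (ref) allele frequency
  q <- 1 - p
  expected <- n * c(p^2, 2 * p * q, q^2)
  sum((c(hom_ref, het, hom_alt) - expected)^2 / expected)
}

# Monte-Carlo two-sided p for a frequency difference under the pooled null,
# by direct binomial simulation
two_prop_mc_oracle <- function(case_alt, case_n, ctrl_alt, ctrl_n,
                               n_draws = 1e6, seed = 42) {
  pbar <- (case_alt + ctrl_alt) / (case_n + ctrl_n)
  obs <- abs(case_alt / case_n - ctrl_alt / ctrl_n)
  withr::with_seed(seed, {
    d <- abs(rbinom(n_draws, case_n, pbar) / case_n -
               rbinom(n_draws, ctrl_n, pbar) / ctrl_n)
    mean(d >= obs - 1e-12)
  })
}
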