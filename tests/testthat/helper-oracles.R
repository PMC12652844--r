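# Independent oracles and fixture builders shared across the test files.
# The oracles deliberately re-derive quantities by explicit enumeration,
# not by calling the package's own vectorized implementations.

# allele count of allele i (1 or 2) in genotype t (1="11", 2="12", 3="22")
ocnt <- function(i, t) matrix(c(2, 1, 0, 0, 1, 2), 2, 3, byrow = TRUE)[i, t]

# frequency objects from explicit frequency tables (white-box: mirrors the
# structure genotype_freqs() returns, for arbitrary non-count frequencies)
freqs1 <- function(f3) {
  f3 <- f3 / sum(f3)
  p1 <- f3[1] + f3[2] / 2
  structure(list(f = stats::setNames(f3, c("11", "12", "22")),
                 n = NA, p = c("1" = p1, "2" = 1 - p1)),
            class = "genotype_freqs_1l")
}
freqs2 <- function(f9) {
  f9 <- f9 / sum(f9)
  structure(list(f = f9, n = NA, f1 = rowSums(f9), f2 = colSums(f9)),
            class = "genotype_freqs_2l")
}

rand_freqs2 <- function(allow_empty = FALSE) {
  f <- matrix(stats::rexp(9), 3)
  if (allow_empty) f[sample(9, sample(0:2, 1))] <- 0
  freqs2(f)
}

# brute-force two-locus partition by explicit loops over the sequential
# residual definitions (term-by-term, no shared code with the package);
# an undefined effect carried with zero allele incidence contributes 0
zmul <- function(a, cc) if (cc == 0) 0 else a * cc
brute_partition_2l <- function(g, f) {
  wsum <- function(wfun) {
    num <- 0; den <- 0
    for (t in 1:3) for (u in 1:3) {
      w <- wfun(t, u)
      if (w > 0) { num <- num + w * g[t, u]; den <- den + w }
    }
    if (den == 0) NA_real_ else num / den
  }
  mu <- wsum(function(t, u) f[t, u])
  mu_a1 <- sapply(1:2, function(i) wsum(function(t, u) ocnt(i, t) * f[t, u]))
  mu_a2 <- sapply(1:2, function(k) wsum(function(t, u) ocnt(k, u) * f[t, u]))
  a1 <- mu_a1 - mu; a2 <- mu_a2 - mu
  mu_g1 <- sapply(1:3, function(tt) wsum(function(t, u) (t == tt) * f[t, u]))
  mu_g2 <- sapply(1:3, function(uu) wsum(function(t, u) (u == uu) * f[t, u]))
  d1 <- sapply(1:3, function(t) mu_g1[t] - mu - zmul(a1[1], ocnt(1, t)) -
                 zmul(a1[2], ocnt(2, t)))
  d2 <- sapply(1:3, function(u) mu_g2[u] - mu - zmul(a2[1], ocnt(1, u)) -
                 zmul(a2[2], ocnt(2, u)))
  aa <- matrix(NA_real_, 2, 2)
  for (i in 1:2) for (k in 1:2) {
    mik <- wsum(function(t, u) ocnt(i, t) * ocnt(k, u) * f[t, u])
    aa[i, k] <- mik - mu - a1[i] - a2[k]
  }
  ad <- matrix(NA_real_, 2, 3)
  for (i in 1:2) for (u in 1:3) {
    miu <- wsum(function(t, uu) ocnt(i, t) * (uu == u) * f[t, uu])
    ad[i, u] <- miu - mu - a1[i] - zmul(a2[1], ocnt(1, u)) -
      zmul(a2[2], ocnt(2, u)) - d2[u] - zmul(aa[i, 1], ocnt(1, u)) -
      zmul(aa[i, 2], ocnt(2, u))
  }
  da <- matrix(NA_real_, 3, 2)
  for (t in 1:3) for (k in 1:2) {
    mtk <- wsum(function(tt, u) (tt == t) * ocnt(k, u) * f[tt, u])
    da[t, k] <- mtk - mu - zmul(a1[1], ocnt(1, t)) - zmul(a1[2], ocnt(2, t)) -
      a2[k] - d1[t] - zmul(aa[1, k], ocnt(1, t)) - zmul(aa[2, k], ocnt(2, t))
  }
  dd <- matrix(NA_real_, 3, 3)
  for (t in 1:3) for (u in 1:3) {
    if (f[t, u] == 0) next
    dd[t, u] <- g[t, u] - mu -
      zmul(a1[1], ocnt(1, t)) - zmul(a1[2], ocnt(2, t)) -
      zmul(a2[1], ocnt(1, u)) - zmul(a2[2], ocnt(2, u)) -
      d1[t] - d2[u] -
      zmul(aa[1, 1], ocnt(1, t) * ocnt(1, u)) -
      zmul(aa[1, 2], ocnt(1, t) * ocnt(2, u)) -
      zmul(aa[2, 1], ocnt(2, t) * ocnt(1, u)) -
      zmul(aa[2, 2], ocnt(2, t) * ocnt(2, u)) -
      zmul(ad[1, u], ocnt(1, t)) - zmul(ad[2, u], ocnt(2, t)) -
      zmul(da[t, 1], ocnt(1, u)) - zmul(da[t, 2], ocnt(2, u))
  }
  list(mu = mu, a1 = a1, a2 = a2, d1 = d1, d2 = d2,
       aa = aa, ad = ad, da = da, dd = dd)
}

# tiny deterministic genotype fixture: 3 individuals x 2 SNPs
tiny_geno <- function() {
  genotype_matrix(codes = rbind(c(0, 1), c(1, 2), c(2, 0)),
                  map = data.frame(snp_id = c("s1", "s2"),
                                   chr = c("1", "1"),
                                   pos = c(100L, 2000L),
                                   allele1 = "1", allele2 = "2"),
                  ids = c("a", "b", "c"))
}

# small simulated dataset with optional planted effects; residual scale is
# deliberately moderate so effects at published sizes are resolvable at
# desk-scale n
small_sim <- function(seed, n = 800, n_snps = 24, n_chr = 3,
                      effects = NULL, sigma2_a = 4, sigma2_e = 100,
                      pta_mode = "true") {
  cfg <- sim_config(n_individuals = n, n_snps = n_snps,
                    n_chromosomes = n_chr, sigma2_a = sigma2_a,
                    sigma2_e = sigma2_e, pta_mode = pta_mode, seed = seed)
  pop <- simulate_population(cfg)
  truth <- if (is.null(effects)) NULL else plant_effects(pop, effects)
  ph <- simulate_phenotypes(pop, truth)
  list(pop = pop, truth = truth, pheno = ph, cfg = cfg)
}
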