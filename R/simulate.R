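# Crossbred-population generator with known truth: two founder breeds with
# diverged allele frequencies, gene-dropped pedigree descendants, planted
# single-locus and pairwise genetic architectures, a pedigree polygenic
# term and PTA values for phenotype correction.

#' Simulation configuration
#'
#' Defaults emulate a Jersey x Holstein admixed cow population measured on a
#' daughter-pregnancy-rate-like scale: founder breed proportions 0.53/0.47,
#' between-breed divergence Fst = 0.10, phenotype mean 55 and standard
#' deviation 33 with heritability 0.04.
#'
#' @param n_individuals total population size across all cohorts.
#' @param n_snps number of SNPs.
#' @param n_chromosomes chromosomes; SNPs are split evenly and evenly
#'   spaced.
#' @param chr_length_bp chromosome length (default 6 Mb, so neighbouring
#'   SNPs fall within the pairwise scan window).
#' @param breed_props founder breed proportions (two breeds, "J" and "H").
#' @param fst Balding-Nichols divergence of breed allele frequencies from
#'   the shared ancestral frequency (0 = indistinguishable breeds).
#' @param maf_floor target minor-allele-frequency floor; the generator
#'   draws ancestral frequencies away from fixation so SNPs usually clear
#'   it, and planting refuses SNPs below it.
#' @param n_generations cohorts: purebred founders plus
#'   `n_generations - 1` generations of random-mating descendants.
#' @param ld_rho AR(1) correlation of the latent Gaussian copula used for
#'   founder haplotypes within a chromosome (induces founder LD between
#'   nearby SNPs; segregation itself is per-SNP independent).
#' @param mu phenotype mean.
#' @param h2,sigma_p narrow-sense heritability and phenotypic standard
#'   deviation; used to derive `sigma2_a`, `sigma2_e` unless those are
#'   given explicitly.
#' @param sigma2_a,sigma2_e variance components (override `h2`/`sigma_p`).
#' @param pta_mode `"blup"` (PTA = pedigree-BLUP breeding value / 2, as in
#'   routine evaluation) or `"true"` (PTA = simulated true breeding
#'   value / 2).
#' @param seed integer seed; mandatory, all randomness derives from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 2000, n_snps = 200,
                       n_chromosomes = 5, chr_length_bp = 6e6,
                       breed_props = c(J = 0.53, H = 0.47),
                       fst = 0.10, maf_floor = 0.05,
                       n_generations = 3, ld_rho = 0.5,
                       mu = 55, h2 = 0.04, sigma_p = 33,
                       sigma2_a = NULL, sigma2_e = NULL,
                       pta_mode = c("blup", "true"), seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  pta_mode <- match.arg(pta_mode)
  stopifnot(n_individuals >= 2 * n_generations, n_snps >= 1,
            n_chromosomes >= 1, chr_length_bp > n_snps,
            length(breed_props) == 2, all(breed_props > 0),
            fst >= 0, fst < 1, maf_floor >= 0, maf_floor <= 0.5,
            n_generations >= 1, ld_rho >= 0, ld_rho < 1,
            h2 > 0, h2 < 1, sigma_p > 0)
  if (maf_floor > 0.3)
    stop("maf_floor ", maf_floor,
         " incompatible with breed divergence: generator cannot keep ",
         "all markers this common")
  breed_props <- breed_props / sum(breed_props)
  names(breed_props) <- c("J", "H")
  structure(list(
    n_individuals = n_individuals, n_snps = n_snps,
    n_chromosomes = n_chromosomes, chr_length_bp = chr_length_bp,
    breed_props = breed_props, fst = fst, maf_floor = maf_floor,
    n_generations = n_generations, ld_rho = ld_rho,
    mu = mu, h2 = h2, sigma_p = sigma_p,
    sigma2_a = sigma2_a %||% (h2 * sigma_p^2),
    sigma2_e = sigma2_e %||% ((1 - h2) * sigma_p^2),
    pta_mode = pta_mode, seed = as.integer(seed)),
    class = "sim_config")
}

# latent AR(1) Gaussian matrix (rows = haplotypes, cols = SNPs) per chr
ar1_latent <- function(n_hap, chr_index, rho) {
  m <- length(chr_index)
  Z <- matrix(stats::rnorm(n_hap * m), n_hap, m)
  if (rho > 0 && m > 1) {
    for (j in 2:m) {
      if (chr_index[j] == chr_index[j - 1])
        Z[, j] <- rho * Z[, j - 1] + sqrt(1 - rho^2) * Z[, j]
    }
  }
  Z
}

#' Simulate a two-breed admixed population
#'
#' Founder haplotypes are drawn from breed-specific allele frequencies
#' (Balding-Nichols divergence around a shared ancestral frequency) with an
#' AR(1) Gaussian copula along each chromosome; descendants are produced by
#' gene dropping over a random-mating pedigree with per-SNP independent
#' Mendelian segregation. Each allele's founder breed origin is tracked.
#'
#' @param cfg a [sim_config()].
#' @return List of class `sim_population`: `geno` (a `genotype_matrix`),
#'   `ped` (animal/sire/dam, founders have parent "0"), `sex`, `cohort`,
#'   `founder_breed` (`NA` for non-founders), `admixture` (realized
#'   Jersey-origin allele fraction per individual), `origins` (two
#'   haplotype origin matrices), `breed_freq` (the generating per-breed
#'   allele-2 frequencies) and `cfg`. Deterministic given `cfg$seed`.
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_individuals; m <- cfg$n_snps
  chr <- rep(seq_len(cfg$n_chromosomes), length.out = m)
  chr <- sort(chr)
  pos <- unlist(lapply(split(seq_len(m), chr), function(ix) {
    k <- length(ix)
    as.integer(round(seq_len(k) * cfg$chr_length_bp / (k + 1)))
  }), use.names = FALSE)
  map <- data.frame(snp_id = sprintf("snp%05d", seq_len(m)),
                    chr = as.character(chr), pos = pos,
                    allele1 = "1", allele2 = "2",
                    stringsAsFactors = FALSE)
  # allele-2 frequencies: shared ancestral, Balding-Nichols per breed
  q <- 0.1 + 0.8 * stats::rbeta(m, 2, 2)
  pfreq <- sapply(c("J", "H"), function(b) {
    if (cfg$fst == 0) q
    else stats::rbeta(m, q * (1 - cfg$fst) / cfg$fst,
                      (1 - q) * (1 - cfg$fst) / cfg$fst)
  })
  pfreq <- pmin(pmax(pfreq, 0.02), 0.98)
  sizes <- diff(round(seq(0, n, length.out = cfg$n_generations + 1)))
  cohort <- rep(seq_along(sizes), sizes)
  ids <- sprintf("ind%05d", seq_len(n))
  sex <- rep_len(c("F", "M"), n)
  H1 <- H2 <- matrix(0L, n, m)
  O1 <- O2 <- matrix(NA_character_, n, m)
  founders <- which(cohort == 1)
  breed <- rep(NA_character_, n)
  breed[founders] <- sample(c("J", "H"), length(founders), replace = TRUE,
                            prob = cfg$breed_props)
  for (hm in 1:2) {
    Z <- ar1_latent(length(founders), chr, cfg$ld_rho)
    P <- t(pfreq[, breed[founders]])      # founder x SNP breed frequency
    hap <- (stats::pnorm(Z) < P) * 1L
    if (hm == 1) { H1[founders, ] <- hap; O1[founders, ] <- breed[founders] }
    else { H2[founders, ] <- hap; O2[founders, ] <- breed[founders] }
  }
  sire <- dam <- rep("0", n)
  for (g in seq_along(sizes)[-1]) {
    kids <- which(cohort == g)
    prev <- which(cohort == g - 1)
    males <- prev[sex[prev] == "M"]; females <- prev[sex[prev] == "F"]
    if (!length(males) || !length(females))
      stop("a cohort lacks one sex; increase n_individuals")
    si <- sample(males, length(kids), replace = TRUE)
    di <- sample(females, length(kids), replace = TRUE)
    sire[kids] <- ids[si]; dam[kids] <- ids[di]
    pick_s <- matrix(stats::runif(length(kids) * m) < 0.5, length(kids), m)
    pick_d <- matrix(stats::runif(length(kids) * m) < 0.5, length(kids), m)
    H1[kids, ] <- ifelse(pick_s, H1[si, , drop = FALSE], H2[si, , drop = FALSE])
    O1[kids, ] <- ifelse(pick_s, O1[si, , drop = FALSE], O2[si, , drop = FALSE])
    H2[kids, ] <- ifelse(pick_d, H1[di, , drop = FALSE], H2[di, , drop = FALSE])
    O2[kids, ] <- ifelse(pick_d, O1[di, , drop = FALSE], O2[di, , drop = FALSE])
  }
  geno <- genotype_matrix(H1 + H2, map, ids)
  ped <- data.frame(animal = ids, sire = sire, dam = dam,
                    stringsAsFactors = FALSE)
  structure(list(geno = geno, ped = ped, sex = sex, cohort = cohort,
                 founder_breed = breed,
                 admixture = (rowSums(O1 == "J") + rowSums(O2 == "J")) / (2 * m),
                 origins = list(O1, O2), breed_freq = pfreq, cfg = cfg),
            class = "sim_population")
}

# genotypic-value maps for the supported planted architectures; the map is
# what is added to the phenotype of each carrier genotype
pattern_map <- function(type, scale) {
  cD <- c(-0.5, 1, -0.5)
  switch(type,
    # slope `scale` per allele-1 copy, so the additive effect (allelic
    # effect gap alpha) is close to `scale` at intermediate frequency
    additive = scale * c(1, 0, -1),
    # both homozygotes positive, heterozygote negative (dominance scan
    # benchmark pattern; scale 1 gives delta = -2.555)
    table2_dominance = scale * c(0.629, -1.280, 1.920),
    # interaction carried by the allele-1/allele-1 combination: value
    # proportional to the number of such allele pairings in the genotype;
    # scale 1 gives an A x A effect of 1 at balanced allele frequencies
    fig6_axa = scale * outer(c(2, 1, 0), c(2, 1, 0)),
    # het-by-homo cells negative, double-het and homo-homo positive;
    # scale 1 gives a dominance x dominance effect of 1
    fig8_dxd = scale / 2.25 * outer(cD, cD),
    null = rep(0, 3),
    stop("unknown planted-effect type: ", type))
}

#' Plant single-locus and pairwise genetic architectures
#'
#' Builds genotypic-value maps for the requested patterns and derives the
#' true scalar effects from each map and the realized genotype frequencies
#' via the partition functions (a single source of truth for what the scan
#' should recover).
#'
#' Patterns: `"additive"` (allelic-effect gap `scale`),
#' `"table2_dominance"` (homozygous advantage / heterozygous disadvantage;
#' `scale` 1 gives delta -2.555), `"fig6_axa"` (one of the four allelic
#' combinations interacts), `"fig8_dxd"` (checkerboard: het-by-homo cells
#' negative; `scale` = the planted dominance x dominance effect), `"null"`.
#'
#' @param pop a [simulate_population()] result.
#' @param effects list of specs `list(type =, snp = | snps = c(,),
#'   scale =)`; SNPs default to high-MAF markers chosen automatically
#'   (pairs: nearby on one chromosome).
#' @return Data frame of class `truth_table`: SNP(s), type, scale, the map
#'   (list column) and the derived true effects (`true_alpha`,
#'   `true_delta` for singles; `true_aa`, `true_ad`, `true_da`, `true_dd`
#'   for pairs).
#' @export
plant_effects <- function(pop, effects) {
  stopifnot(inherits(pop, "sim_population"))
  geno <- pop$geno; cfg <- pop$cfg
  maf <- snp_maf(geno)
  used <- character(0)
  pick_single <- function() {
    cand <- setdiff(names(sort(maf, decreasing = TRUE)), used)
    cand <- cand[maf[cand] >= cfg$maf_floor]
    if (!length(cand)) stop("no unused SNP passes the MAF floor")
    cand[1]
  }
  pick_pair <- function() {
    map <- geno$map
    best <- NULL; best_maf <- -1
    for (j in seq_len(nrow(map) - 1)) {
      a <- map$snp_id[j]; b <- map$snp_id[j + 1]
      if (map$chr[j] != map$chr[j + 1]) next
      if (abs(map$pos[j + 1] - map$pos[j]) > 3e6) next
      if (a %in% used || b %in% used) next
      mm <- min(maf[a], maf[b])
      if (mm >= cfg$maf_floor && mm > best_maf) { best <- c(a, b); best_maf <- mm }
    }
    if (is.null(best)) stop("no unused intra-chromosome SNP pair available")
    best
  }
  rows <- lapply(effects, function(e) {
    stopifnot(!is.null(e$type))
    scale <- e$scale %||% switch(e$type, additive = 2, table2_dominance = 1,
                                 fig6_axa = 3, fig8_dxd = 5, null = 0)
    pairwise <- e$type %in% c("fig6_axa", "fig8_dxd")
    if (pairwise && !is.null(e$snp))
      stop("pattern ", e$type, " needs a SNP pair (use snps = c(a, b))")
    if (!pairwise && !is.null(e$snps))
      stop("pattern ", e$type, " is single-locus (use snp = )")
    snps <- if (pairwise) e$snps %||% pick_pair() else e$snp %||% pick_single()
    bad <- setdiff(snps, geno$map$snp_id)
    if (length(bad)) stop("unknown SNP: ", paste(bad, collapse = ", "))
    low <- snps[maf[snps] < cfg$maf_floor]
    if (length(low))
      stop("planted SNP below MAF floor: ", paste(low, collapse = ", "))
    used <<- c(used, snps)
    map_vals <- pattern_map(e$type, scale)
    j <- match(snps, geno$map$snp_id)
    out <- data.frame(type = e$type, scale = scale,
                      snp1 = snps[1], chr1 = geno$map$chr[j[1]],
                      pos1 = geno$map$pos[j[1]],
                      snp2 = NA_character_, chr2 = NA_character_,
                      pos2 = NA_integer_,
                      true_alpha = NA_real_, true_delta = NA_real_,
                      true_aa = NA_real_, true_ad = NA_real_,
                      true_da = NA_real_, true_dd = NA_real_,
                      stringsAsFactors = FALSE)
    if (pairwise) {
      out$snp2 <- snps[2]; out$chr2 <- geno$map$chr[j[2]]
      out$pos2 <- geno$map$pos[j[2]]
      fr <- genotype_freqs(geno$codes[, j[1]], geno$codes[, j[2]])
      part <- partition_two_locus(map_vals, fr)
      out$true_alpha <- part$alpha1; out$true_delta <- part$delta1
      out$true_aa <- part$aa_effect; out$true_ad <- part$ad_effect
      out$true_da <- part$da_effect; out$true_dd <- part$dd_effect
    } else {
      fr <- genotype_freqs(geno$codes[, j[1]])
      part <- partition_single_locus(map_vals, fr)
      out$true_alpha <- part$alpha; out$true_delta <- part$delta
    }
    out$map <- I(list(map_vals))
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("truth_table", class(out))
  out
}

#' Simulate phenotypes with polygenic term and PTA
#'
#' `y = mu + planted genotypic values + a + e` where `a` is a
#' pedigree-correlated polygenic breeding value (gene-dropped: founders
#' `N(0, sigma2_a)`, offspring mid-parent plus Mendelian-sampling noise)
#' and `e` iid residual. PTA is half the pedigree-BLUP breeding value
#' (`pta_mode = "blup"`, as in routine evaluation) or half the true
#' breeding value (`"true"`).
#'
#' @param pop a [simulate_population()] result.
#' @param truth optional [plant_effects()] truth table.
#' @param pta_mode overrides `cfg$pta_mode`.
#' @param seed overrides the phenotype seed (default `cfg$seed + 1000`),
#'   e.g. to redraw phenotype replicates over one fixed population.
#' @return Phenotype data frame (`id`, `y`, `pta`, `y_star`) with
#'   attributes `true_a` (simulated breeding values) and `truth`.
#'   Deterministic given the config seed.
#' @export
simulate_phenotypes <- function(pop, truth = NULL, pta_mode = NULL,
                                seed = NULL) {
  stopifnot(inherits(pop, "sim_population"))
  cfg <- pop$cfg
  pta_mode <- pta_mode %||% cfg$pta_mode
  set.seed(seed %||% (cfg$seed + 1000L))
  n <- cfg$n_individuals
  ids <- pop$geno$ids
  s2a <- cfg$sigma2_a; s2e <- cfg$sigma2_e
  a <- numeric(n)
  si <- match(pop$ped$sire, ids); di <- match(pop$ped$dam, ids)
  for (i in seq_len(n)) {
    a[i] <- if (is.na(si[i]) || pop$ped$sire[i] == "0")
      stats::rnorm(1, 0, sqrt(s2a))
    else 0.5 * (a[si[i]] + a[di[i]]) + stats::rnorm(1, 0, sqrt(s2a / 2))
  }
  planted <- numeric(n)
  if (!is.null(truth) && nrow(truth)) {
    for (r in seq_len(nrow(truth))) {
      mv <- truth$map[[r]]
      x1 <- pop$geno$codes[, truth$snp1[r]]
      if (is.na(truth$snp2[r])) {
        planted <- planted + ifelse(is.na(x1), 0, mv[x1 + 1L])
      } else {
        x2 <- pop$geno$codes[, truth$snp2[r]]
        v <- mv[cbind(x1 + 1L, x2 + 1L)]
        planted <- planted + ifelse(is.na(v), 0, v)
      }
    }
  }
  e <- stats::rnorm(n, 0, sqrt(s2e))
  y <- cfg$mu + planted + a + e
  pta <- if (pta_mode == "true") a / 2 else {
    A <- build_A(pop$ped)
    fit <- solve_mme(y, matrix(1, n, 1), diag(n), A, lambda = s2e / s2a)
    fit$a_hat / 2
  }
  ph <- data.frame(id = ids, y = y, pta = as.numeric(pta),
                   stringsAsFactors = FALSE)
  ph <- correct_phenotypes(ph)
  attr(ph, "true_a") <- a
  attr(ph, "truth") <- truth
  ph
}
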