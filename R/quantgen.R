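# Kempthorne orthogonal partition of one- and two-locus genotypic values,
# extended to Hardy-Weinberg and linkage disequilibria: all effects are
# deviations of frequency-weighted marginal means from lower-order terms,
# with observed (not equilibrium-fitted) genotype frequencies as weights.

GENO3 <- c("11", "12", "22")
ALLELES <- c("1", "2")
# count of allele i (rows "1","2") carried by genotype t (cols "11","12","22")
ALLELE_COUNT <- matrix(c(2, 1, 0, 0, 1, 2), nrow = 2, byrow = TRUE,
                       dimnames = list(ALLELES, GENO3))
# coefficient vectors whose tensor products define the scalar summary effects
C_ADD <- c("1" = 1, "2" = -1)
C_DOM <- c("11" = -0.5, "12" = 1, "22" = -0.5)

#' Observed genotype frequencies at one or two SNPs
#'
#' Tabulates genotype codes (0/1/2 = count of allele "2") into observed
#' genotype frequencies. No Hardy-Weinberg or linkage equilibrium is assumed
#' or fitted: the frequencies are the raw relative counts, which is what the
#' disequilibrium-aware effect partition weights by.
#'
#' @param codes1 integer vector of genotype codes at the first SNP
#'   (0, 1, 2 or `NA`).
#' @param codes2 optional codes at a second SNP; when supplied, the joint
#'   3 x 3 two-locus frequencies are returned and individuals missing at
#'   either SNP are dropped (complete cases per test).
#' @return For one SNP an object of class `genotype_freqs_1l` with elements
#'   `f` (named frequencies of genotypes "11", "12", "22"), `counts`, `n`
#'   and allele frequencies `p`. For two SNPs a `genotype_freqs_2l` with the
#'   3 x 3 frequency matrix `f` (rows = locus-1 genotypes, columns =
#'   locus-2 genotypes), the per-locus margins `f1`, `f2` and allele
#'   frequencies `p1`, `p2`.
#' @examples
#' genotype_freqs(c(0, 1, 2, 1))
#' @export
genotype_freqs <- function(codes1, codes2 = NULL) {
  stopifnot(all(codes1 %in% c(0:2, NA)))
  if (is.null(codes2)) {
    ok <- !is.na(codes1)
    if (!any(ok)) stop("no non-missing genotypes at this SNP")
    counts <- tabulate(codes1[ok] + 1L, nbins = 3L)
    names(counts) <- GENO3
    f <- counts / sum(counts)
    p1 <- f[["11"]] + f[["12"]] / 2
    structure(list(f = f, counts = counts, n = sum(counts),
                   p = c("1" = p1, "2" = 1 - p1)),
              class = "genotype_freqs_1l")
  } else {
    stopifnot(all(codes2 %in% c(0:2, NA)), length(codes1) == length(codes2))
    ok <- !is.na(codes1) & !is.na(codes2)
    if (!any(ok)) stop("no individuals non-missing at both SNPs")
    counts <- matrix(tabulate(codes1[ok] + 3L * codes2[ok] + 1L, nbins = 9L),
                     nrow = 3, dimnames = list(GENO3, GENO3))
    f <- counts / sum(counts)
    f1 <- rowSums(f); f2 <- colSums(f)
    structure(list(f = f, counts = counts, n = sum(counts),
                   W = build_weight_matrix(f),
                   f1 = f1, f2 = f2,
                   p1 = c("1" = f1[[1]] + f1[[2]] / 2,
                          "2" = f1[[3]] + f1[[2]] / 2),
                   p2 = c("1" = f2[[1]] + f2[[2]] / 2,
                          "2" = f2[[3]] + f2[[2]] / 2)),
              class = "genotype_freqs_2l")
  }
}

# weighted mean that returns NA (not NaN) on zero total weight and ignores
# g values in zero-weight cells (e.g. NA means of empty genotype classes)
wmean <- function(g, w) {
  use <- w > 0
  if (!any(use)) return(NA_real_)
  sum(g[use] * w[use]) / sum(w[use])
}

# normalized weight rows for all 27 two-locus marginals over the 9 cells
# (column-major cell order, locus-1 genotype varying fastest); rows:
# mu | mu_g1 (3) | mu_g2 (3) | mu_a1 (2) | mu_a2 (2) | mu_aa (4, col-major)
# | mu_ag (6, col-major 2x3) | mu_ga (6, col-major 3x2)
build_weight_matrix <- function(f) {
  fv <- as.vector(f)
  tt <- rep(1:3, 3)            # locus-1 genotype of each cell
  uu <- rep(1:3, each = 3)     # locus-2 genotype of each cell
  rows <- c(
    list(fv),
    lapply(1:3, function(t) fv * (tt == t)),
    lapply(1:3, function(u) fv * (uu == u)),
    lapply(1:2, function(i) fv * ALLELE_COUNT[i, tt]),
    lapply(1:2, function(k) fv * ALLELE_COUNT[k, uu]),
    lapply(1:4, function(m) {
      i <- (m - 1) %% 2 + 1; k <- (m - 1) %/% 2 + 1
      fv * ALLELE_COUNT[i, tt] * ALLELE_COUNT[k, uu]
    }),
    lapply(1:6, function(m) {
      i <- (m - 1) %% 2 + 1; u <- (m - 1) %/% 2 + 1
      fv * ALLELE_COUNT[i, tt] * (uu == u)
    }),
    lapply(1:6, function(m) {
      t <- (m - 1) %% 3 + 1; k <- (m - 1) %/% 3 + 1
      fv * (tt == t) * ALLELE_COUNT[k, uu]
    }))
  W <- do.call(rbind, rows)
  rownames(W) <- c("mu", paste0("g1_", 1:3), paste0("g2_", 1:3),
                   paste0("a1_", 1:2), paste0("a2_", 1:2),
                   paste0("aa_", 1:4), paste0("ag_", 1:6),
                   paste0("ga_", 1:6))
  tot <- rowSums(W)
  undefined <- tot == 0
  W <- W / ifelse(undefined, 1, tot)
  W[undefined, ] <- 0
  attr(W, "undefined") <- undefined
  W
}

marginal_weight_matrix <- function(freqs) {
  freqs$W %||% build_weight_matrix(freqs$f)
}

# matrix product where an NA effect multiplied by a zero incidence
# contributes 0 (a non-estimable effect is never carried by that genotype);
# NA propagates only through non-zero incidences
na_safe_mm <- function(A, B) {
  A0 <- A; A0[is.na(A0)] <- 0
  B0 <- B; B0[is.na(B0)] <- 0
  P <- A0 %*% B0
  touch <- (is.na(A) * 1) %*% (B0 != 0) + (A0 != 0) %*% (is.na(B) * 1)
  P[touch > 0] <- NA_real_
  P
}

#' Frequency-weighted marginal means of genotypic values
#'
#' Computes the population mean and all marginal means entering the effect
#' partition. Genotype-indexed marginals weight each cell by its genotype
#' frequency; allele-indexed marginals additionally weight by the count of
#' the indexed allele carried by the genotype (so that the frequency-weighted
#' mean allelic effect is zero even under Hardy-Weinberg disequilibrium).
#'
#' @param g genotypic values: length-3 vector (one locus, order "11","12",
#'   "22") or 3 x 3 matrix (two loci, rows = locus 1).
#' @param freqs matching [genotype_freqs()] object.
#' @return A list of marginal means; undefined marginals (zero total weight)
#'   are `NA`.
#' @export
marginal_means <- function(g, freqs) {
  if (inherits(freqs, "genotype_freqs_1l")) {
    stopifnot(length(g) == 3)
    f <- freqs$f
    mu_allele <- vapply(1:2, function(i) wmean(g, ALLELE_COUNT[i, ] * f), 0)
    list(mu = wmean(g, f),
         mu_genotype = stats::setNames(ifelse(f > 0, g, NA_real_), GENO3),
         mu_allele = stats::setNames(mu_allele, ALLELES))
  } else if (inherits(freqs, "genotype_freqs_2l")) {
    stopifnot(is.matrix(g), all(dim(g) == c(3, 3)))
    W <- marginal_weight_matrix(freqs)
    gv <- as.vector(g)
    g0 <- ifelse(is.na(gv), 0, gv)
    vals <- drop(W %*% g0)
    # a marginal touching an NA cell with positive weight is undefined
    nag <- is.na(gv)
    if (any(nag)) vals[rowSums(W[, nag, drop = FALSE] != 0) > 0] <- NA_real_
    vals[attr(W, "undefined")] <- NA_real_   # zero-total-weight marginals
    m <- list(mu = vals[["mu"]])
    m$mu_g1 <- stats::setNames(vals[2:4], GENO3)
    m$mu_g2 <- stats::setNames(vals[5:7], GENO3)
    m$mu_a1 <- stats::setNames(vals[8:9], ALLELES)
    m$mu_a2 <- stats::setNames(vals[10:11], ALLELES)
    m$mu_aa <- matrix(vals[12:15], 2, 2, dimnames = list(ALLELES, ALLELES))
    m$mu_ag <- matrix(vals[16:21], 2, 3, dimnames = list(ALLELES, GENO3))
    m$mu_ga <- matrix(vals[22:27], 3, 2, dimnames = list(GENO3, ALLELES))
    m
  } else stop("freqs must come from genotype_freqs()")
}

#' Single-locus partition into allelic and dominance effects
#'
#' Decomposes the three genotypic values into the population mean, allelic
#' effects `a_i` (allelic marginal mean minus population mean) and dominance
#' values `d_ij` (genotypic value minus mean and allelic effects), under the
#' observed genotype frequencies. The scalar summaries are the additive
#' effect `alpha = a_1 - a_2` and the dominance effect
#' `delta = d_12 - 0.5 (d_11 + d_22)`.
#'
#' @param g length-3 genotypic values in genotype order "11", "12", "22"
#'   (code 0, 1, 2 = count of allele "2"); `NA` for an unobserved class.
#' @param freqs a `genotype_freqs_1l` object.
#' @return An object of class `effect_partition_1l`: `mu`, `a`, `d`,
#'   `alpha`, `delta`. Effects whose defining marginals are undefined
#'   (empty classes) are `NA`.
#' @examples
#' f <- genotype_freqs(c(0, 1, 1, 2))
#' partition_single_locus(c(1, 0, -1), f)
#' @export
partition_single_locus <- function(g, freqs) {
  stopifnot(inherits(freqs, "genotype_freqs_1l"), length(g) == 3)
  m <- marginal_means(g, freqs)
  a <- m$mu_allele - m$mu
  d <- g - m$mu - as.numeric(na_safe_mm(rbind(a), ALLELE_COUNT))
  d[freqs$f == 0] <- NA_real_
  names(d) <- GENO3
  structure(list(mu = m$mu, a = a, d = d,
                 alpha = additive_effect(a[[1]], a[[2]]),
                 delta = dominance_effect(d[[1]], d[[2]], d[[3]])),
            class = "effect_partition_1l")
}

#' Additive effect from two allelic effects
#'
#' `alpha = a_1 - a_2`, the difference between the allelic effects of
#' allele "1" and allele "2".
#' @param a1,a2 allelic effects.
#' @export
additive_effect <- function(a1, a2) a1 - a2

#' Dominance effect from three dominance values
#'
#' `delta = d_12 - 0.5 (d_11 + d_22)`: the heterozygote dominance value
#' minus the average of the two homozygote dominance values. Negative
#' `delta` with positive homozygote values is the homozygous-advantage /
#' heterozygous-disadvantage pattern.
#' @param d11,d12,d22 dominance values of the three genotypes.
#' @examples
#' dominance_effect(0.629, -1.280, 1.920)
#' @export
dominance_effect <- function(d11, d12, d22) d12 - 0.5 * (d11 + d22)

#' Two-locus partition into additive, dominance and epistasis values
#'
#' Sequential residual decomposition of the nine two-locus genotypic values:
#' each higher-order value is the corresponding frequency-weighted marginal
#' mean minus the population mean and all lower-order values it contains.
#' The classes are allelic effects (`a1`, `a2`), dominance values
#' (`d1`, `d2`), additive x additive (`aa`, 2 x 2 over allele pairs),
#' additive x dominance (`ad`, 2 x 3), dominance x additive (`da`, 3 x 2)
#' and dominance x dominance (`dd`, 3 x 3), satisfying the exact
#' reconstruction of every genotypic value from the sum of its terms.
#'
#' Scalar summaries are tensor-product contrasts of the class grids with the
#' additive coefficients (1, -1) over alleles and the dominance coefficients
#' (-1/2, 1, -1/2) over genotypes: `aa_effect`, `ad_effect`, `da_effect`,
#' `dd_effect` (alongside per-locus `alpha` and `delta`).
#'
#' @param g 3 x 3 matrix of genotypic values, rows = locus-1 genotypes
#'   "11","12","22", columns = locus-2 genotypes; `NA` for empty cells.
#' @param freqs a `genotype_freqs_2l` object.
#' @return An object of class `effect_partition_2l` with the full value
#'   grids, marginal means and scalar summary effects. Values whose
#'   defining marginals are empty are `NA`.
#' @export
partition_two_locus <- function(g, freqs) {
  stopifnot(inherits(freqs, "genotype_freqs_2l"),
            is.matrix(g), all(dim(g) == c(3, 3)))
  f <- freqs$f
  m <- marginal_means(g, freqs)
  a1 <- m$mu_a1 - m$mu
  a2 <- m$mu_a2 - m$mu
  asum1 <- as.numeric(na_safe_mm(rbind(a1), ALLELE_COUNT))  # per locus-1 genotype
  asum2 <- as.numeric(na_safe_mm(rbind(a2), ALLELE_COUNT))  # per locus-2 genotype
  d1 <- m$mu_g1 - m$mu - asum1
  d2 <- m$mu_g2 - m$mu - asum2
  aa <- m$mu_aa - m$mu - outer(a1, a2, `+`)
  # aa carried by a (genotype, allele-at-other-locus) combination
  aa_g1 <- t(na_safe_mm(t(aa), ALLELE_COUNT))  # [t, k] = sum_i cnt_i(t) aa[i,k]
  aa_g2 <- na_safe_mm(aa, ALLELE_COUNT)      # [i, u] = sum_k count_k(u) aa[i,k]
  ad <- m$mu_ag - m$mu - outer(a1, asum2, `+`) -
    matrix(d2, 2, 3, byrow = TRUE) - aa_g2
  da <- m$mu_ga - m$mu - outer(asum1, a2, `+`) -
    matrix(d1, 3, 2) - aa_g1
  lower <- m$mu + outer(asum1, asum2, `+`) +
    matrix(d1, 3, 3) + matrix(d2, 3, 3, byrow = TRUE) +
    na_safe_mm(aa_g1, ALLELE_COUNT) +
    na_safe_mm(t(ALLELE_COUNT), ad) + na_safe_mm(da, ALLELE_COUNT)
  dd <- g - lower
  dd[f == 0] <- NA_real_
  dimnames(dd) <- list(GENO3, GENO3)
  structure(list(
    mu = m$mu, marginals = m,
    a1 = a1, a2 = a2, d1 = d1, d2 = d2,
    aa = aa, ad = ad, da = da, dd = dd,
    alpha1 = additive_effect(a1[[1]], a1[[2]]),
    alpha2 = additive_effect(a2[[1]], a2[[2]]),
    delta1 = dominance_effect(d1[[1]], d1[[2]], d1[[3]]),
    delta2 = dominance_effect(d2[[1]], d2[[2]], d2[[3]]),
    aa_effect = tensor_contrast(aa, C_ADD, C_ADD),
    ad_effect = tensor_contrast(ad, C_ADD, C_DOM),
    da_effect = tensor_contrast(da, C_DOM, C_ADD),
    dd_effect = tensor_contrast(dd, C_DOM, C_DOM)),
    class = "effect_partition_2l")
}

tensor_contrast <- function(grid, c_row, c_col) {
  if (anyNA(grid)) return(NA_real_)
  drop(c_row %*% grid %*% c_col)
}

#' Contrast coefficient vector of a scalar effect over genotypic values
#'
#' Every scalar summary effect (alpha, delta, aa_effect, ad_effect,
#' da_effect, dd_effect) is, for fixed genotype frequencies, a linear
#' functional of the genotypic values. This returns its coefficient row
#' vector `s` such that `s %*% g` equals the effect computed by the
#' partition for any `g`. The coefficients are obtained constructively by
#' evaluating the partition on unit genotypic-value vectors, which is exact
#' because the partition is linear in `g`.
#'
#' @param effect_type one of `"A"`, `"D"` (with one-locus `freqs`) or
#'   `"AxA"`, `"AxD"`, `"DxA"`, `"DxD"` (with two-locus `freqs`).
#' @param freqs a [genotype_freqs()] object of matching arity.
#' @return A named numeric vector of length 3 (one locus) or 9 (two loci,
#'   column-major over the 3 x 3 genotype grid, locus 1 varying fastest),
#'   with attribute `effect_type`. Coefficients tied to empty genotype
#'   classes are 0 where the effect does not involve them, or the whole
#'   vector is `NA` when the effect is non-estimable under `freqs`.
#' @export
contrast_vector <- function(effect_type, freqs) {
  one <- inherits(freqs, "genotype_freqs_1l")
  ok <- if (one) effect_type %in% c("A", "D") else
    effect_type %in% c("AxA", "AxD", "DxA", "DxD")
  if (!ok) stop("effect_type ", effect_type, " incompatible with freqs arity")
  if (one) {
    s <- vapply(1:3, function(m) {
      g <- numeric(3); g[m] <- 1
      p <- partition_single_locus(g, freqs)
      if (effect_type == "A") p$alpha else p$delta
    }, 0)
    names(s) <- GENO3
  } else {
    s <- epistasis_contrasts(freqs)[effect_type, ]
  }
  attr(s, "effect_type") <- effect_type
  s
}

#' All four epistasis contrast vectors at once
#'
#' @param freqs a `genotype_freqs_2l` object.
#' @return 4 x 9 matrix with rows `AxA`, `AxD`, `DxA`, `DxD`; columns in
#'   column-major order over the 3 x 3 genotype grid.
#' @export
epistasis_contrasts <- function(freqs) {
  stopifnot(inherits(freqs, "genotype_freqs_2l"))
  S <- matrix(NA_real_, 4, 9,
              dimnames = list(c("AxA", "AxD", "DxA", "DxD"),
                              as.vector(outer(GENO3, GENO3, paste, sep = "/"))))
  for (m in 1:9) {
    g <- matrix(0, 3, 3); g[m] <- 1
    p <- partition_two_locus(g, freqs)
    S[, m] <- c(p$aa_effect, p$ad_effect, p$da_effect, p$dd_effect)
  }
  S
}

#' Reconstruct genotypic values from a two-locus partition
#'
#' Sums the mean, allelic, dominance and all epistasis values carried by
#' each of the nine genotypes; equals the original genotypic-value grid
#' exactly (the defining identity of the sequential residual partition).
#' @param part an `effect_partition_2l`.
#' @return 3 x 3 matrix of reconstructed genotypic values.
#' @export
reconstruct_two_locus <- function(part) {
  stopifnot(inherits(part, "effect_partition_2l"))
  asum1 <- as.numeric(na_safe_mm(rbind(part$a1), ALLELE_COUNT))
  asum2 <- as.numeric(na_safe_mm(rbind(part$a2), ALLELE_COUNT))
  aa_g1 <- t(na_safe_mm(t(part$aa), ALLELE_COUNT))
  part$mu + outer(asum1, asum2, `+`) +
    matrix(part$d1, 3, 3) + matrix(part$d2, 3, 3, byrow = TRUE) +
    na_safe_mm(aa_g1, ALLELE_COUNT) +
    na_safe_mm(t(ALLELE_COUNT), part$ad) + na_safe_mm(part$da, ALLELE_COUNT) +
    part$dd
}
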