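# Approximate generalized least squares scan machinery: phenotypes are
# pre-corrected by subtracting pedigree breeding values (2 x PTA), genotype
# class means are then fitted by ordinary least squares and effects are
# tested as t-contrasts of the fitted genotypic values.

#' Scan configuration
#'
#' @param maf_threshold minor-allele-frequency filter applied before
#'   scanning (fraction, default 0.05).
#' @param max_intra_distance_bp maximum base-pair distance between two SNPs
#'   on the same chromosome for the pair to be tested (default 3 Mb).
#' @param include_inter_chromosome also enumerate all between-chromosome
#'   pairs (off by default; pair count grows quadratically).
#' @param min_cell_count two-locus genotype cells with fewer individuals
#'   than this flag the pair's contrasts as unstable (default 5).
#' @param threshold_single,threshold_pairwise fixed log10(1/p) significance
#'   thresholds for single-locus (default 8) and pairwise (default 12)
#'   effects.
#' @param seed optional integer seed recorded with the scan.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(maf_threshold = 0.05,
                        max_intra_distance_bp = 3e6,
                        include_inter_chromosome = FALSE,
                        min_cell_count = 5,
                        threshold_single = 8,
                        threshold_pairwise = 12,
                        seed = NULL) {
  stopifnot(maf_threshold >= 0, maf_threshold <= 0.5,
            max_intra_distance_bp > 0, min_cell_count >= 0,
            threshold_single > 0, threshold_pairwise > 0)
  structure(list(maf_threshold = maf_threshold,
                 max_intra_distance_bp = max_intra_distance_bp,
                 include_inter_chromosome = include_inter_chromosome,
                 min_cell_count = min_cell_count,
                 threshold_single = threshold_single,
                 threshold_pairwise = threshold_pairwise,
                 seed = seed),
            class = "scan_config")
}

#' Correct phenotypes by removing pedigree breeding values
#'
#' Sets `y_star = y - 2 * pta`, the phenotype with the pedigree additive
#' (breeding) value removed; `2 * PTA` is the animal's estimated breeding
#' value from routine genetic evaluation. With one record per individual
#' the breeding-value incidence matrix is the identity, so the correction
#' is a plain subtraction.
#'
#' @param pheno data frame with columns `id`, `y`, `pta`.
#' @return The data frame with a `y_star` column added (or recomputed).
#' @export
correct_phenotypes <- function(pheno) {
  stopifnot(all(c("id", "y", "pta") %in% names(pheno)))
  if (anyDuplicated(pheno$id))
    stop("duplicated individual ids: ",
         paste(unique(pheno$id[duplicated(pheno$id)]), collapse = ", "))
  bad <- is.na(pheno$pta)
  if (any(bad))
    stop("missing PTA for individuals: ",
         paste(pheno$id[bad], collapse = ", "))
  pheno$y_star <- pheno$y - 2 * pheno$pta
  pheno
}

#' Least-squares fit of genotype class means
#'
#' Fits the corrected phenotypes to genotype classes by least squares with a
#' generalized inverse, i.e. the fitted genotypic values are the means of
#' the occupied classes and empty classes are `NA`. The residual variance is
#' `v2 = RSS / (n - k)` with `k` the rank of the class design (number of
#' occupied classes).
#'
#' @param y_star numeric corrected phenotypes.
#' @param classes factor of genotype classes (levels define the full class
#'   set, including possibly empty classes); `NA` entries are dropped
#'   together with their phenotypes (complete cases per test).
#' @return Object of class `agls_fit`: `g_hat` (named class means, `NA` for
#'   empty classes), `n_class`, `v2`, `n`, `k`, `df`.
#' @export
fit_genotype_classes <- function(y_star, classes) {
  stopifnot(is.factor(classes), length(y_star) == length(classes))
  ok <- !is.na(y_star) & !is.na(classes)
  y <- y_star[ok]; cl <- classes[ok]
  n_class <- table(cl)
  k <- sum(n_class > 0)
  if (k < 2) stop("fewer than 2 occupied genotype classes")
  sums <- tapply(y, cl, sum, default = NA_real_)
  g_hat <- as.numeric(sums) / as.numeric(n_class)
  names(g_hat) <- levels(cl)
  n <- length(y)
  fitted <- g_hat[as.integer(cl)]
  rss <- sum((y - fitted)^2)
  v2 <- if (n > k) rss / (n - k) else 0
  structure(list(g_hat = g_hat, n_class = as.numeric(n_class),
                 v2 = v2, n = n, k = k, df = n - k),
            class = "agls_fit")
}

# log10(1/p) for a two-sided t statistic, computed on the log scale to
# survive extreme t; capped at 320 to keep output finite
log10_inv_p_t <- function(tstat, df) {
  if (is.na(tstat) || df <= 0) return(NA_real_)
  lp <- stats::pt(abs(tstat), df = df, lower.tail = FALSE, log.p = TRUE) +
    log(2)
  min(320, max(0, -lp / log(10)))
}

#' t-test of a contrast of fitted genotypic values
#'
#' `L = s g_hat`, `var(L) = v2 * s (X'X)^- s'` where the generalized-inverse
#' cross-product submatrix for a class-means design is `diag(1/n_class)`;
#' `t = L / sqrt(var(L))` with `n - k` degrees of freedom, two-sided.
#'
#' @param fit an [fit_genotype_classes()] result.
#' @param s contrast coefficient vector over the fit's classes (e.g. from
#'   [contrast_vector()]); must annihilate constants.
#' @param effect_type label carried into the result.
#' @return One-row data frame: `effect_type`, `value`, `se`, `t`,
#'   `log10_inv_p`, `n`, `df`, `estimable`.
#' @export
test_effect <- function(fit, s, effect_type = attr(s, "effect_type")) {
  stopifnot(inherits(fit, "agls_fit"), length(s) == length(fit$g_hat))
  out <- data.frame(effect_type = effect_type %||% "contrast",
                    value = NA_real_, se = NA_real_, t = NA_real_,
                    log10_inv_p = NA_real_, n = fit$n, df = fit$df,
                    estimable = FALSE, stringsAsFactors = FALSE)
  active <- !is.na(s) & s != 0
  if (anyNA(s) || !any(active) || any(fit$n_class[active] == 0))
    return(out)
  L <- sum(s[active] * fit$g_hat[active])
  varL <- fit$v2 * sum(s[active]^2 / fit$n_class[active])
  out$value <- L
  out$estimable <- TRUE
  if (varL > 0 && fit$df > 0) {
    out$se <- sqrt(varL)
    out$t <- L / out$se
    out$log10_inv_p <- log10_inv_p_t(out$t, fit$df)
  } else if (varL == 0) {
    # noiseless fit: significance unbounded, reported at the cap
    out$se <- 0
    out$t <- if (L == 0) 0 else sign(L) * Inf
    out$log10_inv_p <- if (L == 0) 0 else 320
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# align phenotypes to genotype individual order; hard error on mismatches
align_phenotypes <- function(geno, pheno) {
  if (!"y_star" %in% names(pheno)) pheno <- correct_phenotypes(pheno)
  miss_g <- setdiff(geno$ids, pheno$id)
  miss_p <- setdiff(pheno$id, geno$ids)
  if (length(miss_g) || length(miss_p))
    stop("genotype/phenotype id mismatch; missing phenotypes: ",
         paste(utils::head(miss_g, 5), collapse = ", "),
         "; missing genotypes: ", paste(utils::head(miss_p, 5), collapse = ", "))
  pheno[match(geno$ids, pheno$id), , drop = FALSE]
}

#' Single-locus scan of additive and dominance effects
#'
#' For every SNP passing the MAF filter, fits the three genotype class means
#' of the corrected phenotypes, partitions them into allelic and dominance
#' effects under the observed genotype frequencies, and t-tests the additive
#' contrast `alpha` and the dominance contrast `delta`.
#'
#' @param geno a `genotype_matrix`.
#' @param pheno phenotype data frame (`id`, `y`, `pta`, optionally
#'   `y_star`); ids must match the genotype matrix exactly.
#' @param config a [scan_config()].
#' @return Data frame with two rows per testable SNP (effect types "A" and
#'   "D"), sorted by `log10_inv_p` descending with ties broken by
#'   chromosome and position. Columns include the contrast estimate, its
#'   standard error, t, log10(1/p), and the component allelic/dominance
#'   values and genotype/allele frequencies.
#' @export
scan_single_locus <- function(geno, pheno, config = scan_config()) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(config, "scan_config"))
  geno <- filter_maf(geno, config$maf_threshold)
  pheno <- align_phenotypes(geno, pheno)
  ys <- pheno$y_star
  rows <- vector("list", ncol(geno$codes))
  for (j in seq_len(ncol(geno$codes))) {
    rows[[j]] <- tryCatch({
      x <- geno$codes[, j]
      fr <- genotype_freqs(x[!is.na(ys)])
      cl <- factor(x, levels = 0:2, labels = c("11", "12", "22"))
      fit <- fit_genotype_classes(ys, cl)
      part <- partition_single_locus(fit$g_hat, fr)
      sA <- contrast_vector("A", fr)
      sD <- contrast_vector("D", fr)
      res <- rbind(test_effect(fit, sA), test_effect(fit, sD))
      cbind(data.frame(snp_id = geno$map$snp_id[j],
                       chr = geno$map$chr[j], pos = geno$map$pos[j],
                       stringsAsFactors = FALSE),
            res,
            data.frame(a1 = part$a[[1]], a2 = part$a[[2]],
                       p1 = fr$p[[1]], p2 = fr$p[[2]],
                       d11 = part$d[[1]], d12 = part$d[[2]], d22 = part$d[[3]],
                       f11 = fr$f[[1]], f12 = fr$f[[2]], f22 = fr$f[[3]]))
    }, error = function(e)
      data.frame(snp_id = geno$map$snp_id[j], chr = geno$map$chr[j],
                 pos = geno$map$pos[j], effect_type = c("A", "D"),
                 value = NA_real_, se = NA_real_, t = NA_real_,
                 log10_inv_p = NA_real_, n = NA_integer_, df = NA_integer_,
                 estimable = FALSE, a1 = NA_real_, a2 = NA_real_,
                 p1 = NA_real_, p2 = NA_real_, d11 = NA_real_,
                 d12 = NA_real_, d22 = NA_real_, f11 = NA_real_,
                 f12 = NA_real_, f22 = NA_real_, stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  sort_effect_table(out)
}

sort_effect_table <- function(tbl) {
  ord <- order(-ifelse(is.na(tbl$log10_inv_p), -Inf, tbl$log10_inv_p),
               tbl[[grep("^chr", names(tbl))[1]]],
               tbl[[grep("^pos", names(tbl))[1]]],
               tbl$snp_id %||% tbl$snp1)
  out <- tbl[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("effect_table", class(out))
  out
}

#' Enumerate SNP pairs for the pairwise scan
#'
#' Intra-chromosome pairs within the configured base-pair window, plus all
#' inter-chromosome pairs when enabled.
#' @param map SNP map data frame (`snp_id`, `chr`, `pos`).
#' @param config a [scan_config()].
#' @return Two-column integer matrix of column indices into the map.
#' @export
enumerate_pairs <- function(map, config = scan_config()) {
  m <- nrow(map)
  pairs <- list()
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    idx <- idx[order(map$pos[idx])]
    if (length(idx) < 2) next
    for (ii in seq_len(length(idx) - 1)) {
      d <- map$pos[idx] - map$pos[idx[ii]]
      jj <- which(d > 0 & d <= config$max_intra_distance_bp)
      if (length(jj))
        pairs[[length(pairs) + 1L]] <- cbind(idx[ii], idx[jj])
    }
  }
  if (config$include_inter_chromosome) {
    cmb <- utils::combn(m, 2)
    inter <- cmb[, map$chr[cmb[1, ]] != map$chr[cmb[2, ]], drop = FALSE]
    if (ncol(inter)) pairs[[length(pairs) + 1L]] <- t(inter)
  }
  if (!length(pairs)) return(matrix(integer(0), 0, 2))
  out <- do.call(rbind, pairs)
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Pairwise epistasis scan
#'
#' For every enumerated SNP pair, fits the nine two-locus genotype class
#' means of the corrected phenotypes, partitions them into the Kempthorne
#' value grids under the observed two-locus frequencies, and t-tests the
#' four epistasis contrasts (A x A, A x D, D x A, D x D).
#'
#' @inheritParams scan_single_locus
#' @return Data frame with up to four rows per pair, sorted by
#'   `log10_inv_p` descending. `flagged` marks contrasts touching occupied
#'   cells smaller than `min_cell_count`. The `components` list column
#'   carries the epistasis value grid of each tested effect.
#' @export
scan_pairwise <- function(geno, pheno, config = scan_config()) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(config, "scan_config"))
  geno <- filter_maf(geno, config$maf_threshold)
  pheno <- align_phenotypes(geno, pheno)
  ys <- pheno$y_star
  pairs <- enumerate_pairs(geno$map, config)
  rows <- vector("list", nrow(pairs))
  lab9 <- as.vector(outer(c("11", "12", "22"), c("11", "12", "22"),
                          paste, sep = "/"))
  for (r in seq_len(nrow(pairs))) {
    j1 <- pairs[r, 1]; j2 <- pairs[r, 2]
    rows[[r]] <- tryCatch({
      x1 <- geno$codes[, j1]; x2 <- geno$codes[, j2]
      keep <- !is.na(ys)
      fr <- genotype_freqs(x1[keep], x2[keep])
      cl <- factor(paste(c("11", "12", "22")[x1 + 1L],
                         c("11", "12", "22")[x2 + 1L], sep = "/"),
                   levels = lab9)
      cl[is.na(x1) | is.na(x2)] <- NA
      fit <- fit_genotype_classes(ys, cl)
      ghat <- matrix(fit$g_hat, 3, 3)
      part <- partition_two_locus(ghat, fr)
      S <- epistasis_contrasts(fr)
      grids <- list(AxA = part$aa, AxD = part$ad, DxA = part$da, DxD = part$dd)
      res <- do.call(rbind, lapply(rownames(S), function(ty) {
        s <- S[ty, ]; attr(s, "effect_type") <- ty
        out <- test_effect(fit, s)
        active <- !is.na(s) & s != 0
        out$flagged <- any(fit$n_class[active] > 0 &
                             fit$n_class[active] < config$min_cell_count)
        out
      }))
      res$components <- I(unname(grids))
      cbind(data.frame(snp1 = geno$map$snp_id[j1], chr1 = geno$map$chr[j1],
                       pos1 = geno$map$pos[j1],
                       snp2 = geno$map$snp_id[j2], chr2 = geno$map$chr[j2],
                       pos2 = geno$map$pos[j2], stringsAsFactors = FALSE),
            res)
    }, error = function(e) NULL)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) return(out)
  ord <- order(-ifelse(is.na(out$log10_inv_p), -Inf, out$log10_inv_p),
               out$chr1, out$pos1, out$chr2, out$pos2)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("effect_table", class(out))
  out
}

#' Genome-wide significance thresholds
#'
#' Returns both the fixed log10(1/p) threshold used for declaring effects
#' (defaults 8 single-locus, 12 pairwise) and the literal Bonferroni
#' quantity for `m` SNPs: `0.05 / (2 m)` for the two single-locus tests per
#' SNP, `0.05 / (4 m (m - 1) / 2)` for the four pairwise tests per pair.
#'
#' @param m number of SNPs after filtering.
#' @param mode `"single"` or `"pairwise"`.
#' @param config a [scan_config()] supplying the fixed thresholds.
#' @return List with `log10_inv_p` (fixed threshold) and `bonferroni_p`.
#' @export
significance_threshold <- function(m, mode = c("single", "pairwise"),
                                   config = scan_config()) {
  mode <- match.arg(mode)
  stopifnot(m >= 1)
  if (mode == "single")
    list(log10_inv_p = config$threshold_single,
         bonferroni_p = 0.05 / (2 * m))
  else
    list(log10_inv_p = config$threshold_pairwise,
         bonferroni_p = 0.05 / (4 * m * (m - 1) / 2))
}

#' Genotypic means of raw and corrected phenotypes per SNP
#'
#' For each requested SNP, the genotype-class means of the raw phenotype
#' `y` (breeding values not removed) and of the corrected phenotype
#' `y_star`, with flags for the homozygous-advantage pattern (a homozygote
#' class has the highest mean) and the heterozygous-disadvantage pattern
#' (the heterozygote class has the lowest mean), evaluated on both scales.
#'
#' @param geno a `genotype_matrix`.
#' @param pheno phenotype data frame with `y` and `pta` (or `y_star`).
#' @param snp_ids SNPs to evaluate (default: all).
#' @return Data frame, one row per SNP: `y_11, y_12, y_22, g_11, g_12,
#'   g_22, mu_y, mu_g` and the four pattern flags.
#' @export
genotypic_mean_validation <- function(geno, pheno, snp_ids = geno$map$snp_id) {
  stopifnot(inherits(geno, "genotype_matrix"))
  pheno <- align_phenotypes(geno, pheno)
  bad <- setdiff(snp_ids, geno$map$snp_id)
  if (length(bad)) stop("unknown SNPs: ", paste(bad, collapse = ", "))
  res <- lapply(snp_ids, function(id) {
    j <- match(id, geno$map$snp_id)
    x <- geno$codes[, j]
    mns <- function(v) vapply(0:2, function(cc) {
      ok <- !is.na(x) & x == cc & !is.na(v)
      if (any(ok)) mean(v[ok]) else NA_real_
    }, 0)
    ym <- mns(pheno$y); gm <- mns(pheno$y_star)
    # strict inequalities: ties (e.g. a constant field) are not a pattern
    flags <- function(m3) c(
      hom_adv = !anyNA(m3) && max(m3[c(1, 3)]) > m3[2],
      het_dis = !anyNA(m3) && m3[2] < min(m3[c(1, 3)]))
    fy <- flags(ym); fg <- flags(gm)
    data.frame(snp_id = id, chr = geno$map$chr[j], pos = geno$map$pos[j],
               y_11 = ym[1], y_12 = ym[2], y_22 = ym[3],
               g_11 = gm[1], g_12 = gm[2], g_22 = gm[3],
               mu_y = mean(pheno$y[!is.na(x)], na.rm = TRUE),
               mu_g = mean(pheno$y_star[!is.na(x)], na.rm = TRUE),
               hom_advantage_y = fy[["hom_adv"]],
               het_disadvantage_y = fy[["het_dis"]],
               hom_advantage_g = fg[["hom_adv"]],
               het_disadvantage_g = fg[["het_dis"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
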