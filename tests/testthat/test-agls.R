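test_that("phenotype correction subtracts twice the PTA", {
  ph <- data.frame(id = c("a", "b"), y = c(50, 60), pta = c(1, -2))
  out <- correct_phenotypes(ph)
  expect_equal(out$y_star, c(48, 64))
  ph$pta[2] <- NA
  expect_error(correct_phenotypes(ph), "b")
})

test_that("class-mean fit equals exact means and a pseudo-inverse solve", {
  y <- c(1, 1, 2, 2, 3, 3)
  cl <- factor(c("11", "11", "12", "12", "22", "22"),
               levels = c("11", "12", "22"))
  fit <- fit_genotype_classes(y, cl)
  expect_equal(unname(fit$g_hat), c(1, 2, 3))
  expect_equal(fit$v2, 0)
  expect_equal(fit$k, 3)

  # empty class: rank drops, NA estimate for the empty level
  fit2 <- fit_genotype_classes(c(1, 2, 1.5, 2.5),
                               factor(c("11", "11", "12", "12"),
                                      levels = c("11", "12", "22")))
  expect_equal(fit2$k, 2)
  expect_true(is.na(fit2$g_hat[["22"]]))

  # random instance against a direct normal-equation pseudo-inverse solve
  set.seed(71)
  for (i in 1:20) {
    y <- rnorm(40)
    cl <- factor(sample(c("11", "12", "22"), 40, TRUE),
                 levels = c("11", "12", "22"))
    fit <- fit_genotype_classes(y, cl)
    X <- stats::model.matrix(~ cl - 1)
    bh <- drop(MASS::ginv(crossprod(X)) %*% crossprod(X, y))
    expect_equal(unname(fit$g_hat), bh, tolerance = 1e-10)
    expect_equal(fit$v2, sum((y - X %*% bh)^2) / (40 - fit$k),
                 tolerance = 1e-10)
  }
  expect_error(fit_genotype_classes(rep(1, 3), factor(rep("11", 3),
                                                      levels = c("11", "12"))),
               "fewer than 2")
})

test_that("contrast t equals a hand-computed two-sample pooled t", {
  set.seed(72)
  y <- c(rnorm(15, 0), rnorm(12, 1))
  cl <- factor(rep(c("11", "22"), c(15, 12)), levels = c("11", "12", "22"))
  fit <- fit_genotype_classes(y, cl)
  s <- c(1, 0, -1)
  res <- test_effect(fit, s, "diff")
  tt <- stats::t.test(y[1:15], y[16:27], var.equal = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(10^(-res$log10_inv_p), tt$p.value, tolerance = 1e-8)
  # zero contrast of the estimate: t = 0, p = 1
  res0 <- test_effect(fit, c(0, 0, 0), "null")
  expect_false(res0$estimable)
  # contrast touching the empty class is non-estimable
  res1 <- test_effect(fit, c(1, -1, 0), "het")
  expect_false(res1$estimable)
})

test_that("with PTA = 0 the scan is plain least squares on raw phenotypes", {
  sim <- small_sim(seed = 101, n = 300, n_snps = 8)
  ph <- sim$pheno
  ph$pta <- 0
  ph$y_star <- NULL
  res <- scan_single_locus(sim$pop$geno, ph, scan_config())
  j <- match(res$snp_id[1], sim$pop$geno$map$snp_id)
  x <- sim$pop$geno$codes[, j]
  means <- tapply(ph$y, x, mean)
  row <- res[res$snp_id == res$snp_id[1] & res$effect_type == "A", ]
  fr <- genotype_freqs(x)
  sA <- contrast_vector("A", fr)
  expect_equal(row$value, sum(sA * means), tolerance = 1e-10)
})

test_that("single-locus scan recovers planted effects and ranks them first", {
  sim <- small_sim(seed = 103, n = 1500, sigma2_e = 25,
                   effects = list(list(type = "additive", scale = 2),
                                  list(type = "table2_dominance", scale = 1)))
  res <- scan_single_locus(sim$pop$geno, sim$pheno, scan_config())
  resA <- res[res$effect_type == "A", ]
  resD <- res[res$effect_type == "D", ]
  tr <- sim$truth
  expect_equal(resA$snp_id[1], tr$snp1[tr$type == "additive"])
  expect_equal(resD$snp_id[1], tr$snp1[tr$type == "table2_dominance"])
  rowA <- resA[1, ]; rowD <- resD[1, ]
  expect_lt(abs(rowA$value - tr$true_alpha[tr$type == "additive"]),
            2 * rowA$se)
  expect_lt(abs(rowD$value - tr$true_delta[tr$type == "table2_dominance"]),
            2 * rowD$se)
  # the dominance component values show the planted pattern
  expect_gt(rowD$d11, 0); expect_gt(rowD$d22, 0); expect_lt(rowD$d12, 0)
})

test_that("pairwise scan recovers planted epistasis with the right pattern", {
  sim <- small_sim(seed = 104, n = 1500, sigma2_e = 25,
                   effects = list(list(type = "fig8_dxd", scale = 5),
                                  list(type = "fig6_axa", scale = 3)))
  res <- scan_pairwise(sim$pop$geno, sim$pheno, scan_config())
  tr <- sim$truth
  dxd <- res[res$effect_type == "DxD", ]
  axa <- res[res$effect_type == "AxA", ]
  pr_d <- tr[tr$type == "fig8_dxd", ]
  pr_a <- tr[tr$type == "fig6_axa", ]
  expect_equal(unlist(dxd[1, c("snp1", "snp2")], use.names = FALSE),
               c(pr_d$snp1, pr_d$snp2))
  expect_equal(unlist(axa[1, c("snp1", "snp2")], use.names = FALSE),
               c(pr_a$snp1, pr_a$snp2))
  expect_equal(sign(axa$value[1]), sign(pr_a$true_aa))
  expect_lt(abs(dxd$value[1] - pr_d$true_dd), 2 * dxd$se[1])
  # fitted dominance x dominance grid: the four het-by-homo cells negative
  ddgrid <- dxd$components[[1]]
  expect_true(all(ddgrid[c(2, 4, 6, 8)] < 0))
})

test_that("per-SNP complete-case handling and missing genotypes", {
  geno <- tiny_geno()
  geno$codes[1, 1] <- NA
  ph <- data.frame(id = c("a", "b", "c"), y = c(1, 2, 3), pta = 0)
  # s1 has one missing genotype: fit uses 2 records, 2 occupied classes
  fr <- genotype_freqs(geno$codes[, 1])
  expect_equal(fr$n, 2)
  expect_error(scan_single_locus(geno, ph[1:2, ], scan_config()), "mismatch")
})

test_that("significance thresholds: fixed values and Bonferroni arithmetic", {
  thr <- significance_threshold(75133, "single")
  expect_equal(thr$log10_inv_p, 8)
  expect_equal(thr$bonferroni_p, 0.05 / (2 * 75133))
  thr2 <- significance_threshold(75133, "pairwise")
  expect_equal(thr2$log10_inv_p, 12)
  expect_equal(thr2$bonferroni_p, 0.05 / (2 * 75133 * 75132))
  expect_equal(thr2$bonferroni_p, 4.43e-12, tolerance = 1e-3)
})

test_that("permuted phenotypes yield nothing near the single-locus threshold", {
  sim <- small_sim(seed = 105, n = 400, n_snps = 30)
  ph <- sim$pheno
  set.seed(9)
  for (perm in 1:5) {
    idx <- sample(nrow(ph))
    php <- ph
    php$y <- ph$y[idx]; php$pta <- ph$pta[idx]; php$y_star <- ph$y_star[idx]
    res <- scan_single_locus(sim$pop$geno, php, scan_config())
    expect_lt(max(res$log10_inv_p, na.rm = TRUE), 8)
  }
})

test_that("genotypic-mean validation flags the planted dominance pattern", {
  sim <- small_sim(seed = 106, n = 1200, sigma2_e = 25,
                   effects = list(list(type = "table2_dominance", scale = 3)))
  snp <- sim$truth$snp1[1]
  val <- genotypic_mean_validation(sim$pop$geno, sim$pheno, snp)
  expect_true(val$hom_advantage_y)
  expect_true(val$het_disadvantage_y)
  expect_true(val$het_disadvantage_g)

  # constant phenotype: all means equal, no flags
  ph0 <- sim$pheno; ph0$y <- 5; ph0$pta <- 0; ph0$y_star <- 5
  val0 <- genotypic_mean_validation(sim$pop$geno, ph0, snp)
  expect_false(val0$hom_advantage_y)
  expect_false(val0$het_disadvantage_y)
  expect_equal(val0$y_11, val0$y_12)

  # overdominant anti-pattern: heterozygote best, so no disadvantage flag
  x <- sim$pop$geno$codes[, snp]
  ph1 <- sim$pheno
  ph1$y <- ifelse(x == 1, 10, 0) + rnorm(length(x), 0, 0.01)
  ph1$pta <- 0; ph1$y_star <- ph1$y
  val1 <- genotypic_mean_validation(sim$pop$geno, ph1, snp)
  expect_false(val1$het_disadvantage_y)
  expect_false(val1$hom_advantage_y)
})

test_that("pair enumeration respects the distance window and inter flag", {
  map <- data.frame(snp_id = paste0("s", 1:5),
                    chr = c("1", "1", "1", "2", "2"),
                    pos = c(1e5, 2e6, 9e6, 1e5, 5e5))
  cfg <- scan_config(max_intra_distance_bp = 3e6)
  prs <- enumerate_pairs(map, cfg)
  expect_equal(nrow(prs), 2)  # (1,2) on chr1 and (4,5) on chr2
  cfg2 <- scan_config(max_intra_distance_bp = 3e6,
                      include_inter_chromosome = TRUE)
  prs2 <- enumerate_pairs(map, cfg2)
  expect_equal(nrow(prs2), 2 + 6)
})
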