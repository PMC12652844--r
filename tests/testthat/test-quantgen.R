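test_that("genotype frequency counting, margins and degenerate input", {
  fr <- genotype_freqs(c(0, 1, 2, 1))
  expect_equal(unname(fr$f), c(0.25, 0.5, 0.25))
  expect_equal(fr$p[["1"]], 0.5)
  expect_error(genotype_freqs(c(NA_integer_, NA_integer_)), "non-missing")

  # perfectly correlated pair: off-diagonal two-locus cells empty
  x <- c(0, 0, 1, 1, 2, 2)
  fr2 <- genotype_freqs(x, x)
  expect_equal(sum(fr2$f), 1)
  expect_true(all(fr2$f[row(fr2$f) != col(fr2$f)] == 0))
  expect_equal(fr2$f1, fr2$f2)

  # margins of the joint table match per-locus tabulation
  set.seed(4)
  x1 <- sample(0:2, 50, TRUE); x2 <- sample(0:2, 50, TRUE)
  fr2 <- genotype_freqs(x1, x2)
  expect_equal(unname(fr2$f1), unname(genotype_freqs(x1)$f))
  expect_equal(unname(fr2$f2), unname(genotype_freqs(x2)$f))

  # at linkage equilibrium the joint table approaches the product measure
  set.seed(5)
  x1 <- rbinom(6000, 2, 0.4); x2 <- rbinom(6000, 2, 0.6)
  fr2 <- genotype_freqs(x1, x2)
  expect_lt(max(abs(fr2$f - outer(fr2$f1, fr2$f2))), 0.03)
})

test_that("marginal means match exhaustive enumeration on random instances", {
  set.seed(11)
  for (rep in 1:100) {
    fr <- rand_freqs2(allow_empty = rep > 60)
    g <- matrix(rnorm(9), 3)
    m <- marginal_means(g, fr)
    f <- fr$f
    # enumeration oracle for a representative of each marginal family
    expect_equal(m$mu, sum(f * g))
    num <- 0; den <- 0
    for (t in 1:3) for (u in 1:3) {
      w <- f[t, u] * ocnt(1, t)
      num <- num + w * g[t, u]; den <- den + w
    }
    expect_equal(m$mu_a1[["1"]], if (den > 0) num / den else NA_real_)
    num <- 0; den <- 0
    for (t in 1:3) for (u in 1:3) {
      w <- f[t, u] * ocnt(2, t) * ocnt(1, u)
      num <- num + w * g[t, u]; den <- den + w
    }
    expect_equal(m$mu_aa["2", "1"], if (den > 0) num / den else NA_real_)
    num <- 0; den <- 0
    for (t in 1:3) {
      w <- f[t, 2] * ocnt(1, t)
      num <- num + w * g[t, 2]; den <- den + w
    }
    expect_equal(m$mu_ag["1", "12"], if (den > 0) num / den else NA_real_)
  }
  # constant genotypic values: every defined marginal equals the constant
  fr <- rand_freqs2()
  m <- marginal_means(matrix(7, 3, 3), fr)
  expect_true(all(abs(unlist(m) - 7) < 1e-12))
})

test_that("single-locus partition reproduces published effect arithmetic", {
  # printed dominance-value triples and their delta (3-dp table precision)
  rows <- list(list(d = c(0.629, -1.280, 1.920), delta = -2.555),
               list(d = c(1.850, -0.846, 0.730), delta = -2.136),
               list(d = c(0.667, -0.854, 1.570), delta = -1.973))
  for (r in rows)
    expect_equal(dominance_effect(r$d[1], r$d[2], r$d[3]), r$delta,
                 tolerance = 5e-4)
  # printed allelic-effect pairs and their alpha
  expect_equal(additive_effect(0.966, -1.150), 2.116, tolerance = 5e-4)
  expect_equal(additive_effect(-1.350, 0.655), -2.005, tolerance = 5e-4)

  # the same numbers through the full partition: treat the dominance values
  # as genotypic values (delta is invariant to the additive part)
  fr <- genotype_freqs(c(rep(0, 5), rep(1, 4), rep(2, 2)))
  p <- partition_single_locus(c(0.629, -1.280, 1.920), fr)
  expect_equal(p$delta, -2.5545, tolerance = 1e-12)

  # purely additive genotypic values have no dominance deviation
  for (f3 in list(c(.25, .5, .25), c(.5, .3, .2))) {
    p <- partition_single_locus(c(0, 1.3, 2.6), freqs1(f3))
    expect_equal(p$delta, 0, tolerance = 1e-12)
  }

  # effects are deviations: frequency-weighted reconstruction recovers g
  set.seed(21)
  fr <- genotype_freqs(sample(0:2, 40, TRUE))
  g <- rnorm(3)
  p <- partition_single_locus(g, fr)
  recon <- p$mu + as.numeric(p$a %*% matrix(c(2, 1, 0, 0, 1, 2), 2,
                                            byrow = TRUE)) + p$d
  expect_equal(recon, g, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(sum(fr$f * (recon - p$mu)), 0, tolerance = 1e-12)
})

test_that("two-locus partition: reconstruction, zero-mean classes, oracle", {
  set.seed(31)
  for (rep in 1:200) {
    fr <- rand_freqs2(allow_empty = rep > 150)
    g <- matrix(rnorm(9, sd = 2), 3)
    g[fr$f == 0] <- NA
    p <- partition_two_locus(g, fr)
    b <- brute_partition_2l(g, fr$f)
    for (piece in c("mu", "a1", "a2", "d1", "d2", "aa", "ad", "da", "dd"))
      expect_equal(unclass(p[[piece]]), b[[piece]], ignore_attr = TRUE,
                   tolerance = 1e-9)
    occ <- fr$f > 0
    rec <- reconstruct_two_locus(p)
    expect_lt(max(abs(rec[occ] - g[occ])), 1e-10)
    # every frequency-weighted effect-class mean is zero
    f <- fr$f
    w_a1 <- sapply(1:2, function(i) sum(sweep(f, 1, ocnt(i, 1:3), `*`)))
    if (!anyNA(p$a1)) expect_equal(sum(w_a1 * p$a1), 0, tolerance = 1e-10)
    if (!anyNA(p$d1)) expect_equal(sum(rowSums(f) * p$d1), 0, tolerance = 1e-10)
    if (!anyNA(p$aa)) {
      w_aa <- outer(1:2, 1:2, Vectorize(function(i, k)
        sum(outer(ocnt(i, 1:3), ocnt(k, 1:3)) * f)))
      expect_equal(sum(w_aa * p$aa), 0, tolerance = 1e-10)
    }
    if (!anyNA(p$dd)) expect_equal(sum(f * p$dd), 0, tolerance = 1e-10)
  }
})

test_that("additive-only surfaces produce no interaction values at LE", {
  # at linkage equilibrium (Hardy-Weinberg disequilibrium allowed at each
  # locus) the lower-order terms absorb an additive surface entirely
  set.seed(41)
  for (rep in 1:20) {
    f1 <- rexp(3); f2 <- rexp(3)
    fr <- freqs2(outer(f1 / sum(f1), f2 / sum(f2)))
    g <- outer(rnorm(1) * c(0, 1, 2) + rnorm(1),
               rnorm(1) * c(0, 1, 2) + rnorm(1), `+`)
    p <- partition_two_locus(g, fr)
    expect_lt(max(abs(c(p$aa, p$ad, p$da, p$dd))), 1e-10)
    expect_equal(p$delta1, 0, tolerance = 1e-10)
  }
  # under LD an additive surface does leak into marginal interaction
  # values (the disequilibrium decomposition is not variance-orthogonal)
  set.seed(42)
  fr_ld <- freqs2(matrix(c(.3, .05, .02, .05, .25, .05, .02, .05, .21), 3))
  g <- outer(c(0, 1, 2), c(0, 2, 4), `+`)
  p_ld <- partition_two_locus(g, fr_ld)
  expect_gt(max(abs(p_ld$aa)), 1e-6)
})

test_that("planted dominance-by-dominance surface is recovered exactly", {
  # checkerboard in the span of the dominance x dominance contrast
  cD <- c(-0.5, 1, -0.5)
  fr <- freqs2(outer(c(.25, .5, .25), c(.3, .5, .2)))
  g <- 2 * outer(cD, cD)
  p <- partition_two_locus(g, fr)
  # at one locus in HWE the surface has no additive or one-locus dominance
  expect_lt(max(abs(p$a1)), 1e-10)
  expect_equal(sign(p$dd[c(2, 4, 6, 8)]), rep(-1, 4))  # het-homo cells
  expect_equal(p$dd_effect, 2 * 2.25, tolerance = 1e-10)
})

test_that("contrast vectors agree with the partition and kill constants", {
  set.seed(51)
  for (rep in 1:30) {
    fr <- rand_freqs2()
    S <- epistasis_contrasts(fr)
    expect_lt(max(abs(S %*% rep(1, 9))), 1e-10)
    for (i in 1:5) {
      g <- matrix(rnorm(9), 3)
      p <- partition_two_locus(g, fr)
      expect_equal(drop(S %*% as.vector(g)),
                   c(AxA = p$aa_effect, AxD = p$ad_effect,
                     DxA = p$da_effect, DxD = p$dd_effect),
                   tolerance = 1e-10)
    }
  }
  fr1 <- genotype_freqs(c(0, 0, 1, 1, 1, 2))
  sA <- contrast_vector("A", fr1)
  sD <- contrast_vector("D", fr1)
  expect_equal(unname(sD), c(-0.5, 1, -0.5), ignore_attr = TRUE)
  expect_equal(sum(sA), 0, tolerance = 1e-12)
  for (i in 1:50) {
    g <- rnorm(3)
    p <- partition_single_locus(g, fr1)
    expect_equal(sum(sA * g), p$alpha, tolerance = 1e-12)
    expect_equal(sum(sD * g), p$delta, tolerance = 1e-12)
  }
  expect_error(contrast_vector("AxA", fr1), "arity")
})

test_that("under HWE and LE the partition degenerates to textbook values", {
  # one locus, p = 1/2: g = (0,1,2) gives allelic effects -1/2, +1/2
  p <- partition_single_locus(c(0, 1, 2), freqs1(c(.25, .5, .25)))
  expect_equal(unname(p$a), c(-0.5, 0.5))
  expect_equal(p$alpha, -1)
  expect_equal(p$delta, 0)
  # two loci at LE, both HWE p = 1/2: additive surface, hand-computed
  fr <- freqs2(outer(c(.25, .5, .25), c(.25, .5, .25)))
  g <- outer(c(0, 1, 2), c(0, 2, 4), `+`)
  p2 <- partition_two_locus(g, fr)
  expect_equal(p2$mu, 1 + 2)
  expect_equal(unname(p2$a1), c(-0.5, 0.5))
  expect_equal(unname(p2$a2), c(-1, 1))
  expect_lt(max(abs(c(p2$d1, p2$d2, p2$aa, p2$ad, p2$da, p2$dd))), 1e-12)
  # under HWE + LE the per-cell value assignments of the effect classes
  # are mutually orthogonal under the f-weighted inner product
  set.seed(61)
  cnt <- matrix(c(2, 1, 0, 0, 1, 2), 2, byrow = TRUE)
  g <- matrix(rnorm(9), 3)
  p3 <- partition_two_locus(g, fr)
  cells <- list(
    add = outer(as.numeric(p3$a1 %*% cnt), as.numeric(p3$a2 %*% cnt), `+`),
    dom = matrix(p3$d1, 3, 3) + matrix(p3$d2, 3, 3, byrow = TRUE),
    aa = t(cnt) %*% p3$aa %*% cnt,
    ad = t(cnt) %*% p3$ad,
    da = p3$da %*% cnt,
    dd = p3$dd)
  for (i in seq_along(cells)) for (j in seq_along(cells)) {
    if (i >= j) next
    expect_lt(abs(sum(fr$f * cells[[i]] * cells[[j]])), 1e-12)
  }
})
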