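test_that("nested_F arithmetic and edge behaviour", {
  nf <- nested_F(0.2, 0.5, n_A = 2, n_B = 4, N = 25)
  expect_equal(nf$F, 6.0, tolerance = 1e-12) # (0.3/2) / (0.5/20)
  expect_equal(nf$df1, 2)
  expect_equal(nf$df2, 20)
  expect_equal(nested_F(0.3, 0.3, 1, 3, 20)$F, 0) # no improvement
  inf <- nested_F(0.5, 1, 1, 3, 20)
  expect_true(inf$infinite)
  expect_equal(inf$F, Inf)
  expect_error(nested_F(0.2, 0.5, 3, 3, 25), "n_B > n_A")
  expect_error(nested_F(0.2, 0.5, 1, 24, 25), "N - n_B - 1")
})

test_that("nested_F agrees with the RSS-based ANOVA F to 1e-10", {
  withr::with_seed(23, {
    for (i in 1:20) {
      N <- sample(15:40, 1)
      nA <- sample(1:3, 1)
      nB <- nA + sample(1:3, 1)
      X_B <- matrix(rnorm(N * nB), N, nB)
      X_A <- X_B[, seq_len(nA), drop = FALSE]
      y <- rnorm(N) + X_B %*% rnorm(nB) * 0.5
      F_pkg <- nested_F(multiple_R2(y, X_A), multiple_R2(y, X_B),
                        nA, nB, N)$F
      expect_equal(F_pkg, oracle_anova_F(y, X_A, X_B, N), tolerance = 1e-10)
    }
  })
})

test_that("analytic_F_pvalue matches a quadrature oracle on the F density", {
  f_density <- function(x, d1, d2) {
    exp(lgamma((d1 + d2) / 2) - lgamma(d1 / 2) - lgamma(d2 / 2) +
          (d1 / 2) * log(d1 / d2) + (d1 / 2 - 1) * log(x) -
          ((d1 + d2) / 2) * log(1 + d1 * x / d2))
  }
  p_quad <- integrate(f_density, 6, Inf, d1 = 2, d2 = 20)$value
  expect_equal(analytic_F_pvalue(6, 2, 20), p_quad, tolerance = 1e-8)
  expect_equal(analytic_F_pvalue(0, 3, 10), 1)
  expect_lt(analytic_F_pvalue(1e4, 3, 10), 1e-10)
})

test_that("block permutation preserves within-block LD and add-one bounds", {
  withr::with_seed(33, {
    N <- 60
    y <- rand_dosage(N)
    X_A <- cbind(rand_dosage(N))
    b <- rand_dosage(N)
    X_BmA <- cbind(b, b) # duplicated pair: mutual r2 = 1 by construction
    res <- block_permutation_pvalue(y, X_A, X_BmA, n_perm = 20, seed = 1)
    expect_gt(res$p, 0)
    expect_lte(res$p, 1)
    expect_length(res$F_perm, 20)
    # the joint permutation keeps the within-block duplicate structure:
    # if it does, F is a deterministic function of where the block lands,
    # and a one-column block must give identical F values
    res1 <- block_permutation_pvalue(y, X_A, cbind(b), n_perm = 20, seed = 1)
    # duplicated column adds no fit, only degrees of freedom:
    # F_dup = F_single * (df1_single / df1_dup) * (df2_dup / df2_single)
    expect_equal(res$F_perm, res1$F_perm * (1 / 2) * (res$df2 / res1$df2),
                 tolerance = 1e-9)
    # seeded reruns identical
    res2 <- block_permutation_pvalue(y, X_A, X_BmA, n_perm = 20, seed = 1)
    expect_identical(res, res2)
  })
})

test_that("run_stage2 on a constructed tag-in-B scenario finds the signal", {
  withr::with_seed(77, {
    sc <- stage2_scenario(linked = TRUE)
    N <- n_individuals(sc$g)
    m <- cbind(dosages(sc$g), r1 = sc$y)
    g <- genotype_matrix(m)
    # the constructed carrier set (12/400) needs a looser rare threshold
    vt <- variant_table(variant_id = colnames(m), chromosome = "1",
                        position = c(1000L, 2000L, 1500L),
                        maf = compute_maf(g),
                        rare_threshold = 0.04, common_threshold = 0.045)
    expect_equal(vt$var_class[vt$variant_id == "r1"], "rare")
    res <- run_stage2(g, vt, threshold_A = 0.80, threshold_B = 0.95,
                      n_perm = 99, seed = 5)
    expect_equal(nrow(res), 1)
    expect_equal(res$n_A, 1L)
    expect_equal(res$n_B, 2L)
    expect_gt(res$adjR2_B - res$adjR2_A, 0.3)
    expect_lt(res$p_permutation, 0.05)
    expect_gte(res$R2_B, res$R2_A)
  })
})

test_that("run_stage2 records n_B = n_A rows without tests and skips empty windows", {
  withr::with_seed(41, {
    n <- 60
    x <- rand_dosage(n, 0.3)
    r <- integer(n); r[1] <- 1L
    r_far <- integer(n); r_far[2] <- 1L
    m <- cbind(c1 = x, r1 = r, r2 = r_far)
    g <- genotype_matrix(m)
    vt <- variant_table(variant_id = colnames(m), chromosome = "1",
                        position = c(1000L, 2000L, 5000000L),
                        maf = compute_maf(g))
    res <- run_stage2(g, vt, n_perm = 10, seed = 1)
    expect_equal(res$rare_id, "r1")
    expect_true(is.na(res$F[res$rare_id == "r1"])) # single candidate: B = A
    expect_equal(attr(res, "skipped"), "r2") # no common within 0.5 Mb
  })
})

test_that("compare_stage2_distributions: identical and shifted samples", {
  res <- data.frame(adjR2_A = c(0.1, 0.2, 0.3, 0.4),
                    adjR2_B = c(0.1, 0.2, 0.3, 0.4))
  cmp <- compare_stage2_distributions(res)
  expect_equal(cmp$ks_statistic, 0)
  res2 <- data.frame(adjR2_A = seq(0, 0.3, length.out = 40),
                     adjR2_B = seq(0, 0.3, length.out = 40) +
                       seq(0.45, 0.55, length.out = 40))
  cmp2 <- compare_stage2_distributions(res2)
  expect_lt(cmp2$ks_p, 1e-6)
  expect_lt(cmp2$t_p, 1e-6)
  expect_equal(cmp2$ks_statistic,
               oracle_ks(res2$adjR2_A, res2$adjR2_B), tolerance = 1e-12)
})

test_that("nested-model consistency holds on random rank-deficient fits", {
  withr::with_seed(51, {
    for (i in 1:10) {
      N <- 30
      XA <- cbind(rand_dosage(N), rand_dosage(N))
      XB <- cbind(XA, XA[, 1], rand_dosage(N)) # aliased column inside B
      y <- rand_dosage(N)
      expect_gte(multiple_R2(y, XB) + 1e-12, multiple_R2(y, XA))
    }
  })
})
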