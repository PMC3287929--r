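test_that("make_bins uses floor((p - 1) / bin_size) with 1-based positions", {
  vt <- variant_table(variant_id = paste0("v", 1:6), chromosome = "1",
                      position = c(1L, 1000000L, 1000001L, 1999999L, 2000001L,
                                   2500000L),
                      maf = c(0.005, 0.2, 0.005, 0.2, 0.005, 0.2))
  bins <- make_bins(vt, 1e6)
  expect_length(bins, 3)
  expect_setequal(c(bins[[1]]$rare_ids, bins[[1]]$common_ids), c("v1", "v2"))
  expect_setequal(c(bins[[2]]$rare_ids, bins[[2]]$common_ids), c("v3", "v4"))
  expect_setequal(c(bins[[3]]$rare_ids, bins[[3]]$common_ids), c("v5", "v6"))
  expect_equal(bins[[1]]$start, 1L)
  expect_equal(bins[[1]]$end, 1000000L)
  expect_equal(bins[[2]]$start, 1000001L)
})

test_that("sample_rare_replicates follows the round(n_r/n_s) rule", {
  withr::with_seed(1, {
    reps <- sample_rare_replicates(paste0("r", 1:12), n_s = 5)
    expect_length(reps, 2) # round(2.4) = 2
    expect_true(all(lengths(reps) == 5))
    expect_true(all(unlist(reps) %in% paste0("r", 1:12)))
    expect_true(all(vapply(reps, anyDuplicated, 0L) == 0L)) # w/o replacement
    # ties round half-up: n_r = 15, n_s = 2 -> 8 replicates
    expect_length(sample_rare_replicates(paste0("r", 1:15), n_s = 2), 8)
    # small bin: one replicate of everything
    expect_equal(sample_rare_replicates(paste0("r", 1:3), n_s = 5),
                 list(paste0("r", 1:3)))
    expect_length(sample_rare_replicates(character(0), n_s = 5), 0)
  })
})

test_that("rare_allele_load and collapsing_indicator", {
  g <- genotype_matrix(cbind(r1 = c(0L, 1L, 0L, 2L), r2 = c(1L, 1L, 0L, 0L)))
  expect_equal(unname(rare_allele_load(g, "r1")$values), c(0, 1, 0, 2))
  expect_equal(unname(rare_allele_load(g, c("r1", "r2"))$values), c(1, 2, 0, 2))
  expect_equal(unname(collapsing_indicator(g, c("r1", "r2"))$values),
               c(1, 1, 0, 1))
  z <- genotype_matrix(matrix(0L, 4, 1, dimnames = list(NULL, "r0")))
  expect_equal(unname(collapsing_indicator(z, "r0")$values), rep(0, 4))
})

test_that("max_single_r2 takes the max over hand-computed correlations", {
  withr::with_seed(8, {
    g <- rand_genotypes(25, 3)
    y <- rand_dosage(25)
    by_hand <- sapply(1:3, function(j) oracle_r2(y, dosages(g)[, j]))
    got <- max_single_r2(y, g, variant_ids(g))
    expect_equal(got$r2, max(by_hand), tolerance = 1e-12)
    expect_equal(got$id, variant_ids(g)[which.max(by_hand)])
    # y equal to a common SNP's column -> 1 at that SNP
    got2 <- max_single_r2(dosages(g)[, 2], g, variant_ids(g))
    expect_equal(got2$r2, 1)
    # constant y -> defined as 0 with a warning
    expect_warning(res <- max_single_r2(rep(1, 25), g, variant_ids(g)),
                   "constant")
    expect_equal(res$r2, 0)
  })
})

test_that("multiple_R2 equals the normal-equations solve and handles edges", {
  withr::with_seed(13, {
    y <- rnorm(8)
    X <- matrix(rnorm(16), 8, 2)
    expect_equal(multiple_R2(y, X), oracle_R2(y, X), tolerance = 1e-12)
    # X containing y -> perfect fit
    expect_equal(multiple_R2(y, cbind(X, y)), 1)
    # no predictors -> intercept-only
    expect_equal(multiple_R2(y, NULL), 0)
    expect_equal(multiple_R2(y, matrix(numeric(0), 8, 0)), 0)
    expect_error(multiple_R2(rep(1, 8), X), "constant")
    # rank-deficient X: duplicated column changes nothing
    expect_equal(multiple_R2(y, cbind(X, X[, 1])), multiple_R2(y, X),
                 tolerance = 1e-12)
  })
})

test_that("multiple_R2 dominates any included single-SNP r2 and ignores recoding", {
  withr::with_seed(17, {
    for (i in 1:15) {
      n <- sample(10:40, 1)
      k <- sample(2:5, 1)
      X <- sapply(seq_len(k), function(j) rand_dosage(n))
      y <- rand_dosage(n)
      R2 <- multiple_R2(y, X)
      singles <- apply(X, 2, function(x)
        if (sd(x) == 0) 0 else oracle_r2(y, x))
      expect_gte(R2 + 1e-12, max(singles))
      # column order and affine recoding are irrelevant
      expect_equal(multiple_R2(y, X[, sample(k)]), R2, tolerance = 1e-10)
      expect_equal(multiple_R2(y, sweep(X * 2, 2, 1)), R2, tolerance = 1e-10)
    }
  })
})

test_that("adjusted_R2 formula, monotonicity and degeneracy", {
  expect_equal(adjusted_R2(0.5, N = 11, n = 4), 1 / 6, tolerance = 1e-12)
  expect_equal(adjusted_R2(1, N = 30, n = 5), 1)
  expect_equal(adjusted_R2(0, N = 30, n = 0), 0)
  # strictly decreasing in n for fixed R2 < 1
  vals <- sapply(0:8, function(n) adjusted_R2(0.4, N = 20, n = n))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals <= 0.4))
  expect_warning(expect_true(is.na(adjusted_R2(0.5, N = 5, n = 4))),
                 "degenerate")
})

test_that("run_stage1 bookkeeping on a toy single-bin dataset", {
  withr::with_seed(30, {
    n <- 60 # one carrier in 60 keeps rare MAF 1/120 below 0.01
    m <- cbind(sapply(1:6, function(j) rand_dosage(n, 0.3)),
               sapply(1:7, function(j) { v <- integer(n); v[sample(n, 1)] <- 1L; v }))
    colnames(m) <- c(paste0("c", 1:6), paste0("r", 1:7))
    g <- genotype_matrix(m)
    vt <- variant_table(variant_id = colnames(m), chromosome = "1",
                        position = sort(sample.int(9e5, 13)),
                        maf = compute_maf(g),
                        functional = c(rep("none", 6), rep("synonymous", 4),
                                       rep("nonsynonymous", 3)))
    labels <- population_labels(individual_ids(g), rep("popA", n))
    res <- run_stage1(g, vt, labels, n_s = 5, seed = 4, min_stratum_n = 20)
    # popA duplicates "all"; functional strata have fewer rares
    all_rows <- res[res$stratum == "all" & res$functional == "all", ]
    expect_equal(nrow(all_rows), round(7 / 5)) # n_r = 7 > n_s = 5
    expect_equal(unique(all_rows$n_r), 7)
    expect_equal(unique(all_rows$n_s_used), 5)
    syn_rows <- res[res$stratum == "all" & res$functional == "synonymous", ]
    expect_equal(unique(syn_rows$n_r), 4)
    expect_equal(unique(syn_rows$n_s_used), 4) # n_r <= n_s: all rares, once
    expect_true(all(res$multiple_R2 >= res$max_single_r2 - 1e-12))
    expect_true(all(res$adjusted_R2 <= res$multiple_R2 + 1e-12, na.rm = TRUE))
    # determinism: same seed, same table
    res2 <- run_stage1(g, vt, labels, n_s = 5, seed = 4, min_stratum_n = 20)
    expect_identical(res, res2)
    # with n_s >= n_r the single replicate makes results data-deterministic
    resA <- run_stage1(g, vt, labels, n_s = 7, seed = 1, min_stratum_n = 20,
                       stratify_functional = FALSE)
    resB <- run_stage1(g, vt, labels, n_s = 7, seed = 999, min_stratum_n = 20,
                       stratify_functional = FALSE)
    expect_equal(resA$multiple_R2, resB$multiple_R2)
  })
})

test_that("run_stage1 skips small strata with a warning", {
  withr::with_seed(31, {
    g <- rand_genotypes(30, 4)
    vt <- variant_table(variant_id = variant_ids(g), chromosome = "1",
                        position = c(100L, 200L, 300L, 400L),
                        maf = compute_maf(g))
    vt$var_class <- c("common", "common", "rare", "rare")
    labels <- population_labels(individual_ids(g),
                                rep(c("big", "tiny"), c(25, 5)))
    expect_warning(
      res <- run_stage1(g, vt, labels, min_stratum_n = 20, seed = 2,
                        recompute_class_in_stratum = FALSE,
                        stratify_functional = FALSE),
      "tiny")
    expect_false("tiny" %in% res$stratum)
    expect_true(all(c("all", "big") %in% res$stratum))
  })
})
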