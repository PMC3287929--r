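# Stage 2: per-rare-SNP nested comparison of tag sets A and B -- multiple
# and adjusted R2, nested-model F, analytic and block-permutation p-values.

#' Nested-model F statistic for the gain of set B over set A
#'
#' For tag sets A inside B with `n_A` and `n_B` SNPs and multiple
#' correlations `R2_A <= R2_B`:
#' `F = ((R2_B - R2_A) / (n_B - n_A)) / ((1 - R2_B) / (N - n_B - 1))`,
#' the standard nested-regression F with degrees of freedom
#' `(n_B - n_A, N - n_B - 1)`. `R2_B = 1` yields an infinite F, flagged
#' via the `infinite` element.
#'
#' @param R2_A,R2_B multiple R2 of the smaller and larger model.
#' @param n_A,n_B numbers of SNPs in sets A and B (`n_B > n_A`).
#' @param N number of individuals (`N - n_B - 1 >= 1`).
#' @return list with `F`, `df1`, `df2`, `infinite`.
#' @export
#' @examples
#' nested_F(0.2, 0.5, n_A = 2, n_B = 4, N = 25)$F # 6
nested_F <- function(R2_A, R2_B, n_A, n_B, N) {
  if (n_B <= n_A) stop("nested_F: need n_B > n_A (no added SNPs to test)")
  if (N - n_B - 1 < 1) stop("nested_F: need N - n_B - 1 >= 1")
  if (R2_B < R2_A - 1e-12) stop("nested_F: R2_B < R2_A violates nesting")
  df1 <- n_B - n_A
  df2 <- N - n_B - 1
  if (R2_B >= 1)
    return(list(F = Inf, df1 = df1, df2 = df2, infinite = TRUE))
  Fv <- ((R2_B - R2_A) / df1) / ((1 - R2_B) / df2)
  list(F = max(Fv, 0), df1 = df1, df2 = df2, infinite = FALSE)
}

#' Upper-tail p-value of the F distribution
#'
#' @param F observed F statistic (>= 0).
#' @param df1,df2 degrees of freedom (>= 1).
#' @return `P(F(df1, df2) >= F)`.
#' @export
analytic_F_pvalue <- function(F, df1, df2) {
  if (F < 0 || df1 < 1 || df2 < 1) stop("analytic_F_pvalue: invalid arguments")
  stats::pf(F, df1, df2, lower.tail = FALSE)
}

#' Block-permutation p-value for the nested-model F
#'
#' The analytic F test asks whether adding the B \ A SNPs helps at all;
#' the block permutation asks whether the help comes from their LD with
#' the response rather than from their number. Each replicate applies one
#' shared row permutation jointly to every column of `X_BminusA` --
#' preserving the LD structure within the block while breaking its
#' association with `y` and `X_A` -- and recomputes F with `X_A` fixed.
#' The p-value uses the add-one estimator
#' `(1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`, so it is never 0.
#'
#' @param y response vector (the rare SNP's dosage).
#' @param X_A dosage matrix of set A (may have 0 columns).
#' @param X_BminusA dosage matrix of the added SNPs (>= 1 column).
#' @param n_perm number of permutation replicates (study setting: 1000).
#' @param seed optional seed applied via a temporary RNG state; when NULL
#'   the current RNG state is used.
#' @return list with `p`, `F_obs`, `F_perm` (length `n_perm`), `df1`,
#'   `df2`.
#' @export
block_permutation_pvalue <- function(y, X_A, X_BminusA, n_perm = 1000,
                                     seed = NULL) {
  if (n_perm < 1) stop("block_permutation_pvalue: n_perm must be >= 1")
  X_A <- if (is.null(X_A)) matrix(numeric(0), nrow = length(y), ncol = 0)
         else as.matrix(X_A)
  X_BminusA <- as.matrix(X_BminusA)
  if (ncol(X_BminusA) < 1) stop("block_permutation_pvalue: empty B \\ A block")
  N <- length(y)
  n_A <- ncol(X_A)
  n_B <- n_A + ncol(X_BminusA)
  R2_A <- fit_R2(y, X_A)$R2
  stat <- function(Xb) {
    R2_B <- fit_R2(y, cbind(X_A, Xb))$R2
    nested_F(R2_A, R2_B, n_A, n_B, N)$F
  }
  F_obs <- stat(X_BminusA)
  run <- function() {
    vapply(seq_len(n_perm), function(i) {
      perm <- sample.int(N)
      stat(X_BminusA[perm, , drop = FALSE])
    }, numeric(1))
  }
  F_perm <- if (is.null(seed)) run() else with_seed(seed, run())
  list(p = (1 + sum(F_perm >= F_obs)) / (1 + n_perm),
       F_obs = F_obs, F_perm = F_perm,
       df1 = n_B - n_A, df2 = N - n_B - 1)
}

#' Run the stage-2 per-rare-SNP tag-set comparison
#'
#' For every rare-class variant: select the common SNPs within a window
#' around it ([window_select()]), build the nested tag sets A and B at the
#' given pairwise r2 ceilings ([build_tag_sets()]), regress the rare SNP's
#' own dosage vector on each set, and test the gain of B over A with the
#' nested F -- analytically and against the block-permutation null. Rare
#' SNPs with an empty window are skipped (counted in the `skipped`
#' attribute); those with `n_B = n_A` are recorded with F and p-values
#' absent; models with `df2 < 1` are flagged degenerate and excluded from
#' testing.
#'
#' @param g a [genotype_matrix()] (perfect-LD duplicates removed).
#' @param variants a [variant_table()].
#' @param threshold_A,threshold_B pairwise r2 ceilings; the study's pairs
#'   are (0.80, 0.95) and (0.95, 0.99).
#' @param window_bp total window width around each rare SNP (default 1 Mb).
#' @param n_perm block-permutation replicates (default 1000).
#' @param seed master seed; each rare SNP gets a derived stream.
#' @return `data.frame`, one row per analysed rare SNP: `rare_id`,
#'   `threshold_A`, `threshold_B`, `n_A`, `n_B`, `R2_A`, `R2_B`,
#'   `adjR2_A`, `adjR2_B`, `F`, `df1`, `df2`, `p_analytic`,
#'   `p_permutation`, `n_permutations`, `degenerate_flag`. Attribute
#'   `skipped` lists rare ids with empty windows.
#' @export
run_stage2 <- function(g, variants, threshold_A = 0.80, threshold_B = 0.95,
                       window_bp = 1e6, n_perm = 1000, seed = 1) {
  rare_ids <- variants$variant_id[variants$var_class == "rare"]
  rare_ids <- intersect(rare_ids, variant_ids(g))
  N <- n_individuals(g)
  m <- dosages(g)
  rows <- list()
  skipped <- character(0)
  for (rid in rare_ids) {
    cands <- window_select(variants, rid, width = window_bp)
    cands <- cands[cands %in% colnames(m)]
    cands <- cands[apply(m[, cands, drop = FALSE], 2, stats::sd) > 0]
    if (length(cands) == 0) {
      skipped <- c(skipped, rid)
      rt_log("run_stage2: rare SNP %s has empty window; skipped", rid)
      next
    }
    ts <- build_tag_sets(g, cands, threshold_A, threshold_B,
                         focal_rare_id = rid)
    y <- m[, rid]
    if (stats::sd(y) == 0) { skipped <- c(skipped, rid); next }
    X_A <- m[, ts$set_A, drop = FALSE]
    X_B <- m[, ts$set_B, drop = FALSE]
    R2_A <- fit_R2(y, X_A)$R2
    R2_B <- fit_R2(y, X_B)$R2
    adjA <- if (N - ts$n_A - 1 > 0) adjusted_R2(R2_A, N, ts$n_A) else NA_real_
    adjB <- if (N - ts$n_B - 1 > 0) adjusted_R2(R2_B, N, ts$n_B) else NA_real_
    degenerate <- (N - ts$n_B - 1) < 1
    Fv <- df1 <- df2 <- p_an <- p_perm <- NA_real_
    if (!degenerate && ts$n_B > ts$n_A) {
      nf <- nested_F(R2_A, R2_B, ts$n_A, ts$n_B, N)
      Fv <- nf$F; df1 <- nf$df1; df2 <- nf$df2
      p_an <- if (nf$infinite) 0 else analytic_F_pvalue(nf$F, nf$df1, nf$df2)
      bp <- block_permutation_pvalue(
        y, X_A, m[, setdiff(ts$set_B, ts$set_A), drop = FALSE],
        n_perm = n_perm, seed = derive_seed(seed, "stage2-perm", rid))
      p_perm <- bp$p
    }
    rows[[length(rows) + 1L]] <- data.frame(
      rare_id = rid, threshold_A = threshold_A, threshold_B = threshold_B,
      n_A = ts$n_A, n_B = ts$n_B, R2_A = R2_A, R2_B = R2_B,
      adjR2_A = adjA, adjR2_B = adjB, F = Fv, df1 = df1, df2 = df2,
      p_analytic = p_an, p_permutation = p_perm,
      n_permutations = if (is.na(p_perm)) NA_integer_ else as.integer(n_perm),
      degenerate_flag = degenerate, stringsAsFactors = FALSE)
  }
  out <- if (length(rows) == 0) {
    data.frame(rare_id = character(0), threshold_A = numeric(0),
               threshold_B = numeric(0), n_A = integer(0), n_B = integer(0),
               R2_A = numeric(0), R2_B = numeric(0), adjR2_A = numeric(0),
               adjR2_B = numeric(0), F = numeric(0), df1 = numeric(0),
               df2 = numeric(0), p_analytic = numeric(0),
               p_permutation = numeric(0), n_permutations = integer(0),
               degenerate_flag = logical(0))
  } else do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}

#' Compare the adjusted R2 distributions of sets A and B across rare SNPs
#'
#' Two-sample Kolmogorov-Smirnov test on the `adjR2_A` vs `adjR2_B`
#' samples, plus a paired t test (the samples are per-rare-SNP pairs).
#'
#' @param results a [run_stage2()] table with >= 2 non-degenerate rows.
#' @return one-row `data.frame`: `n`, `mean_adjR2_A`, `mean_adjR2_B`,
#'   `ks_statistic`, `ks_p`, `t_p`.
#' @export
compare_stage2_distributions <- function(results) {
  keep <- !is.na(results$adjR2_A) & !is.na(results$adjR2_B)
  a <- results$adjR2_A[keep]
  b <- results$adjR2_B[keep]
  if (length(a) < 2) stop("compare_stage2_distributions: need >= 2 records")
  ks <- suppressWarnings(stats::ks.test(a, b))
  t_p <- tryCatch(stats::t.test(a, b, paired = TRUE)$p.value,
                  error = function(e) NA_real_)
  data.frame(n = length(a), mean_adjR2_A = mean(a), mean_adjR2_B = mean(b),
             ks_statistic = unname(ks$statistic), ks_p = ks$p.value, t_p = t_p)
}
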