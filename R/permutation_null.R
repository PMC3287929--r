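# Stage-1 permutation null and distribution-level comparisons.

#' Permute each common SNP within a bin across individuals
#'
#' Each column is permuted independently across rows, destroying both the
#' SNP-load association and the SNP-SNP LD inside the bin while preserving
#' every column's multiset of dosages (hence its MAF). Uses the current
#' RNG state; the input is not modified.
#'
#' @param X dosage matrix (individuals x common SNPs).
#' @return matrix of the same shape with independently shuffled columns.
#' @export
permute_common_within_bin <- function(X) {
  X <- as.matrix(X)
  if (length(X) == 0) stop("permute_common_within_bin: empty matrix")
  apply(X, 2, sample)
}

#' Stage-1 null run with within-bin permutation
#'
#' Identical pipeline to [run_stage1()] but with every bin's common SNPs
#' permuted across individuals before correlation. The same master seed
#' drives the rare-SNP sampling streams, so the null rows are paired with
#' the observed rows replicate by replicate and the contrast is
#' attributable purely to the permutation.
#'
#' @inheritParams run_stage1
#' @param ... passed to [run_stage1()].
#' @return as [run_stage1()].
#' @export
null_stage1 <- function(g, variants, labels, seed = 1, ...) {
  run_stage1(g, variants, labels, seed = seed, null = TRUE, ...)
}

#' Compare observed and null correlation distributions
#'
#' Two-sample Kolmogorov-Smirnov test plus a Welch two-sample t test on
#' the means, as used to decide whether observed bin correlations exceed
#' statistical noise. Identical degenerate samples give a KS statistic of
#' 0 and an undefined (NA) t p-value.
#'
#' @param observed,null numeric vectors (length >= 2; NAs dropped).
#' @param statistic_name,stratum labels carried into the result.
#' @return one-row `data.frame` of class `null_comparison`: `stratum`,
#'   `statistic_name`, `n_observed`, `n_null`, `mean_observed`,
#'   `mean_null`, `ks_statistic`, `ks_p`, `t_p`.
#' @export
compare_distributions <- function(observed, null, statistic_name = "statistic",
                                  stratum = "all") {
  observed <- observed[!is.na(observed)]
  null <- null[!is.na(null)]
  if (length(observed) < 2 || length(null) < 2)
    stop("compare_distributions: both samples must have >= 2 values")
  ks <- suppressWarnings(stats::ks.test(observed, null))
  t_p <- tryCatch(stats::t.test(observed, null)$p.value,
                  error = function(e) NA_real_)
  out <- data.frame(stratum = stratum, statistic_name = statistic_name,
                    n_observed = length(observed), n_null = length(null),
                    mean_observed = mean(observed), mean_null = mean(null),
                    ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
                    t_p = t_p, stringsAsFactors = FALSE)
  class(out) <- c("null_comparison", class(out))
  out
}

#' Observed-vs-null comparison table across stage-1 strata
#'
#' Pairs an observed [run_stage1()] table with its [null_stage1()]
#' counterpart and emits one [compare_distributions()] row per
#' (stratum, functional, statistic). Adjusted R2 is compared on
#' non-degenerate rows only; it may legitimately be negative under the
#' null.
#'
#' @param observed,null result tables from [run_stage1()] /
#'   [null_stage1()] run with the same seed and settings.
#' @param statistics which result columns to compare.
#' @return `data.frame`, one row per (stratum, functional, statistic).
#' @export
compare_stage1_null <- function(observed, null,
                                statistics = c("max_single_r2", "multiple_R2",
                                               "adjusted_R2")) {
  combos <- unique(observed[, c("stratum", "functional")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    so <- observed$stratum == combos$stratum[i] &
      observed$functional == combos$functional[i]
    sn <- null$stratum == combos$stratum[i] &
      null$functional == combos$functional[i]
    for (stat in statistics) {
      o <- observed[[stat]][so]
      n <- null[[stat]][sn]
      if (sum(!is.na(o)) < 2 || sum(!is.na(n)) < 2) next
      cmp <- compare_distributions(o, n, statistic_name = stat,
                                   stratum = combos$stratum[i])
      cmp$functional <- combos$functional[i]
      rows[[length(rows) + 1L]] <- cmp
    }
  }
  out <- do.call(rbind, rows)
  out[, c("stratum", "functional", "statistic_name", "n_observed", "n_null",
          "mean_observed", "mean_null", "ks_statistic", "ks_p", "t_p")]
}
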