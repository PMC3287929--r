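# Stage 1: per-bin correlation between common SNPs and the number (or
# presence) of rare alleles carried by each individual.

#' Partition classified variants into fixed non-overlapping genomic bins
#'
#' A variant at 1-based position p on a chromosome falls in bin index
#' `floor((p - 1) / bin_size)`, so positions 1..bin_size share bin 0.
#' Bins containing no classified variant are omitted.
#'
#' @param variants a [variant_table()].
#' @param bin_size bin width in base pairs (default 1 Mb).
#' @return list of bins; each is a list with `chromosome`, `start`, `end`
#'   (half-open, 0-based multiples of `bin_size` + 1 for start), `rare_ids`
#'   and `common_ids` in position order.
#' @export
make_bins <- function(variants, bin_size = 1e6) {
  if (bin_size <= 0) stop("make_bins: bin_size must be positive")
  idx <- floor((variants$position - 1) / bin_size)
  key <- paste(variants$chromosome, idx, sep = ":")
  out <- lapply(split(seq_len(nrow(variants)), key), function(rows) {
    v <- variants[rows, ]
    v <- v[order(v$position), ]
    b <- idx[rows][1]
    list(chromosome = v$chromosome[1],
         start = as.integer(b * bin_size + 1),
         end = as.integer((b + 1) * bin_size),
         rare_ids = v$variant_id[v$var_class == "rare"],
         common_ids = v$variant_id[v$var_class == "common"])
  })
  ord <- order(vapply(out, `[[`, "", "chromosome"),
               vapply(out, `[[`, 0L, "start"))
  unname(out[ord])
}

#' Random rare-SNP subsets for a bin
#'
#' With `n_r` rare SNPs in the bin: if `n_r > n_s`, draws
#' `round(n_r / n_s)` (closest integer, ties half-up) independent
#' without-replacement samples of size `n_s`; if `0 < n_r <= n_s`, one
#' replicate containing every rare SNP; if `n_r = 0`, no replicates.
#' Uses the current RNG state.
#'
#' @param bin a bin from [make_bins()], or a character vector of rare ids.
#' @param n_s sample size per replicate (study setting: 5).
#' @return list of character vectors of rare ids.
#' @export
sample_rare_replicates <- function(bin, n_s = 5) {
  if (n_s < 1) stop("sample_rare_replicates: n_s must be >= 1")
  rare_ids <- if (is.list(bin)) bin$rare_ids else as.character(bin)
  n_r <- length(rare_ids)
  if (n_r == 0) return(list())
  if (n_r <= n_s) return(list(rare_ids))
  n_rep <- floor(n_r / n_s + 0.5) # closest integer, ties half-up
  lapply(seq_len(n_rep), function(i) sample(rare_ids, n_s))
}

#' Per-individual rare-allele load
#'
#' Count mode: `y_i` is the total number of rare alleles individual `i`
#' carries across the sampled rare SNPs (sum of dosages). Collapse mode
#' ([collapsing_indicator()]): the burden-style indicator that at least
#' one rare allele is present.
#'
#' @param g a [genotype_matrix()].
#' @param rare_ids non-empty set of rare variant ids.
#' @return list of class `rare_allele_load` with `values` (length-N named
#'   vector), `mode` and `sampled_rare_ids`.
#' @export
rare_allele_load <- function(g, rare_ids) {
  if (length(rare_ids) == 0) stop("rare_allele_load: empty rare_ids")
  y <- rowSums(dosages(g)[, rare_ids, drop = FALSE])
  structure(list(values = y, mode = "count", sampled_rare_ids = rare_ids),
            class = "rare_allele_load")
}

#' @rdname rare_allele_load
#' @export
collapsing_indicator <- function(g, rare_ids) {
  load <- rare_allele_load(g, rare_ids)
  load$values <- as.numeric(load$values > 0)
  load$mode <- "collapse"
  load
}

#' Maximum single-SNP r2 with a rare-allele load
#'
#' The first stage-1 correlation measure: the Pearson correlation between
#' `y` and each common SNP's dosage, squared, taking the maximum. A
#' constant `y` (no carriers in the stratum) yields a defined-as-0 result
#' with a warning rather than an error, so low-MAF strata are not dropped.
#'
#' @param y a [rare_allele_load()] or numeric vector.
#' @param g a [genotype_matrix()].
#' @param common_ids non-empty common variant ids.
#' @return list with `r2` (the maximum) and `id` (the argmax common SNP,
#'   `NA` when `y` is constant).
#' @export
max_single_r2 <- function(y, g, common_ids) {
  if (length(common_ids) == 0) stop("max_single_r2: empty common_ids")
  yv <- if (inherits(y, "rare_allele_load")) y$values else y
  if (stats::sd(yv) == 0) {
    warning("max_single_r2: constant y; defined as 0")
    return(list(r2 = 0, id = NA_character_))
  }
  m <- dosages(g)[, common_ids, drop = FALSE]
  r2 <- drop(suppressWarnings(stats::cor(yv, m)))^2
  r2[is.na(r2)] <- 0 # monomorphic-in-stratum predictors carry no signal
  j <- which.max(r2)
  list(r2 = unname(r2[j]), id = common_ids[j])
}

# least-squares fit with intercept; pivoted QR drops aliased columns, so
# rank-deficient X still yields the projection onto its column space and
# R2 is well defined (and nested models stay nested).
fit_R2 <- function(y, X) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("fit_R2: constant response")
  if (is.null(X) || NCOL(X) == 0) return(list(R2 = 0, rss = tss, rank = 0L))
  X <- as.matrix(X)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  rss <- sum(fit$residuals^2)
  list(R2 = min(max(1 - rss / tss, 0), 1), rss = rss, rank = fit$rank - 1L)
}

#' Multiple correlation R2 of a response on a set of dosage columns
#'
#' Coefficient of determination of the least-squares fit of `y` on `X`
#' with an intercept. Rank-deficient `X` is handled by pivoted QR: the
#' fitted values are still the projection onto the column space, so R2
#' remains well defined and nested models remain nested. Zero predictors
#' give the intercept-only R2 of 0.
#'
#' @param y numeric response of length N >= 2, non-constant.
#' @param X numeric matrix with N rows (0 or more columns).
#' @return R2 in `[0, 1]`.
#' @export
multiple_R2 <- function(y, X) {
  yv <- if (inherits(y, "rare_allele_load")) y$values else y
  if (length(yv) <= 1) stop("multiple_R2: need N >= 2")
  if (!is.null(X) && NCOL(X) > 0 && NROW(X) != length(yv))
    stop("multiple_R2: nrow(X) must equal length(y)")
  fit_R2(yv, X)$R2
}

#' Adjusted R2
#'
#' `1 - (1 - R2) * (N - 1) / (N - n - 1)`, penalising R2 for the number
#' `n` of explanatory SNPs in the regression. Can be negative. When
#' `N - n - 1 <= 0` the model is degenerate: the result is `NA` with a
#' warning so callers can flag rather than report it.
#'
#' @param R2 coefficient of determination.
#' @param N number of individuals.
#' @param n number of predictors (e.g. `n_A` or `n_B`).
#' @return adjusted R2 (`<= R2`), or `NA` if degenerate.
#' @export
#' @examples
#' adjusted_R2(0.5, N = 11, n = 4) # 1/6
adjusted_R2 <- function(R2, N, n) {
  if (N - n - 1 <= 0) {
    warning("adjusted_R2: N - n - 1 <= 0; degenerate model")
    return(NA_real_)
  }
  1 - (1 - R2) * (N - 1) / (N - n - 1)
}

# one stage-1 replicate: correlations of y against the bin's common SNPs
stage1_replicate <- function(g, sampled_rare_ids, common_ids, mode, N) {
  load <- if (mode == "collapse") collapsing_indicator(g, sampled_rare_ids)
          else rare_allele_load(g, sampled_rare_ids)
  y <- load$values
  n_common <- length(common_ids)
  constant_y <- stats::sd(y) == 0
  degenerate <- n_common >= N - 2
  if (constant_y) {
    max_r2 <- 0; R2 <- 0
  } else {
    max_r2 <- suppressWarnings(max_single_r2(y, g, common_ids)$r2)
    R2 <- multiple_R2(y, dosages(g)[, common_ids, drop = FALSE])
  }
  # constant y keeps the defined-as-0 convention through the adjustment
  adj <- if (degenerate) NA_real_
         else if (constant_y) 0
         else adjusted_R2(R2, N, n_common)
  list(max_single_r2 = max_r2, multiple_R2 = R2, adjusted_R2 = adj,
       n_common = n_common, constant_y = constant_y, degenerate = degenerate)
}

#' Run the stage-1 bin-correlation analysis
#'
#' For each stratum (`"all"` plus each subpopulation with at least
#' `min_stratum_n` individuals) and each functional stratum (`"all"`,
#' `"synonymous"`, `"nonsynonymous"`), rare and common classes are
#' (optionally) recomputed within the stratum, variants are binned, rare
#' subsets are drawn per [sample_rare_replicates()], and per replicate the
#' maximum single-SNP r2, the multiple R2 over the bin's common SNPs and
#' its adjusted form are computed. Bins lacking rare or common SNPs are
#' skipped. When `null = TRUE` the bin's common dosage columns are
#' permuted (independently per column, per replicate) before correlation;
#' the rare samples are shared with the observed run through seed
#' derivation, so observed and null rows are paired by replicate.
#'
#' @param g a [genotype_matrix()] (perfect-LD duplicates already removed).
#' @param variants a [variant_table()] with functional labels.
#' @param labels a [population_labels()] table covering `g`.
#' @param bin_size bin width in bp (default 1 Mb).
#' @param n_s rare SNPs per sample (default 5, the study setting).
#' @param mode `"count"` (number of rare alleles) or `"collapse"`
#'   (presence indicator).
#' @param rare_threshold,common_threshold MAF class boundaries.
#' @param stratify_subpop,stratify_functional include per-subpopulation /
#'   per-functional-class strata in addition to `"all"`.
#' @param recompute_class_in_stratum recompute MAF and classes within each
#'   subpopulation stratum (default) or reuse the global classes.
#' @param min_stratum_n strata smaller than this are skipped with a
#'   warning (default 20).
#' @param seed master seed; all sampling streams derive from it.
#' @param null permute common SNPs within each bin before correlating.
#' @return `data.frame` with one row per
#'   (stratum, functional, bin, replicate): columns `stratum`,
#'   `functional`, `chrom`, `bin_start`, `bin_end` (1-based inclusive),
#'   `replicate`, `n_r`, `n_s_used`, `n_common`, `max_single_r2`,
#'   `multiple_R2`, `adjusted_R2`, `constant_y_flag`, `degenerate_flag`,
#'   `mode`, `sampled_rare_ids` (comma-joined).
#' @export
run_stage1 <- function(g, variants, labels, bin_size = 1e6, n_s = 5,
                       mode = c("count", "collapse"),
                       rare_threshold = 0.01, common_threshold = 0.05,
                       stratify_subpop = TRUE, stratify_functional = TRUE,
                       recompute_class_in_stratum = TRUE,
                       min_stratum_n = 20, seed = 1, null = FALSE) {
  mode <- match.arg(mode)
  check_labels(g, labels)
  strata <- "all"
  if (stratify_subpop) strata <- c(strata, sort(unique(labels$subpopulation)))
  fun_strata <- "all"
  if (stratify_functional) fun_strata <- c(fun_strata, "synonymous", "nonsynonymous")
  rows <- list()
  for (stratum in strata) {
    inds <- if (stratum == "all") individual_ids(g)
            else labels$individual_id[labels$subpopulation == stratum]
    if (length(inds) < min_stratum_n) {
      warning(sprintf("run_stage1: stratum '%s' has %d < %d individuals; skipped",
                      stratum, length(inds), min_stratum_n))
      next
    }
    gs <- subset_genotypes(g, individuals = inds)
    vs <- variants
    if (stratum != "all" && recompute_class_in_stratum) {
      maf_s <- compute_maf(gs)[vs$variant_id]
      keep_class <- vs$var_class == "excluded_perfect_ld"
      cls <- classify_variants(maf_s, rare_threshold, common_threshold)
      vs$maf <- maf_s
      vs$var_class <- ifelse(keep_class, vs$var_class, cls)
    }
    N <- n_individuals(gs)
    for (fun in fun_strata) {
      vf <- vs
      if (fun != "all") {
        drop <- vf$var_class == "rare" & vf$functional != fun
        vf$var_class[drop] <- "neither"
      }
      bins <- make_bins(vf[vf$var_class %in% c("rare", "common"), , drop = FALSE],
                        bin_size)
      for (bin in bins) {
        if (length(bin$rare_ids) == 0 || length(bin$common_ids) == 0) next
        bin_key <- paste(bin$chromosome, bin$start, sep = ":")
        samples <- with_seed(
          derive_seed(seed, "stage1-sample", stratum, fun, bin_key),
          sample_rare_replicates(bin, n_s))
        for (k in seq_along(samples)) {
          gb <- gs
          if (null) {
            perm_seed <- derive_seed(seed, "stage1-perm", stratum, fun, bin_key, k)
            Xp <- with_seed(perm_seed,
              permute_common_within_bin(dosages(gs)[, bin$common_ids, drop = FALSE]))
            m2 <- dosages(gs)
            m2[, bin$common_ids] <- Xp
            gb <- genotype_matrix(m2)
          }
          rep_res <- stage1_replicate(gb, samples[[k]], bin$common_ids, mode, N)
          rows[[length(rows) + 1L]] <- data.frame(
            stratum = stratum, functional = fun, chrom = bin$chromosome,
            bin_start = bin$start, bin_end = bin$end, replicate = k,
            n_r = length(bin$rare_ids), n_s_used = length(samples[[k]]),
            n_common = rep_res$n_common,
            max_single_r2 = rep_res$max_single_r2,
            multiple_R2 = rep_res$multiple_R2,
            adjusted_R2 = rep_res$adjusted_R2,
            constant_y_flag = rep_res$constant_y,
            degenerate_flag = rep_res$degenerate,
            mode = mode,
            sampled_rare_ids = paste(samples[[k]], collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(stratum = character(0), functional = character(0),
                      chrom = character(0), bin_start = integer(0),
                      bin_end = integer(0), replicate = integer(0),
                      n_r = integer(0), n_s_used = integer(0),
                      n_common = integer(0), max_single_r2 = numeric(0),
                      multiple_R2 = numeric(0), adjusted_R2 = numeric(0),
                      constant_y_flag = logical(0), degenerate_flag = logical(0),
                      mode = character(0), sampled_rare_ids = character(0)))
  do.call(rbind, rows)
}
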