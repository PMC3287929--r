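# Genotype container, minor allele frequency, variant classification and
# removal of perfect-LD duplicates.

#' Construct a genotype matrix
#'
#' The substrate of every statistic in the package: an N individuals x M
#' variants matrix of minor-allele dosages in \{0, 1, 2\}. Row and column
#' names carry the individual and variant identifiers and must be unique.
#'
#' @param dosages integer-valued matrix, individuals in rows, variants in
#'   columns, entries in \{0, 1, 2\} with no missing values.
#' @param individual_ids,variant_ids optional identifier vectors; default to
#'   existing dimnames or generated `ind###` / `var###` labels.
#' @return an object of class `genotype_matrix` (a named dosage matrix).
#' @export
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 0, 0, 1), nrow = 3))
#' n_individuals(g)
genotype_matrix <- function(dosages, individual_ids = NULL, variant_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (anyNA(dosages)) stop("genotype_matrix: missing dosages; impute at load time")
  if (!all(dosages %in% 0:2)) stop("genotype_matrix: dosages must be in {0,1,2}")
  individual_ids <- individual_ids %||% rownames(dosages) %||%
    sprintf("ind%03d", seq_len(nrow(dosages)))
  variant_ids <- variant_ids %||% colnames(dosages) %||%
    sprintf("var%03d", seq_len(ncol(dosages)))
  if (anyDuplicated(individual_ids)) stop("genotype_matrix: duplicated individual ids")
  if (anyDuplicated(variant_ids)) stop("genotype_matrix: duplicated variant ids")
  if (length(individual_ids) != nrow(dosages) || length(variant_ids) != ncol(dosages))
    stop("genotype_matrix: id lengths do not match matrix dimensions")
  dimnames(dosages) <- list(as.character(individual_ids), as.character(variant_ids))
  class(dosages) <- c("genotype_matrix", class(dosages))
  dosages
}

#' @rdname genotype_matrix
#' @param g a `genotype_matrix`.
#' @export
dosages <- function(g) {
  m <- unclass(g)
  class(m) <- setdiff(class(m), "genotype_matrix")
  m
}

#' @rdname genotype_matrix
#' @export
n_individuals <- function(g) nrow(g)

#' @rdname genotype_matrix
#' @export
variant_ids <- function(g) colnames(g)

#' @rdname genotype_matrix
#' @export
individual_ids <- function(g) rownames(g)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants\n", nrow(x), ncol(x)))
  invisible(x)
}

# subset keeping class and dimnames
subset_genotypes <- function(g, individuals = NULL, variants = NULL) {
  m <- dosages(g)
  if (!is.null(individuals)) m <- m[individuals, , drop = FALSE]
  if (!is.null(variants)) m <- m[, variants, drop = FALSE]
  genotype_matrix(m)
}

#' Minor allele frequency per variant
#'
#' With `p` the frequency of the allele the dosage counts
#' (`sum(dosage) / (2N)`), the MAF is `min(p, 1 - p)`, so the result is
#' always in `[0, 0.5]` even when a column is not minor-oriented.
#'
#' @param g a [genotype_matrix()].
#' @return named numeric vector of MAF per variant.
#' @export
compute_maf <- function(g) {
  p <- colMeans(dosages(g)) / 2
  pmin(p, 1 - p)
}

#' Classify variants as rare, common, neither or monomorphic
#'
#' Rare means `0 < maf < rare_threshold`; common means
#' `maf > common_threshold`; a MAF of exactly zero is monomorphic.
#' Intermediate-frequency variants (including MAF exactly equal to either
#' threshold) are classified `neither` and take part in no analysis.
#'
#' @param maf numeric vector of minor allele frequencies in `[0, 0.5]`.
#' @param rare_threshold,common_threshold class boundaries; the defaults
#'   (0.01 and 0.05) are the study's settings.
#' @return character vector over
#'   `c("rare", "common", "neither", "monomorphic")`.
#' @export
#' @examples
#' classify_variants(c(0, 0.009, 0.03, 0.30))
classify_variants <- function(maf, rare_threshold = 0.01, common_threshold = 0.05) {
  if (!(rare_threshold > 0 && rare_threshold <= common_threshold &&
        common_threshold < 0.5))
    stop("classify_variants: need 0 < rare_threshold <= common_threshold < 0.5")
  if (any(maf < 0 | maf > 0.5, na.rm = TRUE))
    stop("classify_variants: maf outside [0, 0.5]")
  out <- rep("neither", length(maf))
  out[maf == 0] <- "monomorphic"
  out[maf > 0 & maf < rare_threshold] <- "rare"
  out[maf > common_threshold] <- "common"
  out
}

#' Build a variant table
#'
#' Per-variant metadata driving binning, window selection and
#' stratification: position, MAF, class and functional annotation.
#'
#' @param variant_id,chromosome,position parallel vectors; positions are
#'   1-based base pairs.
#' @param maf minor allele frequencies (see [compute_maf()]).
#' @param var_class classes (see [classify_variants()]); computed from
#'   `maf` when omitted.
#' @param functional `"synonymous"`, `"nonsynonymous"` or `"none"`.
#' @param rare_threshold,common_threshold passed to [classify_variants()]
#'   when `var_class` is omitted.
#' @return a `data.frame` with one row per variant.
#' @export
variant_table <- function(variant_id, chromosome, position, maf,
                          var_class = NULL, functional = "none",
                          rare_threshold = 0.01, common_threshold = 0.05) {
  position <- as.integer(position)
  if (any(position < 1L)) stop("variant_table: positions must be positive")
  if (anyDuplicated(paste(chromosome, position, variant_id)))
    stop("variant_table: (chromosome, position, variant_id) must be unique")
  if (anyDuplicated(variant_id)) stop("variant_table: duplicated variant ids")
  var_class <- var_class %||%
    classify_variants(maf, rare_threshold, common_threshold)
  functional <- rep_len(functional, length(variant_id))
  ok <- functional %in% c("synonymous", "nonsynonymous", "none")
  if (!all(ok)) stop("variant_table: bad functional label(s)")
  data.frame(variant_id = as.character(variant_id),
             chromosome = as.character(chromosome),
             position = position, maf = maf,
             var_class = var_class, functional = functional,
             stringsAsFactors = FALSE)
}

#' Remove variants in perfect LD
#'
#' Among each group of variants whose pairwise dosage r-squared equals 1
#' (within `tol`), only the earliest by (chromosome, position, variant_id)
#' is retained -- or by current column order when no variant table is
#' supplied. Monomorphic variants have undefined r2 and are left untouched.
#'
#' @param g a [genotype_matrix()].
#' @param variants optional [variant_table()]; when given, scan order is
#'   (chromosome, position, variant_id) and excluded rows are re-classed
#'   `excluded_perfect_ld` in the returned table.
#' @param tol tolerance on `1 - r2` for "perfect".
#' @return list with elements `genotypes` (reduced matrix), `excluded`
#'   (character vector of removed ids) and, if supplied, the updated
#'   `variants` table.
#' @export
remove_perfect_ld <- function(g, variants = NULL, tol = 1e-12) {
  ids <- variant_ids(g)
  ord <- seq_along(ids)
  if (!is.null(variants)) {
    vt <- variants[match(ids, variants$variant_id), ]
    ord <- order(vt$chromosome, vt$position, vt$variant_id)
  }
  m <- dosages(g)
  sds <- apply(m, 2, stats::sd)
  poly <- ids[ord][sds[ord] > 0]
  excluded <- character(0)
  if (length(poly) >= 2) {
    cc <- suppressWarnings(stats::cor(m[, poly, drop = FALSE]))
    r2 <- cc^2
    keep <- logical(length(poly))
    for (j in seq_along(poly)) {
      prev <- which(keep)
      keep[j] <- !(length(prev) > 0 && any(r2[prev, j] >= 1 - tol, na.rm = TRUE))
    }
    excluded <- poly[!keep]
  }
  kept_ids <- setdiff(ids, excluded)
  out <- list(genotypes = subset_genotypes(g, variants = kept_ids),
              excluded = excluded)
  if (!is.null(variants)) {
    variants$var_class[variants$variant_id %in% excluded] <- "excluded_perfect_ld"
    out$variants <- variants
  }
  out
}

#' Population labels
#'
#' @param individual_id,subpopulation parallel vectors; every individual
#'   carries exactly one label.
#' @return a `data.frame` with columns `individual_id`, `subpopulation`.
#' @export
population_labels <- function(individual_id, subpopulation) {
  if (anyDuplicated(individual_id)) stop("population_labels: duplicated individuals")
  data.frame(individual_id = as.character(individual_id),
             subpopulation = as.character(subpopulation),
             stringsAsFactors = FALSE)
}

# check labels cover a genotype matrix exactly once
check_labels <- function(g, labels) {
  miss <- setdiff(individual_ids(g), labels$individual_id)
  if (length(miss) > 0)
    stop("population labels missing for: ", paste(utils::head(miss, 5), collapse = ", "))
  invisible(TRUE)
}
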