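# Pairwise LD, windows around a focal variant, and greedy construction of
# the nested tag-SNP sets A and B under pairwise r2 ceilings.

#' Pairwise LD as squared Pearson correlation of dosages
#'
#' Composite (genotypic) LD: the square of the Pearson product-moment
#' correlation between two unphased dosage vectors. This is the r2 used
#' throughout the package -- for perfect-LD removal, tag-set pruning and
#' reporting.
#'
#' @param x,y dosage vectors of equal length >= 3; both must be
#'   non-constant (exclude monomorphic variants first).
#' @return r2 in `[0, 1]`.
#' @export
#' @examples
#' pairwise_r2(c(0, 0, 1, 1), c(2, 2, 1, 1)) # perfect linear relation -> 1
pairwise_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("pairwise_r2: vectors must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pairwise_r2: correlation undefined for a constant vector")
  r2 <- stats::cor(x, y)^2
  min(max(r2, 0), 1)
}

#' Common variants within a window around a focal variant
#'
#' Returns the ids of common-class variants on the focal chromosome with
#' `|position - focal_position| <= width / 2`, excluding the focal variant
#' itself, ordered by position. The default 1 Mb total width reads
#' "within a 1 Mb region" as a centered window of +/- 500 kb.
#'
#' @param variants a [variant_table()].
#' @param focal_id id of the focal (typically rare) variant.
#' @param width total window width in base pairs.
#' @return character vector of variant ids (possibly empty).
#' @export
window_select <- function(variants, focal_id, width = 1e6) {
  if (width <= 0) stop("window_select: width must be positive")
  i <- match(focal_id, variants$variant_id)
  if (is.na(i)) stop("window_select: focal variant not in table")
  sel <- variants$var_class == "common" &
    variants$chromosome == variants$chromosome[i] &
    abs(variants$position - variants$position[i]) <= width / 2 &
    variants$variant_id != focal_id
  v <- variants[sel, ]
  v$variant_id[order(v$position)]
}

#' Build nested tag-SNP sets A and B under pairwise r2 ceilings
#'
#' Greedy forward selection in position order. First pass: a candidate
#' enters set A if its maximum r2 with the current members of A is at most
#' `threshold_A`. Second pass over the rejected candidates, again in
#' position order: one enters B \ A if its maximum r2 with the current
#' members of B (A plus any B \ A members accepted so far) is at most
#' `threshold_B`. Then B = A plus B \ A, so A is always a subset of B and
#' both sets satisfy their pairwise ceilings.
#'
#' The exact maximal-set problem is NP-hard and the choice of pruning
#' order is a convention; position-order greedy selection is deterministic
#' and standard tag-SNP practice.
#'
#' @param g a [genotype_matrix()] containing all candidates.
#' @param candidate_ids candidate common-variant ids in position order;
#'   must be non-constant with no perfect-LD pairs (see
#'   [remove_perfect_ld()]).
#' @param threshold_A,threshold_B pairwise r2 ceilings with
#'   `threshold_A < threshold_B < 1`. The study's pairs are (0.80, 0.95)
#'   and (0.95, 0.99).
#' @param focal_rare_id optional id recorded on the result.
#' @return an object of class `tag_set_pair`: list with `focal_rare_id`,
#'   `set_A`, `set_B`, `threshold_A`, `threshold_B`, `n_A`, `n_B`.
#' @export
build_tag_sets <- function(g, candidate_ids, threshold_A = 0.80,
                           threshold_B = 0.95, focal_rare_id = NA_character_) {
  if (!(threshold_A < threshold_B && threshold_B < 1))
    stop("build_tag_sets: need threshold_A < threshold_B < 1")
  candidate_ids <- as.character(candidate_ids)
  if (length(candidate_ids) == 0) {
    out <- list(focal_rare_id = focal_rare_id, set_A = character(0),
                set_B = character(0), threshold_A = threshold_A,
                threshold_B = threshold_B, n_A = 0L, n_B = 0L)
    class(out) <- "tag_set_pair"
    return(out)
  }
  m <- dosages(g)[, candidate_ids, drop = FALSE]
  r2 <- suppressWarnings(stats::cor(m))^2
  in_A <- logical(length(candidate_ids))
  for (j in seq_along(candidate_ids)) {
    prev <- which(in_A)
    in_A[j] <- !(length(prev) > 0 && max(r2[prev, j]) > threshold_A)
  }
  in_B <- in_A
  for (j in which(!in_A)) {
    members <- which(in_B)
    if (max(r2[members, j]) <= threshold_B) in_B[j] <- TRUE
  }
  set_A <- candidate_ids[in_A]
  set_B <- candidate_ids[in_B]
  out <- list(focal_rare_id = focal_rare_id, set_A = set_A, set_B = set_B,
              threshold_A = threshold_A, threshold_B = threshold_B,
              n_A = length(set_A), n_B = length(set_B))
  class(out) <- "tag_set_pair"
  out
}

#' @export
print.tag_set_pair <- function(x, ...) {
  cat(sprintf("tag_set_pair (focal %s): |A| = %d at r2 <= %.2f, |B| = %d at r2 <= %.2f\n",
              x$focal_rare_id, x$n_A, x$threshold_A, x$n_B, x$threshold_B))
  invisible(x)
}

#' Pairwise r2 table for a set of variants
#'
#' Audit helper: all pairs (id1, id2, r2) among the given variants.
#'
#' @param g a [genotype_matrix()].
#' @param ids variant ids (default all).
#' @return a `data.frame` with columns `id1`, `id2`, `r2`.
#' @export
ld_table <- function(g, ids = variant_ids(g)) {
  m <- dosages(g)[, ids, drop = FALSE]
  cc <- suppressWarnings(stats::cor(m))^2
  idx <- which(upper.tri(cc), arr.ind = TRUE)
  data.frame(id1 = ids[idx[, 1]], id2 = ids[idx[, 2]],
             r2 = cc[idx], stringsAsFactors = FALSE)
}
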