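# File interchange: VCF (via VariantAnnotation), dosage-matrix TSV,
# annotation / population / truth TSVs.

#' Write genotypes to a minimal VCF
#'
#' Emits VCF v4.2 with biallelic placeholder alleles (REF `A`, ALT `C`)
#' and a single `GT` FORMAT field; dosage 0/1/2 maps to `0/0`, `0/1`,
#' `1/1`. The ALT allele is the allele the dosage counts, so a
#' minor-oriented matrix round-trips exactly through [read_vcf()].
#'
#' @param g a [genotype_matrix()].
#' @param variants a [variant_table()] covering every column of `g`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, variants, path) {
  vt <- variants[match(variant_ids(g), variants$variant_id), ]
  if (anyNA(vt$variant_id)) stop("write_vcf: variants table does not cover matrix")
  ord <- order(vt$chromosome, vt$position)
  vt <- vt[ord, ]
  m <- dosages(g)[, vt$variant_id, drop = FALSE]
  gt <- c("0/0", "0/1", "1/1")[t(m) + 1L]
  gt <- matrix(gt, nrow = ncol(m), ncol = nrow(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", individual_ids(g)), collapse = "\t")),
             con)
  body <- paste(vt$chromosome, vt$position, vt$variant_id, "A", "C", ".", ".",
                ".", "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Uses `VariantAnnotation::readVcf` (biallelic SNPs, `GT` field).
#' Missing calls are imputed to the per-variant rounded mean dosage and
#' counted; columns whose ALT allele is the major allele are re-oriented
#' so dosages always count the minor allele.
#'
#' @param path VCF file path.
#' @param genome genome tag passed to `readVcf` (cosmetic).
#' @return list with `genotypes` (a [genotype_matrix()]), `variants` (a
#'   [variant_table()] without functional labels), `n_imputed` and
#'   `flipped` (ids re-oriented to minor allele).
#' @export
read_vcf <- function(path, genome = "synthetic") {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path, genome = genome)
  gt <- VariantAnnotation::geno(vcf)$GT  # variants x samples
  rr <- SummarizedExperiment::rowRanges(vcf)
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0L
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gt %in% c("1/1", "1|1")] <- 2L
  n_imputed <- sum(is.na(dos))
  if (n_imputed > 0) {
    for (i in which(rowSums(is.na(dos)) > 0)) {
      fill <- as.integer(round(mean(dos[i, ], na.rm = TRUE)))
      if (is.na(fill)) fill <- 0L
      dos[i, is.na(dos[i, ])] <- fill
    }
    rt_log("read_vcf: imputed %d missing calls to rounded mean dosage", n_imputed)
  }
  m <- t(dos)  # individuals x variants
  p <- colMeans(m) / 2
  flipped <- colnames(m)[p > 0.5]
  if (length(flipped) > 0) m[, flipped] <- 2L - m[, flipped]
  g <- genotype_matrix(m)
  vt <- variant_table(variant_id = rownames(gt),
                      chromosome = as.character(GenomeInfoDb::seqnames(rr)),
                      position = BiocGenerics::start(rr),
                      maf = compute_maf(g))
  list(genotypes = g, variants = vt, n_imputed = n_imputed, flipped = flipped)
}

#' Dosage-matrix TSV interchange
#'
#' Plain alternative to VCF: a header row of variant ids, then one row per
#' individual whose first column is the individual id.
#'
#' @param g a [genotype_matrix()].
#' @param path file path.
#' @return `write_dosage_tsv`: `path` invisibly; `read_dosage_tsv`: a
#'   [genotype_matrix()].
#' @export
write_dosage_tsv <- function(g, path) {
  df <- data.frame(individual_id = individual_ids(g), dosages(g),
                   check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  genotype_matrix(m)
}

#' Read variant annotation and population label TSVs
#'
#' The annotation TSV carries `variant_id`, `chromosome`, `position` and a
#' `functional` column in \{synonymous, nonsynonymous, none\}; the
#' population TSV carries `individual_id` and `subpopulation`.
#'
#' @param path file path.
#' @return a `data.frame`.
#' @export
read_annotation_tsv <- function(path) {
  df <- read_tsv(path)
  need <- c("variant_id", "chromosome", "position", "functional")
  if (!all(need %in% names(df)))
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname read_annotation_tsv
#' @export
read_population_tsv <- function(path) {
  df <- read_tsv(path)
  if (!all(c("individual_id", "subpopulation") %in% names(df)))
    stop("population TSV must have columns individual_id, subpopulation")
  population_labels(df$individual_id, df$subpopulation)
}
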