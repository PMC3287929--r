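# Haplotype-mosaic genotype simulator: multi-subpopulation cohorts with
# spatially decaying LD among common SNPs and rare variants whose carriers
# either ride or ignore common-haplotype backgrounds.

#' Simulation configuration
#'
#' Defaults emulate the cohort the analysis was designed for: 7
#' subpopulations of ~90 individuals (630 total), human-scale divergence
#' (Fst 0.1), one 10-Mb chromosome carrying 400 common SNPs (40 per Mb)
#' and 100 rare SNPs, founder-haplotype LD with a ~100-kb correlation
#' length, ~1 template switch per Mb, and rare variants carried
#' heterozygously by 5 individuals (MAF 5/1260 ~ 0.004 < 0.01).
#'
#' @param n_per_subpop individuals per subpopulation.
#' @param n_subpops number of subpopulations.
#' @param fst Balding-Nichols divergence in `[0, 1)`, applied to founder
#'   weights (not per-SNP draws) so within-population LD stays realistic.
#' @param chromosome_length chromosome length in bp.
#' @param n_common,n_rare numbers of common and rare SNPs.
#' @param ld_decay per-bp decay of founder-haplotype correlation; the
#'   flip probability between adjacent founder sites distance `d` apart is
#'   `0.5 * (1 - exp(-ld_decay * d))`.
#' @param n_founders founder haplotypes per cohort.
#' @param mosaic_switch_rate per-bp probability governing template
#'   switches along each individual haplotype
#'   (`P(switch) = 1 - exp(-rate * d)`).
#' @param rare_mode `"linked"` (carriers drawn from individuals bearing a
#'   designated founder template at the nearest common site) or
#'   `"unlinked"` (carriers uniform at random).
#' @param rare_carrier_count heterozygous carriers per rare SNP; must keep
#'   the rare MAF below `rare_threshold`.
#' @param p_nonsynonymous probability a rare SNP is labelled nonsynonymous.
#' @param rare_threshold,common_threshold MAF class boundaries.
#' @param seed master seed; generation is fully deterministic given it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_per_subpop = 90, n_subpops = 7, fst = 0.1,
                       chromosome_length = 10e6, n_common = 400, n_rare = 100,
                       ld_decay = 1e-5, n_founders = 20,
                       mosaic_switch_rate = 1e-6,
                       rare_mode = c("linked", "unlinked"),
                       rare_carrier_count = 5, p_nonsynonymous = 0.5,
                       rare_threshold = 0.01, common_threshold = 0.05,
                       seed = 1) {
  rare_mode <- match.arg(rare_mode)
  cfg <- list(n_per_subpop = n_per_subpop, n_subpops = n_subpops, fst = fst,
              chromosome_length = chromosome_length, n_common = n_common,
              n_rare = n_rare, ld_decay = ld_decay, n_founders = n_founders,
              mosaic_switch_rate = mosaic_switch_rate, rare_mode = rare_mode,
              rare_carrier_count = rare_carrier_count,
              p_nonsynonymous = p_nonsynonymous,
              rare_threshold = rare_threshold,
              common_threshold = common_threshold, seed = seed)
  with(cfg, {
    stopifnot(n_per_subpop >= 1, n_subpops >= 1, fst >= 0, fst < 1,
              chromosome_length > n_common + n_rare, n_common >= 1,
              n_rare >= 0, ld_decay >= 0, n_founders >= 2,
              mosaic_switch_rate >= 0, rare_carrier_count >= 1,
              p_nonsynonymous >= 0, p_nonsynonymous <= 1)
    N <- n_per_subpop * n_subpops
    if (rare_carrier_count / (2 * N) >= rare_threshold)
      stop("sim_config: rare_carrier_count / (2N) must stay below rare_threshold")
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate founder haplotypes with spatially decaying LD
#'
#' Each founder is a 0/1 vector over the common sites generated by a
#' first-order Markov chain along positions: the first site is
#' Bernoulli(1/2) and each subsequent allele copies its left neighbour
#' except with flip probability `0.5 * (1 - exp(-ld_decay * d))` for
#' inter-site distance `d`. `ld_decay -> 0` gives fully correlated sites;
#' `ld_decay -> Inf` gives independent sites. Marginal frequency is 1/2
#' at every site. Uses the current RNG state.
#'
#' @param n_founders number of founder haplotypes.
#' @param positions sorted site positions in bp.
#' @param ld_decay per-bp decay rate.
#' @return 0/1 matrix, founders x sites.
#' @export
simulate_founders <- function(n_founders, positions, ld_decay) {
  M <- length(positions)
  flip <- 0.5 * (1 - exp(-ld_decay * diff(positions)))
  f <- matrix(0L, n_founders, M)
  f[, 1] <- stats::rbinom(n_founders, 1, 0.5)
  for (j in seq_len(M - 1)) {
    do_flip <- stats::rbinom(n_founders, 1, flip[j])
    f[, j + 1] <- ifelse(do_flip == 1L, 1L - f[, j], f[, j])
  }
  f
}

#' Balding-Nichols subpopulation frequency draw
#'
#' Draws a subpopulation allele frequency around `base_freq` from
#' `Beta(base_freq * (1 - fst) / fst, (1 - base_freq) * (1 - fst) / fst)`,
#' whose mean is `base_freq` and variance `fst * p * (1 - p)`. `fst = 0`
#' returns `base_freq` exactly. Uses the current RNG state.
#'
#' @param base_freq ancestral frequency in (0, 1).
#' @param fst divergence parameter in `[0, 1)`.
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
simulate_subpopulation_frequencies <- function(base_freq, fst, n = 1) {
  if (base_freq <= 0 || base_freq >= 1) stop("base_freq must be in (0, 1)")
  if (fst < 0 || fst >= 1) stop("fst must be in [0, 1)")
  if (fst == 0) return(rep(base_freq, n))
  stats::rbeta(n, base_freq * (1 - fst) / fst,
               (1 - base_freq) * (1 - fst) / fst)
}

# one haplotype: a mosaic of founder templates; returns list(template, allele)
mosaic_haplotype <- function(founders, weights, switch_prob) {
  M <- ncol(founders)
  sw <- stats::runif(M - 1) < switch_prob
  seg <- cumsum(c(1L, sw))
  tpl_per_seg <- sample.int(nrow(founders), max(seg), replace = TRUE,
                            prob = weights)
  tpl <- tpl_per_seg[seg]
  list(template = tpl, allele = founders[cbind(tpl, seq_len(M))])
}

#' Simulate diploid individuals as founder-template mosaics
#'
#' Each of the `2n` haplotypes copies founder templates, switching
#' template at each inter-site step with probability
#' `1 - exp(-mosaic_switch_rate * d)`; templates are drawn with the given
#' founder weights, which is how subpopulation divergence enters. The two
#' haplotypes are summed to dosages. Uses the current RNG state.
#'
#' @param founders founder haplotype matrix from [simulate_founders()].
#' @param weights founder sampling weights for this subpopulation.
#' @param mosaic_switch_rate per-bp switch rate.
#' @param n number of individuals.
#' @param positions site positions (bp), matching `founders` columns.
#' @return list with `dosages` (n x sites integer matrix) and `template1`,
#'   `template2` (n x sites founder indices, used for linked rare
#'   placement).
#' @export
simulate_individuals <- function(founders, weights, mosaic_switch_rate, n,
                                 positions) {
  M <- ncol(founders)
  switch_prob <- 1 - exp(-mosaic_switch_rate * diff(positions))
  dos <- matrix(0L, n, M)
  t1 <- matrix(0L, n, M)
  t2 <- matrix(0L, n, M)
  for (i in seq_len(n)) {
    h1 <- mosaic_haplotype(founders, weights, switch_prob)
    h2 <- mosaic_haplotype(founders, weights, switch_prob)
    dos[i, ] <- h1$allele + h2$allele
    t1[i, ] <- h1$template
    t2[i, ] <- h2$template
  }
  list(dosages = dos, template1 = t1, template2 = t2)
}

# place one rare variant; returns list(column, founder, anchor, carriers)
place_one_rare <- function(position, mode, common_positions, template1,
                           template2, n_carriers, max_tries = 50) {
  N <- nrow(template1)
  col <- integer(N)
  if (mode == "unlinked") {
    carriers <- sample.int(N, n_carriers)
    col[carriers] <- 1L
    return(list(column = col, founder = NA_integer_, anchor = NA_integer_,
                carriers = carriers))
  }
  anchor <- which.min(abs(common_positions - position))
  founders_here <- unique(c(template1[, anchor], template2[, anchor]))
  for (try in seq_len(max_tries)) {
    f <- founders_here[sample.int(length(founders_here), 1)]
    eligible <- which(template1[, anchor] == f | template2[, anchor] == f)
    if (length(eligible) >= n_carriers) {
      carriers <- if (length(eligible) == n_carriers) eligible
                  else eligible[sample.int(length(eligible), n_carriers)]
      col[carriers] <- 1L
      return(list(column = col, founder = f, anchor = anchor,
                  carriers = carriers))
    }
  }
  stop("place_one_rare: no founder segment with enough carriers after retries")
}

#' Place rare variants on a simulated cohort
#'
#' Linked mode: carriers are drawn only from individuals carrying a
#' designated founder template at the common site nearest the rare
#' position, so the rare allele rides a common-haplotype background that
#' common SNPs can tag. Unlinked mode: carriers are uniform at random,
#' independent of all genotypes. Carriers are heterozygous (dosage 1),
#' consistent with MAF < 0.01 in cohorts of a few hundred. Uses the
#' current RNG state.
#'
#' @param rare_positions positions of the rare SNPs (bp).
#' @param mode `"linked"` or `"unlinked"`.
#' @param common_positions positions of the common sites.
#' @param template1,template2 template matrices from
#'   [simulate_individuals()] (row-bound across subpopulations).
#' @param n_carriers carriers per rare SNP.
#' @return list with `columns` (N x n_rare 0/1 matrix) and `truth`
#'   (`data.frame`: `variant_index`, `mode`, `founder`, `anchor_index`,
#'   `n_carriers`, `carriers` comma-joined row indices).
#' @export
place_rare_variants <- function(rare_positions, mode, common_positions,
                                template1, template2, n_carriers) {
  N <- nrow(template1)
  cols <- matrix(0L, N, length(rare_positions))
  truth <- vector("list", length(rare_positions))
  for (k in seq_along(rare_positions)) {
    pr <- place_one_rare(rare_positions[k], mode, common_positions,
                         template1, template2, n_carriers)
    cols[, k] <- pr$column
    truth[[k]] <- data.frame(variant_index = k, mode = mode,
                             founder = pr$founder, anchor_index = pr$anchor,
                             n_carriers = n_carriers,
                             carriers = paste(sort(pr$carriers), collapse = ","),
                             stringsAsFactors = FALSE)
  }
  list(columns = cols, truth = do.call(rbind, truth))
}

#' Simulate a complete dataset
#'
#' Runs the full generator under `config`: unique sorted positions with
#' rare sites interleaved among common sites, founder haplotypes,
#' Balding-Nichols founder weights per subpopulation, mosaic individuals,
#' common-MAF enforcement (columns realizing MAF at or below the common
#' threshold have their founder alleles redrawn, cohort-wide, up to 30
#' times), rare placement per `rare_mode`, and minor-allele orientation
#' (columns with dosage frequency above 0.5 are flipped so every column
#' counts the minor allele, which also makes VCF round-trips exact).
#' Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_dataset`: `genotypes` (a
#'   [genotype_matrix()], columns in position order), `variants` (a
#'   [variant_table()] with functional labels), `labels`
#'   ([population_labels()]), `truth` (per-rare-variant ground truth with
#'   `variant_id`), and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  N <- config$n_per_subpop * config$n_subpops
  n_var <- config$n_common + config$n_rare
  pos <- sort(sample.int(config$chromosome_length, n_var))
  rare_slot <- sort(sample(seq_len(n_var), config$n_rare))
  common_pos <- pos[setdiff(seq_len(n_var), rare_slot)]
  rare_pos <- pos[rare_slot]

  founders <- simulate_founders(config$n_founders, common_pos, config$ld_decay)
  weights <- matrix(1 / config$n_founders, config$n_subpops, config$n_founders)
  if (config$fst > 0) {
    for (s in seq_len(config$n_subpops)) {
      w <- simulate_subpopulation_frequencies(1 / config$n_founders,
                                              config$fst, config$n_founders)
      weights[s, ] <- w / sum(w)
    }
  }

  dos <- matrix(0L, N, config$n_common)
  t1 <- matrix(0L, N, config$n_common)
  t2 <- matrix(0L, N, config$n_common)
  subpop <- character(N)
  for (s in seq_len(config$n_subpops)) {
    rows <- ((s - 1) * config$n_per_subpop + 1):(s * config$n_per_subpop)
    sim <- simulate_individuals(founders, weights[s, ],
                                config$mosaic_switch_rate,
                                config$n_per_subpop, common_pos)
    dos[rows, ] <- sim$dosages
    t1[rows, ] <- sim$template1
    t2[rows, ] <- sim$template2
    subpop[rows] <- sprintf("pop%d", s)
  }

  # enforce realized common MAF > threshold by redrawing founder alleles
  # for violating columns (keeps mosaic-driven LD via shared templates)
  freq <- colMeans(dos) / 2
  maf_c <- pmin(freq, 1 - freq)
  for (j in which(maf_c <= config$common_threshold)) {
    best <- dos[, j]; best_maf <- maf_c[j]
    for (try in seq_len(30)) {
      fj <- stats::rbinom(config$n_founders, 1, 0.5)
      cand <- fj[t1[, j]] + fj[t2[, j]]
      fr <- mean(cand) / 2
      mf <- min(fr, 1 - fr)
      if (mf > best_maf) { best <- cand; best_maf <- mf }
      if (best_maf > config$common_threshold) break
    }
    dos[, j] <- best
    if (best_maf <= config$common_threshold)
      warning(sprintf("simulate_dataset: common site %d realized MAF %.3f <= %.2f",
                      j, best_maf, config$common_threshold))
  }

  rare <- if (config$n_rare > 0)
    place_rare_variants(rare_pos, config$rare_mode, common_pos, t1, t2,
                        config$rare_carrier_count)
  else list(columns = matrix(0L, N, 0),
            truth = data.frame(variant_index = integer(0), mode = character(0),
                               founder = integer(0), anchor_index = integer(0),
                               n_carriers = integer(0), carriers = character(0)))

  # minor-allele orientation
  flip <- colMeans(dos) / 2 > 0.5
  dos[, flip] <- 2L - dos[, flip]

  common_ids <- sprintf("c%04d", seq_len(config$n_common))
  rare_ids <- sprintf("r%04d", seq_len(config$n_rare))
  m <- cbind(dos, rare$columns)
  colnames(m) <- c(common_ids, rare_ids)
  all_pos <- c(common_pos, rare_pos)
  ord <- order(all_pos)
  m <- m[, ord, drop = FALSE]
  rownames(m) <- sprintf("ind%04d", seq_len(N))
  g <- genotype_matrix(m)

  functional <- c(rep("none", config$n_common),
                  ifelse(stats::runif(config$n_rare) < config$p_nonsynonymous,
                         "nonsynonymous", "synonymous"))
  vt <- variant_table(variant_id = c(common_ids, rare_ids)[ord],
                      chromosome = "1", position = all_pos[ord],
                      maf = compute_maf(g),
                      functional = functional[ord],
                      rare_threshold = config$rare_threshold,
                      common_threshold = config$common_threshold)
  truth <- rare$truth
  truth$variant_id <- rare_ids[truth$variant_index]
  truth$anchor_common_id <- ifelse(is.na(truth$anchor_index), NA_character_,
                                   common_ids[truth$anchor_index])
  truth <- truth[, c("variant_id", "mode", "founder", "anchor_common_id",
                     "n_carriers", "carriers")]
  out <- list(genotypes = g, variants = vt,
              labels = population_labels(rownames(m), subpop),
              truth = truth, config = config)
  class(out) <- "sim_dataset"
  out
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d individuals (%d subpops), %d common + %d rare SNPs, mode %s\n",
              n_individuals(x$genotypes), x$config$n_subpops,
              x$config$n_common, x$config$n_rare, x$config$rare_mode))
  invisible(x)
}

#' Write / read a simulated dataset as VCF + TSVs
#'
#' Emits `genotypes.vcf`, `annotation.tsv` (variant_id, chromosome,
#' position, functional), `populations.tsv` and `truth.tsv` into `dir`.
#' No timestamps are written, so output is byte-identical across runs
#' with the same seed. `read_dataset` reverses the operation (dosages
#' round-trip exactly; MAF and classes are recomputed from genotypes).
#'
#' @param dataset a `sim_dataset` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `write_dataset`: the directory, invisibly; `read_dataset`: a
#'   list with `genotypes`, `variants`, `labels` and (if present) `truth`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(dataset$genotypes, dataset$variants, file.path(dir, "genotypes.vcf"))
  write_tsv(dataset$variants[, c("variant_id", "chromosome", "position",
                                 "functional")],
            file.path(dir, "annotation.tsv"))
  write_tsv(dataset$labels, file.path(dir, "populations.tsv"))
  write_tsv(dataset$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' @rdname write_dataset
#' @param rare_threshold,common_threshold class boundaries used when
#'   rebuilding the variant table.
#' @export
read_dataset <- function(dir, rare_threshold = 0.01, common_threshold = 0.05) {
  vcf <- read_vcf(file.path(dir, "genotypes.vcf"))
  ann <- read_annotation_tsv(file.path(dir, "annotation.tsv"))
  vt <- vcf$variants
  vt$functional <- ann$functional[match(vt$variant_id, ann$variant_id)]
  vt$functional[is.na(vt$functional)] <- "none"
  vt$var_class <- classify_variants(vt$maf, rare_threshold, common_threshold)
  out <- list(genotypes = vcf$genotypes, variants = vt,
              labels = read_population_tsv(file.path(dir, "populations.tsv")))
  truth_path <- file.path(dir, "truth.tsv")
  if (file.exists(truth_path)) out$truth <- read_tsv(truth_path)
  out
}
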