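# Orchestration: run configuration, end-to-end pipeline, report tables
# and the command-line entry point.

#' Run configuration
#'
#' Bundles every tunable of the two-stage analysis. Defaults are the
#' study's settings: 1-Mb bins and windows, rare samples of `n_s = 5`,
#' MAF thresholds 0.01/0.05, stage-2 ceiling pairs (0.80, 0.95) and
#' (0.95, 0.99), 1000 block permutations, and a reporting filter on
#' adjusted-R2 increases above 0.30.
#'
#' @param simulation a [sim_config()] (used by the `simulate`/`all`
#'   stages), or NULL when loading data from files.
#' @param bin_size,window_bp stage-1 bin width and stage-2 window (bp).
#' @param n_s rare SNPs per stage-1 sample.
#' @param rare_threshold,common_threshold MAF class boundaries.
#' @param threshold_pairs list of `c(threshold_A, threshold_B)` pairs for
#'   stage 2.
#' @param n_perm stage-2 block permutations.
#' @param mode stage-1 load mode, `"count"` or `"collapse"`.
#' @param min_stratum_n minimum individuals per stage-1 stratum.
#' @param report_delta adjusted-R2 increase flagged in the stage-2 report.
#' @param seed master seed for every source of randomness.
#' @return list of class `run_config`.
#' @export
run_config <- function(simulation = sim_config(), bin_size = 1e6, n_s = 5,
                       rare_threshold = 0.01, common_threshold = 0.05,
                       threshold_pairs = list(c(0.80, 0.95), c(0.95, 0.99)),
                       n_perm = 1000, window_bp = 1e6,
                       mode = c("count", "collapse"), min_stratum_n = 20,
                       report_delta = 0.30, seed = 1) {
  mode <- match.arg(mode)
  cfg <- list(simulation = simulation, bin_size = bin_size, n_s = n_s,
              rare_threshold = rare_threshold,
              common_threshold = common_threshold,
              threshold_pairs = threshold_pairs, n_perm = n_perm,
              window_bp = window_bp, mode = mode,
              min_stratum_n = min_stratum_n, report_delta = report_delta,
              seed = seed)
  class(cfg) <- "run_config"
  cfg
}

config_to_json <- function(cfg, path) {
  x <- unclass(cfg)
  if (!is.null(x$simulation)) x$simulation <- unclass(x$simulation)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from JSON
#'
#' Missing fields fall back to the [run_config()] / [sim_config()]
#' defaults.
#'
#' @param path JSON file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- NULL
  if (!is.null(x$simulation)) {
    sim_args <- x$simulation[names(x$simulation) %in% names(formals(sim_config))]
    sim <- do.call(sim_config, sim_args)
  }
  args <- x[names(x) %in% setdiff(names(formals(run_config)), "simulation")]
  if (!is.null(args$threshold_pairs) && is.matrix(args$threshold_pairs))
    args$threshold_pairs <- lapply(seq_len(nrow(args$threshold_pairs)),
                                   function(i) args$threshold_pairs[i, ])
  do.call(run_config, c(list(simulation = sim), args))
}

# QC shared by every entry route: classify variants, drop perfect LD
prepare_dataset <- function(dataset, cfg) {
  vt <- dataset$variants
  vt$maf <- compute_maf(dataset$genotypes)[vt$variant_id]
  vt$var_class <- classify_variants(vt$maf, cfg$rare_threshold,
                                    cfg$common_threshold)
  red <- remove_perfect_ld(dataset$genotypes, vt)
  list(genotypes = red$genotypes, variants = red$variants,
       labels = dataset$labels, n_excluded_perfect_ld = length(red$excluded))
}

#' Run the full pipeline
#'
#' simulate (or load) -> QC (classification, perfect-LD removal) ->
#' stage 1 observed + permutation null + distribution comparison ->
#' stage 2 at each threshold pair -> report tables. All outputs are TSV
#' (plus the resolved config as JSON) and contain no timestamps, so two
#' runs with the same seed produce byte-identical files.
#'
#' Files written to `outdir`: `config.json`, the dataset
#' (`genotypes.vcf`, `annotation.tsv`, `populations.tsv`, `truth.tsv`),
#' `stage1_results.tsv`, `stage1_null_results.tsv`,
#' `stage1_null_comparison.tsv`, `stage2_results_A<...>_B<...>.tsv` and
#' `stage2_scatter_A<...>_B<...>.tsv` per threshold pair,
#' `table1_summary.tsv`, `figure2_points.tsv`, `manifest.json`.
#'
#' @param cfg a [run_config()].
#' @param outdir output directory.
#' @param dataset optional pre-built dataset (list with `genotypes`,
#'   `variants`, `labels`); when NULL, `cfg$simulation` is used.
#' @return invisibly, a list with the in-memory result tables.
#' @export
run_pipeline <- function(cfg = run_config(), outdir, dataset = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  config_to_json(cfg, file.path(outdir, "config.json"))
  if (is.null(dataset)) {
    if (is.null(cfg$simulation)) stop("run_pipeline: no dataset and no simulation config")
    dataset <- simulate_dataset(cfg$simulation)
    write_dataset(dataset, outdir)
  }
  prep <- prepare_dataset(dataset, cfg)

  s1_args <- list(g = prep$genotypes, variants = prep$variants,
                  labels = prep$labels, bin_size = cfg$bin_size, n_s = cfg$n_s,
                  mode = cfg$mode, rare_threshold = cfg$rare_threshold,
                  common_threshold = cfg$common_threshold,
                  min_stratum_n = cfg$min_stratum_n, seed = cfg$seed)
  stage1 <- do.call(run_stage1, s1_args)
  stage1_null <- do.call(run_stage1, c(s1_args, list(null = TRUE)))
  write_tsv(stage1, file.path(outdir, "stage1_results.tsv"))
  write_tsv(stage1_null, file.path(outdir, "stage1_null_results.tsv"))
  s1_cmp <- compare_stage1_null(stage1, stage1_null)
  write_tsv(s1_cmp, file.path(outdir, "stage1_null_comparison.tsv"))

  stage2 <- list()
  for (pair in cfg$threshold_pairs) {
    tag <- sprintf("A%03.0f_B%03.0f", pair[1] * 100, pair[2] * 100)
    res <- run_stage2(prep$genotypes, prep$variants,
                      threshold_A = pair[1], threshold_B = pair[2],
                      window_bp = cfg$window_bp, n_perm = cfg$n_perm,
                      seed = cfg$seed)
    write_tsv(res, file.path(outdir, sprintf("stage2_results_%s.tsv", tag)))
    sc <- stage2_scatter(res, cfg$report_delta)
    write_tsv(sc, file.path(outdir, sprintf("stage2_scatter_%s.tsv", tag)))
    stage2[[tag]] <- res
  }

  rep <- report_tables(stage1, stage1_null, stage2, cfg$report_delta)
  write_tsv(rep$table1, file.path(outdir, "table1_summary.tsv"))
  write_tsv(rep$figure2, file.path(outdir, "figure2_points.tsv"))

  manifest <- list(
    n_individuals = n_individuals(prep$genotypes),
    n_variants = length(variant_ids(prep$genotypes)),
    n_excluded_perfect_ld = prep$n_excluded_perfect_ld,
    class_counts = as.list(table(prep$variants$var_class)),
    stage2_skipped = lapply(stage2, function(r) attr(r, "skipped")),
    seed = cfg$seed)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(stage1 = stage1, stage1_null = stage1_null,
                 stage1_comparison = s1_cmp, stage2 = stage2,
                 report = rep, prepared = prep))
}

# per-rare-SNP (adjR2_A, adjR2_B) points with significance flags
stage2_scatter <- function(res, report_delta = 0.30) {
  data.frame(rare_id = res$rare_id, adjR2_A = res$adjR2_A,
             adjR2_B = res$adjR2_B, delta = res$adjR2_B - res$adjR2_A,
             flag_delta = !is.na(res$adjR2_B) & !is.na(res$adjR2_A) &
               (res$adjR2_B - res$adjR2_A) > report_delta,
             p_analytic = res$p_analytic, p_permutation = res$p_permutation,
             stringsAsFactors = FALSE)
}

#' Aggregate stage results into summary tables
#'
#' `table1`: per (stratum, pooling) the mean observed and null adjusted
#' R2 with KS/t p-values, plus the synonymous and nonsynonymous means and
#' their Welch t p-value. Two poolings are offered: `replicates` (every
#' replicate row pooled) and `bins` (replicates averaged within a bin
#' first). `figure2`: per threshold pair, the per-rare-SNP
#' (adjR2_A, adjR2_B) points with the `delta > report_delta` flag.
#'
#' @param stage1,stage1_null [run_stage1()] / [null_stage1()] tables.
#' @param stage2 named list of [run_stage2()] tables.
#' @param report_delta adjusted-R2 increase flagged in `figure2`.
#' @return list with `table1` and `figure2` data frames.
#' @export
report_tables <- function(stage1, stage1_null, stage2, report_delta = 0.30) {
  pool <- function(df, how) {
    df <- df[df$functional == "all" & !is.na(df$adjusted_R2), ]
    if (how == "bins") {
      key <- paste(df$stratum, df$chrom, df$bin_start)
      agg <- stats::aggregate(df$adjusted_R2, list(key = key, stratum = df$stratum),
                              mean)
      split(agg$x, agg$stratum)
    } else split(df$adjusted_R2, df$stratum)
  }
  fun_means <- function(df, stratum, fun) {
    v <- df$adjusted_R2[df$stratum == stratum & df$functional == fun]
    v[!is.na(v)]
  }
  rows <- list()
  for (how in c("replicates", "bins")) {
    obs <- pool(stage1, how)
    nul <- pool(stage1_null, how)
    for (stratum in names(obs)) {
      o <- obs[[stratum]]; n <- nul[[stratum]] %||% numeric(0)
      if (length(o) < 2 || length(n) < 2) next
      cmp <- compare_distributions(o, n, "adjusted_R2", stratum)
      syn <- fun_means(stage1, stratum, "synonymous")
      nsyn <- fun_means(stage1, stratum, "nonsynonymous")
      t_syn_nsyn <- if (length(syn) >= 2 && length(nsyn) >= 2)
        tryCatch(stats::t.test(syn, nsyn)$p.value, error = function(e) NA_real_)
      else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = stratum, pooling = how,
        mean_observed = cmp$mean_observed, mean_null = cmp$mean_null,
        t_p = cmp$t_p, ks_p = cmp$ks_p,
        mean_synonymous = if (length(syn)) mean(syn) else NA_real_,
        mean_nonsynonymous = if (length(nsyn)) mean(nsyn) else NA_real_,
        t_p_syn_vs_nonsyn = t_syn_nsyn, stringsAsFactors = FALSE)
    }
  }
  table1 <- do.call(rbind, rows)
  fig <- list()
  for (tag in names(stage2)) {
    sc <- stage2_scatter(stage2[[tag]], report_delta)
    if (nrow(sc) > 0) sc <- cbind(threshold_pair = tag, sc)
    fig[[tag]] <- sc
  }
  fig <- fig[vapply(fig, nrow, 0L) > 0]
  figure2 <- if (length(fig)) do.call(rbind, c(fig, make.row.names = FALSE))
             else data.frame()
  list(table1 = table1, figure2 = figure2)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a dataset), `stage1`, `stage2` (run one
#' stage on a dataset directory), `report` (rebuild summary tables from
#' stage TSVs), `all` (full pipeline). Flags: `--config <json>`,
#' `--out <dir>`, `--data <dir>` (for stage1/stage2/report),
#' `--seed <int>`, `--threshold-a`, `--threshold-b`, `--n-perm`,
#' `--window-bp`. Install target: `inst/scripts/raretag.R`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
raretag_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: raretag <simulate|stage1|stage2|report|all> [--config cfg.json]",
    "[--out dir] [--data dir] [--seed n] [--threshold-a x] [--threshold-b x]",
    "[--n-perm n] [--window-bp n]")
  if (length(args) == 0) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- list()
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1 > length(args)) { message("missing value for --", key); return(invisible(1L)) }
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  out <- opts$out %||% "raretag_out"
  cfg <- if (!is.null(opts$config)) read_run_config(opts$config) else run_config()
  if (!is.null(opts$seed)) {
    cfg$seed <- as.integer(opts$seed)
    if (!is.null(cfg$simulation)) cfg$simulation$seed <- as.integer(opts$seed)
  }
  if (!is.null(opts[["n-perm"]])) cfg$n_perm <- as.integer(opts[["n-perm"]])
  if (!is.null(opts[["window-bp"]])) cfg$window_bp <- as.numeric(opts[["window-bp"]])
  if (!is.null(opts[["threshold-a"]]) && !is.null(opts[["threshold-b"]]))
    cfg$threshold_pairs <- list(c(as.numeric(opts[["threshold-a"]]),
                                  as.numeric(opts[["threshold-b"]])))
  status <- tryCatch({
    switch(cmd,
      simulate = {
        write_dataset(simulate_dataset(cfg$simulation), out)
        message("dataset written to ", out)
      },
      all = run_pipeline(cfg, out),
      stage1 = {
        d <- read_dataset(opts$data %||% out, cfg$rare_threshold,
                          cfg$common_threshold)
        prep <- prepare_dataset(d, cfg)
        s1 <- run_stage1(prep$genotypes, prep$variants, prep$labels,
                         bin_size = cfg$bin_size, n_s = cfg$n_s,
                         mode = cfg$mode, min_stratum_n = cfg$min_stratum_n,
                         seed = cfg$seed)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_tsv(s1, file.path(out, "stage1_results.tsv"))
        s1n <- run_stage1(prep$genotypes, prep$variants, prep$labels,
                          bin_size = cfg$bin_size, n_s = cfg$n_s,
                          mode = cfg$mode, min_stratum_n = cfg$min_stratum_n,
                          seed = cfg$seed, null = TRUE)
        write_tsv(s1n, file.path(out, "stage1_null_results.tsv"))
        write_tsv(compare_stage1_null(s1, s1n),
                  file.path(out, "stage1_null_comparison.tsv"))
      },
      stage2 = {
        d <- read_dataset(opts$data %||% out, cfg$rare_threshold,
                          cfg$common_threshold)
        prep <- prepare_dataset(d, cfg)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        for (pair in cfg$threshold_pairs) {
          tag <- sprintf("A%03.0f_B%03.0f", pair[1] * 100, pair[2] * 100)
          res <- run_stage2(prep$genotypes, prep$variants,
                            threshold_A = pair[1], threshold_B = pair[2],
                            window_bp = cfg$window_bp, n_perm = cfg$n_perm,
                            seed = cfg$seed)
          write_tsv(res, file.path(out, sprintf("stage2_results_%s.tsv", tag)))
          write_tsv(stage2_scatter(res, cfg$report_delta),
                    file.path(out, sprintf("stage2_scatter_%s.tsv", tag)))
        }
      },
      report = {
        src <- opts$data %||% out
        s1 <- read_tsv(file.path(src, "stage1_results.tsv"))
        s1n <- read_tsv(file.path(src, "stage1_null_results.tsv"))
        s2_files <- list.files(src, "^stage2_results_.*\\.tsv$", full.names = TRUE)
        s2 <- lapply(s2_files, read_tsv)
        names(s2) <- sub("^stage2_results_(.*)\\.tsv$", "\\1", basename(s2_files))
        rep <- report_tables(s1, s1n, s2, cfg$report_delta)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_tsv(rep$table1, file.path(out, "table1_summary.tsv"))
        write_tsv(rep$figure2, file.path(out, "figure2_points.tsv"))
      },
      { message("unknown subcommand: ", cmd); message(usage); return(invisible(1L)) })
    0L
  }, error = function(e) { message("raretag error: ", conditionMessage(e)); 1L })
  invisible(status)
}
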