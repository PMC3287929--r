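# Shared fixtures: all built in code at test time, no stored data.

read_tsv_file <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

# random non-constant dosage column
rand_dosage <- function(n, p = stats::runif(1, 0.2, 0.8)) {
  repeat {
    x <- stats::rbinom(n, 2, p)
    if (stats::sd(x) > 0) return(x)
  }
}

# random genotype matrix with unique ids and no intended structure
rand_genotypes <- function(n, m) {
  g <- sapply(seq_len(m), function(j) rand_dosage(n))
  genotype_matrix(g, sprintf("i%03d", seq_len(n)), sprintf("v%03d", seq_len(m)))
}

# standard normal discretized to dosage-like {0,1,2} (probs .25/.5/.25)
discretize_normal <- function(x) {
  as.integer(cut(x, breaks = c(-Inf, stats::qnorm(0.25), stats::qnorm(0.75), Inf))) - 1L
}

rand_discrete_matrix <- function(n, m) {
  matrix(discretize_normal(stats::rnorm(n * m)), n, m)
}

# --- independent oracles -------------------------------------------------

# Pearson r^2 from the raw definition
oracle_r2 <- function(x, y) {
  cxy <- sum((x - mean(x)) * (y - mean(y)))
  (cxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
}

# multiple R^2 via explicit normal equations (full-rank X only)
oracle_R2 <- function(y, X) {
  X1 <- cbind(1, X)
  beta <- solve(t(X1) %*% X1, t(X1) %*% y)
  rss <- sum((y - X1 %*% beta)^2)
  1 - rss / sum((y - mean(y))^2)
}

oracle_rss <- function(y, X) {
  X1 <- cbind(1, X)
  beta <- solve(t(X1) %*% X1, t(X1) %*% y)
  sum((y - X1 %*% beta)^2)
}

# two-model ANOVA F from residual sums of squares
oracle_anova_F <- function(y, X_A, X_B, N) {
  rss_A <- oracle_rss(y, X_A)
  rss_B <- oracle_rss(y, X_B)
  df1 <- ncol(X_B) - ncol(X_A)
  df2 <- N - ncol(X_B) - 1
  ((rss_A - rss_B) / df1) / (rss_B / df2)
}

# brute-force two-sample KS statistic: max ECDF gap over pooled points
oracle_ks <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(pts) - stats::ecdf(b)(pts)))
}

# --- constructed stage-2 scenario ---------------------------------------
# One common SNP c1 enters set A; c2 = c1 + carrier indicator (plus noise)
# sits in B \ A with r2(c1, c2) in (0.80, 0.95]. In linked mode the rare
# variant's carriers coincide with most of the indicator, so the gain of
# B over A is large; in unlinked mode carriers are independent draws.
stage2_scenario <- function(linked, N = 400, n_carriers = 12, n_noise = 2) {
  repeat {
    c1 <- rand_dosage(N, 0.3)
    elig <- which(c1 <= 1)
    tagged <- sample(elig, n_carriers)
    e <- integer(N)
    e[tagged] <- 1L
    c2 <- c1 + e
    r2_12 <- pairwise_r2(c1, c2)
    if (r2_12 <= 0.80 || r2_12 > 0.95) next
    carriers <- if (linked) {
      c(sample(tagged, n_carriers - n_noise),
        sample(setdiff(elig, tagged), n_noise))
    } else sample(elig, n_carriers)
    y <- integer(N)
    y[carriers] <- 1L
    if (stats::sd(y) == 0) next
    m <- cbind(c1 = c1, c2 = c2)
    g <- genotype_matrix(m, sprintf("i%03d", seq_len(N)), c("c1", "c2"))
    return(list(g = g, y = y, r2_12 = r2_12))
  }
}

# QC a simulated dataset the way every pipeline entry route does:
# perfect-LD duplicates removed before any statistic is computed
qc_dataset <- function(ds) {
  red <- remove_perfect_ld(ds$genotypes, ds$variants)
  list(genotypes = red$genotypes, variants = red$variants, labels = ds$labels)
}

# small simulated-cohort configs used across tests (scaled down for speed)
small_sim_config <- function(seed, rare_mode = "linked", ...) {
  sim_config(n_per_subpop = 150, n_subpops = 1, fst = 0,
             chromosome_length = 1e6, n_common = 25, n_rare = 20,
             n_founders = 8, ld_decay = 1e-5, mosaic_switch_rate = 1e-6,
             rare_carrier_count = 2, rare_mode = rare_mode, seed = seed, ...)
}

tiny_pipeline_config <- function(seed = 11) {
  run_config(simulation = sim_config(n_per_subpop = 30, n_subpops = 2,
                                     chromosome_length = 2e6, n_common = 40,
                                     n_rare = 24, n_founders = 8,
                                     rare_carrier_count = 1, seed = seed),
             n_perm = 25, min_stratum_n = 20, seed = seed)
}
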