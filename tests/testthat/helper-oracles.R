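# Independent oracles and small fixture builders shared across the suite.
# These deliberately re-derive results with naive, literal implementations so
# the package's vectorised code is checked against a second route.

# Literal sliding-window ROH oracle: enumerate every window, apply the rules
# exactly as stated, and collect qualifying runs.  O(n * window) on purpose.
roh_oracle <- function(g, pos, params) {
  n <- length(g)
  w <- params$window_snps
  eligible <- rep(FALSE, n)
  if (n >= w) {
    n_win <- n - w + 1
    window_hit <- logical(n_win)
    for (s in seq_len(n_win)) {
      win <- g[s:(s + w - 1)]
      n_het <- sum(win == 1L, na.rm = TRUE)
      n_mis <- sum(is.na(win))
      window_hit[s] <- n_het <= params$window_het_allowance &&
        n_mis <= params$window_missing_allowance
    }
    for (i in seq_len(n)) {
      covering <- max(1, i - w + 1):min(i, n_win)
      frac <- sum(window_hit[covering]) / length(covering)
      eligible[i] <- frac > params$window_hit_threshold
    }
  }
  segs <- list()
  run <- integer(0)
  flush <- function(run) {
    if (length(run) == 0) return(NULL)
    a <- run[1]; b <- run[length(run)]
    len <- pos[b] - pos[a] + 1
    if (length(run) >= params$min_snps &&
        len >= params$min_length_kb * 1000 &&
        (len / 1000) / length(run) <= params$max_density_kb_per_snp)
      data.frame(start = pos[a], end = pos[b], n_snps = length(run),
                 length_bp = len)
    else NULL
  }
  for (i in seq_len(n)) {
    if (!eligible[i]) {
      segs[[length(segs) + 1]] <- flush(run); run <- integer(0)
    } else if (length(run) > 0 &&
               pos[i] - pos[run[length(run)]] > params$max_gap_kb * 1000) {
      segs[[length(segs) + 1]] <- flush(run); run <- i
    } else run <- c(run, i)
  }
  segs[[length(segs) + 1]] <- flush(run)
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (length(segs) == 0)
    return(data.frame(start = integer(), end = integer(),
                      n_snps = integer(), length_bp = integer()))
  do.call(rbind, segs)
}

# Textbook Welch t statistic and Satterthwaite df.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = tstat, df = df,
       p_value = 2 * pt(-abs(tstat), df))
}

# Small hand-built genotype matrix with explicit depth/AD evidence.
toy_gm <- function(gt, dp = NULL, ad_minor = NULL, pos = NULL,
                   chrom = NULL, ref = NULL, alt = NULL) {
  gt <- as.matrix(gt)
  n <- nrow(gt)
  sites <- data.frame(
    chrom = if (is.null(chrom)) rep("chr1", n) else chrom,
    pos = if (is.null(pos)) seq_len(n) * 1000L else pos,
    ref = if (is.null(ref)) rep("A", n) else ref,
    alt = if (is.null(alt)) rep("G", n) else alt,
    stringsAsFactors = FALSE)
  ids <- sprintf("s%02d", seq_len(ncol(gt)))
  genotype_matrix(gt, sites, ids, dp = dp, ad_minor = ad_minor)
}

# Random single-sample genotype vector + positions for ROH property tests.
random_roh_instance <- function(n, p_het, p_miss, mean_gap_bp = 5000) {
  g <- sample(c(0L, 1L, 2L, NA),  n, replace = TRUE,
              prob = c((1 - p_het - p_miss) * 0.7,
                       p_het, p_miss, (1 - p_het - p_miss) * 0.3))
  # occasionally implant a long homozygous tract so segments actually occur
  if (runif(1) < 0.7 && n > 60) {
    a <- sample(n - 50, 1)
    g[a:(a + sample(20:50, 1))] <- sample(c(0L, 2L), 1)
  }
  pos <- cumsum(1L + rgeom(n, 1 / mean_gap_bp))
  list(g = g, pos = pos)
}

# Derived matrix straight from simulator truth (reference allele is the
# founder/ancestral allele, so genotypes are already derived-allele counts).
dm_from_truth <- function(geno) {
  sites <- geno$sites
  sites$ancestral <- sites$ref
  sites$derived <- sites$alt
  drop_invariant(derived_matrix(geno$gt, sites, geno$samples))
}

# Tiny fast sim config for end-to-end tests.
tiny_sim <- function(seed, mu = 1e-7, ...) {
  sim_config(n_mainland = 50, n_island = 10, split_generation = 40,
             total_generations = 80, chrom_length_bp = 1e6,
             n_chromosomes = 2L, mu = mu, n_sample_island = 5,
             n_sample_mainland = 5, seed = seed, ...)
}
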