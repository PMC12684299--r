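#' Parameters for sliding-window ROH detection
#'
#' Window dialect of the classic PLINK `--homozyg` family: a scanning window of
#' `window_snps` consecutive SNPs is a "hit" when it contains at most
#' `window_het_allowance` heterozygous and at most `window_missing_allowance`
#' missing calls; a SNP is ROH-eligible when the fraction of hit windows among
#' the windows containing it exceeds `window_hit_threshold` (strict `>`; ties
#' are not eligible).  Maximal runs of eligible SNPs become segments when they
#' hold at least `min_snps` SNPs, span at least `min_length_kb`, have at most
#' `max_density_kb_per_snp` kb per SNP, and contain no inter-SNP gap larger
#' than `max_gap_kb` (a larger gap splits the run).
#'
#' `min_snps` is the false-positive-calibrated minimum SNP count L (see
#' [min_roh_snps()]); the scanning window length defaults to L itself.
#' `min_length_kb` defaults to 100 kb so that sub-megabase ("historical") ROH
#' remain detectable.
#'
#' @param min_snps minimum (and default window) number of SNPs per ROH.
#' @param window_snps scanning window length in SNPs (default: `min_snps`).
#' @param window_het_allowance,window_missing_allowance maximum heterozygous /
#'   missing calls tolerated per window (defaults 1 and 5).
#' @param window_hit_threshold minimum hit-window fraction, in `(0, 1]`
#'   (default 0.05).
#' @param min_length_kb minimum segment span in kb (default 100).
#' @param max_gap_kb maximum gap between consecutive SNPs in a run (default
#'   1000 kb).
#' @param max_density_kb_per_snp maximum kb per SNP within a segment
#'   (default 50).
#' @param alpha false-positive ROH threshold used when deriving `min_snps`
#'   (default 0.05); carried for reporting.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(min_snps = 50L, window_snps = NULL,
                       window_het_allowance = 1L,
                       window_missing_allowance = 5L,
                       window_hit_threshold = 0.05,
                       min_length_kb = 100, max_gap_kb = 1000,
                       max_density_kb_per_snp = 50, alpha = 0.05) {
  if (is.null(window_snps)) window_snps <- min_snps
  stopifnot(min_snps >= 1, window_snps >= 1,
            window_het_allowance >= 0, window_missing_allowance >= 0,
            window_hit_threshold > 0, window_hit_threshold <= 1,
            min_length_kb > 0, max_gap_kb > 0, max_density_kb_per_snp > 0,
            alpha > 0, alpha < 1)
  structure(list(min_snps = as.integer(min_snps),
                 window_snps = as.integer(window_snps),
                 window_het_allowance = as.integer(window_het_allowance),
                 window_missing_allowance = as.integer(window_missing_allowance),
                 window_hit_threshold = window_hit_threshold,
                 min_length_kb = min_length_kb, max_gap_kb = max_gap_kb,
                 max_density_kb_per_snp = max_density_kb_per_snp,
                 alpha = alpha),
            class = "roh_params")
}

#' Per-individual autosomal heterozygosity
#'
#' Fraction of a sample's non-missing genotypes that are heterozygous, over
#' the biallelic SNP sites in the matrix.
#'
#' @param x a [genotype_matrix()] or [derived_matrix()].
#' @param sample sample id or column index; if omitted, returns a named vector
#'   over all samples.
#' @return Heterozygosity in `[0, 1]`.
#' @export
heterozygosity <- function(x, sample = NULL) {
  m <- if (inherits(x, "derived_matrix")) x$der else x$gt
  one <- function(j) {
    g <- m[, j]
    n <- sum(!is.na(g))
    if (n == 0) stop("sample ", colnames(m)[j], " has no genotyped sites")
    sum(g == 1L, na.rm = TRUE) / n
  }
  if (is.null(sample))
    return(setNames(vapply(seq_len(ncol(m)), one, numeric(1)), colnames(m)))
  j <- if (is.character(sample)) match(sample, colnames(m)) else sample
  if (is.na(j)) stop("unknown sample: ", sample)
  one(j)
}

#' Calibrated minimum number of SNPs constituting a ROH
#'
#' Scales the minimum ROH SNP count by the within-species mean heterozygosity
#' to control the false-positive ROH rate:
#' `L = ceiling( ln(alpha / (n_s * n_i)) / ln(1 - het) )`,
#' where `n_s` is the number of genotyped SNPs, `n_i` the number of genotyped
#' individuals, `alpha` the false-positive ROH threshold and `het` the mean
#' per-SNP heterozygosity.  The ceiling keeps the false-positive control
#' conservative.
#'
#' @param n_s number of genotyped SNPs.
#' @param n_i number of genotyped individuals.
#' @param alpha false-positive ROH threshold (default 0.05).
#' @param het mean heterozygosity, strictly between 0 and 1.
#' @return Integer L.
#' @export
min_roh_snps <- function(n_s, n_i, alpha = 0.05, het) {
  stopifnot(n_s >= 1, n_i >= 1, alpha > 0, alpha < 1)
  if (het <= 0 || het >= 1)
    stop("het must lie strictly between 0 and 1")
  as.integer(ceiling(log(alpha / (as.numeric(n_s) * n_i)) / log(1 - het)))
}

# Eligible-SNP flags for one chromosome under the sliding-window rules.
roh_eligible <- function(g, params) {
  n <- length(g)
  w <- params$window_snps
  if (n < w) return(rep(FALSE, n))
  het <- as.integer(!is.na(g) & g == 1L)
  mis <- as.integer(is.na(g))
  ch <- c(0L, cumsum(het)); cm <- c(0L, cumsum(mis))
  starts <- seq_len(n - w + 1L)
  hit <- (ch[starts + w] - ch[starts]) <= params$window_het_allowance &
         (cm[starts + w] - cm[starts]) <= params$window_missing_allowance
  chit <- c(0L, cumsum(hit))
  i <- seq_len(n)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, n - w + 1L)
  (chit[hi + 1L] - chit[lo]) / (hi - lo + 1L) > params$window_hit_threshold
}

#' Detect runs of homozygosity for one sample
#'
#' Sliding-window ROH caller (see [roh_params()] for the dialect).  Sites must
#' be position-sorted within each chromosome; windows are only formed where
#' `window_snps` SNPs exist, so chromosomes with fewer SNPs yield no segments.
#'
#' @param x a [genotype_matrix()] or [derived_matrix()].
#' @param sample sample id or column index.
#' @param params a [roh_params()].
#' @return Data frame with columns `sample`, `chrom`, `start`, `end`
#'   (1-based inclusive bp), `n_snps`, `length_bp`.
#' @export
detect_roh <- function(x, sample, params) {
  stopifnot(inherits(params, "roh_params"))
  g_all <- geno_vector(x, sample)
  sites <- x$sites
  id <- if (is.character(sample)) sample else x$samples$sample_id[sample]
  out <- list()
  for (chrom in unique(sites$chrom)) {
    sel <- sites$chrom == chrom
    pos <- sites$pos[sel]
    if (is.unsorted(pos))
      stop("sites on ", chrom, " are not position-sorted")
    g <- g_all[sel]
    elig <- roh_eligible(g, params)
    idx <- which(elig)
    if (length(idx) == 0) next
    gap_bp <- params$max_gap_kb * 1000
    new_run <- c(TRUE, diff(idx) != 1L |
                   diff(pos[idx]) > gap_bp)
    run <- cumsum(new_run)
    for (r in unique(run)) {
      ii <- idx[run == r]
      a <- ii[1]; b <- ii[length(ii)]
      n_snps <- length(ii)
      len <- pos[b] - pos[a] + 1
      if (n_snps < params$min_snps) next
      if (len < params$min_length_kb * 1000) next
      if ((len / 1000) / n_snps > params$max_density_kb_per_snp) next
      out[[length(out) + 1L]] <- data.frame(
        sample = id, chrom = chrom, start = pos[a], end = pos[b],
        n_snps = n_snps, length_bp = len, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer(), n_snps = integer(),
                      length_bp = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Synthetic homozygous genome
#'
#' Replaces every heterozygous genotype with a homozygote (the allele choice is
#' immaterial to the ROH window logic); missing genotypes stay missing.  ROH
#' detected on this copy give the maximal detectable ROH extent used to
#' normalise F_ROH, absorbing genome-specific artefacts such as uncallable
#' regions.
#'
#' @param x a [genotype_matrix()] or [derived_matrix()].
#' @return The same class of object, fully homozygified.
#' @export
synthetic_homozygous <- function(x) {
  if (inherits(x, "derived_matrix")) {
    x$der[x$der == 1L] <- 0L
  } else {
    x$gt[x$gt == 1L] <- 0L
  }
  x
}

#' Inbreeding coefficient F_ROH normalised by the synthetic homozygous genome
#'
#' `F_ROH = L_ROH / L_ROH,HOM`: the summed length of a sample's detected ROH
#' divided by the summed ROH length of its synthetic homozygous genome under
#' identical detection parameters.  Returns 0 when both are empty.
#'
#' @param segments ROH table for the sample ([detect_roh()]).
#' @param segments_hom ROH table for the synthetic homozygous genome, same
#'   sample and parameters.
#' @return F_ROH in `[0, 1]`.
#' @export
f_roh <- function(segments, segments_hom) {
  l <- sum(as.numeric(segments$length_bp))
  l_hom <- sum(as.numeric(segments_hom$length_bp))
  if (l_hom == 0) {
    if (l > 0)
      stop("L_ROH > 0 with empty synthetic-homozygous ROH: ",
           "segments were not produced with identical parameters")
    return(0)
  }
  l / l_hom
}

#' Recombination clock for ROH age
#'
#' Expected coalescent age of a ROH of length `l` Mb on a genome with
#' recombination rate `r` cM/Mb: `g = 100 / (2 r l)` generations, equivalently
#' `l = 50 / (r g)`.
#'
#' @param l_mb ROH length in Mb.
#' @param g age in generations.
#' @param r recombination rate in cM/Mb.
#' @return Generations (`roh_age_generations`) or Mb (`roh_length_for_age`).
#' @export
roh_age_generations <- function(l_mb, r) {
  stopifnot(all(l_mb > 0), all(r > 0))
  100 / (2 * r * l_mb)
}

#' @rdname roh_age_generations
#' @export
roh_length_for_age <- function(g, r) {
  stopifnot(all(g > 0), all(r > 0))
  50 / (r * g)
}

#' Recombination-clock configuration for ROH age classes
#'
#' Fixes the boundary between "contemporary" ROH (arising within
#' `generation_threshold` generations, i.e. at least `length_threshold_mb`
#' long) and older "historical" ROH.  With the rhesus macaque genome-wide
#' average rate r = 0.448 cM/Mb and g = 110 generations the clock length
#' `50/(r g)` = 1.01 Mb rounds to the 1 Mb boundary; at an 11-year generation
#' time 110 generations is roughly 1200 years before present.
#'
#' @param r recombination rate in cM/Mb (default 0.448).
#' @param generation_time generation time in years (default 11).
#' @param generation_threshold age-class boundary in generations (default 110).
#' @param length_threshold_mb physical boundary in Mb; by default the clock
#'   length `50/(r * generation_threshold)` rounded to the nearest whole Mb.
#' @return A list of class `recomb_clock` with the boundary in Mb, generations
#'   and years.
#' @export
recomb_clock <- function(r = 0.448, generation_time = 11,
                         generation_threshold = 110,
                         length_threshold_mb = NULL) {
  stopifnot(r > 0, generation_time > 0, generation_threshold > 0)
  exact <- roh_length_for_age(generation_threshold, r)
  if (is.null(length_threshold_mb)) length_threshold_mb <- round(exact)
  structure(list(r = r, generation_time = generation_time,
                 generation_threshold = generation_threshold,
                 length_threshold_mb = length_threshold_mb,
                 length_exact_mb = exact,
                 years_before_present = generation_threshold * generation_time),
            class = "recomb_clock")
}

#' Classify ROH segments into contemporary vs historical age classes
#'
#' A segment is `"contemporary"` when its physical length reaches the clock's
#' boundary (`length_bp >= length_threshold_mb`, boundary inclusive), else
#' `"historical"`.
#'
#' @param segments ROH table from [detect_roh()].
#' @param clock a [recomb_clock()].
#' @return The table with an `age_class` column added.
#' @export
classify_roh_age <- function(segments, clock) {
  stopifnot(inherits(clock, "recomb_clock"))
  thr <- clock$length_threshold_mb * 1e6
  segments$age_class <- ifelse(segments$length_bp >= thr,
                               "contemporary", "historical")
  segments
}

#' Per-sample ROH and diversity summary
#'
#' Runs [detect_roh()] on each sample and on its synthetic homozygous genome,
#' classifies segment ages, and tabulates heterozygosity, total ROH length,
#' the synthetic-homozygous normaliser, and F_ROH overall and partitioned into
#' contemporary and historical components (which sum to the total).
#'
#' @param x a [genotype_matrix()] or [derived_matrix()].
#' @param params a [roh_params()].
#' @param clock a [recomb_clock()].
#' @return List with `summary` (one row per sample) and `segments` (all ROH,
#'   age-classified).
#' @export
roh_summary <- function(x, params, clock = recomb_clock()) {
  hom <- synthetic_homozygous(x)
  ids <- x$samples$sample_id
  seg_all <- list()
  rows <- lapply(ids, function(id) {
    seg <- classify_roh_age(detect_roh(x, id, params), clock)
    seg_hom <- detect_roh(hom, id, params)
    seg_all[[id]] <<- seg
    l_hom <- sum(as.numeric(seg_hom$length_bp))
    l_tot <- sum(as.numeric(seg$length_bp))
    l_con <- sum(as.numeric(seg$length_bp[seg$age_class == "contemporary"]))
    l_his <- l_tot - l_con
    data.frame(
      sample_id = id, het = heterozygosity(x, id),
      n_roh = nrow(seg), l_roh_bp = l_tot, l_roh_hom_bp = l_hom,
      f_roh = f_roh(seg, seg_hom),
      f_roh_contemporary = if (l_hom > 0) l_con / l_hom else 0,
      f_roh_historical = if (l_hom > 0) l_his / l_hom else 0,
      stringsAsFactors = FALSE)
  })
  list(summary = do.call(rbind, rows),
       segments = do.call(rbind, c(seg_all, list(make.row.names = FALSE))))
}
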