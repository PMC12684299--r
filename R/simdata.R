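#' Simulation configuration for an island-mainland population pair
#'
#' Defines a forward-time Wright-Fisher scenario: a large mainland population
#' runs to mutation-drift (dis)equilibrium, then a small island population is
#' founded from it and both evolve in isolation until the present.  Mutations
#' fall into four effect classes (synonymous, tolerated missense, deleterious
#' missense, loss-of-function), each with its own selection coefficient and
#' dominance.  Fitness is multiplicative across sites with per-site genotype
#' fitness 1, 1-hs and 1-s for ancestral-homozygote, heterozygote and
#' derived-homozygote.
#'
#' Defaults describe the reference scenario used throughout the package:
#' a 500-diploid mainland, a 50-diploid island founded 200 generations before
#' present, eight 2.5-Mb chromosomes and the rhesus macaque genome-wide
#' average recombination rate 0.448 cM/Mb, with all classes selectively
#' neutral (selection is switched on explicitly, e.g.
#' `sel_coeff = c(lof = 0.5)` with `dominance = c(lof = 0)` for recessive LoF
#' purging scenarios).  Two desk-scale departures from literal primate values
#' matter: the per-site mutation rate (2.5e-8) is higher than the primate
#' point rate so that a 20-Mb genome reaches a SNP density at which inter-SNP
#' spacing is small relative to the identity-by-descent segments the
#' bottleneck creates (the regime whole-genome data occupy, and the one in
#' which window-based ROH detection is informative); and the genome is split
#' into eight linkage groups so that per-run drift outcomes average over
#' enough independent genealogies for neutral expectations (e.g. conservation
#' of derived-allele abundance) to hold at the simulated scale.
#'
#' @param n_mainland,n_island diploid population sizes (island much smaller).
#' @param split_generation generations before present at which the island was
#'   founded.
#' @param total_generations total run length, including the pre-split burn-in
#'   (`total_generations - split_generation` generations).
#' @param chrom_length_bp,n_chromosomes chromosome length (bp) and count.
#' @param mu per-site per-generation mutation rate.
#' @param r_cm_per_mb recombination rate in cM/Mb.
#' @param class_fractions named proportions of new mutations per effect class;
#'   must sum to 1.
#' @param sel_coeff,dominance named per-class selection coefficients s and
#'   dominance h, each in `[0, 1]`; partial named vectors override defaults.
#' @param mean_depth mean sequencing depth for the emission noise model.
#' @param n_sample_island,n_sample_mainland individuals sampled ("sequenced")
#'   per population at the end of the run.
#' @param species species label written to the sample metadata.
#' @param seed integer seed; fully determines the simulator output.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_mainland = 500L, n_island = 50L,
                       split_generation = 200L, total_generations = 260L,
                       chrom_length_bp = 2.5e6, n_chromosomes = 8L,
                       mu = 2.5e-8, r_cm_per_mb = 0.448,
                       class_fractions = NULL, sel_coeff = NULL,
                       dominance = NULL, mean_depth = 30,
                       n_sample_island = 8L, n_sample_mainland = 8L,
                       species = "sim_guenon", seed = 1L) {
  classes <- c("synonymous", "missense_tolerated", "missense_deleterious", "lof")
  frac <- c(synonymous = 0.5, missense_tolerated = 0.2,
            missense_deleterious = 0.2, lof = 0.1)
  s <- c(synonymous = 0, missense_tolerated = 0,
         missense_deleterious = 0, lof = 0)
  h <- c(synonymous = 0.5, missense_tolerated = 0.5,
         missense_deleterious = 0.5, lof = 0)
  override <- function(base, x, what) {
    if (is.null(x)) return(base)
    if (is.null(names(x)) && length(x) == length(base)) {
      names(x) <- names(base); return(x)
    }
    if (!all(names(x) %in% names(base)))
      stop("unknown ", what, " class: ",
           paste(setdiff(names(x), names(base)), collapse = ", "))
    base[names(x)] <- x
    base
  }
  frac <- override(frac, class_fractions, "class_fractions")
  s <- override(s, sel_coeff, "sel_coeff")
  h <- override(h, dominance, "dominance")
  if (abs(sum(frac) - 1) > 1e-8) stop("class_fractions must sum to 1")
  if (any(frac < 0)) stop("class_fractions must be non-negative")
  if (any(s < 0 | s > 1)) stop("selection coefficients must lie in [0, 1]")
  if (any(h < 0 | h > 1)) stop("dominance coefficients must lie in [0, 1]")
  if (n_island < 2 || n_mainland < 2) stop("population sizes must be >= 2")
  if (n_island >= n_mainland)
    warning("island population is not smaller than the mainland population")
  if (total_generations <= split_generation)
    stop("total_generations must exceed split_generation (burn-in needed)")
  if (n_sample_island > n_island || n_sample_mainland > n_mainland)
    stop("cannot sample more individuals than the population holds")
  structure(list(
    n_mainland = as.integer(n_mainland), n_island = as.integer(n_island),
    split_generation = as.integer(split_generation),
    total_generations = as.integer(total_generations),
    chrom_length_bp = as.integer(chrom_length_bp),
    n_chromosomes = as.integer(n_chromosomes),
    mu = mu, r_cm_per_mb = r_cm_per_mb,
    class_fractions = frac[classes], sel_coeff = s[classes],
    dominance = h[classes], mean_depth = mean_depth,
    n_sample_island = as.integer(n_sample_island),
    n_sample_mainland = as.integer(n_sample_mainland),
    species = species, seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> mainland N=%d, island N=%d, split %d of %d generations\n",
    "  genome: %d x %.1f Mb, mu=%.3g, r=%.3f cM/Mb, seed=%d\n"),
    x$n_mainland, x$n_island, x$split_generation, x$total_generations,
    x$n_chromosomes, x$chrom_length_bp / 1e6, x$mu, x$r_cm_per_mb, x$seed))
  invisible(x)
}

# ---- internal engine ---------------------------------------------------------

.lof_consequences <- c("stop_gained", "stop_lost", "start_lost",
                       "splice_acceptor_variant", "splice_donor_variant",
                       "splice_region_variant")

.gene_span_bp <- 50000L  # toy gene model: one gene per 50-kb tile

# Multiplicative viability per diploid individual.  Rows of H are haplotypes
# in block layout: individual i owns rows i (maternal copy) and N+i (paternal
# copy).  Returns NULL for a uniform-fitness (neutral) population so callers
# can skip weighted sampling.
fitness_weights <- function(H, site_s, site_h) {
  sel <- which(site_s > 0)
  if (length(sel) == 0L || ncol(H) == 0L) return(NULL)
  G <- hap_genotypes(H, sel)
  s <- site_s[sel]; h <- site_h[sel]
  lw_het <- log(pmax(1 - h * s, 1e-300))
  lw_hom <- log(pmax(1 - s, 1e-300))
  lw <- (G == 1L) %*% lw_het + (G == 2L) %*% lw_hom
  exp(drop(lw))
}

# One gamete per parent (block layout: parent p's haplotypes are rows p and
# N+p); Poisson crossovers per chromosome at r cM/Mb.  Compiled kernel.
make_gametes <- function(H, parents, chrom_idx, pos, cfg) {
  morgans <- cfg$r_cm_per_mb * (cfg$chrom_length_bp / 1e6) / 100
  make_gametes_cpp(H, parents, chrom_idx, as.numeric(pos), morgans,
                   cfg$n_chromosomes, as.numeric(cfg$chrom_length_bp))
}

# Advance one population one generation.  K is the kinship matrix of the
# current generation (diag = self-kinship 0.5*(1+F)); returns children in
# block layout (maternal gametes first, then paternal).
wf_step <- function(H, K, n_off, sites, cfg) {
  N <- nrow(H) %/% 2L
  w <- fitness_weights(H, sites$s, sites$h)
  if (!is.null(w) && all(w == 0))
    stop("population extinct: no viable parents")
  mothers <- sample.int(N, n_off, replace = TRUE, prob = w)
  fathers <- sample.int(N, n_off, replace = TRUE, prob = w)
  # one gather for all 2*n_off gametes; rows 1..n_off are maternal copies
  H2 <- make_gametes(H, c(mothers, fathers), sites$chrom_idx, sites$pos, cfg)
  kin <- kinship_update_cpp(K, mothers, fathers)
  list(H = H2, K = kin$K, f_ped = kin$f_ped)
}

# Draw positions and annotations for new mutations across n_hap haplotypes
# (infinite-sites: collisions with occupied positions are discarded).
# Returns NULL or list(row, sites) with one entry per accepted mutation.
draw_mutations <- function(n_hap, sites, cfg, origin_pop, gen) {
  L_tot <- as.numeric(cfg$n_chromosomes) * cfg$chrom_length_bp
  n_new <- rpois(1L, n_hap * cfg$mu * L_tot)
  if (n_new == 0L) return(NULL)
  row <- sample.int(n_hap, n_new, replace = TRUE)
  chrom <- sample.int(cfg$n_chromosomes, n_new, replace = TRUE)
  pos <- sample.int(cfg$chrom_length_bp, n_new, replace = TRUE)
  key <- chrom * (cfg$chrom_length_bp + 1) + pos
  ok <- !duplicated(key) &
    !(key %in% (sites$chrom_idx * (cfg$chrom_length_bp + 1) + sites$pos))
  if (!any(ok)) return(NULL)
  row <- row[ok]; chrom <- chrom[ok]; pos <- pos[ok]
  n_keep <- length(row)
  cls <- sample(names(cfg$class_fractions), n_keep, replace = TRUE,
                prob = cfg$class_fractions)
  ex <- rep(NA_real_, n_keep)
  ex[cls == "missense_tolerated"] <-
    runif(sum(cls == "missense_tolerated"), 0.30, 1.00)
  ex[cls == "missense_deleterious"] <-
    runif(sum(cls == "missense_deleterious"), 0.00, 0.25)
  csq <- character(n_keep)
  csq[cls == "synonymous"] <- "synonymous_variant"
  csq[cls %in% c("missense_tolerated", "missense_deleterious")] <-
    "missense_variant"
  n_lof <- sum(cls == "lof")
  csq[cls == "lof"] <- sample(.lof_consequences, n_lof, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  ref_i <- sample.int(4L, n_keep, replace = TRUE)
  # alt drawn uniformly from the three non-ref bases
  alt_i <- (ref_i - 1L + sample.int(3L, n_keep, replace = TRUE)) %% 4L + 1L
  list(row = row, sites = list(
    chrom_idx = chrom, pos = pos, ref = bases[ref_i], alt = bases[alt_i],
    class = cls, s = unname(cfg$sel_coeff[cls]),
    h = unname(cfg$dominance[cls]), ex_score = ex, consequence = csq,
    gene_id = sprintf("gene_%d_%d", chrom, (pos - 1L) %/% .gene_span_bp + 1L),
    origin_pop = rep(origin_pop, n_keep), origin_gen = rep(gen, n_keep)))
}

# New-mutation indicator columns for haplotype rows `row` (within 1..n_hap).
# Haplotypes are stored one byte per allele.
mutation_columns <- function(n_hap, row, n_keep, offset = 0L) {
  M <- matrix(as.raw(0L), n_hap, n_keep)
  sel <- row > offset & row <= offset + n_hap
  M[cbind(row[sel] - offset, which(sel))] <- as.raw(1L)
  M
}

# Extend both populations with jointly drawn new mutations (mutation rate is
# per haplotype, so the draw pools the two populations' haplotypes).
joint_mutations <- function(Hm, Hi, sites, cfg, gen) {
  n_m <- nrow(Hm); n_i <- nrow(Hi)
  mut <- draw_mutations(n_m + n_i, sites, cfg, "mainland", gen)
  if (is.null(mut)) return(list(Hm = Hm, Hi = Hi, sites = sites))
  mut$sites$origin_pop[mut$row > n_m] <- "island"
  n_keep <- length(mut$row)
  list(Hm = cbind(Hm, mutation_columns(n_m, mut$row, n_keep)),
       Hi = cbind(Hi, mutation_columns(n_i, mut$row, n_keep, offset = n_m)),
       sites = Map(c, sites, mut$sites))
}

# Extend one population with its own new mutations.
add_mutations <- function(H, sites, cfg, origin_pop, gen) {
  mut <- draw_mutations(nrow(H), sites, cfg, origin_pop, gen)
  if (is.null(mut)) return(list(H = H, sites = sites))
  n_keep <- length(mut$row)
  list(H = cbind(H, mutation_columns(nrow(H), mut$row, n_keep)),
       sites = Map(c, sites, mut$sites))
}

#' Forward-time Wright-Fisher simulation of an island-mainland pair
#'
#' Runs the scenario described by a [sim_config()]: discrete non-overlapping
#' generations, fitness-weighted multinomial parent sampling (monoecious,
#' selfing allowed), Poisson crossovers per chromosome per meiosis, and
#' infinite-sites mutation so every variant has an unambiguous ancestral
#' (founder) allele.  The mainland population burns in alone; at
#' `split_generation` generations before present the island is founded as a
#' bottleneck draw from the mainland gene pool and the two populations evolve
#' in complete isolation.  Pedigree kinship is tracked throughout, giving each
#' sampled individual a realised pedigree inbreeding coefficient.
#'
#' Sites lost during the burn-in are dropped and sites fixed before the split
#' are treated as substitutions to the founder background; after the split a
#' site is kept while any copy survives in either population, so differential
#' fixation between the populations is observable.  The emitted reference
#' allele is the ancestral (founder) allele, mirroring analyses aligned to an
#' outgroup reference genome.
#'
#' @param config a [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{geno}{[genotype_matrix()] of clean (noise-free) genotypes for the
#'       sampled individuals, sites sorted by chromosome and position, with
#'       gene ids, consequence strings and EX scores in `$sites`.}
#'     \item{truth}{`sim_truth` list: per-site effect class, s, h, origin
#'       population/generation and true population derived-allele frequencies;
#'       per-sample pedigree inbreeding `f_ped`; the config.}
#'   }
#' @export
wf_simulate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    cfg <- config
    # site bookkeeping as parallel vectors (cheap to extend and subset)
    sites <- list(
      chrom_idx = integer(), pos = integer(), ref = character(),
      alt = character(), class = character(), s = numeric(), h = numeric(),
      ex_score = numeric(), consequence = character(), gene_id = character(),
      origin_pop = character(), origin_gen = integer())
    site_subset <- function(sites, keep) lapply(sites, function(v) v[keep])
    N <- cfg$n_mainland
    H <- matrix(as.raw(0L), 2L * N, 0L)
    K <- diag(0.5, N)
    t_split <- cfg$total_generations - cfg$split_generation

    # fixation and loss are absorbing, so pruning every few generations (and
    # once at the end) yields the same final state as pruning every generation
    for (t in seq_len(t_split)) {
      stp <- wf_step(H, K, N, sites, cfg)
      H <- stp$H; K <- stp$K
      mut <- add_mutations(H, sites, cfg, "ancestral", t)
      H <- mut$H; sites <- mut$sites
      if (t %% 4L == 0L || t == t_split) {
        cnt <- hap_col_counts(H)
        keep <- cnt > 0L & cnt < 2L * N
        H <- H[, keep, drop = FALSE]; sites <- site_subset(sites, keep)
      }
    }

    # Found both daughter populations from the final burn-in generation.
    stp_m <- wf_step(H, K, cfg$n_mainland, sites, cfg)
    stp_i <- wf_step(H, K, cfg$n_island, sites, cfg)
    Hm <- stp_m$H; Km <- stp_m$K; Fm <- stp_m$f_ped
    Hi <- stp_i$H; Ki <- stp_i$K; Fi <- stp_i$f_ped
    gen0 <- t_split + 1L
    mut <- joint_mutations(Hm, Hi, sites, cfg, gen0)
    Hm <- mut$Hm; Hi <- mut$Hi; sites <- mut$sites

    prune <- function() {
      cnt <- hap_col_counts(Hm) + hap_col_counts(Hi)
      keep <- cnt > 0L
      Hm <<- Hm[, keep, drop = FALSE]
      Hi <<- Hi[, keep, drop = FALSE]
      sites <<- site_subset(sites, keep)
    }
    prune()

    if (cfg$split_generation > 1L) {
      for (t in (gen0 + 1L):cfg$total_generations) {
        stp_m <- wf_step(Hm, Km, cfg$n_mainland, sites, cfg)
        Hm <- stp_m$H; Km <- stp_m$K; Fm <- stp_m$f_ped
        stp_i <- wf_step(Hi, Ki, cfg$n_island, sites, cfg)
        Hi <- stp_i$H; Ki <- stp_i$K; Fi <- stp_i$f_ped
        mut <- joint_mutations(Hm, Hi, sites, cfg, t)
        Hm <- mut$Hm; Hi <- mut$Hi; sites <- mut$sites
        if (t %% 4L == 0L || t == cfg$total_generations) prune()
      }
    }

    # Sample individuals (populations are exchangeable, take the first k);
    # block layout: individual i owns haplotype rows i and N+i.
    geno_sample <- function(H, k) {
      G <- hap_genotypes(H, seq_len(ncol(H)))
      t(G[seq_len(k), , drop = FALSE])
    }
    gt <- cbind(geno_sample(Hi, cfg$n_sample_island),
                geno_sample(Hm, cfg$n_sample_mainland))
    ids <- c(sprintf("isl_%02d", seq_len(cfg$n_sample_island)),
             sprintf("mnl_%02d", seq_len(cfg$n_sample_mainland)))
    samples <- data.frame(
      sample_id = ids, species = cfg$species,
      population = rep(c("island", "mainland"),
                       c(cfg$n_sample_island, cfg$n_sample_mainland)),
      stringsAsFactors = FALSE)

    ord <- order(sites$chrom_idx, sites$pos)
    sites <- site_subset(sites, ord)
    gt <- gt[ord, , drop = FALSE]
    Hi <- Hi[, ord, drop = FALSE]; Hm <- Hm[, ord, drop = FALSE]

    site_tab <- data.frame(
      chrom = sprintf("chr%d", sites$chrom_idx), pos = sites$pos,
      ref = sites$ref, alt = sites$alt, ancestral = sites$ref,
      gene_id = sites$gene_id, consequence = sites$consequence,
      ex_score = sites$ex_score, stringsAsFactors = FALSE)
    contigs <- data.frame(chrom = paste0("chr", seq_len(cfg$n_chromosomes)),
                          length = cfg$chrom_length_bp)
    geno <- genotype_matrix(gt, site_tab, samples, contigs = contigs)
    truth_sites <- data.frame(
      chrom = site_tab$chrom, pos = site_tab$pos,
      class = sites$class, s = sites$s, h = sites$h,
      origin_pop = sites$origin_pop, origin_gen = sites$origin_gen,
      ancestral = sites$ref, derived = sites$alt,
      freq_island = hap_col_counts(Hi) / nrow(Hi),
      freq_mainland = hap_col_counts(Hm) / nrow(Hm),
      stringsAsFactors = FALSE)
    truth <- structure(list(
      sites = truth_sites,
      f_ped = setNames(c(Fi[seq_len(cfg$n_sample_island)],
                         Fm[seq_len(cfg$n_sample_mainland)]), ids),
      config = cfg), class = "sim_truth")
    list(geno = geno, truth = truth)
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d segregating sites; %d sampled individuals\n",
              nrow(x$sites), length(x$f_ped)))
  invisible(x)
}
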