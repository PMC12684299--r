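#' Pipeline configuration
#'
#' Bundles either a [sim_config()] (synthetic mode) or a set of input paths
#' (real-data mode) with the analysis parameters: the masking threshold, the
#' false-positive ROH level used to calibrate the minimum ROH SNP count, the
#' ROH window dialect, the recombination clock and the EX deleteriousness
#' threshold.  Exactly one of `sim` / `paths` must be given.
#'
#' @param sim a [sim_config()] for synthetic mode.
#' @param paths named list for real-data mode: `vcf`, `metadata`, `sites`
#'   (annotation TSV), `outgroups`.
#' @param min_support_fraction allelic-balance masking threshold (default
#'   0.25).
#' @param alpha false-positive ROH threshold for [min_roh_snps()] (default
#'   0.05).
#' @param roh a [roh_params()] or `NULL` to calibrate `min_snps` from the data
#'   via [min_roh_snps()].
#' @param clock a [recomb_clock()] (default: r = 0.448 cM/Mb, 11-year
#'   generations, 110-generation / 1 Mb boundary).
#' @param ex_threshold EX deleterious/tolerated boundary (default 0.256).
#' @param seed integer seed driving emission noise and outgroup corruption in
#'   synthetic mode.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL,
                            min_support_fraction = 0.25, alpha = 0.05,
                            roh = NULL, clock = recomb_clock(),
                            ex_threshold = 0.256, seed = 1L) {
  if (is.null(sim) == is.null(paths))
    stop("exactly one of `sim` (synthetic mode) or `paths` must be given")
  if (!is.null(paths)) {
    need <- c("vcf", "metadata", "sites", "outgroups")
    if (!all(need %in% names(paths)))
      stop("paths must name: ", paste(need, collapse = ", "))
    missing_files <- unlist(paths[need])[!file.exists(unlist(paths[need]))]
    if (length(missing_files))
      stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
  }
  structure(list(sim = sim, paths = paths,
                 min_support_fraction = min_support_fraction, alpha = alpha,
                 roh = roh, clock = clock, ex_threshold = ex_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full island-mainland analysis pipeline
#'
#' Orchestrates simulate (synthetic mode) -> emit -> read -> allelic-balance
#' and depth masking -> outgroup polarisation -> invariant-site removal ->
#' heterozygosity, calibrated ROH detection and F_ROH with age classes ->
#' per-category genetic load (relative abundance, derived homozygosity, fixed
#' homozygous LoF genes) -> differentially fixed variants with the LoF-gene
#' filter -> Welch group comparisons.  All stage outputs are written to
#' `outdir` together with a JSON manifest (parameters, seed, record counts and
#' md5 checksums); rerunning an identical configuration reproduces identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return (Invisibly) a list with the per-sample summary, ROH segments, load
#'   summary, fixed differences, group comparisons and the manifest.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_counts <- list()
  p <- function(f) file.path(outdir, f)

  if (!is.null(config$sim)) {
    sim <- wf_simulate(config$sim)
    emit_vcf(sim$geno, p("genotypes.vcf"),
             mean_depth = config$sim$mean_depth, seed = config$seed)
    og <- emit_outgroups(sim$geno$sites, discordant_fraction = 0.02,
                         het_fraction = 0.02, seed = config$seed + 1L)
    write_outgroups(og, p("outgroups.tsv"))
    write_site_table(sim$geno$sites, p("sites.tsv"))
    write_sample_metadata(sim$geno$samples, p("samples.tsv"))
    paths <- list(vcf = p("genotypes.vcf"), metadata = p("samples.tsv"),
                  sites = p("sites.tsv"), outgroups = p("outgroups.tsv"))
  } else paths <- config$paths

  meta <- read_sample_metadata(paths$metadata)
  gm <- read_genotype_vcf(paths$vcf, samples = meta)
  gm <- annotate_sites(gm, read_site_table(paths$sites))
  outgroups <- read_outgroups(paths$outgroups)
  log_counts$sites_read <- nrow(gm$gt)
  log_counts$samples <- ncol(gm$gt)

  gm <- suppressWarnings(mask_allelic_balance(gm, config$min_support_fraction))
  log_counts$genotypes_masked_allelic_balance <- attr(gm, "n_masked_ab")
  gm <- mask_depth(gm)
  log_counts$genotypes_masked_depth <- attr(gm, "n_masked_depth")

  dm <- polarize(gm, outgroups)
  log_counts$sites_polarised <- nrow(dm$der)
  dm <- drop_invariant(dm)
  log_counts$sites_after_invariant_filter <- nrow(dm$der)

  het <- heterozygosity(gm)
  params <- config$roh
  if (is.null(params)) {
    L <- min_roh_snps(nrow(gm$gt), ncol(gm$gt), config$alpha, mean(het))
    params <- roh_params(min_snps = max(L, 2L), alpha = config$alpha)
  }
  roh <- roh_summary(gm, params, config$clock)

  effects <- classify_effect(dm$sites$consequence, dm$sites$ex_score,
                             config$ex_threshold)
  load <- load_summary(dm, effects)
  lof_fixed_island <- fixed_homozygous_lof_genes(dm, effects, "island")
  fixed <- differentially_fixed(dm)
  fixed_flt <- filter_lof_genes(fixed, dm$sites)
  log_counts$fixed_differences <- nrow(fixed)
  log_counts$fixed_differences_after_lof_gene_filter <- nrow(fixed_flt$fixed)

  isl <- meta$sample_id[meta$population == "island"]
  mnl <- meta$sample_id[meta$population == "mainland"]
  comparisons <- list(
    heterozygosity = compare_groups(het[isl], het[mnl]),
    f_roh = compare_groups(
      roh$summary$f_roh[match(isl, roh$summary$sample_id)],
      roh$summary$f_roh[match(mnl, roh$summary$sample_id)]))
  for (cat in unique(load$category)) {
    sub <- load[load$category == cat, ]
    comparisons[[paste0("ra_", cat)]] <- compare_groups(
      sub$ra[sub$population == "island"],
      sub$ra[sub$population == "mainland"])
  }

  sample_summary <- merge(
    data.frame(sample_id = meta$sample_id, population = meta$population,
               het = het[meta$sample_id], row.names = NULL),
    roh$summary[, c("sample_id", "n_roh", "l_roh_bp", "l_roh_hom_bp",
                    "f_roh", "f_roh_contemporary", "f_roh_historical")],
    by = "sample_id", sort = TRUE)
  write.table(sample_summary, p("sample_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  seg <- roh$segments
  if (nrow(seg) > 0) seg <- seg[order(seg$sample, seg$chrom, seg$start), ]
  writeLines(c("# ROH segments; coordinates are 1-based inclusive bp",
               paste(c("sample", "chrom", "start", "end", "n_snps",
                       "length_bp", "age_class"), collapse = "\t"),
               if (nrow(seg) > 0)
                 do.call(paste, c(seg, sep = "\t"))),
             p("roh_segments.tsv"))
  write.table(load, p("load_summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(fixed_flt$fixed, p("fixed_differences.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(lof_fixed_island, p("fixed_homozygous_lof_genes_island.txt"))
  write_derived_vcf(dm, p("derived.vcf"),
                    contigs = if (!is.null(config$sim)) {
                      data.frame(chrom = paste0("chr",
                                   seq_len(config$sim$n_chromosomes)),
                                 length = config$sim$chrom_length_bp)
                    } else NULL)

  report <- c(
    "island-mainland diversity and load pipeline",
    sprintf("seed: %d", config$seed),
    sprintf("sites read: %d; samples: %d", log_counts$sites_read,
            log_counts$samples),
    sprintf("genotypes masked (allelic balance < %.2f): %d",
            config$min_support_fraction,
            log_counts$genotypes_masked_allelic_balance),
    sprintf("genotypes masked (depth < 0.5x or > 2x sample mean): %d",
            log_counts$genotypes_masked_depth),
    sprintf("sites retained after outgroup polarisation: %d",
            log_counts$sites_polarised),
    sprintf("sites after invariant removal: %d",
            log_counts$sites_after_invariant_filter),
    sprintf("ROH parameters: L = %d SNPs (alpha = %.2f), window = %d",
            params$min_snps, params$alpha, params$window_snps),
    sprintf("age boundary: %.0f Mb (~%d generations, ~%d years)",
            config$clock$length_threshold_mb,
            config$clock$generation_threshold,
            config$clock$years_before_present),
    sprintf("fixed differences (coding, LoF-gene filtered): %d",
            log_counts$fixed_differences_after_lof_gene_filter),
    sprintf("island genes with fixed homozygous LoF: %d",
            length(lof_fixed_island)),
    "",
    "per-sample summary:",
    utils::capture.output(print(sample_summary, row.names = FALSE)))
  writeLines(report, p("report.txt"))

  files <- c("genotypes.vcf", "outgroups.tsv", "sites.tsv", "samples.tsv",
             "sample_summary.tsv", "roh_segments.tsv", "load_summary.tsv",
             "fixed_differences.tsv", "fixed_homozygous_lof_genes_island.txt",
             "derived.vcf", "report.txt")
  files <- files[file.exists(file.path(outdir, files))]
  manifest <- list(
    seed = config$seed,
    parameters = list(
      min_support_fraction = config$min_support_fraction,
      alpha = config$alpha, ex_threshold = config$ex_threshold,
      roh = unclass(params), clock = unclass(config$clock),
      sim = if (!is.null(config$sim)) unclass(config$sim) else NULL),
    counts = log_counts,
    md5 = as.list(tools::md5sum(file.path(outdir, files))))
  names(manifest$md5) <- files
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(sample_summary = sample_summary, segments = roh$segments,
                 load = load, fixed = fixed_flt, comparisons = comparisons,
                 lof_fixed_island = lof_fixed_island, manifest = manifest,
                 params = params))
}
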