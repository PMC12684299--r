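.lof_consequence_set <- c(
  "transcript_ablation", "stop_gained", "stop_lost", "start_lost",
  "frameshift_variant", "splice_region_variant", "splice_donor_variant",
  "splice_acceptor_variant")

#' Classify variant consequences into mutational-effect categories
#'
#' Maps picked VEP-style consequence strings to the four load categories:
#' loss-of-function (transcript ablation, stop gained/lost, start lost,
#' frameshift, splice region/donor/acceptor), missense split by the
#' experimental amino-acid exchangeability score into deleterious
#' (EX <= `ex_threshold`, boundary inclusive) vs tolerated, and synonymous.
#' Every other consequence is reported as `"excluded"`.
#'
#' @param consequence character vector of consequence strings (spaces or
#'   underscores accepted).
#' @param ex_score numeric EX scores; required (non-`NA`) for missense
#'   variants.
#' @param ex_threshold deleterious/tolerated boundary (default 0.256).
#' @return Character vector of categories: `"lof"`, `"missense_deleterious"`,
#'   `"missense_tolerated"`, `"synonymous"` or `"excluded"`.
#' @export
classify_effect <- function(consequence, ex_score = NULL,
                            ex_threshold = 0.256) {
  csq <- gsub(" ", "_", tolower(consequence))
  if (is.null(ex_score)) ex_score <- rep(NA_real_, length(csq))
  stopifnot(length(ex_score) == length(csq))
  out <- rep("excluded", length(csq))
  out[csq %in% .lof_consequence_set] <- "lof"
  out[csq == "synonymous_variant"] <- "synonymous"
  mis <- csq == "missense_variant"
  if (any(mis & is.na(ex_score)))
    stop("missense variant(s) without an EX score: ",
         sum(mis & is.na(ex_score)), " site(s)")
  out[mis & ex_score <= ex_threshold] <- "missense_deleterious"
  out[mis & ex_score > ex_threshold] <- "missense_tolerated"
  out
}

#' Per-sample derived-allele counts within an effect category
#'
#' For the given sample and category, counts the derived heterozygous
#' (`n_het`) and derived homozygous (`n_hom`) positions over the sample's
#' non-missing genotypes, and `n_p`, the total number of category positions
#' carrying a derived allele in any genome of the species (island and mainland
#' pooled) — the species-wide standardiser of the relative-abundance
#' statistic.
#'
#' @param dm a polarised, invariant-filtered [derived_matrix()].
#' @param effects category per site ([classify_effect()] on `dm$sites`).
#' @param sample sample id or column index.
#' @param category one of the effect categories.
#' @return Named list `n_het`, `n_hom`, `n_p`.
#' @export
load_counts <- function(dm, effects, sample, category) {
  stopifnot(inherits(dm, "derived_matrix"), length(effects) == nrow(dm$der))
  in_cat <- effects == category
  g <- geno_vector(dm, sample)[in_cat]
  seg <- rowSums(dm$der[in_cat, , drop = FALSE], na.rm = TRUE) > 0
  list(n_het = sum(g == 1L, na.rm = TRUE),
       n_hom = sum(g == 2L, na.rm = TRUE),
       n_p = sum(seg))
}

#' Relative abundance of derived alleles
#'
#' Individual genetic load standardised by the species-wide number of derived
#' positions in the category: `RA = (n_het + 2 n_hom) / (2 n_p)`.  Because
#' genetic drift alone does not change the expected count of derived alleles,
#' RA is expected to differ between populations only under selection.
#'
#' @param n_het derived heterozygous positions of the individual.
#' @param n_hom derived homozygous positions of the individual.
#' @param n_p species-wide number of derived positions in the category.
#' @return RA in `[0, 1]`.
#' @export
relative_abundance <- function(n_het, n_hom, n_p) {
  stopifnot(n_het >= 0, n_hom >= 0)
  if (n_p < 1) stop("n_p must be >= 1 (no derived positions in category)")
  (n_het + 2 * n_hom) / (2 * n_p)
}

#' Derived-allele homozygosity
#'
#' Fraction of an individual's derived positions that are homozygous:
#' `n_hom / (n_het + n_hom)`.  Undefined (returned as `NA`) when the
#' individual carries no derived alleles in the category.
#'
#' @param n_het,n_hom derived heterozygous / homozygous position counts.
#' @return Fraction in `[0, 1]`, or `NA` if both counts are zero.
#' @export
derived_homozygosity <- function(n_het, n_hom) {
  stopifnot(n_het >= 0, n_hom >= 0)
  if (n_het + n_hom == 0) return(NA_real_)
  n_hom / (n_het + n_hom)
}

#' Per-sample, per-category genetic-load summary
#'
#' Tabulates `n_het`, `n_hom`, `n_p`, relative abundance and derived
#' homozygosity for every sample and every effect category present.
#'
#' @param dm a polarised, invariant-filtered [derived_matrix()].
#' @param effects category per site; computed from `dm$sites` when omitted.
#' @return Data frame with one row per sample x category.
#' @export
load_summary <- function(dm, effects = NULL) {
  if (is.null(effects))
    effects <- classify_effect(dm$sites$consequence, dm$sites$ex_score)
  cats <- intersect(c("lof", "missense_deleterious", "missense_tolerated",
                      "synonymous"), unique(effects))
  rows <- list()
  for (cat in cats) {
    for (id in dm$samples$sample_id) {
      ct <- load_counts(dm, effects, id, cat)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = id,
        population = dm$samples$population[dm$samples$sample_id == id],
        category = cat, n_het = ct$n_het, n_hom = ct$n_hom, n_p = ct$n_p,
        ra = if (ct$n_p >= 1)
          relative_abundance(ct$n_het, ct$n_hom, ct$n_p) else NA_real_,
        derived_homozygosity = derived_homozygosity(ct$n_het, ct$n_hom),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Genes with LoF variants fixed homozygous in a population
#'
#' Returns the genes having at least one loss-of-function site at which every
#' non-missing genotype in the population is homozygous derived (and at least
#' one individual is genotyped).
#'
#' @param dm a [derived_matrix()] with `gene_id` in `$sites`.
#' @param effects category per site; computed from `dm$sites` when omitted.
#' @param population population label (`"island"` or `"mainland"`), or a
#'   character vector of sample ids.
#' @return Character vector of gene ids (possibly empty).
#' @export
fixed_homozygous_lof_genes <- function(dm, effects = NULL, population) {
  if (is.null(effects))
    effects <- classify_effect(dm$sites$consequence, dm$sites$ex_score)
  ids <- if (length(population) == 1 &&
             population %in% c("island", "mainland"))
    population_samples(dm, population) else population
  m <- dm$der[, ids, drop = FALSE]
  lof <- effects == "lof"
  n_geno <- rowSums(!is.na(m))
  all_hom <- rowSums(m == 2L, na.rm = TRUE) == n_geno & n_geno >= 1
  sort(unique(dm$sites$gene_id[lof & all_hom]))
}

#' Welch's two-sample comparison with a small-sample guard
#'
#' Welch's unequal-variance t-test between two groups of per-individual values
#' when both groups have at least three observations; otherwise the comparison
#' is reported as not testable, mirroring the convention of only testing
#' island-mainland contrasts with N >= 3 genomes per group.
#'
#' @param values_a,values_b numeric vectors (NAs dropped).
#' @return List with `testable`, and either `p_value`, `statistic`, `df`,
#'   `estimate` (mean difference a - b) or `reason`.
#' @export
compare_groups <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 3 || length(b) < 3)
    return(list(testable = FALSE,
                reason = sprintf("N < 3 genomes in one of the groups (%d vs %d)",
                                 length(a), length(b))))
  tt <- t.test(a, b, var.equal = FALSE)
  list(testable = TRUE, p_value = unname(tt$p.value),
       statistic = unname(tt$statistic), df = unname(tt$parameter),
       estimate = unname(mean(a) - mean(b)))
}
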