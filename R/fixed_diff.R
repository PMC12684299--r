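#' Variants fixed for alternative alleles between island and mainland
#'
#' A protein-coding site qualifies as differentially fixed when all non-missing
#' island genotypes are homozygous for one allele, all non-missing mainland
#' genotypes are homozygous for the other allele, and each population has at
#' least one genotyped individual.  Missing genotypes do not disqualify a site
#' (fixation is judged on the observed genotypes); sites are restricted to
#' coding consequences (LoF, missense, synonymous).
#'
#' @param x a [genotype_matrix()] or [derived_matrix()] with `gene_id` and
#'   `consequence` site annotations.
#' @param island_samples,mainland_samples sample id vectors; default to the
#'   `population` column of the object's sample metadata.
#' @param coding_only restrict to coding consequences (default `TRUE`).
#' @return Data frame `chrom`, `pos`, `island_allele`, `mainland_allele`
#'   (genotype codes 0 or 2 on the object's coding), `gene_id`, `consequence`.
#' @export
differentially_fixed <- function(x, island_samples = NULL,
                                 mainland_samples = NULL, coding_only = TRUE) {
  m <- if (inherits(x, "derived_matrix")) x$der else x$gt
  if (is.null(island_samples)) island_samples <- population_samples(x, "island")
  if (is.null(mainland_samples))
    mainland_samples <- population_samples(x, "mainland")
  if (length(island_samples) == 0 || length(mainland_samples) == 0)
    stop("both populations need at least one sample")
  mi <- m[, island_samples, drop = FALSE]
  mm <- m[, mainland_samples, drop = FALSE]
  fixed_code <- function(mat) {
    n <- rowSums(!is.na(mat))
    lo <- suppressWarnings(apply(mat, 1, min, na.rm = TRUE))
    hi <- suppressWarnings(apply(mat, 1, max, na.rm = TRUE))
    code <- ifelse(n >= 1 & lo == hi & lo %in% c(0L, 2L), lo, NA_integer_)
    code[n == 0] <- NA_integer_
    code
  }
  ci <- fixed_code(mi)
  cm <- fixed_code(mm)
  qual <- !is.na(ci) & !is.na(cm) & ci != cm
  if (coding_only) {
    if (is.null(x$sites$consequence))
      stop("site table has no consequence annotation")
    eff <- classify_effect(x$sites$consequence, x$sites$ex_score)
    qual <- qual & eff != "excluded"
  }
  data.frame(chrom = x$sites$chrom[qual], pos = x$sites$pos[qual],
             island_allele = ci[qual], mainland_allele = cm[qual],
             gene_id = if (!is.null(x$sites$gene_id))
               x$sites$gene_id[qual] else NA_character_,
             consequence = if (!is.null(x$sites$consequence))
               x$sites$consequence[qual] else NA_character_,
             stringsAsFactors = FALSE)
}

#' Remove fixed differences in genes containing LoF variants
#'
#' Variants can become differentially fixed in pseudogenes by drift alone; as
#' a pseudogene proxy, every gene containing any loss-of-function variant
#' anywhere in the combined dataset (either population) is removed.
#'
#' @param fixed data frame from [differentially_fixed()].
#' @param sites full site table with `gene_id`, `consequence` (and `ex_score`)
#'   columns — the complete annotation, not just the fixed sites.
#' @return List with `fixed` (the surviving rows) and `genes` (surviving gene
#'   ids).
#' @export
filter_lof_genes <- function(fixed, sites) {
  eff <- classify_effect(sites$consequence, sites$ex_score)
  lof_genes <- unique(sites$gene_id[eff == "lof"])
  keep <- !(fixed$gene_id %in% lof_genes)
  list(fixed = fixed[keep, , drop = FALSE],
       genes = sort(unique(fixed$gene_id[keep])))
}

#' Cross-species overlap of differentially fixed gene sets
#'
#' Tabulates, for every gene appearing in any species' set, its per-species
#' membership and the number of species carrying it.  The "shared" set holds
#' genes present in at least two species; the full intersection is reported
#' separately.
#'
#' @param gene_sets named list (one character vector of gene ids per species).
#' @return List with `table` (gene x species membership data frame with an
#'   `n_species` column), `shared` (genes in >= 2 sets) and `intersection`
#'   (genes in all sets).
#' @export
cross_species_overlap <- function(gene_sets) {
  stopifnot(length(gene_sets) >= 2)
  if (is.null(names(gene_sets)))
    names(gene_sets) <- paste0("species_", seq_along(gene_sets))
  genes <- sort(unique(unlist(gene_sets)))
  memb <- vapply(gene_sets, function(s) genes %in% s,
                 logical(length(genes)))
  memb <- matrix(memb, nrow = length(genes),
                 dimnames = list(NULL, names(gene_sets)))
  tab <- data.frame(gene_id = genes, memb, n_species = rowSums(memb),
                    stringsAsFactors = FALSE, check.names = FALSE)
  list(table = tab,
       shared = genes[tab$n_species >= 2],
       intersection = genes[tab$n_species == length(gene_sets)])
}
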