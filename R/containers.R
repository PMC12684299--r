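#' Genotype matrix container
#'
#' Diploid genotypes for biallelic autosomal SNPs, coded against the reference
#' allele: 0 = hom-ref, 1 = het, 2 = hom-alt, `NA` = missing.  Sites are rows
#' (VCF order), samples are columns.  Optional per-genotype read depth (`dp`)
#' and minor-allele read support (`ad_minor`) matrices of the same shape carry
#' the evidence the masking filters act on.
#'
#' @param gt integer matrix, sites x samples, values in `c(0L, 1L, 2L, NA)`.
#' @param sites data frame with one row per site; must contain `chrom`, `pos`,
#'   `ref`, `alt`; may contain `gene_id`, `consequence`, `ex_score`.
#' @param samples data frame with columns `sample_id`, `species`, `population`
#'   (`"island"` or `"mainland"`), one row per column of `gt`; a bare character
#'   vector of sample ids is also accepted.
#' @param dp,ad_minor optional numeric matrices, same shape as `gt`: total read
#'   depth and minor-allele read support per genotype.
#' @param contigs optional data frame (`chrom`, `length`) used for VCF headers.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(gt, sites, samples, dp = NULL, ad_minor = NULL,
                            contigs = NULL) {
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  if (is.character(samples)) {
    samples <- data.frame(sample_id = samples, species = "unknown",
                          population = NA_character_)
  }
  stopifnot(nrow(sites) == nrow(gt), nrow(samples) == ncol(gt))
  if (!all(gt %in% c(0L, 1L, 2L) | is.na(gt)))
    stop("genotypes must be 0, 1, 2 or NA")
  for (m in list(dp, ad_minor))
    if (!is.null(m)) stopifnot(all(dim(m) == dim(gt)))
  if (!is.null(dp) && !is.null(ad_minor) &&
      any(ad_minor > dp, na.rm = TRUE))
    stop("minor-allele support exceeds depth at some genotypes")
  colnames(gt) <- samples$sample_id
  structure(
    list(gt = gt, sites = as.data.frame(sites), samples = as.data.frame(samples),
         dp = dp, ad_minor = ad_minor, contigs = contigs),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sites x %d samples\n",
              nrow(x$gt), ncol(x$gt)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$sites$chrom), collapse = ", ")))
  cat(sprintf("  missing genotypes: %d; depth/AD: %s\n",
              sum(is.na(x$gt)),
              if (is.null(x$dp)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$gt)

#' Derived-allele matrix container
#'
#' Genotypes recoded as counts of the derived allele (0, 1, 2 or `NA`) after
#' outgroup polarisation.  Each retained site carries exactly one ancestral and
#' one derived allele in `sites$ancestral` / `sites$derived`.
#'
#' @param der integer matrix, sites x samples, derived-allele counts.
#' @param sites data frame as in [genotype_matrix()], plus `ancestral` and
#'   `derived` columns.
#' @param samples sample data frame (see [genotype_matrix()]).
#'
#' @return An object of class `derived_matrix`.
#' @export
derived_matrix <- function(der, sites, samples) {
  der <- as.matrix(der)
  storage.mode(der) <- "integer"
  stopifnot(nrow(sites) == nrow(der),
            all(c("ancestral", "derived") %in% names(sites)))
  if (is.character(samples))
    samples <- data.frame(sample_id = samples, species = "unknown",
                          population = NA_character_)
  stopifnot(nrow(samples) == ncol(der))
  bad <- sites$ancestral == sites$derived
  if (any(bad)) stop("ancestral and derived alleles identical at some sites")
  colnames(der) <- samples$sample_id
  structure(list(der = der, sites = as.data.frame(sites),
                 samples = as.data.frame(samples)),
            class = "derived_matrix")
}

#' @export
print.derived_matrix <- function(x, ...) {
  cat(sprintf("<derived_matrix> %d polarised sites x %d samples\n",
              nrow(x$der), ncol(x$der)))
  invisible(x)
}

#' @export
dim.derived_matrix <- function(x) dim(x$der)

# Internal: genotype codes for one sample as an integer vector, for either
# container (gt for genotype_matrix, der for derived_matrix).
geno_vector <- function(x, sample) {
  m <- if (inherits(x, "derived_matrix")) x$der else x$gt
  if (is.character(sample)) {
    j <- match(sample, colnames(m))
    if (is.na(j)) stop("unknown sample: ", sample)
  } else j <- sample
  m[, j]
}

# Internal: resolve sample ids for a population label.
population_samples <- function(x, population) {
  ids <- x$samples$sample_id[x$samples$population == population]
  if (length(ids) == 0) stop("no samples in population '", population, "'")
  ids
}
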