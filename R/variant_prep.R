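#' Read a multi-sample VCF of biallelic SNPs into a genotype matrix
#'
#' Parses GT, DP and AD fields via the `vcfR` package.  Multi-allelic sites
#' and indels are rejected at read time: only sites whose REF and ALT are both
#' single bases and whose ALT holds exactly one allele are kept (a message
#' reports the number dropped).  The per-genotype minor-allele read support is
#' `min(AD)` of the two allele depths.
#'
#' @param path VCF file (plain or gzipped).
#' @param samples optional sample metadata data frame (`sample_id`, `species`,
#'   `population`) to attach; defaults to bare ids from the VCF header.
#' @return A [genotype_matrix()].
#' @export
read_genotype_vcf <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    ids <- colnames(v@gt)[-1]
    gt <- matrix(NA_integer_, 0, length(ids))
    sites <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character())
    smp <- if (is.null(samples)) ids else samples
    return(genotype_matrix(gt, sites, smp))
  }
  snp <- !is.na(fix$ALT) & nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (any(!snp))
    message("read_genotype_vcf: dropped ", sum(!snp),
            " non-biallelic-SNP records")
  v <- v[snp, ]
  fix <- fix[snp, , drop = FALSE]
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x == "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x == "1/1"] <- 2L
    out
  }
  gt <- matrix(code(gt_raw), nrow(gt_raw), ncol(gt_raw),
               dimnames = dimnames(gt_raw))
  dp <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  ad <- vcfR::extract.gt(v, element = "AD")
  ad_minor <- NULL
  if (!all(is.na(ad))) {
    a1 <- suppressWarnings(vcfR::masplit(ad, record = 1L, sort = 0))
    a2 <- suppressWarnings(vcfR::masplit(ad, record = 2L, sort = 0))
    ad_minor <- pmin(a1, a2)
  }
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  ids <- colnames(gt)
  smp <- if (is.null(samples)) ids else {
    m <- match(ids, samples$sample_id)
    if (anyNA(m)) stop("metadata missing for samples: ",
                       paste(ids[is.na(m)], collapse = ", "))
    samples[m, , drop = FALSE]
  }
  genotype_matrix(gt, sites, smp, dp = dp, ad_minor = ad_minor)
}

#' Attach site annotations (gene, consequence, EX score, ancestral allele)
#'
#' Left-joins an annotation table onto the sites of a genotype matrix by
#' chromosome and position.
#'
#' @param gm a [genotype_matrix()].
#' @param annot data frame with `chrom`, `pos` and any of `gene_id`,
#'   `consequence`, `ex_score`, `ancestral`.
#' @return The genotype matrix with extended `$sites`.
#' @export
annotate_sites <- function(gm, annot) {
  key <- function(d) paste(d$chrom, d$pos)
  m <- match(key(gm$sites), key(annot))
  for (col in setdiff(names(annot), c("chrom", "pos")))
    gm$sites[[col]] <- annot[[col]][m]
  gm
}

#' Mask heterozygous genotypes with skewed allelic balance
#'
#' Heterozygous genotypes whose minor-allele read fraction
#' (`minor support / depth`) is strictly below `min_support_fraction` are set
#' to missing.  Homozygous and already-missing genotypes are untouched.
#' Genotypes without usable AD/DP evidence are left unmasked; their number is
#' reported via a warning and returned in the `n_no_ad` attribute.
#'
#' @param gm a [genotype_matrix()] with `dp` and `ad_minor`.
#' @param min_support_fraction allelic-balance threshold in `[0, 0.5]`
#'   (default 0.25).
#' @return The masked genotype matrix.
#' @export
mask_allelic_balance <- function(gm, min_support_fraction = 0.25) {
  stopifnot(min_support_fraction >= 0, min_support_fraction <= 0.5)
  het <- !is.na(gm$gt) & gm$gt == 1L
  if (is.null(gm$ad_minor) || is.null(gm$dp)) {
    n_bad <- sum(het)
    warning("no AD/DP fields: ", n_bad, " heterozygous genotypes left unmasked")
    attr(gm, "n_no_ad") <- n_bad
    return(gm)
  }
  frac <- gm$ad_minor / gm$dp
  no_ev <- het & (is.na(frac) | !is.finite(frac))
  if (any(no_ev))
    warning(sum(no_ev), " heterozygous genotypes lack AD/DP evidence; ",
            "left unmasked")
  mask <- het & !is.na(frac) & is.finite(frac) & frac < min_support_fraction
  gm$gt[mask] <- NA_integer_
  attr(gm, "n_no_ad") <- sum(no_ev)
  attr(gm, "n_masked_ab") <- sum(mask)
  gm
}

#' Mask genotypes with outlying read depth
#'
#' For each sample, genotypes with depth strictly below half or strictly above
#' double that sample's genome-wide mean depth are set to missing.  The mean is
#' computed per sample over every genotype carrying depth evidence (genotypes
#' the caller originally emitted), not over the currently unmasked ones, so
#' the thresholds do not shift as genotypes are removed and the mask commutes
#' with the allelic-balance mask and with itself.
#'
#' @param gm a [genotype_matrix()] with `dp`.
#' @return The masked genotype matrix (attribute `n_masked_depth` holds the
#'   count of newly masked genotypes).
#' @export
mask_depth <- function(gm) {
  if (is.null(gm$dp)) stop("genotype matrix has no depth (DP) information")
  ok <- !is.na(gm$gt)
  all_missing <- colSums(ok) == 0
  if (any(all_missing))
    stop("sample(s) with no genotyped sites: ",
         paste(gm$samples$sample_id[all_missing], collapse = ", "))
  mean_dp <- colMeans(gm$dp, na.rm = TRUE)
  lo <- matrix(0.5 * mean_dp, nrow(gm$gt), ncol(gm$gt), byrow = TRUE)
  hi <- matrix(2.0 * mean_dp, nrow(gm$gt), ncol(gm$gt), byrow = TRUE)
  mask <- ok & !is.na(gm$dp) & (gm$dp < lo | gm$dp > hi)
  gm$gt[mask] <- NA_integer_
  attr(gm, "n_masked_depth") <- sum(mask)
  gm
}

#' Polarise genotypes to derived-allele counts using three outgroups
#'
#' A site is retained if and only if all three outgroup genotypes are
#' non-missing, homozygous, mutually identical, and the shared allele equals
#' the site's REF or ALT.  The shared allele is the ancestral allele; the
#' other allele is derived; genotypes are recoded to derived-allele counts
#' (0/1/2, missing preserved).
#'
#' @param gm a [genotype_matrix()].
#' @param outgroups outgroup table from [emit_outgroups()] /
#'   [read_outgroups()]: `chrom`, `pos`, `out1`, `out2`, `out3` with
#'   `"A/A"`-style genotype strings (`"./."` or `NA` = missing).
#' @return A [derived_matrix()] restricted to the retained sites.
#' @export
polarize <- function(gm, outgroups) {
  key <- function(d) paste(d$chrom, d$pos)
  m <- match(key(gm$sites), key(outgroups))
  og <- outgroups[m, c("out1", "out2", "out3"), drop = FALSE]
  split_gt <- function(x) {
    x[is.na(x) | x == "./." | x == "."] <- NA
    a <- substr(x, 1, 1)
    b <- substr(x, 3, 3)
    list(a = a, b = b)
  }
  g1 <- split_gt(og$out1); g2 <- split_gt(og$out2); g3 <- split_gt(og$out3)
  hom1 <- !is.na(g1$a) & g1$a == g1$b
  hom2 <- !is.na(g2$a) & g2$a == g2$b
  hom3 <- !is.na(g3$a) & g3$a == g3$b
  concordant <- hom1 & hom2 & hom3 & g1$a == g2$a & g2$a == g3$a
  shared <- ifelse(concordant, g1$a, NA)
  keep <- !is.na(shared) &
    (shared == gm$sites$ref | shared == gm$sites$alt)
  anc <- shared[keep]
  sites <- gm$sites[keep, , drop = FALSE]
  der_allele <- ifelse(anc == sites$ref, sites$alt, sites$ref)
  der <- gm$gt[keep, , drop = FALSE]
  flip <- anc != sites$ref
  der[flip, ] <- 2L - der[flip, , drop = FALSE]
  sites$ancestral <- anc
  sites$derived <- der_allele
  derived_matrix(der, sites, gm$samples)
}

#' Remove sites with no observed derived allele
#'
#' Drops polarised sites at which no sampled genome carries a derived allele
#' (ancestral-invariant sites).  Sites fixed for the derived allele are
#' retained: they are variable relative to the ancestor and carry load and
#' fixation information.
#'
#' @param dm a [derived_matrix()].
#' @return The filtered derived matrix.
#' @export
drop_invariant <- function(dm) {
  stopifnot(inherits(dm, "derived_matrix"))
  n_der <- rowSums(dm$der, na.rm = TRUE)
  keep <- n_der > 0
  dm$der <- dm$der[keep, , drop = FALSE]
  dm$sites <- dm$sites[keep, , drop = FALSE]
  dm
}

#' Write a derived matrix as VCF with the standard AA (ancestral allele) tag
#'
#' Genotypes are written in reference coding (recovered from the derived
#' counts) with `INFO/AA` carrying the ancestral allele.
#'
#' @param dm a [derived_matrix()].
#' @param path output VCF path.
#' @param contigs optional contig table (`chrom`, `length`) for the header.
#' @return `path`, invisibly.
#' @export
write_derived_vcf <- function(dm, path, contigs = NULL) {
  gt <- dm$der
  flip <- dm$sites$ancestral != dm$sites$ref
  gt[flip, ] <- 2L - gt[flip, , drop = FALSE]
  gm <- genotype_matrix(gt, dm$sites, dm$samples,
                        dp = matrix(1L, nrow(gt), ncol(gt)),
                        ad_minor = matrix(0L, nrow(gt), ncol(gt)),
                        contigs = contigs)
  gm$dp <- NULL; gm$ad_minor <- NULL
  emit_vcf(gm, path, seed = 0L)
  invisible(path)
}
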