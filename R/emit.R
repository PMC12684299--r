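#' Write a genotype matrix as a VCF 4.2 file with a sequencing-noise model
#'
#' Serialises genotypes with `GT:DP:AD` fields.  If the genotype matrix has no
#' depth information (the simulator's clean truth genotypes), per-genotype
#' depth is drawn from a Poisson with mean `mean_depth` and the allele depth of
#' heterozygotes is split binomially (p = 0.5) between the two alleles, so the
#' written file carries realistic allelic-balance noise while the genotype
#' calls themselves remain the truth.  Matrices that already carry `dp` /
#' `ad_minor` are written as-is.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path (plain-text `.vcf`).
#' @param mean_depth Poisson mean for the depth model (ignored when `gm`
#'   already has depths).
#' @param seed integer seed for the noise draws; `NULL` uses the current RNG
#'   state.
#' @return `path`, invisibly.
#' @export
emit_vcf <- function(gm, path, mean_depth = 30, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  writer <- function() {
    n_site <- nrow(gm$gt); n_samp <- ncol(gm$gt)
    if (is.null(gm$dp)) {
      dp <- matrix(rpois(n_site * n_samp, mean_depth), n_site, n_samp)
      alt_reads <- matrix(0L, n_site, n_samp)
      het <- which(gm$gt == 1L)
      alt_reads[het] <- rbinom(length(het), dp[het], 0.5)
      hom_alt <- which(gm$gt == 2L)
      alt_reads[hom_alt] <- dp[hom_alt]
    } else {
      dp <- gm$dp
      # reconstruct alt reads from minor support: minor allele is the one the
      # genotype carries fewer copies of
      alt_reads <- matrix(0L, n_site, n_samp)
      alt_reads[gm$gt == 2L] <- dp[gm$gt == 2L]
      het <- which(gm$gt == 1L)
      alt_reads[het] <- gm$ad_minor[het]
    }
    gt_str <- matrix("./.:.:.", n_site, n_samp)
    ok <- !is.na(gm$gt)
    code <- c("0/0", "0/1", "1/1")
    gt_str[ok] <- paste0(code[gm$gt[ok] + 1L], ":", dp[ok], ":",
                         dp[ok] - alt_reads[ok], ",", alt_reads[ok])
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=islandload",
      if (!is.null(gm$contigs))
        sprintf("##contig=<ID=%s,length=%d>", gm$contigs$chrom,
                as.integer(gm$contigs$length)),
      "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", gm$samples$sample_id), collapse = "\t"))
    info <- if (!is.null(gm$sites$ancestral))
      paste0("AA=", gm$sites$ancestral) else rep(".", n_site)
    body <- if (n_site > 0) {
      fixed <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref,
                     gm$sites$alt, ".", "PASS", info, "GT:DP:AD", sep = "\t")
      paste(fixed, apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
    } else character()
    writeLines(c(header, body), path)
  }
  if (is.null(seed)) writer() else with_seed(seed, writer())
  invisible(path)
}

#' Emit an outgroup genotype table for ancestral-allele polarisation
#'
#' Produces three outgroup genotype columns per site.  By default all three
#' outgroups are homozygous for the true ancestral allele; the requested
#' fractions of sites are corrupted to exercise the polarisation filter: at a
#' "discordant" site one random outgroup is homozygous for the derived allele,
#' at a "heterozygous" site one random outgroup carries an
#' ancestral/derived heterozygote.  The two corrupted sets are disjoint.
#'
#' @param sites site table with `chrom`, `pos`, `ref`, `alt` and `ancestral`
#'   columns (e.g. `gm$sites` from [wf_simulate()]).
#' @param discordant_fraction,het_fraction fractions in `[0, 1]` of sites made
#'   discordant / heterozygous.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return Data frame `chrom`, `pos`, `out1`, `out2`, `out3` with genotypes as
#'   `"A/A"`-style strings, plus a logical `corrupted` attribute-free column
#'   set (`status`: `"concordant"`, `"discordant"` or `"het"`).
#' @export
emit_outgroups <- function(sites, discordant_fraction = 0, het_fraction = 0,
                           seed = NULL) {
  stopifnot(discordant_fraction >= 0, discordant_fraction <= 1,
            het_fraction >= 0, het_fraction <= 1,
            discordant_fraction + het_fraction <= 1)
  build <- function() {
    n <- nrow(sites)
    anc <- sites$ancestral
    der <- ifelse(anc == sites$ref, sites$alt, sites$ref)
    og <- matrix(paste0(anc, "/", anc), n, 3)
    status <- rep("concordant", n)
    n_disc <- round(discordant_fraction * n)
    n_het <- round(het_fraction * n)
    pick <- if (n > 0) sample.int(n, min(n, n_disc + n_het)) else integer()
    disc <- pick[seq_len(min(n_disc, length(pick)))]
    hets <- setdiff(pick, disc)
    if (length(disc)) {
      col <- sample.int(3L, length(disc), replace = TRUE)
      og[cbind(disc, col)] <- paste0(der[disc], "/", der[disc])
      status[disc] <- "discordant"
    }
    if (length(hets)) {
      col <- sample.int(3L, length(hets), replace = TRUE)
      og[cbind(hets, col)] <- paste0(anc[hets], "/", der[hets])
      status[hets] <- "het"
    }
    data.frame(chrom = sites$chrom, pos = sites$pos,
               out1 = og[, 1], out2 = og[, 2], out3 = og[, 3],
               status = status, stringsAsFactors = FALSE)
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Write/read tab-separated site annotations, outgroups and sample metadata
#'
#' Plain TSV serialisation of the auxiliary tables: the per-site annotation
#' table (chrom, pos, ref, alt, ancestral, gene_id, consequence, ex_score),
#' the outgroup genotype table and the sample metadata table
#' (sample_id, species, population).
#'
#' @param x the table to write.
#' @param path file path.
#' @return `path` (writers, invisibly) or the table (readers).
#' @export
write_site_table <- function(x, path) {
  if (inherits(x, "genotype_matrix")) x <- x$sites
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname write_site_table
#' @export
write_outgroups <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_outgroups <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname write_site_table
#' @export
write_sample_metadata <- function(x, path) {
  if (inherits(x, "genotype_matrix")) x <- x$samples
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_sample_metadata <- function(path) {
  md <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "species", "population")
  if (!all(need %in% names(md)))
    stop("sample metadata must have columns: ", paste(need, collapse = ", "))
  md
}
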