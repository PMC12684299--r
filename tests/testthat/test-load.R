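test_that("consequence classification maps the LoF list and EX boundary", {
  expect_equal(classify_effect("stop_gained"), "lof")
  expect_equal(classify_effect("splice_region_variant"), "lof")
  expect_equal(classify_effect("transcript_ablation"), "lof")
  expect_equal(classify_effect("synonymous_variant"), "synonymous")
  expect_equal(classify_effect("missense_variant", 0.256),
               "missense_deleterious")            # boundary inclusive
  expect_equal(classify_effect("missense_variant", 0.2561),
               "missense_tolerated")
  expect_equal(classify_effect("missense_variant", 0.30),
               "missense_tolerated")
  expect_equal(classify_effect("intron_variant"), "excluded")
  expect_equal(classify_effect("stop gained"), "lof")   # space tolerated
  expect_error(classify_effect("missense_variant"), "EX score")
})

test_that("every site lands in exactly one category bucket", {
  sim <- wf_simulate(tiny_sim(13))
  eff <- classify_effect(sim$geno$sites$consequence, sim$geno$sites$ex_score)
  cats <- c("lof", "missense_deleterious", "missense_tolerated",
            "synonymous", "excluded")
  expect_true(all(eff %in% cats))
  expect_equal(sum(table(eff)), nrow(sim$geno$gt))
})

make_dm <- function(der, gene = NULL, csq = "synonymous_variant", ex = NA,
                    pops = NULL) {
  der <- as.matrix(der)
  n <- nrow(der)
  sites <- data.frame(chrom = "chr1", pos = seq_len(n), ref = "A", alt = "G",
                      ancestral = "A", derived = "G",
                      gene_id = if (is.null(gene)) rep("g1", n) else gene,
                      consequence = rep(csq, length.out = n),
                      ex_score = rep(ex, length.out = n))
  ids <- sprintf("s%d", seq_len(ncol(der)))
  samples <- data.frame(sample_id = ids, species = "toy",
                        population = if (is.null(pops))
                          rep("island", ncol(der)) else pops)
  derived_matrix(der, sites, samples)
}

test_that("load counts follow the species-wide n_p definition", {
  # 10 sites, 3 samples; sample 1 het at 2 sites, hom at 1
  der <- matrix(0L, 10, 3)
  der[1, 1] <- 1L; der[2, 1] <- 1L; der[3, 1] <- 2L
  der[4:10, 2] <- 1L      # keeps the remaining sites segregating species-wide
  dm <- make_dm(der)
  eff <- rep("synonymous", 10)
  ct <- load_counts(dm, eff, "s1", "synonymous")
  expect_equal(ct, list(n_het = 2L, n_hom = 1L, n_p = 10L))
  # a sample with no derived alleles
  expect_equal(load_counts(dm, eff, "s3", "synonymous"),
               list(n_het = 0L, n_hom = 0L, n_p = 10L))
  # hom-derived everywhere
  dm2 <- make_dm(matrix(2L, 5, 2))
  expect_equal(load_counts(dm2, rep("synonymous", 5), "s1", "synonymous"),
               list(n_het = 0L, n_hom = 5L, n_p = 5L))
})

test_that("relative abundance evaluates (n_het + 2 n_hom) / (2 n_p)", {
  expect_equal(relative_abundance(0, 10, 10), 1.0)
  expect_equal(relative_abundance(0, 0, 10), 0.0)
  expect_equal(relative_abundance(2, 1, 10), 0.2)
  expect_error(relative_abundance(1, 1, 0), "n_p")
})

test_that("RA ignores sites outside n_p and increases with derived counts", {
  # invariant sites never enter n_p, so adding them leaves RA unchanged
  der <- matrix(c(1L, 2L, 0L, 0L, 1L, 1L), 3, 2)
  dm <- make_dm(der)
  eff <- rep("synonymous", 3)
  ct <- load_counts(dm, eff, "s1", "synonymous")
  ra1 <- relative_abundance(ct$n_het, ct$n_hom, ct$n_p)
  der_plus <- rbind(der, c(0L, 0L))      # ancestral-invariant addition
  # (drop_invariant would remove it; even retained it stays out of n_p)
  dm2 <- make_dm(der_plus)
  ct2 <- load_counts(dm2, rep("synonymous", 4), "s1", "synonymous")
  expect_equal(relative_abundance(ct2$n_het, ct2$n_hom, ct2$n_p), ra1)
  # strictly increasing in each count
  expect_gt(relative_abundance(3, 1, 10), relative_abundance(2, 1, 10))
  expect_gt(relative_abundance(2, 2, 10), relative_abundance(2, 1, 10))
})

test_that("derived homozygosity handles the undefined case", {
  expect_equal(derived_homozygosity(0, 5), 1.0)
  expect_equal(derived_homozygosity(3, 1), 0.25)
  expect_true(is.na(derived_homozygosity(0, 0)))
})

test_that("fixed homozygous LoF genes require every genotype hom-derived", {
  der <- matrix(2L, 3, 4)
  dm <- make_dm(der, gene = c("gA", "gA", "gB"),
                csq = c("stop_gained", "synonymous_variant", "stop_gained"))
  eff <- classify_effect(dm$sites$consequence, dm$sites$ex_score)
  expect_equal(fixed_homozygous_lof_genes(dm, eff, paste0("s", 1:4)),
               c("gA", "gB"))
  # one het carrier breaks fixation
  der2 <- der; der2[3, 2] <- 1L
  dm2 <- make_dm(der2, gene = c("gA", "gA", "gB"),
                 csq = c("stop_gained", "synonymous_variant", "stop_gained"))
  expect_equal(fixed_homozygous_lof_genes(dm2, eff, paste0("s", 1:4)), "gA")
  # missing genotypes are ignored, not disqualifying
  der3 <- der; der3[1, 1] <- NA
  dm3 <- make_dm(der3, gene = c("gA", "gA", "gB"),
                 csq = c("stop_gained", "synonymous_variant", "stop_gained"))
  expect_equal(fixed_homozygous_lof_genes(dm3, eff, paste0("s", 1:4)),
               c("gA", "gB"))

  # brute-force recount on a random 5-gene toy
  set.seed(33)
  genes <- sprintf("g%d", sample(1:5, 30, TRUE))
  csq <- sample(c("stop_gained", "missense_variant", "synonymous_variant"),
                30, TRUE, prob = c(.3, .3, .4))
  ex <- ifelse(csq == "missense_variant", runif(30), NA)
  der4 <- matrix(sample(c(0L, 1L, 2L, NA), 30 * 6, TRUE,
                        prob = c(.2, .2, .5, .1)), 30, 6)
  der4[rowSums(der4, na.rm = TRUE) == 0, 1] <- 1L
  dm4 <- make_dm(der4, gene = genes, csq = csq, ex = ex)
  eff4 <- classify_effect(csq, ex)
  want <- sort(unique(genes[vapply(seq_len(30), function(i) {
    eff4[i] == "lof" && sum(!is.na(der4[i, ])) >= 1 &&
      all(der4[i, !is.na(der4[i, ])] == 2L)
  }, logical(1))]))
  expect_equal(fixed_homozygous_lof_genes(dm4, eff4, paste0("s", 1:6)), want)
})

test_that("group comparison applies the Welch test with an N >= 3 guard", {
  out <- compare_groups(c(1, 2), c(1, 2, 3, 4, 5, 6, 7, 8))
  expect_false(out$testable)
  expect_match(out$reason, "N < 3")

  x <- c(0.1, 0.2, 0.3, 0.4)
  same <- compare_groups(x, x)
  expect_true(same$testable)
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  set.seed(9)
  a <- rnorm(20, 0, 1); b <- rnorm(20, 0.8, 1.6)
  got <- compare_groups(a, b)
  want <- welch_oracle(a, b)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
  expect_equal(got$df, want$df, tolerance = 1e-9)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
})

test_that("the per-sample load table is consistent with its own counts", {
  sim <- wf_simulate(tiny_sim(17))
  dm <- dm_from_truth(sim$geno)
  tab <- load_summary(dm)
  expect_true(all(tab$ra >= 0 & tab$ra <= 1, na.rm = TRUE))
  expect_equal(tab$ra, (tab$n_het + 2 * tab$n_hom) / (2 * tab$n_p))
  hz <- ifelse(tab$n_het + tab$n_hom == 0, NA,
               tab$n_hom / (tab$n_het + tab$n_hom))
  expect_equal(tab$derived_homozygosity, hz)
})
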