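test_that("allelic-balance masking applies the < 0.25 rule to hets only", {
  gt <- matrix(c(1L, 1L, 2L, 0L), nrow = 4)          # one sample
  dp <- matrix(10, 4, 1)
  ad <- matrix(c(2, 5, 0, 0), 4, 1)                  # minor-allele reads
  gm <- toy_gm(gt, dp = dp, ad_minor = ad)
  out <- mask_allelic_balance(gm, 0.25)
  expect_true(is.na(out$gt[1, 1]))     # het 2/10 = 0.20 < 0.25 -> masked
  expect_identical(unname(out$gt[2, 1]), 1L)   # het 5/10 = 0.50 -> kept
  expect_identical(unname(out$gt[3, 1]), 2L)   # hom-alt untouched by the rule
  expect_identical(unname(out$gt[4, 1]), 0L)
  expect_equal(attr(out, "n_masked_ab"), 1L)
})

test_that("allelic-balance boundary 0.25 itself is retained", {
  gm <- toy_gm(matrix(1L, 1, 1), dp = matrix(12, 1, 1),
               ad_minor = matrix(3, 1, 1))            # exactly 0.25
  out <- mask_allelic_balance(gm, 0.25)
  expect_identical(unname(out$gt[1, 1]), 1L)
})

test_that("hets without AD evidence are reported, not masked", {
  gm <- toy_gm(matrix(1L, 2, 1), dp = matrix(c(10, NA), 2, 1),
               ad_minor = matrix(c(5, NA), 2, 1))
  expect_warning(out <- mask_allelic_balance(gm), "lack AD/DP")
  expect_identical(unname(out$gt[2, 1]), 1L)
  expect_equal(attr(out, "n_no_ad"), 1L)
})

test_that("depth masking uses strict half/double bounds per sample", {
  # sample mean depth is exactly 30 over the non-missing genotypes
  dp <- matrix(c(14, 15, 61, 60, 30, 0), ncol = 1)
  dp[6] <- 180 - sum(dp[1:5])          # forces mean = 30
  gt <- matrix(0L, 6, 1)
  gm <- toy_gm(gt, dp = dp, ad_minor = matrix(0, 6, 1))
  out <- mask_depth(gm)
  expect_true(is.na(out$gt[1, 1]))     # 14 < 15 -> masked
  expect_identical(unname(out$gt[2, 1]), 0L)   # 15 == 0.5 x mean -> retained
  expect_true(is.na(out$gt[3, 1]))     # 61 > 60 -> masked
  expect_identical(unname(out$gt[4, 1]), 0L)   # 60 == 2 x mean -> retained
})

test_that("depth masking errors on an all-missing sample, naming it", {
  gt <- matrix(c(NA, NA, 0L, 1L), 2, 2)
  gm <- toy_gm(gt, dp = matrix(10, 2, 2), ad_minor = matrix(5, 2, 2))
  expect_error(mask_depth(gm), "s01")
})

test_that("masks are idempotent, order-independent and value-preserving", {
  set.seed(71)
  for (i in 1:15) {
    n <- 40; k <- 4
    gt <- matrix(sample(c(0L, 1L, 2L, NA), n * k, TRUE,
                        prob = c(.4, .3, .25, .05)), n, k)
    if (any(colSums(!is.na(gt)) == 0)) next
    dp <- matrix(rpois(n * k, 20), n, k)
    ad <- matrix(rbinom(n * k, dp, 0.3), n, k)
    ad <- pmin(ad, dp - ad)                       # make it the minor count
    gm <- toy_gm(gt, dp = dp, ad_minor = ad)
    ab_then_dp <- mask_depth(mask_allelic_balance(gm))
    dp_then_ab <- mask_allelic_balance(mask_depth(gm))
    expect_identical(ab_then_dp$gt, dp_then_ab$gt)
    twice <- mask_depth(mask_allelic_balance(ab_then_dp))
    expect_identical(twice$gt, ab_then_dp$gt)
    # masking only introduces missingness; surviving values are unchanged
    kept <- !is.na(ab_then_dp$gt)
    expect_identical(ab_then_dp$gt[kept], gm$gt[kept])
    expect_identical(dim(ab_then_dp$gt), dim(gm$gt))
  }
})

make_og <- function(gm, o1, o2, o3) {
  data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos,
             out1 = o1, out2 = o2, out3 = o3, stringsAsFactors = FALSE)
}

test_that("polarisation keeps concordant homozygous outgroups only", {
  gm <- toy_gm(matrix(c(0L, 1L, 2L, 0L), 4, 1), ref = rep("A", 4),
               alt = rep("G", 4))
  og <- make_og(gm,
                o1 = c("A/A", "A/A", "A/G", "T/T"),
                o2 = c("A/A", "A/A", "A/A", "T/T"),
                o3 = c("A/A", "G/G", "A/A", "T/T"))
  dm <- polarize(gm, og)
  # site 1: concordant A -> retained, derived = G
  # site 2: discordant -> dropped; site 3: het outgroup -> dropped
  # site 4: shared allele matches neither ref nor alt -> dropped
  expect_equal(nrow(dm$der), 1L)
  expect_equal(dm$sites$ancestral, "A")
  expect_equal(dm$sites$derived, "G")
  expect_equal(unname(dm$der[1, 1]), 0L)
})

test_that("polarisation flips coding when the alt allele is ancestral", {
  gm <- toy_gm(matrix(c(0L, 1L, 2L, NA), 4, 1), ref = rep("A", 4),
               alt = rep("G", 4))
  og <- make_og(gm, rep("G/G", 4), rep("G/G", 4), rep("G/G", 4))
  dm <- polarize(gm, og)
  expect_equal(nrow(dm$der), 4L)
  expect_true(all(dm$sites$ancestral == "G" & dm$sites$derived == "A"))
  expect_identical(unname(dm$der[, 1]), c(2L, 1L, 0L, NA))
})

test_that("missing outgroup genotypes drop a site", {
  gm <- toy_gm(matrix(0L, 2, 1))
  og <- make_og(gm, c("A/A", "./."), c("A/A", "A/A"), c("A/A", NA))
  dm <- polarize(gm, og)
  expect_equal(nrow(dm$der), 1L)
})

test_that("invariant-site removal keeps segregating and fixed-derived sites", {
  der <- matrix(c(0L, 0L, 0L,   # invariant ancestral -> dropped
                  1L, 0L, 0L,   # one het -> kept
                  2L, 2L, 2L,   # fixed derived -> kept
                  0L, NA, 0L),  # invariant with missing -> dropped
                nrow = 4, byrow = TRUE)
  sites <- data.frame(chrom = "chr1", pos = 1:4, ref = "A", alt = "G",
                      ancestral = "A", derived = "G")
  dm <- derived_matrix(der, sites, c("a", "b", "c"))
  out <- drop_invariant(dm)
  expect_equal(out$sites$pos, c(2L, 3L))

  # direct-recount toy: 10 sites, 3 invariant
  set.seed(4)
  der10 <- matrix(sample(c(0L, 1L, 2L), 30, TRUE), 10, 3)
  der10[c(2, 5, 9), ] <- 0L
  keep_truth <- rowSums(der10) > 0
  dm10 <- derived_matrix(der10, data.frame(chrom = "chr1", pos = 1:10,
                                           ref = "A", alt = "C",
                                           ancestral = "A", derived = "C"),
                         c("a", "b", "c"))
  expect_equal(nrow(drop_invariant(dm10)$der), sum(keep_truth))
})

test_that("VCF reader rejects indels and multi-allelic records", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1",
    "chr1\t200\t.\tAT\tA\t.\tPASS\t.\tGT\t0/1",
    "chr1\t300\t.\tA\tG,T\t.\tPASS\t.\tGT\t1/2",
    "chr1\t400\t.\tC\tT\t.\tPASS\t.\tGT\t1/1"), path)
  expect_message(gm <- read_genotype_vcf(path), "dropped 2")
  expect_equal(gm$sites$pos, c(100L, 400L))
  expect_identical(unname(gm$gt[, 1]), c(1L, 2L))
})

test_that("polarisation recovers the simulator's ancestral allele exactly", {
  sim <- wf_simulate(tiny_sim(21))
  og <- emit_outgroups(sim$geno$sites, 0, 0, seed = 2)
  dm <- polarize(sim$geno, og)
  expect_equal(nrow(dm$der), nrow(sim$geno$gt))
  expect_identical(dm$sites$ancestral, sim$truth$sites$ancestral)
  expect_identical(unname(dm$der), unname(sim$geno$gt))
})
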