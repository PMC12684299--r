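test_that("heterozygosity counts hets over non-missing genotypes", {
  expect_equal(heterozygosity(toy_gm(matrix(1L, 5, 1)), 1), 1.0)
  expect_equal(heterozygosity(toy_gm(matrix(c(0L, 2L, 0L), 3, 1)), 1), 0.0)
  g <- matrix(c(rep(1L, 3), rep(0L, 7), NA, NA), ncol = 1)
  expect_equal(heterozygosity(toy_gm(g), 1), 0.3)
  expect_error(heterozygosity(toy_gm(matrix(NA_integer_, 2, 1)), 1),
               "no genotyped")
})

test_that("the calibrated minimum ROH SNP count follows the log formula", {
  # ceil( ln(0.05 / (100*1)) / ln(0.5) ) = ceil(10.97) = 11
  expect_equal(min_roh_snps(100, 1, 0.05, 0.5), 11L)
  # whole-genome scale: inverting the formula against a published L of 77
  # for 18,415,827 SNPs over 8 genomes gives het ~ 0.2467
  expect_equal(min_roh_snps(18415827, 8, 0.05, 0.2467), 77L)
  expect_error(min_roh_snps(100, 1, 0.05, 0), "strictly between")
  expect_error(min_roh_snps(100, 1, 0.05, 1), "strictly between")
})

test_that("ROH detection handles the degenerate extremes", {
  p <- roh_params(min_snps = 10, min_length_kb = 1)
  het_gm <- toy_gm(matrix(1L, 200, 1), pos = seq(1, 2e5, length.out = 200))
  expect_equal(nrow(detect_roh(het_gm, 1, p)), 0L)
  hom_gm <- toy_gm(matrix(0L, 200, 1),
                   pos = as.integer(seq(1, 2e5, length.out = 200)))
  seg <- detect_roh(hom_gm, 1, p)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start, hom_gm$sites$pos[1])
  expect_equal(seg$end, hom_gm$sites$pos[200])
  expect_equal(seg$n_snps, 200L)
})

test_that("ROH detection refuses unsorted positions", {
  gm <- toy_gm(matrix(0L, 3, 1), pos = c(10L, 5L, 20L))
  expect_error(detect_roh(gm, 1, roh_params(min_snps = 2)), "sorted")
})

test_that("ROH caller matches the literal window oracle on random cases", {
  set.seed(202)
  for (i in 1:40) {
    n <- sample(60:400, 1)
    inst <- random_roh_instance(n, runif(1, 0.02, 0.3), runif(1, 0, 0.1))
    p <- roh_params(min_snps = sample(5:30, 1),
                    window_het_allowance = sample(0:2, 1),
                    window_missing_allowance = sample(0:5, 1),
                    window_hit_threshold = runif(1, 0.01, 0.9),
                    min_length_kb = sample(c(1, 10, 50), 1),
                    max_gap_kb = sample(c(20, 100, 1000), 1),
                    max_density_kb_per_snp = sample(c(10, 50), 1))
    gm <- toy_gm(matrix(inst$g, ncol = 1), pos = inst$pos)
    got <- detect_roh(gm, 1, p)
    want <- roh_oracle(inst$g, inst$pos, p)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_snps, want$n_snps)
      expect_equal(got$length_bp, want$length_bp)
    }
  }
})

test_that("synthetic homozygous genomes lose hets and keep missingness", {
  gm <- toy_gm(matrix(c(1L, 1L, 0L, 2L, NA, 1L), 6, 1))
  hom <- synthetic_homozygous(gm)
  expect_equal(sum(hom$gt == 1L, na.rm = TRUE), 0L)
  expect_equal(sum(is.na(hom$gt)), 1L)
  expect_identical(synthetic_homozygous(hom)$gt, hom$gt)
  all_het <- synthetic_homozygous(toy_gm(matrix(1L, 4, 1)))
  expect_true(all(all_het$gt != 1L))
})

test_that("F_ROH is a ratio of summed lengths with guarded edge cases", {
  seg <- function(lens) data.frame(length_bp = lens)
  expect_equal(f_roh(seg(25e6), seg(100e6)), 0.25)
  expect_equal(f_roh(seg(numeric(0)), seg(numeric(0))), 0)
  expect_equal(f_roh(seg(numeric(0)), seg(5e6)), 0)
  expect_error(f_roh(seg(1e6), seg(numeric(0))), "identical parameters")
  # self-normalisation: a synthetic homozygous genome scores 1 against itself
  gm <- toy_gm(matrix(sample(c(0L, 1L, 2L), 300, TRUE), ncol = 1),
               pos = as.integer(seq(1, 3e5, length.out = 300)))
  hom <- synthetic_homozygous(gm)
  p <- roh_params(min_snps = 20, min_length_kb = 10)
  s <- detect_roh(hom, 1, p)
  expect_equal(f_roh(s, s), 1.0)
})

test_that("the recombination clock evaluates and inverts exactly", {
  expect_equal(roh_length_for_age(110, 0.448), 50 / (0.448 * 110))
  expect_equal(round(roh_length_for_age(110, 0.448)), 1)  # ~1.01 Mb
  expect_equal(roh_age_generations(0.5, 1), 100)
  g <- c(10, 110, 1450); r <- c(0.448, 1, 2.3)
  expect_equal(roh_age_generations(roh_length_for_age(g, r), r), g)
  expect_error(roh_age_generations(-1, 0.448))
  expect_error(roh_length_for_age(110, 0))
})

test_that("age classification is boundary-inclusive at the clock length", {
  clock <- recomb_clock()           # 0.448 cM/Mb, 110 generations -> 1 Mb
  expect_equal(clock$length_threshold_mb, 1)
  expect_equal(clock$years_before_present, 1210)
  seg <- data.frame(length_bp = c(1000000, 999999, 77000))
  out <- classify_roh_age(seg, clock)
  expect_equal(out$age_class, c("contemporary", "historical", "historical"))
})

test_that("contemporary and historical components partition F_ROH", {
  sim <- wf_simulate(tiny_sim(31))
  p <- roh_params(min_snps = 20, min_length_kb = 10)
  rs <- roh_summary(sim$geno, p)
  s <- rs$summary
  expect_true(all(s$f_roh >= 0 & s$f_roh <= 1))
  expect_equal(s$f_roh_contemporary + s$f_roh_historical, s$f_roh)
  with_seg <- s$sample_id[s$n_roh > 0]
  expect_true(length(with_seg) > 0)   # the bottleneck must generate ROH
  for (id in with_seg) {
    seg <- rs$segments[rs$segments$sample == id, ]
    expect_equal(sum(seg$length_bp), s$l_roh_bp[s$sample_id == id])
  }
})

test_that("F_ROH is monotonically non-increasing in the minimum SNP count", {
  sim <- wf_simulate(tiny_sim(55))
  gm <- sim$geno
  id <- "isl_01"
  hom <- synthetic_homozygous(gm)
  vals <- vapply(c(10L, 20L, 40L, 80L), function(L) {
    # window held fixed so only the run-length filter varies
    p <- roh_params(min_snps = L, window_snps = 15L, min_length_kb = 10)
    f_roh(detect_roh(gm, id, p), detect_roh(hom, id, p))
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})
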