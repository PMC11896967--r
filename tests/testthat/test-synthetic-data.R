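test_that("place_sites returns sorted unique in-bounds sites, deterministically", {
  gmap <- genetic_map("chr1", 1e7)
  s <- place_sites(gmap, 5, seed = 7)
  expect_equal(nrow(s), 5)
  expect_true(all(s$pos >= 1 & s$pos <= 1e7))
  expect_false(is.unsorted(s$pos))
  expect_false(anyDuplicated(paste(s$chrom, s$pos)) > 0)
  expect_identical(s, place_sites(gmap, 5, seed = 7))

  causal <- list(chrom = "chr1", pos = 5e6)
  s2 <- place_sites(gmap, 5, seed = 7, causal = causal)
  expect_true(any(s2$chrom == "chr1" & s2$pos == 5e6))

  tiny <- genetic_map("chr1", 4)
  expect_error(place_sites(tiny, 10, seed = 1), "exceeds")
  expect_error(place_sites(gmap, 3, causal = list(chrom = "chr1", pos = 2e7)),
               "outside")
})

test_that("sites spread over chromosomes roughly proportional to length", {
  gmap <- genetic_map(c("chr1", "chr2"), c(9e6, 1e6))
  s <- place_sites(gmap, 4000, seed = 11)
  frac <- mean(s$chrom == "chr1")
  expect_gt(frac, 0.85); expect_lt(frac, 0.95)  # expect 0.9
})

test_that("F2 segregation is 3:1 and the phenotype rule is recessive", {
  gmap <- genetic_map("chr1", 1e7)
  causal <- list(chrom = "chr1", pos = 5e6)
  sites <- place_sites(gmap, 9, seed = 2, causal = causal)
  pop <- simulate_f2(gmap, sites, causal, n_f2 = 20000, seed = 3)
  p_gt <- mean(pop$phenotype == "GT")
  se <- sqrt(0.25 * 0.75 / 20000)
  expect_lt(abs(p_gt - 0.25), 4 * se)
  ci <- pop$causal_index
  expect_identical(pop$phenotype == "GT", unname(pop$dosage[, ci] == 2L))
})

test_that("zero map distance gives identical alleles; huge distance gives independence", {
  gmap <- genetic_map("chr1", 1e10)
  # adjacent base pairs: d = 1e-6 cM, r ~ 1e-8 -- effectively 0 bp apart
  sites0 <- data.frame(chrom = "chr1", pos = c(1000, 1001))
  pop0 <- simulate_f2(gmap, sites0, list(chrom = "chr1", pos = 1000),
                      n_f2 = 500, seed = 4)
  expect_identical(pop0$dosage[, 1], pop0$dosage[, 2])

  # d = 10 000 cM: Haldane r -> 1/2, dosages uncorrelated
  sitesF <- data.frame(chrom = "chr1", pos = c(1, 1e10))
  popF <- simulate_f2(gmap, sitesF, list(chrom = "chr1", pos = 1),
                      n_f2 = 5000, seed = 5)
  expect_lt(abs(cor(popF$dosage[, 1], popF$dosage[, 2])), 0.06)
})

test_that("suppressed intervals shorten the genetic map locally", {
  si <- data.frame(chrom = "chr1", start = 1e6, end = 2e6, multiplier = 0)
  gmap <- genetic_map("chr1", 1e7, recomb_rate = 1,
                      suppressed_intervals = si)
  # positions flanking the suppressed Mb are ~0 cM apart
  d <- bsamap:::genetic_position(gmap, "chr1", 2e6 + 1) -
       bsamap:::genetic_position(gmap, "chr1", 1e6 - 1)
  expect_lt(d, 0.01)
  plain <- genetic_map("chr1", 1e7)
  expect_equal(bsamap:::genetic_position(plain, "chr1", 3e6), 3, tolerance = 1e-9)
})

test_that("form_bulks samples exactly bulk_size per class and errors when short", {
  pop <- fake_population(rep(c("WT", "GT"), c(40, 20)))
  expect_error(form_bulks(pop, 30), "GT")
  gmap <- genetic_map("chr1", 1e7)
  causal <- list(chrom = "chr1", pos = 5e6)
  sites <- place_sites(gmap, 9, seed = 2, causal = causal)
  rich <- simulate_f2(gmap, sites, causal, n_f2 = 1000, seed = 6)
  b <- form_bulks(rich, 30, seed = 7)
  expect_length(b$wt, 30); expect_length(b$gt, 30)
  ci <- rich$causal_index
  expect_true(all(rich$dosage[b$gt, ci] == 2L))
  expect_true(all(rich$dosage[b$wt, ci] %in% 0:1))
})

test_that("pooled read sampling follows the stated binomial model", {
  fixed2 <- matrix(2L, 30, 2000)  # p = 1 at every site
  r0 <- simulate_pool_reads(fixed2, mean_depth = 30, seq_error = 0,
                            seed = 8)
  expect_true(all(r0$ref == 0))
  expect_true(all(r0$alt == r0$ref + r0$alt))

  r1 <- simulate_pool_reads(fixed2, mean_depth = 30, seq_error = 0.001,
                            depth_law = "fixed", seed = 9)
  # E[alt fraction] = 0.999; SE of the mean over 2000x30 reads ~ 1.3e-4
  expect_equal(sum(r1$alt) / sum(r1$ref + r1$alt), 0.999,
               tolerance = 1e-3)
  expect_error(simulate_pool_reads(fixed2, seq_error = 0.6), "seq_error")
})

test_that("emit_vcf writes a valid two-sample VCF that round-trips", {
  dir <- withr::local_tempdir()
  sites <- data.frame(chrom = "chr1", pos = c(100, 200),
                      ref = c("A", "T"), alt = c("G", "TAA"))
  wt <- data.frame(ref = c(21, 18), alt = c(10, 9))
  gt <- data.frame(ref = c(0, 0), alt = c(28, 28))
  p <- file.path(dir, "toy.vcf")
  emit_vcf(sites, wt, gt, p, chrom_lengths = c(chr1 = 1e6))
  lines <- readLines(p)
  expect_true(any(grepl("^#CHROM\\t.*WT_pool\\tGT_pool$", lines)))
  expect_true(any(grepl("1/1:0,28:28", lines)))   # AD "0,D" in the GT pool
  tab <- read_pool_vcf(p)
  expect_equal(tab$wt_ref, wt$ref); expect_equal(tab$wt_alt, wt$alt)
  expect_equal(tab$gt_ref, gt$ref); expect_equal(tab$gt_alt, gt$alt)
  expect_equal(tab$alt, sites$alt)
})

test_that("identical seeds give bit-identical simulated VCFs", {
  dir <- withr::local_tempdir()
  gmap <- genetic_map("chr1", 5e6)
  cfg <- sim_config(n_f2 = 240, n_sites = 200, causal_chrom = "chr1",
                    causal_pos_bp = 2.5e6, seed = 42)
  p1 <- file.path(dir, "a.vcf"); p2 <- file.path(dir, "b.vcf")
  sim1 <- simulate_bsa(gmap, cfg, vcf_path = p1)
  sim2 <- simulate_bsa(gmap, cfg, vcf_path = p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(sim1$sites, sim2$sites)
  # truth record is consistent with the emitted table
  expect_equal(nrow(sim1$sites), length(sim1$truth$p_wt))
  expect_equal(sim1$sites$pos[sim1$truth$causal_index], 2.5e6)
})

test_that("config validation catches inconsistent designs", {
  expect_error(sim_config(n_f2 = 50, bulk_size = 30), "bulk_size")
  expect_error(sim_config(seq_error = 0.7), "seq_error")
  expect_error(genetic_map("chr1", 1e6,
    suppressed_intervals = data.frame(chrom = "chr1", start = 10,
                                      end = 2e6, multiplier = 0)),
    "outside")
})
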