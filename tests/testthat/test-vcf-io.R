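write_mini_vcf <- function(lines, path) {
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               lines), path)
  path
}

test_that("GT fields code to dosages with half-calls treated as missing", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(c(
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "a", "b", "c", sep = "\t"),
    paste("s1", "100", ".", "A", "G", "30", "PASS", ".", "GT",
          "0/0", "0/1", "./.", sep = "\t"),
    paste("s1", "200", ".", "C", "T", "30", "PASS", ".", "GT",
          "1/1", "1/0", "./1", sep = "\t")), f)
  gm <- read_vcf(f, c(a = "X", b = "X", c = "Y"))
  expect_equal(unname(gm$geno[1, ]), c(0L, 1L, NA))
  expect_equal(unname(gm$geno[2, ]), c(2L, 1L, NA))   # half-call missing
})

test_that("empty VCF body yields a valid zero-variant matrix", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", "a", sep = "\t"), f)
  gm <- read_vcf(f, c(a = "X"))
  expect_s3_class(gm, "geno_matrix")
  expect_equal(n_variants(gm), 0L)
})

test_that("multiallelic records are dropped and errors are informative", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(c(
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "a", sep = "\t"),
    paste("s1", "100", ".", "A", "G,T", "30", "PASS", ".", "GT", "1/2",
          sep = "\t"),
    paste("s1", "200", ".", "C", "T", "30", "PASS", ".", "GT", "1/1",
          sep = "\t")), f)
  gm <- read_vcf(f, c(a = "X"))
  expect_equal(n_variants(gm), 1L)
  expect_equal(gm$variants$pos, 200L)
  expect_error(read_vcf(f, c(zz = "X")), "absent from popmap.*a")
  # unsorted VCF rejected
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(c(
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "a", sep = "\t"),
    paste("s1", "300", ".", "A", "G", "30", "PASS", ".", "GT", "0/0",
          sep = "\t"),
    paste("s1", "100", ".", "C", "T", "30", "PASS", ".", "GT", "1/1",
          sep = "\t")), f2)
  expect_error(read_vcf(f2, c(a = "X")), "sorted")
})

test_that("simulator output survives a VCF round trip exactly", {
  sim <- simulate_populations(sim_config(
    n_pops = 2, samples_per_pop = 5, scaffolds = c(s1 = 2e5, s2 = 1e5),
    target_F = 0.1, seed = 9))
  f <- withr::local_tempfile(fileext = ".vcf")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_vcf(sim$gm, f)
  write_popmap(sim$gm$pops, p)
  back <- read_vcf(f, p)
  expect_identical(unname(back$geno), unname(sim$gm$geno))
  expect_equal(back$variants$pos, sim$gm$variants$pos)
  expect_equal(back$variants$qual, sim$gm$variants$qual)
  expect_equal(unname(back$depth), unname(sim$gm$depth * 1.0))
  expect_equal(back$pops, sim$gm$pops)
  expect_equal(back$scaffolds, sim$gm$scaffolds)
})

test_that("quality filter keeps the Q20 boundary inclusive", {
  gm <- make_gm(matrix(0:2, 3, 3), qual = c(19.9, 20, 35))
  expect_equal(n_variants(filter_quality(gm, 20)), 2L)
  expect_equal(filter_quality(gm, 20)$variants$qual, c(20, 35))
  expect_identical(filter_quality(gm, 0)$variants, gm$variants)
  # brute-force recount on random qualities
  set.seed(1)
  quals <- round(runif(100, 0, 40), 2)
  gm2 <- make_gm(matrix(1L, 100, 2), qual = quals)
  expect_equal(n_variants(filter_quality(gm2, 20)), sum(quals >= 20))
})

test_that("spacing filter follows the greedy keep-first rule", {
  gm <- make_gm(matrix(1L, 4, 2), pos = c(100L, 103L, 106L, 112L))
  expect_equal(filter_spacing(gm, 5)$variants$pos, c(100L, 106L, 112L))
  gm1 <- make_gm(matrix(1L, 1, 2), pos = 50L)
  expect_equal(n_variants(filter_spacing(gm1, 5)), 1L)
  gm2 <- make_gm(matrix(1L, 10, 2), pos = seq(10L, 100L, by = 10L))
  expect_identical(filter_spacing(gm2, 5)$variants, gm2$variants)
})

test_that("depth filter brackets the genome-wide mean per site", {
  depth <- rbind(c(2, 2), c(10, 10), c(35, 35))
  gm <- make_gm(matrix(1L, 3, 2), depth = depth)
  # with reference mean 10: 2 < 10/3 dropped, 10 kept, 35 > 30 dropped
  out <- filter_depth(gm, 1 / 3, 3, genome_mean = 10)
  expect_equal(n_variants(out), 1L)
  expect_equal(out$depth[1, 1], 10)
  # vacuous bounds: identity
  expect_equal(n_variants(filter_depth(gm, 0, Inf)), 3L)
  # uniform depth equals the mean: kept for any factors spanning 1
  gmu <- make_gm(matrix(1L, 3, 2), depth = matrix(7, 3, 2))
  expect_equal(n_variants(filter_depth(gmu, 0.9, 1.1)), 3L)
  # no depth: warning and pass-through
  gmn <- make_gm(matrix(1L, 3, 2))
  expect_warning(out2 <- filter_depth(gmn), "skipped")
  expect_equal(n_variants(out2), 3L)
})

test_that("filters are idempotent and commute with scaffold partitioning", {
  sim <- simulate_populations(sim_config(
    n_pops = 2, samples_per_pop = 4, scaffolds = c(s1 = 2e5, s2 = 2e5),
    target_F = 0.1, seed = 13))
  gm <- sim$gm
  for (flt in list(function(x) filter_quality(x, 20),
                   function(x) filter_spacing(x, 200),
                   function(x) filter_depth(x, 0.5, 1.5))) {
    once <- flt(gm)
    twice <- flt(once)
    expect_identical(twice$variants, once$variants)
    expect_identical(twice$geno, once$geno)
  }
  # per-scaffold filtering then concatenation == whole-matrix filtering
  gw_mean <- mean(rowMeans(gm$depth))
  whole <- filter_depth(filter_spacing(filter_quality(gm, 20), 50),
                        0.5, 1.5, genome_mean = gw_mean)
  parts <- lapply(names(gm$scaffolds), function(sc) {
    part <- subset_variants(gm, gm$variants$chrom == sc)
    filter_depth(filter_spacing(filter_quality(part, 20), 50),
                 0.5, 1.5, genome_mean = gw_mean)
  })
  expect_equal(do.call(rbind, lapply(parts, function(p) p$variants)),
               whole$variants)
})

test_that("filtered output written to VCF re-reads identically", {
  sim <- simulate_populations(sim_config(
    n_pops = 2, samples_per_pop = 4, scaffolds = c(s1 = 2e5),
    target_F = 0.1, seed = 21))
  fl <- filter_snps(sim$gm)
  expect_equal(fl$report$stage, c("input", "quality", "spacing", "depth"))
  expect_true(all(diff(fl$report$n_variants) <= 0))
  f <- withr::local_tempfile(fileext = ".vcf")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_vcf(fl$gm, f); write_popmap(fl$gm$pops, p)
  back <- read_vcf(f, p)
  expect_identical(unname(back$geno), unname(fl$gm$geno))
  expect_equal(back$variants, fl$gm$variants)
})
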