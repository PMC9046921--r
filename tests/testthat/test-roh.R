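# A deterministic single-sample fixture: SNPs every 4 kb, an all-
# heterozygous background with a homozygous tract of given span inserted,
# so the scanning-window algorithm's boundaries can be checked exactly.
roh_fixture <- function(tract_bp, spacing = 4000L, total_bp = 3e6,
                        tract_start = 1e6) {
  pos <- seq(spacing, total_bp, by = spacing)
  g <- rep(1L, length(pos))
  inside <- pos > tract_start & pos <= tract_start + tract_bp
  g[inside] <- 0L
  gm <- make_gm(matrix(g, ncol = 1), pos = as.integer(pos),
                pops = "A", scaffolds = c(s1 = total_bp))
  list(gm = gm, first = min(pos[inside]), last = max(pos[inside]),
       n_inside = sum(inside))
}

test_that("an all-heterozygous sample yields no segments", {
  gm <- make_gm(matrix(1L, 300, 1), pos = seq(4000L, 1200000L, by = 4000L),
                pops = "A", scaffolds = c(s1 = 1200000))
  expect_equal(nrow(scan_sample(gm, "S01")), 0L)
})

test_that("a 600-kb 150-SNP tract is found as one exactly-bounded segment", {
  fx <- roh_fixture(600000)
  expect_equal(fx$n_inside, 150L)
  segs <- scan_sample(fx$gm, "S01")
  expect_equal(nrow(segs), 1L)
  # trimmed to the outermost homozygous calls: exact boundaries here
  expect_equal(segs$start, fx$first)
  expect_equal(segs$end, fx$last)
  expect_equal(segs$n_snps, 150L)
  expect_gte(segs$length_kb, 500)
})

test_that("a 400-kb tract fails the length filter", {
  fx <- roh_fixture(400000)
  expect_equal(nrow(scan_sample(fx$gm, "S01")), 0L)
})

test_that("segments respect the density and gap constraints", {
  # 150 homozygous SNPs spread over 9 Mb: 60 kb/SNP > 50 kb/SNP limit,
  # and consecutive SNPs are 60 kb apart, so density rejects the run
  pos <- seq(60000L, 9000000L, by = 60000L)
  gm <- make_gm(matrix(0L, length(pos), 1), pos = pos, pops = "A",
                scaffolds = c(s1 = 9e6))
  expect_equal(nrow(scan_sample(gm, "S01")), 0L)
  # a gap larger than max_gap_kb splits the run; halves fail min_snps
  fx <- roh_fixture(600000)
  g <- fx$gm$geno[, 1]
  pos2 <- fx$gm$variants$pos
  inside <- which(pos2 >= fx$first & pos2 <= fx$last)
  drop <- inside[70:80]                      # carve a 44-kb hole... then
  pos3 <- pos2; pos3[drop] <- NA             # widen it beyond 1 Mb by
  keep <- !is.na(pos3)                       # removing SNPs and shifting
  shift <- ifelse(pos2 > pos2[max(drop)], 1100000L, 0L)
  gm2 <- make_gm(matrix(g[keep], ncol = 1),
                 pos = as.integer((pos2 + shift)[keep]),
                 pops = "A", scaffolds = c(s1 = 4200000))
  segs <- scan_sample(gm2, "S01")
  expect_equal(nrow(segs), 0L)               # both halves < 100 SNPs
})

test_that("ROH calls are invariant to allele-coding flips", {
  fx <- roh_fixture(600000)
  gmf <- fx$gm
  set.seed(2)
  flip <- sample(n_variants(gmf), 200)
  gmf$geno[flip, ] <- 2L - gmf$geno[flip, ]
  expect_equal(scan_sample(gmf, "S01"), scan_sample(fx$gm, "S01"))
})

test_that("relaxing min_kb or min_snps never removes segments", {
  sim <- simulate_populations(sim_config(
    n_pops = 1, samples_per_pop = 2, scaffolds = c(s1 = 4e6),
    snp_density = 0.0004, target_F = 0, seed = 31, missing_rate = 0))
  r <- inject_roh(sim$gm, sim$truth, "P1_01", "s1", 5e5, 1.3e6)
  r <- inject_roh(r$gm, r$truth, "P1_01", "s1", 2.5e6, 3.1e6)
  strict <- nrow(scan_sample(r$gm, "P1_01", roh_params()))
  relaxed_kb <- nrow(scan_sample(r$gm, "P1_01", roh_params(min_kb = 200)))
  relaxed_snps <- nrow(scan_sample(r$gm, "P1_01",
                                   roh_params(min_snps = 60,
                                              window_snps = 50)))
  expect_gte(relaxed_kb, strict)
  expect_gte(relaxed_snps, strict)
})

test_that("F_ROH is the ROH fraction of the autosome", {
  segs <- data.frame(sample = c("a", "a", "b"), scaffold = "s1",
                     start = c(1, 2e6, 1), end = c(1e6, 3e6, 5e5),
                     n_snps = 200L, length_kb = 1)
  rep <- f_roh(segs, c(s1 = 1e9, s2 = 9e9), samples = c("a", "b", "c"))
  # segments are inclusive: (1e6 - 1 + 1) + (3e6 - 2e6 + 1) bp in ROH
  expect_equal(rep$f_roh[rep$sample == "a"], (1e6 + 1e6 + 1) / 1e10)
  expect_equal(rep$f_roh[rep$sample == "c"], 0)
  expect_true(all(rep$f_roh >= 0 & rep$f_roh <= 1))
  # L_ROH = 100 Mb over L_AUTO = 1000 Mb
  segs2 <- data.frame(sample = "x", scaffold = "s1", start = 1,
                      end = 1e8, n_snps = 1000L, length_kb = 1e5)
  expect_equal(f_roh(segs2, c(s1 = 1e9))$f_roh, 0.1)
  expect_error(f_roh(segs2, c(other = 1e9)), "absent from the autosome")
})

test_that("F_ROH recovers injected autozygosity within boundary slack", {
  sim <- simulate_populations(sim_config(
    n_pops = 1, samples_per_pop = 2, scaffolds = c(s1 = 5e6),
    snp_density = 0.0004, target_F = 0, seed = 8, missing_rate = 0))
  r <- inject_roh(sim$gm, sim$truth, "P1_01", "s1", 1e6, 1.8e6)
  r <- inject_roh(r$gm, r$truth, "P1_01", "s1", 3e6, 3.7e6)
  segs <- scan_sample(r$gm, "P1_01")
  rep <- f_roh(segs, c(s1 = 5e6))
  truth_f <- (8e5 + 7e5) / 5e6
  # slack: a few inter-SNP intervals (mean spacing 2.5 kb) per boundary
  expect_lt(abs(rep$f_roh - truth_f), 4 * 4 * 2500 / 5e6)
})

test_that("breed summary averages per population", {
  rep <- data.frame(sample = c("a", "b", "c"), n_segments = c(2L, 4L, 1L),
                    l_roh_bp = c(1e6, 3e6, 2e6), l_auto_bp = 1e7,
                    f_roh = c(0.1, 0.3, 0.2))
  pops <- c(a = "X", b = "X", c = "Y")
  bs <- breed_summary(rep, pops)
  expect_equal(bs$mean_f_roh[bs$pop == "X"], 0.2)
  expect_equal(bs$mean_n_segments[bs$pop == "X"], 3)
  # single-sample population equals that sample's values
  expect_equal(bs$mean_f_roh[bs$pop == "Y"], 0.2)
  expect_equal(bs$n_samples, c(2L, 1L))
})
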