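test_that("per-site diversity matches its closed form", {
  # one site, two alleles, one of each: maximal diversity 1
  gm <- make_gm(matrix(1L, 1, 1), pops = c("A"))
  expect_equal(site_pi(gm, "A"), 1)
  # n = 10 alleles, 3 alt: 2*3*7/(10*9)
  gm2 <- make_gm(matrix(c(2L, 1L, 0L, 0L, 0L), 1, 5), pops = rep("A", 5))
  expect_equal(site_pi(gm2, "A"), 2 * 3 * 7 / (10 * 9))
  expect_equal(site_pi(gm2, "A"), oracle_site_pi(c(2L, 1L, 0L, 0L, 0L)))
  # monomorphic: 0
  gm3 <- make_gm(matrix(2L, 1, 5), pops = rep("A", 5))
  expect_equal(site_pi(gm3, "A"), 0)
  # fewer than two called alleles: flagged NA
  gm4 <- make_gm(matrix(NA_integer_, 1, 3), pops = rep("A", 3))
  expect_true(is.na(site_pi(gm4, "A")))
  # a single called sample still has two alleles: one het gives pi = 1
  gm5 <- make_gm(matrix(c(1L, NA, NA), 1, 3), pops = rep("A", 3))
  expect_equal(site_pi(gm5, "A"), 1)
})

test_that("windowed pi normalises by window span and handles monomorphy", {
  g <- rbind(rep(1L, 4), rep(0L, 4), rep(1L, 4))
  gm <- make_gm(g, pos = c(100L, 200L, 1500L), pops = rep("A", 4),
                scaffolds = c(s1 = 2000))
  w <- windowed_pi(gm, "A", size = 1000, step = 1000)
  # window [0,1000): two sites, pi_site = 4/7 and 0
  expect_equal(w$pi[1], (2 * 4 * 4 / (8 * 7)) / 1000)
  expect_equal(w$n_snps, c(2L, 1L))
})

test_that("log2 ratio conventions: identity, doubling, +Inf sentinel", {
  expect_equal(log2_pi_ratio(0.02, 0.02), 0)
  expect_equal(log2_pi_ratio(0.04, 0.02), 1)
  expect_identical(log2_pi_ratio(0.01, 0), Inf)
  expect_true(is.nan(log2_pi_ratio(0, 0)))
  expect_error(log2_pi_ratio(1:3, 1:2), "mismatch")
})

test_that("joint outliers equal brute-force nearest-rank intersection", {
  set.seed(5)
  n <- 100
  base <- data.frame(scaffold = "s1",
                     start = seq(0, by = 20000, length.out = n),
                     end = seq(40000, by = 20000, length.out = n),
                     n_snps = 50L, fst = NA_real_, usable = TRUE,
                     pi_target = 0.01, pi_control = 0.01,
                     log2_ratio = NA_real_)
  for (i in 1:20) {
    st <- base
    st$fst <- runif(n)
    st$log2_ratio <- rnorm(n)
    got <- which(joint_outliers(st, 0.05)$outlier)
    expect_equal(got, oracle_joint_top(st$fst, st$log2_ratio, 0.05))
  }
  # same 5 windows top both rankings -> exactly those 5
  st <- base
  st$fst <- c(seq_len(95) / 100, 2, 3, 4, 5, 6)
  st$log2_ratio <- c(seq_len(95) / 100, 12, 13, 14, 15, 16)
  expect_equal(which(joint_outliers(st, 0.05)$outlier), 96:100)
})

test_that("outlier degenerate cases: ties, q = 1, too few windows", {
  n <- 30
  st <- data.frame(scaffold = "s1", start = seq(0, by = 2e4, length.out = n),
                   end = seq(4e4, by = 2e4, length.out = n), n_snps = 50L,
                   fst = 0.5, usable = TRUE, pi_target = 0.01,
                   pi_control = 0.02, log2_ratio = 1)
  # identical scores: the tie rule admits every window
  expect_true(all(joint_outliers(st, 0.05)$outlier))
  # q = 1: vacuous threshold, all usable windows returned
  st$fst <- runif(n); st$log2_ratio <- rnorm(n)
  expect_true(all(joint_outliers(st, 1)$outlier))
  expect_error(joint_outliers(st[1:10, ], 0.05), "usable windows")
})

test_that("+Inf log2 ratios rank above all finite values", {
  n <- 40
  st <- data.frame(scaffold = "s1", start = seq(0, by = 2e4, length.out = n),
                   end = seq(4e4, by = 2e4, length.out = n), n_snps = 50L,
                   fst = seq_len(n) / n, usable = TRUE, pi_target = 0.01,
                   pi_control = 0.02, log2_ratio = rnorm(n))
  st$pi_target[n] <- 0
  st$log2_ratio[n] <- Inf
  out <- joint_outliers(st, 0.05)
  expect_true(out$outlier[n])
})

test_that("region merging equals the transitive-merge oracle", {
  mk <- function(scaffold, start, end) {
    data.frame(scaffold = scaffold, start = start, end = end,
               n_snps = 10L, fst = 0.5, usable = TRUE, pi_target = 1,
               pi_control = 1, log2_ratio = 0, outlier = TRUE)
  }
  # overlapping windows merge
  r <- merge_regions(mk("s1", c(0, 20000), c(40000, 60000)))
  expect_equal(r[c("start", "end")], data.frame(start = 0, end = 60000))
  # book-ended windows merge
  r2 <- merge_regions(mk("s1", c(0, 40000), c(40000, 80000)))
  expect_equal(nrow(r2), 1L)
  # different scaffolds never merge
  r3 <- merge_regions(mk(c("s1", "s2"), c(0, 0), c(40000, 40000)))
  expect_equal(nrow(r3), 2L)
  # randomized sets against the oracle
  set.seed(11)
  for (i in 1:10) {
    k <- sample(3:12, 1)
    sc <- sample(c("s1", "s2"), k, replace = TRUE)
    start <- sample(seq(0, 2e5, by = 2e4), k, replace = TRUE)
    got <- merge_regions(mk(sc, start, start + 4e4))
    want <- oracle_merge(sc, start, start + 4e4)
    got <- got[order(got$scaffold, got$start), c("scaffold", "start", "end")]
    rownames(got) <- NULL
    expect_equal(got, want)
  }
  # empty outlier set gives an empty region table
  empty <- mk("s1", 0, 40000); empty$outlier <- FALSE
  expect_equal(nrow(merge_regions(empty)), 0L)
})

test_that("window grid anchors at zero with truncated final window", {
  sim <- simulate_populations(sim_config(
    n_pops = 2, samples_per_pop = 4, scaffolds = c(s1 = 90000),
    target_F = 0.1, seed = 1))
  w <- windowed_fst(sim$gm, "P1", "P2", size = 40000, step = 20000)
  expect_equal(w$start, c(0, 20000, 40000, 60000, 80000))
  expect_equal(w$end, c(40000, 60000, 80000, 90000, 90000))
  expect_true(all(w$end - w$start <= 40000))
})
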