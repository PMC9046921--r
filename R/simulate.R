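#' Simulation configuration
#'
#' Parameters for the Balding-Nichols multi-population genotype simulator.
#' Population allele frequencies are Beta-distributed around an ancestral
#' frequency with a single differentiation parameter `target_F` per
#' population, so the expected genome-wide Weir & Cockerham F_ST between
#' two populations simulated at the same `F` is `F` itself — which makes
#' recovery tests self-calibrating.
#'
#' @param n_pops number of populations (>= 2 for differentiation scans).
#' @param samples_per_pop diploid samples per population; recycled to
#'   `n_pops`.  Default 8, the scale of a small resequenced breed panel.
#' @param scaffolds named numeric vector of scaffold lengths in bp.
#' @param snp_density expected SNPs per bp.  Default 0.005, roughly the
#'   genome-wide SNP rate of a 5-10x resequencing panel.
#' @param target_F Balding-Nichols differentiation parameter in `[0, 1)`;
#'   recycled per population.  `F = 0` makes populations exchangeable.
#' @param recomb_rate per-bp founder-switch probability of the haplotype
#'   mosaic.  `0` (default) draws each individual's two alleles
#'   independently from the population frequency — sites are then
#'   unlinked, which is what the F_ST recovery analyses assume.  A
#'   positive rate copies each haplotype from a finite founder pool with
#'   recombination breakpoints, producing r^2 that decays with physical
#'   distance.  Because the mosaic stands in for many generations of
#'   recombination, this is an effective (population-scaled) rate, not a
#'   per-meiosis one: around `1e-5` gives an LD decay scale of ~100 kb.
#' @param n_founders founder haplotypes per population for the mosaic model.
#' @param mean_depth mean of the Poisson per-sample read depth written to
#'   the VCF `DP` field (default 8, a typical low-coverage resequencing
#'   depth).
#' @param missing_rate per-call missing-genotype probability (default 0.01).
#' @param seed integer RNG seed; fixing it makes all outputs byte-identical.
#'
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_pops = 2,
                       samples_per_pop = 8,
                       scaffolds = c(scaffold_1 = 5e6, scaffold_2 = 5e6),
                       snp_density = 0.005,
                       target_F = 0.1,
                       recomb_rate = 0,
                       n_founders = 20,
                       mean_depth = 8,
                       missing_rate = 0.01,
                       seed = 1) {
  n_pops <- as.integer(n_pops)
  samples_per_pop <- as.integer(rep_len(samples_per_pop, n_pops))
  target_F <- rep_len(target_F, n_pops)
  if (n_pops < 1L) stop("n_pops must be >= 1")
  if (any(samples_per_pop <= 0L)) stop("samples_per_pop must be positive")
  if (is.null(names(scaffolds)) || any(scaffolds <= 0))
    stop("scaffolds must be a named vector of positive lengths")
  if (any(target_F < 0) || any(target_F >= 1))
    stop("target_F must lie in [0, 1)")
  if (snp_density <= 0 || recomb_rate < 0 || n_founders < 2 ||
      mean_depth <= 0 || missing_rate < 0 || missing_rate >= 1)
    stop("invalid simulator parameter")
  structure(list(n_pops = n_pops, samples_per_pop = samples_per_pop,
                 scaffolds = scaffolds, snp_density = snp_density,
                 target_F = target_F, recomb_rate = recomb_rate,
                 n_founders = as.integer(n_founders),
                 mean_depth = mean_depth, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# mosaic haplotype: copy from founder pool with recombination breakpoints
.mosaic_haplotype <- function(founders, pos, recomb_rate) {
  m <- nrow(founders)
  k <- ncol(founders)
  if (m == 1L) return(founders[, sample.int(k, 1L)])
  p_switch <- 1 - exp(-recomb_rate * diff(pos))
  switches <- stats::runif(m - 1L) < p_switch
  seg <- cumsum(c(TRUE, switches))           # segment index per SNP
  ids <- sample.int(k, max(seg), replace = TRUE)
  founders[cbind(seq_len(m), ids[seg])]
}

#' Simulate multi-population genotypes under the Balding-Nichols model
#'
#' For each SNP an ancestral allele frequency `p` is drawn from
#' Uniform(0.05, 0.95); each population's frequency is drawn from
#' Beta(p(1-F)/F, (1-p)(1-F)/F) (or equals `p` when `F = 0`).  Genotypes
#' are then binomial draws from the population frequency, or haplotype
#' mosaics copied from `n_founders` founder haplotypes with recombination
#' when `recomb_rate > 0`.  Monomorphic draws are retained so downstream
#' code is exercised on degenerate sites.
#'
#' @param config a [sim_config()].
#' @return a list with components `gm` (a [geno_matrix()]) and `truth`
#'   (a `sim_truth` object holding `target_F`, per-SNP ancestral and
#'   population allele frequencies, and empty sweep/ROH interval tables
#'   to be filled by [inject_sweep()] / [inject_roh()]).
#' @export
simulate_populations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pops <- paste0("P", seq_len(config$n_pops))
  samples <- unlist(lapply(seq_len(config$n_pops), function(i)
    sprintf("%s_%02d", pops[i], seq_len(config$samples_per_pop[i]))))
  popmap <- rep(pops, config$samples_per_pop)
  names(popmap) <- samples

  chrom <- character(0); pos <- integer(0)
  anc <- numeric(0)
  pf <- matrix(numeric(0), 0, config$n_pops)
  geno <- NULL
  for (sc in names(config$scaffolds)) {
    len <- config$scaffolds[[sc]]
    m <- max(1L, as.integer(round(len * config$snp_density)))
    p_sc <- sort(sample.int(len, m))
    anc_sc <- stats::runif(m, 0.05, 0.95)
    pf_sc <- sapply(seq_len(config$n_pops), function(i) {
      f <- config$target_F[i]
      if (f == 0) anc_sc
      else stats::rbeta(m, anc_sc * (1 - f) / f, (1 - anc_sc) * (1 - f) / f)
    })
    g_sc <- matrix(NA_integer_, m, length(samples))
    col0 <- 0L
    for (i in seq_len(config$n_pops)) {
      k <- config$samples_per_pop[i]
      if (config$recomb_rate > 0) {
        founders <- matrix(
          stats::rbinom(m * config$n_founders, 1L, pf_sc[, i]),
          m, config$n_founders)
        for (s in seq_len(k)) {
          h1 <- .mosaic_haplotype(founders, p_sc, config$recomb_rate)
          h2 <- .mosaic_haplotype(founders, p_sc, config$recomb_rate)
          g_sc[, col0 + s] <- h1 + h2
        }
      } else {
        g_sc[, col0 + seq_len(k)] <-
          matrix(stats::rbinom(m * k, 2L, pf_sc[, i]), m, k)
      }
      col0 <- col0 + k
    }
    chrom <- c(chrom, rep(sc, m)); pos <- c(pos, p_sc)
    anc <- c(anc, anc_sc); pf <- rbind(pf, pf_sc)
    geno <- rbind(geno, g_sc)
  }

  n <- length(pos)
  qual <- round(stats::rgamma(n, shape = 4, scale = 10), 1)
  depth <- matrix(stats::rpois(n * length(samples), config$mean_depth),
                  n, length(samples))
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * length(samples)) < config$missing_rate,
                   n, length(samples))
    geno[miss] <- NA_integer_
  }

  variants <- data.frame(chrom = chrom, pos = pos,
                         ref = "A", alt = "G", qual = qual,
                         stringsAsFactors = FALSE)
  gm <- geno_matrix(geno, variants, samples, popmap, depth = depth,
                    scaffolds = config$scaffolds)
  colnames(pf) <- pops
  truth <- structure(list(
    target_F = stats::setNames(config$target_F, pops),
    sweep_intervals = data.frame(scaffold = character(0),
                                 start = integer(0), end = integer(0),
                                 pop = character(0),
                                 stringsAsFactors = FALSE),
    roh_intervals = data.frame(sample = character(0),
                               scaffold = character(0),
                               start = integer(0), end = integer(0),
                               stringsAsFactors = FALSE),
    ancestral_freqs = data.frame(chrom = chrom, pos = pos, p = anc,
                                 pf, stringsAsFactors = FALSE)),
    class = "sim_truth")
  list(gm = gm, truth = truth)
}

# variant row indices inside a 0-based half-open interval on one scaffold
.interval_idx <- function(gm, scaffold, start, end) {
  which(gm$variants$chrom == scaffold &
          gm$variants$pos - 1L >= start & gm$variants$pos - 1L < end)
}

.check_interval <- function(gm, scaffold, start, end) {
  lens <- scaffold_lengths(gm)
  if (!scaffold %in% names(lens))
    stop("unknown scaffold '", scaffold, "'")
  if (start < 0 || end > lens[[scaffold]])
    stop("interval [", start, ", ", end, ") outside scaffold '",
         scaffold, "' (length ", lens[[scaffold]], ")")
}

#' Inject a selective-sweep signature
#'
#' Drives a fraction `intensity` of the SNPs inside a 0-based half-open
#' interval to fixation for the majority allele of the target population,
#' mimicking the local loss of nucleotide diversity (and gain in
#' differentiation) left by a strong sweep.  The interval is recorded in
#' the truth object for later recovery checks.
#'
#' @param gm a [geno_matrix()]; @param truth the matching `sim_truth`.
#' @param scaffold,start,end interval (0-based half-open bp).
#' @param pop target population label.
#' @param intensity fraction of interval SNPs fixed, in `[0, 1]`.
#' @return list with updated `gm` and `truth`.
#' @export
inject_sweep <- function(gm, truth, scaffold, start, end, pop,
                         intensity = 0.9) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(truth, "sim_truth"),
            intensity >= 0, intensity <= 1)
  .check_interval(gm, scaffold, start, end)
  if (end <= start) {
    warning("empty sweep interval; no-op")
    return(list(gm = gm, truth = truth))
  }
  if (!pop %in% gm$pops) stop("unknown population '", pop, "'")
  idx <- .interval_idx(gm, scaffold, start, end)
  if (length(idx) && intensity > 0) {
    k <- round(intensity * length(idx))
    chosen <- if (k >= length(idx)) idx else sort(sample(idx, k))
    cols <- which(gm$pops == pop)
    sub <- gm$geno[chosen, cols, drop = FALSE]
    alt_freq <- rowMeans(sub, na.rm = TRUE) / 2
    fixed <- ifelse(!is.na(alt_freq) & alt_freq > 0.5, 2L, 0L)
    for (j in seq_along(chosen)) {
      row <- gm$geno[chosen[j], cols]
      row[!is.na(row)] <- fixed[j]
      gm$geno[chosen[j], cols] <- row
    }
  }
  truth$sweep_intervals <- rbind(
    truth$sweep_intervals,
    data.frame(scaffold = scaffold, start = as.integer(start),
               end = as.integer(end), pop = pop, stringsAsFactors = FALSE))
  list(gm = gm, truth = truth)
}

#' Inject an autozygous (run-of-homozygosity) tract
#'
#' Within the interval, every heterozygous call of the sample is replaced
#' by a homozygote, as if one haplotype had been copied over the other;
#' missing calls stay missing.  Intervals overlapping a previously
#' injected tract of the same sample are merged in the truth table.
#'
#' @inheritParams inject_sweep
#' @param sample sample ID.
#' @return list with updated `gm` and `truth`.
#' @export
inject_roh <- function(gm, truth, sample, scaffold, start, end) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(truth, "sim_truth"))
  .check_interval(gm, scaffold, start, end)
  if (end <= start) return(list(gm = gm, truth = truth))
  if (!sample %in% gm$samples) stop("unknown sample '", sample, "'")
  idx <- .interval_idx(gm, scaffold, start, end)
  col <- match(sample, gm$samples)
  het <- idx[!is.na(gm$geno[idx, col]) & gm$geno[idx, col] == 1L]
  if (length(het))
    gm$geno[het, col] <- 2L * stats::rbinom(length(het), 1L, 0.5)
  ri <- truth$roh_intervals
  new <- data.frame(sample = sample, scaffold = scaffold,
                    start = as.integer(start), end = as.integer(end),
                    stringsAsFactors = FALSE)
  same <- ri$sample == sample & ri$scaffold == scaffold &
    ri$start <= new$end & ri$end >= new$start
  if (any(same)) {
    new$start <- min(new$start, ri$start[same])
    new$end <- max(new$end, ri$end[same])
    ri <- ri[!same, , drop = FALSE]
  }
  truth$roh_intervals <- rbind(ri, new)
  rownames(truth$roh_intervals) <- NULL
  list(gm = gm, truth = truth)
}

# full-precision numeric formatting so truth tables round-trip losslessly
.fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Write / read simulation ground truth
#'
#' Serialises a `sim_truth` object as a set of TSV tables under a
#' directory (`target_f.tsv`, `sweeps.tsv`, `roh.tsv`, `freqs.tsv`).
#' Numeric columns are written with 17 significant digits so that
#' [read_truth()] reproduces the object exactly.
#'
#' @param truth a `sim_truth`.
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create truth directory: ", path)
  tf <- data.frame(pop = names(truth$target_F),
                   target_F = .fmt_num(unname(truth$target_F)))
  utils::write.table(tf, file.path(path, "target_f.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$sweep_intervals, file.path(path, "sweeps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$roh_intervals, file.path(path, "roh.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fr <- truth$ancestral_freqs
  num <- vapply(fr, is.numeric, logical(1)) & names(fr) != "pos"
  fr[num] <- lapply(fr[num], .fmt_num)
  utils::write.table(fr, file.path(path, "freqs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  rd <- function(f) utils::read.table(file.path(path, f), sep = "\t",
                                      header = TRUE, colClasses = NA,
                                      stringsAsFactors = FALSE)
  tf <- rd("target_f.tsv")
  sw <- rd("sweeps.tsv")
  ro <- rd("roh.tsv")
  fr <- rd("freqs.tsv")
  if (nrow(sw) == 0)
    sw <- data.frame(scaffold = character(0), start = integer(0),
                     end = integer(0), pop = character(0),
                     stringsAsFactors = FALSE)
  if (nrow(ro) == 0)
    ro <- data.frame(sample = character(0), scaffold = character(0),
                     start = integer(0), end = integer(0),
                     stringsAsFactors = FALSE)
  structure(list(
    target_F = stats::setNames(as.numeric(tf$target_F), tf$pop),
    sweep_intervals = sw, roh_intervals = ro, ancestral_freqs = fr),
    class = "sim_truth")
}
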