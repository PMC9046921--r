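# Two-locus LD from unphased genotypes.
#
# Haplotype frequencies are estimated by EM over the 3x3 joint genotype
# table; only the double-heterozygote cell is phase-ambiguous.  The EM is
# vectorised across pairs: all pairs are iterated simultaneously with
# elementwise updates, which keeps genome-scale decay curves fast in
# plain R.

# joint genotype counts for pair columns: 9-vector in (gA, gB) order
# 00,01,02,10,11,12,20,21,22 over complete cases
.pair_counts <- function(ga, gb) {
  ok <- !is.na(ga) & !is.na(gb)
  tabulate(3L * ga[ok] + gb[ok] + 1L, nbins = 9L)
}

# Batched EM over a P x 9 count matrix.  Returns haplotype frequencies
# (fAB refers to ref-ref), allele freqs, r2 and iteration/convergence info.
.em_r2_batch <- function(counts, max_iter = 1000, tol = 1e-10,
                         trace = FALSE) {
  counts <- matrix(as.numeric(counts), ncol = 9)
  n2 <- 2 * rowSums(counts)                      # haplotype total
  # fixed haplotype contributions from unambiguous cells
  # columns: 1=(0,0) 2=(0,1) 3=(0,2) 4=(1,0) 5=(1,1) 6=(1,2) 7=(2,0)
  #          8=(2,1) 9=(2,2); allele 0 = ref.  h00=ref-ref, h01=ref-alt,
  #          h10=alt-ref, h11=alt-alt
  k00 <- 2 * counts[, 1] + counts[, 2] + counts[, 4]
  k01 <- counts[, 2] + 2 * counts[, 3] + counts[, 6]
  k10 <- counts[, 4] + 2 * counts[, 7] + counts[, 8]
  k11 <- counts[, 6] + counts[, 8] + 2 * counts[, 9]
  dh <- counts[, 5]                              # double heterozygotes
  # linkage-equilibrium initialisation
  pA_ref <- (k00 + k01 + dh) / n2                # ref freq locus A
  pB_ref <- (k00 + k10 + dh) / n2
  f00 <- pA_ref * pB_ref
  f01 <- pA_ref * (1 - pB_ref)
  f10 <- (1 - pA_ref) * pB_ref
  f11 <- (1 - pA_ref) * (1 - pB_ref)
  loglik <- function(f00, f01, f10, f11) {
    g <- cbind(f00^2, 2 * f00 * f01, f01^2,
               2 * f00 * f10, 2 * (f00 * f11 + f01 * f10), 2 * f01 * f11,
               f10^2, 2 * f10 * f11, f11^2)
    rowSums(counts * log(pmax(g, 1e-300)))
  }
  ll <- loglik(f00, f01, f10, f11)
  ll_trace <- if (trace) list(ll) else NULL
  iters <- integer(nrow(counts))
  active <- rep(TRUE, nrow(counts))
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    denom <- f00 * f11 + f01 * f10
    w <- ifelse(denom > 0, f00 * f11 / denom, 0.5)  # P(phase is 00/11)
    f00n <- (k00 + dh * w) / n2
    f01n <- (k01 + dh * (1 - w)) / n2
    f10n <- (k10 + dh * (1 - w)) / n2
    f11n <- (k11 + dh * w) / n2
    f00[active] <- f00n[active]; f01[active] <- f01n[active]
    f10[active] <- f10n[active]; f11[active] <- f11n[active]
    lln <- loglik(f00, f01, f10, f11)
    if (trace) ll_trace[[it + 1L]] <- lln
    conv <- abs(lln - ll) < tol
    iters[active] <- it
    ll <- lln
    active <- active & !conv
  }
  pA <- f10 + f11                                # alt freqs
  pB <- f01 + f11
  D <- f11 - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- ifelse(denom > 0, D^2 / denom, NA_real_)
  list(r2 = pmin(1, pmax(0, r2)),
       f = cbind(f00 = f00, f01 = f01, f10 = f10, f11 = f11),
       D = D, iters = iters, loglik = ll,
       loglik_trace = if (trace) do.call(rbind, ll_trace) else NULL)
}

# direct haplotype counting; exact when no double heterozygotes
.direct_r2 <- function(counts) {
  n2 <- 2 * sum(counts)
  k00 <- 2 * counts[1] + counts[2] + counts[4]
  k01 <- counts[2] + 2 * counts[3] + counts[6]
  k10 <- counts[4] + 2 * counts[7] + counts[8]
  k11 <- counts[6] + counts[8] + 2 * counts[9]
  f <- c(k00, k01, k10, k11) / n2
  pA <- f[3] + f[4]; pB <- f[2] + f[4]
  D <- f[4] - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  if (denom <= 0) return(NA_real_)
  min(1, max(0, D^2 / denom))
}

#' Pairwise r-squared between two loci from unphased genotypes
#'
#' Two-locus haplotype frequencies are estimated by EM over the 3x3
#' genotype table (initialised at linkage equilibrium, converged when the
#' log-likelihood changes by less than 1e-10, at most 1,000 iterations);
#' then `r2 = D^2 / (pA (1-pA) pB (1-pB))` with `D = pAB - pA pB`.  When
#' the table contains no double heterozygotes the phase is unambiguous
#' and haplotypes are counted directly (an exact shortcut the EM agrees
#' with).
#'
#' @param gm a [geno_matrix()].
#' @param pop population label whose samples are used.
#' @param locus_a,locus_b variant row indices.
#' @return list: `r2`, `method` ("EM" or "direct"), `iters`.
#' @export
pair_r2 <- function(gm, pop, locus_a, locus_b) {
  cols <- gm$pops == pop
  ga <- gm$geno[locus_a, cols]
  gb <- gm$geno[locus_b, cols]
  counts <- .pair_counts(ga, gb)
  pA <- sum(counts * rep(0:2, each = 3)) / (2 * sum(counts))
  pB <- sum(counts * rep(0:2, times = 3)) / (2 * sum(counts))
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("monomorphic locus in population '", pop, "'")
  if (counts[5] == 0)
    return(list(r2 = .direct_r2(counts), method = "direct", iters = 0L))
  res <- .em_r2_batch(matrix(counts, ncol = 9))
  list(r2 = res$r2[1], method = "EM", iters = res$iters[1])
}

#' LD-decay curve
#'
#' All intra-scaffold pairs of loci at most `max_window` bp apart, with
#' both minor-allele frequencies at least `min_maf` in the population,
#' are assigned to physical-distance bins of `bin_bp`; r-squared is
#' EM-estimated for every pair and averaged per bin (bins pooled across
#' scaffolds, weighted by pair count).
#'
#' @inheritParams pair_r2
#' @param max_window maximum pair distance in bp (default 500 kb).
#' @param min_maf minor-allele-frequency filter (default 0.05).
#' @param bin_bp distance bin width (default 1 kb).
#' @param max_pairs optional cap on the number of pairs; when exceeded a
#'   uniform random subsample of pairs is used (seed-controlled by the
#'   caller).
#' @return data.frame: `bin_start`, `bin_end`, `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(gm, pop, max_window = 500000, min_maf = 0.05,
                     bin_bp = 1000, max_pairs = NULL) {
  cols <- gm$pops == pop
  g <- gm$geno[, cols, drop = FALSE]
  n_called <- rowSums(!is.na(g))
  af <- rowSums(g, na.rm = TRUE) / (2 * pmax(1L, n_called))
  maf <- pmin(af, 1 - af)
  use <- which(n_called >= 2 & maf >= min_maf)
  pair_a <- list(); pair_b <- list()
  for (sc in unique(gm$variants$chrom)) {
    idx <- use[gm$variants$chrom[use] == sc]
    if (length(idx) < 2) next
    pos <- gm$variants$pos[idx]
    # for each left locus, right partners within max_window
    hi <- findInterval(pos + max_window, pos)
    cnt <- pmax(0L, hi - seq_along(idx))
    a <- rep(idx, cnt)
    b <- idx[sequence(cnt) + rep(seq_along(idx), cnt)]
    pair_a[[sc]] <- a; pair_b[[sc]] <- b
  }
  ia <- unlist(pair_a, use.names = FALSE)
  ib <- unlist(pair_b, use.names = FALSE)
  if (is.null(ia)) ia <- integer(0)
  if (!length(ia)) {
    warning("no qualifying pairs for the LD-decay curve")
    return(data.frame(bin_start = integer(0), bin_end = integer(0),
                      mean_r2 = numeric(0), n_pairs = integer(0)))
  }
  if (!is.null(max_pairs) && length(ia) > max_pairs) {
    keep <- sort(sample.int(length(ia), max_pairs))
    ia <- ia[keep]; ib <- ib[keep]
  }
  # vectorised joint-genotype tabulation: cell code 3*gA + gB in 0..8
  code <- 3L * g[ia, , drop = FALSE] + g[ib, , drop = FALSE]
  counts <- vapply(0:8, function(cc) rowSums(code == cc, na.rm = TRUE),
                   numeric(length(ia)))
  counts <- matrix(counts, ncol = 9)
  r2 <- .em_r2_batch(counts)$r2
  dist <- gm$variants$pos[ib] - gm$variants$pos[ia]
  bin <- (dist - 1L) %/% as.integer(bin_bp)
  ok <- !is.na(r2)
  mean_r2 <- tapply(r2[ok], bin[ok], mean)
  n_pairs <- tapply(r2[ok], bin[ok], length)
  b <- as.integer(names(mean_r2))
  data.frame(bin_start = b * as.integer(bin_bp),
             bin_end = (b + 1L) * as.integer(bin_bp),
             mean_r2 = as.numeric(mean_r2),
             n_pairs = as.integer(n_pairs))
}

#' Mean r-squared within arbitrary distance intervals
#'
#' Convenience summary over a [ld_decay()]-style pair computation,
#' reporting the pair-count-weighted mean r-squared inside each
#' `[lo, hi]` bp distance interval — e.g. to contrast short-range
#' (0-10 kb) with long-range (200-500 kb) LD.
#'
#' @param curve a [ld_decay()] result.
#' @param intervals list of numeric `c(lo, hi)` distance intervals in bp.
#' @return data.frame: `lo`, `hi`, `mean_r2`, `n_pairs`.
#' @export
ld_interval_means <- function(curve, intervals) {
  out <- lapply(intervals, function(iv) {
    sel <- curve$bin_start >= iv[1] & curve$bin_end <= iv[2]
    n <- sum(curve$n_pairs[sel])
    data.frame(lo = iv[1], hi = iv[2],
               mean_r2 = if (n > 0)
                 sum(curve$mean_r2[sel] * curve$n_pairs[sel]) / n
               else NA_real_,
               n_pairs = n)
  })
  do.call(rbind, out)
}
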