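# Independent brute-force oracles and small fixture builders.  Oracles are
# deliberately written as plain scalar transcriptions of the defining
# formulas (loops, no shared code with the package internals).

# build a geno_matrix from a plain dosage matrix (variants x samples)
make_gm <- function(geno, pos = seq_len(nrow(as.matrix(geno))) * 100L,
                    chrom = "s1", pops = NULL, qual = NULL, depth = NULL,
                    scaffolds = NULL) {
  geno <- as.matrix(geno)
  n <- ncol(geno)
  samples <- sprintf("S%02d", seq_len(n))
  if (is.null(pops)) pops <- stats::setNames(rep("A", n), samples)
  else names(pops) <- samples
  variants <- data.frame(chrom = rep_len(chrom, nrow(geno)), pos = pos,
                         ref = "A", alt = "G",
                         qual = if (is.null(qual)) rep(50, nrow(geno))
                                else qual,
                         stringsAsFactors = FALSE)
  geno_matrix(geno, variants, samples, pops, depth = depth,
              scaffolds = scaffolds)
}

# Weir & Cockerham per-locus variance components, scalar transcription.
# genos: list of integer dosage vectors, one per population (NA = missing).
oracle_wc <- function(genos) {
  r <- length(genos)
  n <- p <- h <- numeric(r)
  for (i in 1:r) {
    g <- genos[[i]][!is.na(genos[[i]])]
    n[i] <- length(g)
    p[i] <- sum(g) / (2 * n[i])
    h[i] <- sum(g == 1) / n[i]
  }
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c <- hbar / 2
  list(a = a, b = b, c = c, fst = a / (a + b + c))
}

# per-site nucleotide diversity, scalar transcription
oracle_site_pi <- function(g) {
  g <- g[!is.na(g)]
  n <- 2 * length(g)
  if (n < 2) return(NA_real_)
  alt <- sum(g)
  2 * (n - alt) * alt / (n * (n - 1))
}

# repeated-pass transitive merge of half-open intervals (overlap or
# book-ended, same scaffold) — quadratic but obviously correct
oracle_merge <- function(scaffold, start, end) {
  iv <- data.frame(scaffold = scaffold, start = start, end = end)
  repeat {
    merged <- FALSE
    i <- 1
    while (i <= nrow(iv)) {
      j <- i + 1
      while (j <= nrow(iv)) {
        if (iv$scaffold[i] == iv$scaffold[j] &&
            iv$start[i] <= iv$end[j] && iv$end[i] >= iv$start[j]) {
          iv$start[i] <- min(iv$start[i], iv$start[j])
          iv$end[i] <- max(iv$end[i], iv$end[j])
          iv <- iv[-j, , drop = FALSE]
          merged <- TRUE
        } else j <- j + 1
      }
      i <- i + 1
    }
    if (!merged) break
  }
  iv <- iv[order(iv$scaffold, iv$start), , drop = FALSE]
  rownames(iv) <- NULL
  iv
}

# direct haplotype-count r2 for tables without double heterozygotes
oracle_direct_r2 <- function(ga, gb) {
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]; gb <- gb[ok]
  haps <- matrix(0, 0, 2)
  for (i in seq_along(ga)) {
    stopifnot(!(ga[i] == 1 && gb[i] == 1))   # phase must be unambiguous
    h1 <- c(if (ga[i] >= 1) 1 else 0, if (gb[i] >= 1) 1 else 0)
    h2 <- c(if (ga[i] == 2) 1 else 0, if (gb[i] == 2) 1 else 0)
    haps <- rbind(haps, h1, h2)
  }
  pA <- mean(haps[, 1]); pB <- mean(haps[, 2])
  pAB <- mean(haps[, 1] == 1 & haps[, 2] == 1)
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# exact-combination counts of gene sets via power-set enumeration
oracle_overlap_counts <- function(sets) {
  nm <- names(sets)
  universe <- sort(unique(unlist(sets)))
  combos <- list()
  for (g in universe) {
    members <- nm[vapply(sets, function(s) g %in% s, logical(1))]
    key <- paste(members, collapse = "&")
    combos[[key]] <- c(combos[[key]], g)
  }
  sort(vapply(combos, length, integer(1)))
}

# top-q outlier selection by explicit descending sort: take the top
# ceiling(q*n) values of each statistic (plus ties with the last one) and
# intersect the two window sets
oracle_joint_top <- function(fst, ratio, q) {
  n <- length(fst)
  k <- ceiling(q * n)
  if (k < 1) return(integer(0))
  top_of <- function(x) {
    cutoff <- x[order(x, decreasing = TRUE)][min(k, n)]
    which(x >= cutoff)
  }
  sort(intersect(top_of(fst), top_of(ratio)))
}
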