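#' Parameters for the scanning-window ROH algorithm
#'
#' Defaults reproduce the classic PLINK 1.07 run-of-homozygosity settings
#' used for low-coverage livestock resequencing panels: a final segment
#' must contain at least 100 SNPs, span at least 500 kb, average at most
#' 50 kb per SNP, and contain no inter-SNP gap above 1,000 kb; the
#' scanning window holds 50 SNPs and tolerates at most 2 heterozygous and
#' 5 missing calls; a SNP is in a homozygous state when at least 5% of the
#' scanning windows covering it pass (PLINK's undocumented
#' `--homozyg-window-threshold` default).
#'
#' @param min_snps minimum SNPs per segment.
#' @param min_kb minimum segment length in kb.
#' @param density_kb_per_snp maximum segment kb per SNP.
#' @param max_gap_kb maximum inter-SNP gap inside a segment, kb.
#' @param window_snps scanning-window size in SNPs.
#' @param window_max_het maximum heterozygous calls per passing window.
#' @param window_max_missing maximum missing calls per passing window.
#' @param hit_threshold minimum fraction of passing windows covering a
#'   SNP for it to be flagged homozygous-state.
#' @return a `roh_params` list.
#' @export
roh_params <- function(min_snps = 100, min_kb = 500,
                       density_kb_per_snp = 50, max_gap_kb = 1000,
                       window_snps = 50, window_max_het = 2,
                       window_max_missing = 5, hit_threshold = 0.05) {
  p <- list(min_snps = as.integer(min_snps), min_kb = min_kb,
            density_kb_per_snp = density_kb_per_snp,
            max_gap_kb = max_gap_kb, window_snps = as.integer(window_snps),
            window_max_het = as.integer(window_max_het),
            window_max_missing = as.integer(window_max_missing),
            hit_threshold = hit_threshold)
  if (any(unlist(p) <= 0 & names(unlist(p)) %in%
          c("min_snps", "min_kb", "density_kb_per_snp", "max_gap_kb",
            "window_snps", "hit_threshold")))
    stop("ROH parameters must be positive")
  if (p$window_snps > p$min_snps)
    stop("window_snps must not exceed min_snps")
  structure(p, class = "roh_params")
}

# one sample, one scaffold: returns segments as data.frame
.roh_scan_vector <- function(dos, pos, params) {
  m <- length(dos)
  W <- params$window_snps
  if (m < W) return(NULL)
  het <- as.integer(!is.na(dos) & dos == 1L)
  mis <- as.integer(is.na(dos))
  ch <- cumsum(het); cm <- cumsum(mis)
  nw <- m - W + 1L
  # window i spans SNPs i..i+W-1
  het_w <- ch[seq_len(nw) + W - 1L] - c(0L, ch)[seq_len(nw)]
  mis_w <- cm[seq_len(nw) + W - 1L] - c(0L, cm)[seq_len(nw)]
  passing <- as.integer(het_w <= params$window_max_het &
                          mis_w <= params$window_max_missing)
  cp <- c(0L, cumsum(passing))
  j <- seq_len(m)
  lo <- pmax(1L, j - W + 1L)           # first window covering SNP j
  hi <- pmin(j, nw)                    # last window covering SNP j
  n_cover <- pmax(0L, hi - lo + 1L)
  n_pass <- ifelse(n_cover > 0, cp[hi + 1L] - cp[lo], 0L)
  flagged <- n_cover > 0 & n_pass / pmax(1L, n_cover) >= params$hit_threshold
  if (!any(flagged)) return(NULL)
  # maximal runs of flagged SNPs, broken at large physical gaps
  runs <- rle(flagged)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  segs <- NULL
  for (r in which(runs$values)) {
    i0 <- starts[r]; i1 <- ends[r]
    idx <- i0:i1
    gap_break <- which(diff(pos[idx]) > params$max_gap_kb * 1000)
    piece_start <- c(i0, idx[gap_break + 1L])
    piece_end <- c(idx[gap_break], i1)
    for (k in seq_along(piece_start)) {
      seg <- .trim_and_filter(dos, pos, piece_start[k], piece_end[k], params)
      if (!is.null(seg)) segs <- rbind(segs, seg)
    }
  }
  segs
}

# trim a candidate run to its outermost homozygous non-missing calls and
# apply the length / SNP-count / density filters
.trim_and_filter <- function(dos, pos, i0, i1, params) {
  idx <- i0:i1
  hom <- idx[!is.na(dos[idx]) & dos[idx] != 1L]
  if (!length(hom)) return(NULL)
  i0 <- min(hom); i1 <- max(hom)
  n_snps <- i1 - i0 + 1L
  length_bp <- pos[i1] - pos[i0] + 1L
  length_kb <- length_bp / 1000
  if (n_snps < params$min_snps) return(NULL)
  if (length_kb < params$min_kb) return(NULL)
  if (length_kb / n_snps > params$density_kb_per_snp) return(NULL)
  data.frame(start = pos[i0], end = pos[i1], n_snps = n_snps,
             length_kb = length_kb)
}

#' Detect runs of homozygosity for one sample
#'
#' Scanning-window algorithm: a window of `window_snps` consecutive SNPs
#' passes when it contains at most `window_max_het` heterozygous and
#' `window_max_missing` missing calls; each SNP's hit-rate is the
#' proportion of windows covering it that pass, and SNPs with hit-rate at
#' least `hit_threshold` are in a homozygous state.  Maximal runs of such
#' SNPs — split wherever consecutive SNPs are more than `max_gap_kb`
#' apart — are trimmed to their outermost homozygous non-missing calls
#' and kept when they satisfy the SNP-count, length and density filters.
#'
#' @param gm a [geno_matrix()].
#' @param sample sample ID.
#' @param params a [roh_params()].
#' @return data.frame of segments: `sample`, `scaffold`, `start`, `end`
#'   (1-based inclusive SNP positions, PLINK-style), `n_snps`,
#'   `length_kb`; zero rows when none found.
#' @export
scan_sample <- function(gm, sample, params = roh_params()) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(params, "roh_params"))
  col <- match(sample, gm$samples)
  if (is.na(col)) stop("unknown sample '", sample, "'")
  segs <- NULL
  short <- character(0)
  for (sc in unique(gm$variants$chrom)) {
    rows <- which(gm$variants$chrom == sc)
    if (length(rows) < params$window_snps) {
      short <- c(short, sc)
      next
    }
    s <- .roh_scan_vector(gm$geno[rows, col], gm$variants$pos[rows], params)
    if (!is.null(s)) {
      s <- cbind(sample = sample, scaffold = sc, s,
                 stringsAsFactors = FALSE)
      segs <- rbind(segs, s)
    }
  }
  if (length(short))
    warning("scaffold(s) with fewer SNPs than the scanning window, ",
            "skipped: ", paste(short, collapse = ", "))
  if (is.null(segs))
    segs <- data.frame(sample = character(0), scaffold = character(0),
                       start = integer(0), end = integer(0),
                       n_snps = integer(0), length_kb = numeric(0),
                       stringsAsFactors = FALSE)
  rownames(segs) <- NULL
  segs
}

#' Detect runs of homozygosity for all samples
#'
#' @inheritParams scan_sample
#' @return row-bound [scan_sample()] results for every sample.
#' @export
detect_roh <- function(gm, params = roh_params()) {
  out <- lapply(gm$samples, function(s)
    suppressWarnings(scan_sample(gm, s, params)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genomic inbreeding coefficient F_ROH
#'
#' `F_ROH = L_ROH / L_AUTO`: the summed length of a sample's ROH segments
#' divided by the total autosome length.
#'
#' @param segments segment table from [detect_roh()] / [scan_sample()].
#' @param autosome_lengths named numeric vector of autosomal scaffold
#'   lengths in bp; every segment scaffold must be present.
#' @param samples optional character vector of all samples to report
#'   (samples without segments get `F_ROH = 0`); defaults to the samples
#'   present in `segments`.
#' @return data.frame: `sample`, `n_segments`, `l_roh_bp`, `l_auto_bp`,
#'   `f_roh`.
#' @export
f_roh <- function(segments, autosome_lengths, samples = NULL) {
  orphan <- setdiff(unique(segments$scaffold), names(autosome_lengths))
  if (length(orphan))
    stop("segment scaffold(s) absent from the autosome table: ",
         paste(orphan, collapse = ", "))
  l_auto <- sum(autosome_lengths)
  if (is.null(samples)) samples <- unique(segments$sample)
  len <- segments$end - segments$start + 1
  per <- data.frame(
    sample = samples,
    n_segments = vapply(samples, function(s)
      sum(segments$sample == s), integer(1), USE.NAMES = FALSE),
    l_roh_bp = vapply(samples, function(s)
      sum(len[segments$sample == s]), numeric(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  per$l_auto_bp <- l_auto
  per$f_roh <- per$l_roh_bp / l_auto
  rownames(per) <- NULL
  per
}

#' Per-population ROH and inbreeding summary
#'
#' @param reports per-sample table from [f_roh()].
#' @param pops named character vector mapping samples to populations.
#' @return data.frame per population: mean segment count, mean total ROH
#'   length (bp), mean F_ROH, sample count.
#' @export
breed_summary <- function(reports, pops) {
  pop <- unname(pops[reports$sample])
  if (anyNA(pop)) stop("sample(s) missing from the population map")
  agg <- function(x) tapply(x, pop, mean)
  u <- sort(unique(pop))
  data.frame(pop = u,
             n_samples = as.integer(table(pop)[u]),
             mean_n_segments = as.numeric(agg(reports$n_segments)[u]),
             mean_l_roh_bp = as.numeric(agg(reports$l_roh_bp)[u]),
             mean_f_roh = as.numeric(agg(reports$f_roh)[u]),
             stringsAsFactors = FALSE)
}
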