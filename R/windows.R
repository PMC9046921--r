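# Sliding-window machinery for the selection scan.
#
# Windows are anchored at coordinate 0 of each scaffold, use 0-based
# half-open [start, end) intervals, and by default span 40 kb with a
# 20-kb step; the final window of a scaffold may be truncated.  A SNP at
# 1-based position p belongs to a window iff start <= p-1 < end.

.make_windows <- function(scaffold, length, size, step) {
  starts <- seq(0L, max(0L, as.integer(ceiling(length)) - 1L), by = step)
  data.frame(scaffold = scaffold, start = starts,
             end = pmin(starts + size, as.integer(ceiling(length))),
             stringsAsFactors = FALSE)
}

# window frame for all scaffolds plus, per window, the variant row indices
.window_frame <- function(gm, size, step) {
  lens <- scaffold_lengths(gm)
  win <- do.call(rbind, lapply(names(lens), function(sc)
    .make_windows(sc, lens[[sc]], size, step)))
  rownames(win) <- NULL
  win
}

#' Windowed ratio-of-sums F_ST
#'
#' Slides windows of `size` bp with `step` bp increments over every
#' scaffold and combines the per-locus Weir & Cockerham components as
#' `sum(a) / sum(a+b+c)` within each window.  Windows with fewer than
#' `min_snps` usable SNPs, or a zero denominator, are flagged unusable
#' and excluded from quantile computations downstream.
#'
#' @param gm a filtered [geno_matrix()].
#' @param pop_a,pop_b the two population labels to contrast.
#' @param size,step window size and increment in bp (defaults 40 kb and
#'   20 kb).
#' @param min_snps minimum usable SNPs for a window to enter quantiles
#'   (default 10).
#' @return data.frame with `scaffold`, `start`, `end`, `n_snps`,
#'   `fst_num`, `fst_den`, `fst`, `usable`.
#' @export
windowed_fst <- function(gm, pop_a, pop_b, size = 40000, step = 20000,
                         min_snps = 10) {
  comp <- wc_components(gm, c(pop_a, pop_b))
  ok <- comp$usable
  num <- ifelse(ok, comp$a, 0)
  den <- ifelse(ok, comp$a + comp$b + comp$c, 0)
  agg <- .aggregate_windows(gm, cbind(num = num, den = den,
                                      n = as.numeric(ok)),
                            size, step)
  agg$n_snps <- as.integer(agg$n)
  agg$fst_num <- agg$num
  agg$fst_den <- agg$den
  agg$fst <- ifelse(agg$fst_den > 0, agg$fst_num / agg$fst_den, NA_real_)
  agg$usable <- agg$n_snps >= min_snps & !is.na(agg$fst)
  agg[c("scaffold", "start", "end", "n_snps", "fst_num", "fst_den",
        "fst", "usable")]
}

# core aggregation: sum value columns per sliding window
.aggregate_windows <- function(gm, values, size, step) {
  win <- .window_frame(gm, size, step)
  values <- as.matrix(values)
  sums <- matrix(0, nrow(win), ncol(values),
                 dimnames = list(NULL, colnames(values)))
  pos0 <- gm$variants$pos - 1L
  k_max <- ceiling(size / step)
  win_id <- paste(win$scaffold, win$start)
  row_of <- stats::setNames(seq_len(nrow(win)), win_id)
  for (k in seq_len(k_max) - 1L) {
    ws <- (pos0 %/% step - k) * step
    ok <- ws >= 0 & pos0 < ws + size
    if (!any(ok)) next
    rows <- unname(row_of[paste(gm$variants$chrom[ok], ws[ok])])
    good <- !is.na(rows)
    if (!any(good)) next
    idx <- which(ok)[good]
    rows <- rows[good]
    for (j in seq_len(ncol(values))) {
      v <- values[idx, j]
      v[is.na(v)] <- 0
      add <- rowsum(v, rows)
      sums[as.integer(rownames(add)), j] <-
        sums[as.integer(rownames(add)), j] + add[, 1]
    }
  }
  cbind(win, as.data.frame(sums))
}

#' Windowed nucleotide diversity (theta-pi)
#'
#' Per-site diversity is the unbiased heterozygosity
#' `pi_site = 2 * c_ref * c_alt / (n * (n - 1))` where `n` is the number
#' of non-missing alleles in the population at the site; window theta-pi
#' is the sum of per-site values divided by the window span in bp.  Sites
#' with fewer than two called alleles contribute zero.
#'
#' @param gm a [geno_matrix()].
#' @param pop population label.
#' @inheritParams windowed_fst
#' @return data.frame with `scaffold`, `start`, `end`, `n_snps`, `pi`
#'   (per-bp diversity).
#' @export
windowed_pi <- function(gm, pop, size = 40000, step = 20000) {
  pi_site <- site_pi(gm, pop)
  agg <- .aggregate_windows(gm, cbind(pi_sum = pi_site,
                                      n = as.numeric(!is.na(pi_site))),
                            size, step)
  agg$n_snps <- as.integer(agg$n)
  agg$pi <- agg$pi_sum / (agg$end - agg$start)
  agg[c("scaffold", "start", "end", "n_snps", "pi")]
}

#' Per-site nucleotide diversity within one population
#'
#' @inheritParams windowed_pi
#' @return numeric vector of `pi_site` per variant; `NA` where fewer than
#'   two alleles are called (such sites are excluded from window counts
#'   and contribute zero to window sums).
#' @export
site_pi <- function(gm, pop) {
  g <- gm$geno[, gm$pops == pop, drop = FALSE]
  if (!ncol(g)) stop("no samples in population '", pop, "'")
  n <- 2L * rowSums(!is.na(g))
  alt <- rowSums(g, na.rm = TRUE)
  ifelse(n >= 2, 2 * (n - alt) * alt / (n * (n - 1)), NA_real_)
}

#' Joint F_ST / diversity-ratio sweep scan
#'
#' Runs [windowed_fst()] and [windowed_pi()] for a (target, control)
#' population contrast on one shared window grid and attaches
#' `log2_ratio = log2(pi_control / pi_target)`, the orientation in which
#' diversity *loss* in the target population gives large positive values.
#' A window where only the target diversity is zero receives `+Inf`
#' (the strongest possible signal, ranked above all finite values); a
#' window where both diversities are zero is unusable.
#'
#' @param gm a filtered [geno_matrix()].
#' @param target_pop population scanned for sweeps.
#' @param control_pop reference population (numerator of the ratio).
#' @inheritParams windowed_fst
#' @return data.frame of per-window statistics (`fst`, `pi_target`,
#'   `pi_control`, `log2_ratio`, `usable`).
#' @export
sweep_scan_windows <- function(gm, target_pop, control_pop, size = 40000,
                               step = 20000, min_snps = 10) {
  fst <- windowed_fst(gm, target_pop, control_pop, size, step, min_snps)
  pit <- windowed_pi(gm, target_pop, size, step)
  pic <- windowed_pi(gm, control_pop, size, step)
  stopifnot(identical(fst[c("scaffold", "start", "end")],
                      pit[c("scaffold", "start", "end")]))
  out <- fst[c("scaffold", "start", "end", "n_snps", "fst", "usable")]
  out$pi_target <- pit$pi
  out$pi_control <- pic$pi
  out$log2_ratio <- log2_pi_ratio(pic$pi, pit$pi)
  out$usable <- out$usable & !(out$pi_target == 0 & out$pi_control == 0)
  out
}

#' log2 diversity ratio
#'
#' `log2(pi_control / pi_target)` with the conventions used by the scan:
#' `+Inf` when the target diversity is zero but the control is not, `NaN`
#' (unusable) when both are zero.
#'
#' @param pi_control,pi_target per-window diversity vectors on identical
#'   windows.
#' @return numeric vector of log2 ratios.
#' @export
log2_pi_ratio <- function(pi_control, pi_target) {
  if (length(pi_control) != length(pi_target))
    stop("window sets mismatch between control and target pi tracks")
  ifelse(pi_target == 0 & pi_control == 0, NaN,
         log2(pi_control / pi_target))
}

# nearest-rank threshold for the top tail-mass q: the smallest value of
# the top ceiling(q * n) order statistics, so selecting `x >= threshold`
# returns exactly that many windows apart from ties, which are included
.nearest_rank_threshold <- function(x, q) {
  n <- length(x)
  k <- n - ceiling(q * n) + 1
  if (k > n) return(Inf)
  if (k < 1) k <- 1
  sort(x)[k]
}

#' Joint top-quantile outlier windows
#'
#' Computes nearest-rank empirical `1 - q` thresholds separately for
#' windowed F_ST and the log2 diversity ratio over *usable* windows, and
#' returns the windows at or above both thresholds simultaneously — the
#' candidate windows under strong selective sweeps.  Ties at a threshold
#' are included.
#'
#' @param stats window statistics from [sweep_scan_windows()].
#' @param q upper tail mass (default 0.05 for the top 5%).
#' @return the input rows flagged with `outlier`; thresholds attached as
#'   attributes `fst_threshold` and `ratio_threshold`.
#' @export
joint_outliers <- function(stats, q = 0.05) {
  usable <- which(stats$usable)
  if (length(usable) < 20)
    stop("only ", length(usable),
         " usable windows; need >= 20 for quantile thresholds")
  thr_fst <- .nearest_rank_threshold(stats$fst[usable], q)
  thr_ratio <- .nearest_rank_threshold(stats$log2_ratio[usable], q)
  stats$outlier <- FALSE
  stats$outlier[usable] <- stats$fst[usable] >= thr_fst &
    stats$log2_ratio[usable] >= thr_ratio
  attr(stats, "fst_threshold") <- thr_fst
  attr(stats, "ratio_threshold") <- thr_ratio
  stats
}

#' Merge outlier windows into candidate regions
#'
#' Overlapping or book-ended outlier windows on the same scaffold are
#' merged into maximal candidate regions, each carrying the number of
#' member windows and the extreme statistics observed inside it.
#'
#' @param stats output of [joint_outliers()] (uses the `outlier` flag),
#'   or any window frame with an `outlier` column.
#' @return data.frame of regions: `scaffold`, `start`, `end` (0-based
#'   half-open), `n_windows`, `max_fst`, `max_log2_ratio`.
#' @export
merge_regions <- function(stats) {
  out <- stats[stats$outlier, , drop = FALSE]
  if (!nrow(out))
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      max_fst = numeric(0), max_log2_ratio = numeric(0),
                      stringsAsFactors = FALSE))
  gr <- GenomicRanges::GRanges(out$scaffold,
                               IRanges::IRanges(out$start + 1L, out$end))
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  data.frame(
    scaffold = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    n_windows = lengths(revmap),
    max_fst = vapply(revmap, function(i) max(out$fst[i]), numeric(1)),
    max_log2_ratio = vapply(revmap, function(i) max(out$log2_ratio[i]),
                            numeric(1)),
    stringsAsFactors = FALSE)
}
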