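#' Per-locus Weir & Cockerham variance components
#'
#' Computes the variance components `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals) of the
#' Weir & Cockerham (1984) F_ST estimator for every variant, over an
#' arbitrary set of populations.  With `r` populations of sample sizes
#' `n_i`, alt-allele frequencies `p_i` and heterozygote proportions `h_i`:
#'
#' \deqn{\bar n = \sum n_i / r, \quad
#'       n_c = (r\bar n - \sum n_i^2/(r\bar n))/(r-1), \quad
#'       \bar p = \sum n_i p_i / (r\bar n)}
#' \deqn{s^2 = \sum n_i (p_i-\bar p)^2 / ((r-1)\bar n), \quad
#'       \bar h = \sum n_i h_i / (r\bar n)}
#' \deqn{a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}
#'       \left(\bar p(1-\bar p) - \frac{r-1}{r}s^2 -
#'       \frac{\bar h}{4}\right)\right]}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) -
#'       \frac{r-1}{r}s^2 - \frac{2\bar n - 1}{4\bar n}\bar h\right],
#'       \quad c = \bar h / 2}
#'
#' The per-locus estimate is `a/(a+b+c)`; the recommended multi-locus
#' combination is the ratio of sums (see [windowed_fst()]).  A locus where
#' any population has no non-missing genotype, or where the mean sample
#' size does not exceed 1, is flagged unusable; a locus monomorphic in all
#' populations has `a = b = c = 0` and contributes nothing to window sums.
#'
#' @param gm a [geno_matrix()].
#' @param pops character vector of >= 2 population labels.
#' @return data.frame with one row per variant: `a`, `b`, `c`, `usable`.
#' @export
wc_components <- function(gm, pops) {
  stopifnot(inherits(gm, "geno_matrix"), length(pops) >= 2)
  missing_pops <- setdiff(pops, gm$pops)
  if (length(missing_pops))
    stop("unknown population(s): ", paste(missing_pops, collapse = ", "))
  r <- length(pops)
  m <- n_variants(gm)
  n_i <- p_i <- h_i <- matrix(0, m, r)
  for (k in seq_len(r)) {
    g <- gm$geno[, gm$pops == pops[k], drop = FALSE]
    ok <- !is.na(g)
    n_i[, k] <- rowSums(ok)
    tot <- rowSums(g, na.rm = TRUE)
    p_i[, k] <- ifelse(n_i[, k] > 0, tot / (2 * n_i[, k]), NA_real_)
    h_i[, k] <- ifelse(n_i[, k] > 0,
                       rowSums(g == 1L, na.rm = TRUE) / n_i[, k], NA_real_)
  }
  nbar <- rowSums(n_i) / r
  usable <- apply(n_i > 0, 1L, all) & nbar > 1
  nc <- (r * nbar - rowSums(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(n_i * p_i) / (r * nbar)
  s2 <- rowSums(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  # monomorphic across all populations: define components as exactly zero
  mono <- usable & (pbar == 0 | pbar == 1)
  a[mono] <- 0; b[mono] <- 0; cc[mono] <- 0
  a[!usable] <- NA_real_; b[!usable] <- NA_real_; cc[!usable] <- NA_real_
  data.frame(a = a, b = b, c = cc, usable = usable)
}

#' Per-locus F_ST estimates
#'
#' Convenience wrapper returning `a/(a+b+c)` per variant; `NaN` where the
#' denominator is zero (monomorphic loci).
#'
#' @inheritParams wc_components
#' @return numeric vector of per-locus F_ST.
#' @export
locus_fst <- function(gm, pops) {
  comp <- wc_components(gm, pops)
  comp$a / (comp$a + comp$b + comp$c)
}

#' Genome-wide ratio-of-sums F_ST
#'
#' `sum(a) / sum(a + b + c)` over all usable, polymorphic loci — the
#' multi-locus combination recommended for the Weir & Cockerham
#' estimator.
#'
#' @inheritParams wc_components
#' @return a single F_ST estimate.
#' @export
global_fst <- function(gm, pops) {
  comp <- wc_components(gm, pops)
  ok <- comp$usable & !is.na(comp$a)
  sum(comp$a[ok]) / sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
}
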