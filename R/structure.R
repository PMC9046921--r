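#' Allele-sharing distance matrix
#'
#' Pairwise distance between diploid samples:
#' `d(i, j) = mean(|g_i - g_j| / 2)` over the loci where both calls are
#' present — 0 for identical genotypes, 1 for opposite homozygotes at
#' every shared locus.
#'
#' @param gm a [geno_matrix()].
#' @return symmetric numeric matrix with zero diagonal, dimnames set to
#'   sample IDs.
#' @export
allele_sharing_distance <- function(gm) {
  g <- gm$geno
  n <- ncol(g)
  d <- matrix(0, n, n, dimnames = list(gm$samples, gm$samples))
  for (i in seq_len(n - 1)) {
    gi <- g[, i]
    for (j in (i + 1):n) {
      ok <- !is.na(gi) & !is.na(g[, j])
      if (!any(ok))
        stop("samples '", gm$samples[i], "' and '", gm$samples[j],
             "' share no non-missing loci")
      d[i, j] <- d[j, i] <- mean(abs(gi[ok] - g[ok, j])) / 2
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}), which reconstructs the
#' generating tree exactly when the input distances are additive.
#' Negative branch lengths — an artefact the estimator can produce on
#' noisy distances — are clamped to zero with the deficit transferred to
#' the sister branch, preserving path lengths through the parent node.
#'
#' @param dm symmetric distance matrix with sample dimnames.
#' @return an \pkg{ape} `phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (!isSymmetric(unname(as.matrix(dm)), tol = 1e-12))
    stop("distance matrix must be symmetric")
  tree <- ape::nj(as.matrix(dm))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1]
    sisters <- which(tree$edge[, 1] == parent)
    sisters <- setdiff(sisters, e)
    if (length(sisters))
      tree$edge.length[sisters[1]] <-
        tree$edge.length[sisters[1]] + tree$edge.length[e]
    tree$edge.length[e] <- 0
  }
  tree
}

#' Bootstrap support for the NJ tree
#'
#' Resamples loci with replacement, recomputes the allele-sharing
#' distance and NJ tree per replicate, and reports for every internal
#' bipartition of the full-data tree the percentage of replicates that
#' contain it.  Supports are attached as `node.label`.
#'
#' @param gm a [geno_matrix()].
#' @param tree optional full-data tree; recomputed when `NULL`.
#' @param n_reps bootstrap replicates (1,000 for publication-grade runs;
#'   100 is plenty for desk-scale checks).
#' @param seed integer seed for the locus resampling.
#' @return the tree with `node.label` set to support percentages (the
#'   root's label is empty).
#' @export
bootstrap_support <- function(gm, tree = NULL, n_reps = 1000, seed = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (is.null(tree)) tree <- nj_tree(allele_sharing_distance(gm))
  set.seed(seed)
  m <- n_variants(gm)
  boot <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    rs <- sample.int(m, m, replace = TRUE)
    boot[[b]] <- nj_tree(allele_sharing_distance(subset_variants(gm, rs)))
  }
  cnt <- ape::prop.clades(tree, boot, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  support <- round(100 * cnt / n_reps, 1)
  tree$node.label <- as.character(support)
  tree$node.label[1] <- ""          # root of the unrooted representation
  attr(tree, "support") <- support
  tree
}

#' Genotype PCA with EIGENSOFT-style normalisation
#'
#' Drops monomorphic loci, normalises each variant column as
#' `(g - 2 p) / sqrt(2 p (1 - p))` with `p` the sample alt-allele
#' frequency, imputes missing entries to 0 (the post-centering mean), and
#' eigendecomposes the sample covariance matrix.  Coordinates are the
#' eigenvectors scaled by the square root of their eigenvalues.
#'
#' @param gm a [geno_matrix()].
#' @param k number of axes to return (truncated to `n_samples - 1` with a
#'   warning when larger).
#' @return list: `eigenvalues` (all, descending), `coords`
#'   (samples x k), `varprop` (proportion of variance per axis).
#' @export
genotype_pca <- function(gm, k = 10) {
  g <- gm$geno
  n <- ncol(g)
  if (n < 2) stop("need >= 2 samples")
  called <- rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / (2 * pmax(1L, called))
  poly <- called > 0 & p > 0 & p < 1
  if (sum(poly) < 2) stop("need >= 2 polymorphic loci")
  g <- g[poly, , drop = FALSE]
  p <- p[poly]
  x <- (g - 2 * p) / sqrt(2 * p * (1 - p))
  x[is.na(x)] <- 0
  cov <- crossprod(x) / nrow(x)     # samples x samples
  eig <- eigen(cov, symmetric = TRUE)
  if (k > n - 1) {
    warning("k truncated to ", n - 1)
    k <- n - 1
  }
  vals <- pmax(eig$values, 0)
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)]), k, k)
  dimnames(coords) <- list(gm$samples, paste0("PC", seq_len(k)))
  list(eigenvalues = vals, coords = coords,
       varprop = vals / sum(vals))
}
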