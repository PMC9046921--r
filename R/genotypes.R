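#' Genotype matrix container
#'
#' The central data structure of the package: a biallelic SNP dosage matrix
#' (variants in rows, samples in columns) together with variant metadata,
#' a sample-to-population map, optional per-sample sequencing depth, and
#' optional scaffold lengths.  Dosages count copies of the alternate allele
#' (0, 1 or 2); `NA` encodes a missing call.
#'
#' @param geno integer matrix, variants x samples; entries in `c(0L, 1L, 2L, NA)`.
#' @param variants data.frame with columns `chrom` (character), `pos`
#'   (1-based integer position), `ref`, `alt` (single-base alleles), and
#'   optionally `qual` (phred-scaled site quality).  Must be sorted by
#'   `(chrom, pos)`.
#' @param samples character vector of sample IDs (column names of `geno`).
#' @param pops named character vector mapping every sample to a population
#'   label.
#' @param depth optional numeric matrix of per-sample read depth, same
#'   dimensions as `geno`.
#' @param scaffolds optional named numeric vector of scaffold lengths in bp.
#'   When absent, downstream window code falls back to the last SNP position
#'   per scaffold.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(geno, variants, samples, pops, depth = NULL,
                        scaffolds = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos") %in% names(variants)),
            nrow(geno) == nrow(variants),
            ncol(geno) == length(samples))
  if (anyNA(match(samples, names(pops))))
    stop("samples missing from the population map: ",
         paste(setdiff(samples, names(pops)), collapse = ", "))
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA")
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  # sortedness: scaffolds in first-appearance order, positions increasing
  ord <- order(match(variants$chrom, unique(variants$chrom)), variants$pos)
  if (!identical(ord, seq_len(nrow(variants))))
    stop("variants must be sorted by (chrom, pos)")
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    stopifnot(identical(dim(depth), dim(geno)))
  }
  if (!is.null(scaffolds)) {
    stopifnot(!is.null(names(scaffolds)), all(scaffolds > 0))
    orphan <- setdiff(unique(variants$chrom), names(scaffolds))
    if (length(orphan))
      stop("variants on scaffolds absent from the scaffold table: ",
           paste(orphan, collapse = ", "))
  }
  colnames(geno) <- samples
  rownames(variants) <- NULL
  structure(list(geno = geno, variants = variants,
                 samples = as.character(samples),
                 pops = pops[samples], depth = depth,
                 scaffolds = scaffolds),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$geno), "variants x", length(x$samples),
      "samples\n")
  cat("  scaffolds:", length(unique(x$variants$chrom)),
      " populations:", paste(unique(x$pops), collapse = ", "), "\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missingness: %.2f%%  depth: %s\n", 100 * miss,
              if (is.null(x$depth)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Number of variants in a geno_matrix
#' @param gm a [geno_matrix()].
#' @return integer count of variant records.
#' @export
n_variants <- function(gm) nrow(gm$geno)

#' Subset a geno_matrix to a set of variant rows
#'
#' Keeps sample set, population map and scaffold table intact; used by all
#' variant filters so that filters compose and remain idempotent.
#'
#' @param gm a [geno_matrix()].
#' @param keep logical or integer index over variant rows.
#' @return the subsetted `geno_matrix`.
#' @export
subset_variants <- function(gm, keep) {
  gm$geno <- gm$geno[keep, , drop = FALSE]
  gm$variants <- gm$variants[keep, , drop = FALSE]
  rownames(gm$variants) <- NULL
  if (!is.null(gm$depth)) gm$depth <- gm$depth[keep, , drop = FALSE]
  gm
}

#' Samples belonging to one population
#' @param gm a [geno_matrix()].
#' @param pop population label.
#' @return character vector of sample IDs.
#' @export
pop_samples <- function(gm, pop) {
  s <- gm$samples[gm$pops == pop]
  if (!length(s)) stop("no samples in population '", pop, "'")
  s
}

# scaffold lengths with fallback to last SNP position
scaffold_lengths <- function(gm) {
  if (!is.null(gm$scaffolds)) return(gm$scaffolds)
  tapply(gm$variants$pos, gm$variants$chrom, max)[unique(gm$variants$chrom)]
}
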