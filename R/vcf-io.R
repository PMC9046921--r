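#' Write a geno_matrix as VCF 4.2
#'
#' Emits plain-text VCF with one biallelic SNP per record, `GT:DP` sample
#' fields (depth omitted when absent), populated `QUAL`, and `##contig`
#' headers from the scaffold table.  Output is fully deterministic for a
#' given object, so simulator runs with a fixed seed are byte-identical.
#'
#' @param gm a [geno_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con, sep = "\n")
  w("##fileformat=VCFv4.2",
    "##source=popgenscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  has_dp <- !is.null(gm$depth)
  if (has_dp)
    w('##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  if (!is.null(gm$scaffolds))
    w(sprintf("##contig=<ID=%s,length=%d>", names(gm$scaffolds),
              as.integer(gm$scaffolds)))
  w(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t"))
  n <- nrow(gm$geno)
  if (n > 0) {
    gt <- matrix(c("0/0", "0/1", "1/1")[gm$geno + 1L], nrow = n)
    gt[is.na(gm$geno)] <- "./."
    if (has_dp) {
      dp <- matrix(as.character(gm$depth), nrow = n)
      dp[is.na(gm$depth)] <- "."
      gt <- matrix(paste(gt, dp, sep = ":"), nrow = n)
    }
    qual <- if ("qual" %in% names(gm$variants))
      formatC(gm$variants$qual, format = "g", digits = 6) else "."
    body <- paste(gm$variants$chrom, gm$variants$pos, ".",
                  gm$variants$ref, gm$variants$alt, qual, "PASS", ".",
                  if (has_dp) "GT:DP" else "GT",
                  apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    w(body)
  }
  invisible(path)
}

#' Write / read a two-column sample-to-population map
#'
#' @param pops named character vector (names = sample IDs, values =
#'   population labels), or for reading, the file path.
#' @param path output path (tab-separated, no header).
#' @return `path` invisibly, or the named vector for [read_popmap()].
#' @export
write_popmap <- function(pops, path) {
  utils::write.table(data.frame(sample = names(pops), pop = unname(pops)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_popmap
#' @export
read_popmap <- function(path) {
  pm <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("sample", "pop"),
                          colClasses = "character")
  stats::setNames(pm$pop, pm$sample)
}

#' Read a multi-sample VCF into a geno_matrix
#'
#' Parses a (optionally bgzipped) VCF via `vcfR`, keeps biallelic SNP
#' records only (multiallelic records are dropped), converts `GT` to alt
#' dosage with any genotype containing `.` treated as fully missing, and
#' attaches per-sample `DP` when present.  Every sample in the VCF must
#' appear in the population map; the variant ordering invariant
#' (sorted by scaffold then position) is enforced.
#'
#' @param path VCF file path.
#' @param popmap_path two-column sample/population TSV, or a named
#'   character vector as produced by [read_popmap()].
#' @return a [geno_matrix()].
#' @export
read_vcf <- function(path, popmap_path) {
  pops <- if (is.character(popmap_path) && length(popmap_path) == 1 &&
              file.exists(popmap_path)) read_popmap(popmap_path)
          else popmap_path
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  missing_pop <- setdiff(samples, names(pops))
  if (length(missing_pop))
    stop("VCF sample(s) absent from popmap: ",
         paste(missing_pop, collapse = ", "))
  keep <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp_raw <- if (any(grepl("DP", v@gt[, "FORMAT"])))
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE) else NULL
  if (nrow(fix) > 0 && !all(keep)) {
    fix <- fix[keep, , drop = FALSE]
    gt_raw <- gt_raw[keep, , drop = FALSE]
    if (!is.null(dp_raw)) dp_raw <- dp_raw[keep, , drop = FALSE]
  }
  n <- nrow(fix)
  gt <- matrix(NA_integer_, n, length(samples))
  if (n > 0) {
    g <- gsub("\\|", "/", gt_raw)
    gt[g == "0/0"] <- 0L
    gt[g %in% c("0/1", "1/0")] <- 1L
    gt[g == "1/1"] <- 2L             # anything containing "." stays NA
  }
  variants <- data.frame(chrom = as.character(fix$CHROM),
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         qual = suppressWarnings(as.numeric(fix$QUAL)),
                         stringsAsFactors = FALSE)
  ord <- order(match(variants$chrom, unique(variants$chrom)), variants$pos)
  if (!identical(ord, seq_len(n))) stop("VCF is not coordinate-sorted")
  scaffolds <- NULL
  meta <- v@meta
  ctg <- meta[grepl("^##contig=", meta)]
  if (length(ctg)) {
    ids <- sub('.*ID=([^,>]+).*', "\\1", ctg)
    lens <- suppressWarnings(as.numeric(sub('.*length=([0-9]+).*', "\\1", ctg)))
    if (!anyNA(lens)) scaffolds <- stats::setNames(lens, ids)
  }
  geno_matrix(gt, variants, samples, pops,
              depth = if (is.null(dp_raw)) NULL else unname(dp_raw),
              scaffolds = scaffolds)
}

#' SNP quality filter
#'
#' Retains variants whose phred-scaled site quality is at least
#' `min_qual`.  The default Q20 keeps sites with an estimated error rate
#' of at most 1%; the boundary is inclusive since Q20 corresponds to
#' exactly that rate.
#'
#' @param gm a [geno_matrix()] with `qual` populated.
#' @param min_qual minimum phred quality (default 20).
#' @return filtered `geno_matrix`.
#' @export
filter_quality <- function(gm, min_qual = 20) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (!"qual" %in% names(gm$variants)) stop("variants carry no QUAL")
  subset_variants(gm, !is.na(gm$variants$qual) &
                    gm$variants$qual >= min_qual)
}

#' SNP spacing filter
#'
#' Greedy left-to-right scan per scaffold: the first variant is always
#' retained, and each subsequent variant is dropped when it lies closer
#' than `min_spacing` bp to the last *retained* variant.  Deterministic
#' and independent of site quality.
#'
#' @param gm a [geno_matrix()] (sorted, as guaranteed by construction).
#' @param min_spacing minimum distance in bp between retained SNPs
#'   (default 5).
#' @return filtered `geno_matrix`.
#' @export
filter_spacing <- function(gm, min_spacing = 5) {
  stopifnot(inherits(gm, "geno_matrix"))
  keep <- logical(n_variants(gm))
  for (sc in unique(gm$variants$chrom)) {
    idx <- which(gm$variants$chrom == sc)
    pos <- gm$variants$pos[idx]
    k <- logical(length(idx))
    last <- -Inf
    for (j in seq_along(pos)) {
      if (pos[j] - last >= min_spacing) {
        k[j] <- TRUE
        last <- pos[j]
      }
    }
    keep[idx] <- k
  }
  subset_variants(gm, keep)
}

#' Site depth filter
#'
#' Computes the mean depth per site across samples and retains sites whose
#' mean lies within `[low_factor, high_factor]` times the genome-wide mean
#' depth.  The default window (1/3, 3) brackets the average depth; the
#' stricter multipliers 1, 3 and 5 used in resequencing pipelines are
#' available through the same two parameters.
#'
#' @param gm a [geno_matrix()] with per-sample depth.
#' @param low_factor,high_factor positive multipliers of the genome-wide
#'   mean site depth, `low_factor < high_factor`.
#' @param genome_mean genome-wide mean depth; computed from the data when
#'   `NULL` (the default), but can be supplied when the matrix at hand is
#'   a subset of a larger call set.
#' @return filtered `geno_matrix`.
#' @export
filter_depth <- function(gm, low_factor = 1 / 3, high_factor = 3,
                         genome_mean = NULL) {
  stopifnot(inherits(gm, "geno_matrix"), low_factor < high_factor,
            low_factor >= 0)
  if (is.null(gm$depth) || all(is.na(gm$depth))) {
    warning("no depth information; depth filter skipped")
    return(gm)
  }
  site <- rowMeans(gm$depth, na.rm = TRUE)
  # the reference mean is computed once and cached on the object, so the
  # filter is idempotent and partition-invariant once a mean is fixed
  gw <- if (!is.null(genome_mean)) genome_mean
        else if (!is.null(gm$depth_genome_mean)) gm$depth_genome_mean
        else mean(site, na.rm = TRUE)
  keep <- !is.na(site) & site >= low_factor * gw & site <= high_factor * gw
  gm <- subset_variants(gm, keep)
  gm$depth_genome_mean <- gw
  gm
}

#' Apply the standard SNP filter chain with a per-stage report
#'
#' Quality, then spacing, then depth, mirroring a typical resequencing
#' QC recipe (Q20, >= 5 bp spacing, site depth within a window around the
#' genome-wide mean).
#'
#' @param gm a [geno_matrix()].
#' @param min_qual,min_spacing,low_factor,high_factor see the individual
#'   filters.
#' @return list with `gm` (the filtered matrix) and `report`
#'   (data.frame of variant counts after each stage).
#' @export
filter_snps <- function(gm, min_qual = 20, min_spacing = 5,
                        low_factor = 1 / 3, high_factor = 3) {
  n0 <- n_variants(gm)
  gm <- filter_quality(gm, min_qual); n1 <- n_variants(gm)
  gm <- filter_spacing(gm, min_spacing); n2 <- n_variants(gm)
  gm <- if (is.null(gm$depth)) gm else
    filter_depth(gm, low_factor, high_factor)
  n3 <- n_variants(gm)
  list(gm = gm,
       report = data.frame(stage = c("input", "quality", "spacing", "depth"),
                           n_variants = c(n0, n1, n2, n3)))
}
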