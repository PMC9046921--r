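#' Read gene models from BED or GFF3
#'
#' BED intervals are taken as 0-based half-open; GFF3 features of type
#' `gene` are converted from 1-based inclusive coordinates.  Gene IDs
#' come from BED column 4 or from the first available GFF3 attribute
#' among `ID`, `gene_id` and `Name`; duplicate IDs are de-duplicated
#' keeping the first record.
#'
#' @param path a `.bed`, `.gff`, `.gff3` or `.gtf`-style file.
#' @return data.frame: `gene_id`, `scaffold`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @export
read_gene_models <- function(path) {
  is_gff <- grepl("\\.(gff3?|gtf)(\\.gz)?$", path, ignore.case = TRUE)
  if (is_gff) {
    gr <- rtracklayer::import(path)
    mc <- S4Vectors::mcols(gr)
    if ("type" %in% names(mc)) gr <- gr[mc$type == "gene"]
    mc <- S4Vectors::mcols(gr)
    id <- rep(NA_character_, length(gr))
    for (key in c("ID", "gene_id", "Name"))
      if (key %in% names(mc))
        id[is.na(id)] <- as.character(mc[[key]])[is.na(id)]
    id[is.na(id)] <- paste0("gene_", which(is.na(id)))
    out <- data.frame(gene_id = id,
                      scaffold = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    mc <- S4Vectors::mcols(gr)
    id <- if ("name" %in% names(mc)) as.character(mc$name)
          else paste0("gene_", seq_along(gr))
    out <- data.frame(gene_id = id,
                      scaffold = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
  }
  stopifnot(all(out$start <= out$end))
  out <- out[!duplicated(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes overlapping candidate regions
#'
#' A gene is included when it overlaps any candidate region by at least
#' one bp (or by at least `min_overlap_frac` of the gene length when
#' set); each gene is counted once.  Both inputs use 0-based half-open
#' coordinates, so a gene ending where a region starts does not overlap.
#'
#' @param regions data.frame from [merge_regions()] (`scaffold`, `start`,
#'   `end`).
#' @param genes data.frame from [read_gene_models()].
#' @param min_overlap_frac minimum overlap as a fraction of gene length
#'   (default 0: any overlap).
#' @return character vector of gene IDs (sorted, unique).
#' @export
regions_to_genes <- function(regions, genes, min_overlap_frac = 0) {
  if (!nrow(regions)) return(character(0))
  if (!length(intersect(unique(regions$scaffold), unique(genes$scaffold))))
    stop("no scaffold names shared between regions and gene models; ",
         "check/rename scaffolds")
  rg <- GenomicRanges::GRanges(regions$scaffold,
                               IRanges::IRanges(regions$start + 1L,
                                                regions$end))
  gg <- GenomicRanges::GRanges(genes$scaffold,
                               IRanges::IRanges(genes$start + 1L,
                                                genes$end))
  hits <- GenomicRanges::findOverlaps(gg, rg, minoverlap = 1L)
  if (min_overlap_frac > 0) {
    ov <- GenomicRanges::pintersect(gg[S4Vectors::queryHits(hits)],
                                    rg[S4Vectors::subjectHits(hits)])
    frac <- GenomicRanges::width(ov) /
      GenomicRanges::width(gg[S4Vectors::queryHits(hits)])
    hits <- hits[frac >= min_overlap_frac]
  }
  sort(unique(genes$gene_id[S4Vectors::queryHits(hits)]))
}

#' Exact-combination overlap of contrast gene sets
#'
#' For two or more contrast gene sets (e.g. one per target-vs-control
#' scan), computes the membership matrix over the union of genes, the
#' count of genes falling in *exactly* each non-empty combination of
#' contrasts (the numbers an upset or Venn diagram displays), and the
#' full all-contrast intersection.
#'
#' @param sets named list of character vectors of gene IDs.
#' @return list: `membership` (logical data.frame genes x contrasts),
#'   `counts` (data.frame of `combo` label and `n` per exact
#'   combination), `intersection` (IDs in every set).
#' @export
overlap_sets <- function(sets) {
  if (length(sets) < 2) stop("need >= 2 gene sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("set", seq_along(sets))
  universe <- sort(unique(unlist(sets)))
  membership <- as.data.frame(
    lapply(sets, function(s) universe %in% s),
    row.names = universe, optional = TRUE)
  combo <- apply(membership, 1L, function(r)
    paste(names(sets)[r], collapse = "&"))
  counts <- as.data.frame(table(combo), stringsAsFactors = FALSE)
  names(counts) <- c("combo", "n")
  counts <- counts[order(-counts$n, counts$combo), , drop = FALSE]
  rownames(counts) <- NULL
  list(membership = membership, counts = counts,
       intersection = universe[rowSums(membership) == length(sets)])
}
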