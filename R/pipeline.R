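#' Default pipeline configuration
#'
#' Returns the nested list of stage parameters the pipeline runs with:
#' 40-kb windows with 20-kb increments and a joint top-5% threshold for
#' the sweep scan, the classic PLINK ROH parameters (100 SNPs / 500 kb /
#' density 50 / gap 1,000 kb, 50-SNP windows with at most 2 hets and 5
#' missing), MAF 0.05 with a 500-kb pair window for LD, and 1,000
#' bootstrap replicates for the NJ tree.  Override any entry through the
#' `config` argument of [run_pipeline()].
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1,
    filter = list(min_qual = 20, min_spacing = 5,
                  depth_low = 1 / 3, depth_high = 3),
    sweep = list(window = 40000, step = 20000, quantile = 0.05,
                 min_snps = 10, contrasts = NULL),
    roh = list(min_snps = 100, min_kb = 500, density_kb_per_snp = 50,
               max_gap_kb = 1000, window_snps = 50, window_max_het = 2,
               window_max_missing = 5, hit_threshold = 0.05),
    ld = list(max_window = 500000, min_maf = 0.05, bin_bp = 1000,
              max_pairs = 200000),
    structure = list(boot_reps = 1000, pca_k = 10),
    annotate = list(min_overlap_frac = 0)
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the whole scan pipeline from one configuration
#'
#' Orchestrates simulate (or load) -> filter -> sweep scan(s) -> ROH ->
#' LD -> structure -> annotate -> overlap, writing every stage's tables
#' under `outdir` together with a JSON manifest (parameters, seed, input
#' checksums, package version).  With a fixed seed the whole run is
#' byte-reproducible.
#'
#' The input is either a simulation block (`config$sim`, a [sim_config()]
#' or its argument list) or real data paths (`config$vcf` +
#' `config$popmap`, optionally `config$genes`) — exactly one of the two.
#' Contrasts are ordered `(target, control)` pairs; when unset, every
#' population is scanned against the first population as control.
#'
#' @param config nested list (see [default_config()]), or the path of a
#'   YAML file holding one.
#' @param outdir output directory (created; must be empty or absent).
#' @return (invisibly) a list with the key in-memory results: the
#'   filtered matrix, per-contrast window stats and candidate regions,
#'   ROH/F_ROH tables, LD curve, tree and PCA, and per-contrast gene
#'   sets.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- .merge_config(default_config(), config)
  has_sim <- !is.null(cfg$sim)
  has_vcf <- !is.null(cfg$vcf)
  if (has_sim == has_vcf)
    stop("config must contain exactly one of: a 'sim' block, or ",
         "'vcf' (+ 'popmap') input paths")
  if (has_vcf && is.null(cfg$popmap))
    stop("real-VCF mode needs a 'popmap' path")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  inputs <- character(0)
  if (has_sim) {
    sim_args <- cfg$sim
    if (!is.null(sim_args$scaffolds)) {
      sim_args$scaffolds <- unlist(sim_args$scaffolds)
    }
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    sc <- do.call(sim_config, sim_args[names(sim_args) %in%
                                         names(formals(sim_config))])
    sim <- simulate_populations(sc)
    gm <- sim$gm
    truth <- sim$truth
    for (sw in cfg$sim_sweeps %||% list()) {
      r <- do.call(inject_sweep, c(list(gm, truth), sw))
      gm <- r$gm; truth <- r$truth
    }
    for (ro in cfg$sim_roh %||% list()) {
      r <- do.call(inject_roh, c(list(gm, truth), ro))
      gm <- r$gm; truth <- r$truth
    }
    write_vcf(gm, file.path(outdir, "simulated.vcf"))
    write_popmap(gm$pops, file.path(outdir, "popmap.tsv"))
    write_truth(truth, file.path(outdir, "truth"))
  } else {
    gm <- read_vcf(cfg$vcf, cfg$popmap)
    inputs <- c(cfg$vcf, cfg$popmap)
  }

  fl <- filter_snps(gm, min_qual = cfg$filter$min_qual,
                    min_spacing = cfg$filter$min_spacing,
                    low_factor = cfg$filter$depth_low,
                    high_factor = cfg$filter$depth_high)
  gm <- fl$gm
  .write_tsv(fl$report, file.path(outdir, "filter_report.tsv"))
  write_vcf(gm, file.path(outdir, "filtered.vcf"))

  pops <- unique(unname(gm$pops))
  contrasts <- cfg$sweep$contrasts
  if (is.null(contrasts))
    contrasts <- lapply(pops[-1], function(p) c(p, pops[1]))
  scan_results <- list()
  regions <- list()
  for (ct in contrasts) {
    label <- paste0(ct[1], "_vs_", ct[2])
    st <- sweep_scan_windows(gm, target_pop = ct[1], control_pop = ct[2],
                             size = cfg$sweep$window, step = cfg$sweep$step,
                             min_snps = cfg$sweep$min_snps)
    st <- joint_outliers(st, q = cfg$sweep$quantile)
    rg <- merge_regions(st)
    scan_results[[label]] <- st
    regions[[label]] <- rg
    .write_tsv(st, file.path(outdir, paste0("windows_", label, ".tsv")))
    bed <- rg[c("scaffold", "start", "end")]
    utils::write.table(bed, file.path(outdir,
                                      paste0("regions_", label, ".bed")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    jsonlite::write_json(
      list(contrast = label,
           fst_threshold = attr(st, "fst_threshold"),
           ratio_threshold = attr(st, "ratio_threshold"),
           n_usable = sum(st$usable), n_outlier = sum(st$outlier),
           n_regions = nrow(rg)),
      file.path(outdir, paste0("thresholds_", label, ".json")),
      auto_unbox = TRUE, digits = NA)
  }

  params <- do.call(roh_params, cfg$roh)
  segs <- detect_roh(gm, params)
  froh <- f_roh(segs, scaffold_lengths(gm), samples = gm$samples)
  breed <- breed_summary(froh, gm$pops)
  .write_tsv(segs, file.path(outdir, "roh_segments.tsv"))
  .write_tsv(froh, file.path(outdir, "f_roh.tsv"))
  .write_tsv(breed, file.path(outdir, "roh_breed_summary.tsv"))

  set.seed(cfg$seed)
  ld <- lapply(pops, function(p)
    cbind(pop = p, ld_decay(gm, p, max_window = cfg$ld$max_window,
                            min_maf = cfg$ld$min_maf,
                            bin_bp = cfg$ld$bin_bp,
                            max_pairs = cfg$ld$max_pairs)))
  ld <- do.call(rbind, ld)
  .write_tsv(ld, file.path(outdir, "ld_decay.tsv"))

  dm <- allele_sharing_distance(gm)
  tree <- bootstrap_support(gm, nj_tree(dm), n_reps = cfg$structure$boot_reps,
                            seed = cfg$seed)
  ape::write.tree(tree, file.path(outdir, "nj_tree.nwk"))
  utils::write.table(round(dm, 10), file.path(outdir, "distance_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  pca <- genotype_pca(gm, k = min(cfg$structure$pca_k,
                                  length(gm$samples) - 1))
  .write_tsv(data.frame(sample = rownames(pca$coords), pca$coords,
                        check.names = FALSE),
             file.path(outdir, "pca_coords.tsv"))
  .write_tsv(data.frame(axis = seq_along(pca$eigenvalues),
                        eigenvalue = pca$eigenvalues,
                        varprop = pca$varprop),
             file.path(outdir, "pca_eigenvalues.tsv"))

  gene_sets <- NULL
  if (!is.null(cfg$genes)) {
    genes <- read_gene_models(cfg$genes)
    inputs <- c(inputs, cfg$genes)
    gene_sets <- lapply(regions, regions_to_genes, genes = genes,
                        min_overlap_frac = cfg$annotate$min_overlap_frac)
    for (label in names(gene_sets))
      writeLines(gene_sets[[label]],
                 file.path(outdir, paste0("genes_", label, ".txt")))
    if (length(gene_sets) >= 2) {
      ov <- overlap_sets(gene_sets)
      .write_tsv(cbind(gene_id = rownames(ov$membership), ov$membership),
                 file.path(outdir, "gene_membership.tsv"))
      jsonlite::write_json(
        list(counts = ov$counts, intersection = ov$intersection),
        file.path(outdir, "gene_overlap.json"), digits = NA)
    }
  }

  manifest <- list(
    package = "popgenscan",
    version = as.character(utils::packageVersion("popgenscan")),
    seed = cfg$seed,
    config = cfg,
    input_md5 = as.list(stats::setNames(tools::md5sum(inputs),
                                        basename(inputs))),
    output_md5 = local({
      f <- sort(list.files(outdir, full.names = TRUE,
                           pattern = "\\.(tsv|bed|nwk|json|vcf|txt)$"))
      as.list(stats::setNames(tools::md5sum(f), basename(f)))
    }))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(gm = gm, windows = scan_results, regions = regions,
                 roh = segs, f_roh = froh, breed_summary = breed,
                 ld = ld, tree = tree, pca = pca, gene_sets = gene_sets))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
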