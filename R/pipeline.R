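#' Assemble a pipeline run configuration
#'
#' Collects every tunable of the workflow with its mapping-design
#' default: depth bounds 25/250 on combined pool depth, 1 Mb windows
#' advanced by 100 kb, top-1-percent window threshold, top-5-percent
#' ideal-frequency selection, 2000 bp promoters, pool genotype cutoffs
#' 0.1/0.9, bulks of 30 at 30x. Either `vcf` (+ optional `gff`, `fasta`)
#' or a `simulate` block (a [sim_config()] plus [genetic_map()]) must be
#' supplied to [run_pipeline()].
#'
#' @param vcf,gff,fasta input paths (real-data mode).
#' @param map,simulate a [genetic_map()] and [sim_config()] (synthetic
#'   mode).
#' @param wt_sample,gt_sample VCF sample names of the two pools.
#' @param dp_min,dp_max,per_pool_depth depth-filter settings.
#' @param hom_ref_max,hom_alt_min,min_call_depth pool genotype cutoffs.
#' @param window_bp,step_bp scan window geometry.
#' @param region_quantile window-score quantile for region calling.
#' @param per_chrom_quantile threshold per chromosome instead of
#'   genome-wide.
#' @param region_classes classes eligible for candidate ranking; `NULL`
#'   disables the restriction (used when no annotation is available).
#' @param top_fraction fraction of eligible sites reported as candidates.
#' @param promoter_len promoter window for region classification, bp.
#' @param scan_stat statistic averaged in windows (default `"ed"`).
#' @param seed integer seed for the run.
#' @param out_dir artifact directory; `NULL` for none.
#' @return object of class `bsa_config` (a validated list).
#' @export
bsa_config <- function(vcf = NULL, gff = NULL, fasta = NULL,
                       map = NULL, simulate = NULL,
                       wt_sample = "WT_pool", gt_sample = "GT_pool",
                       dp_min = 25, dp_max = 250, per_pool_depth = FALSE,
                       hom_ref_max = 0.1, hom_alt_min = 0.9,
                       min_call_depth = 5,
                       window_bp = 1e6, step_bp = 1e5,
                       region_quantile = 0.99,
                       per_chrom_quantile = FALSE,
                       region_classes = c("exonic", "promoter"),
                       top_fraction = 0.05, promoter_len = 2000,
                       scan_stat = "ed", seed = 1, out_dir = NULL) {
  if (is.null(vcf) && is.null(simulate))
    stop("supply either 'vcf' or a 'simulate' block")
  if (!is.null(simulate)) {
    stopifnot(inherits(simulate, "sim_config"),
              inherits(map, "genetic_map"))
  }
  cfg <- list(vcf = vcf, gff = gff, fasta = fasta, map = map,
              simulate = simulate, wt_sample = wt_sample,
              gt_sample = gt_sample, dp_min = dp_min, dp_max = dp_max,
              per_pool_depth = per_pool_depth, hom_ref_max = hom_ref_max,
              hom_alt_min = hom_alt_min, min_call_depth = min_call_depth,
              window_bp = window_bp, step_bp = step_bp,
              region_quantile = region_quantile,
              per_chrom_quantile = per_chrom_quantile,
              region_classes = region_classes,
              top_fraction = top_fraction, promoter_len = promoter_len,
              scan_stat = scan_stat, seed = as.integer(seed),
              out_dir = out_dir)
  class(cfg) <- "bsa_config"
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full bulked-segregant mapping pipeline
#'
#' Executes, in order: input (VCF read or simulation), region
#' classification (when gene models are available), depth filter, shared
#' hom-alt filter, shared het filter, per-site statistics, sliding-window
#' scan, candidate-region calling, ideal-frequency ranking, and
#' consequence annotation of selected coding indels (when annotation and
#' genome sequence are available). Per-filter attrition is recorded, and
#' when `out_dir` is set all artifacts (site stats TSV, windows TSV+BED,
#' regions BED, candidates TSV, JSON summary with the resolved config)
#' are written there.
#'
#' @param config a [bsa_config()].
#' @return a report list: `config`, `attrition`, `stats`, `windows`,
#'   `regions`, `candidates`, `consequences`, `truth` (synthetic mode
#'   only), `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "bsa_config"))
  set.seed(config$seed)
  models <- NULL; genome <- NULL; truth <- NULL

  sites <- if (!is.null(config$simulate)) {
    sim <- .stage("simulate",
                  simulate_bsa(config$map, config$simulate))
    truth <- sim$truth
    sim$sites
  } else {
    .stage("read_vcf",
           read_pool_vcf(config$vcf, config$wt_sample, config$gt_sample))
  }
  n0 <- nrow(sites)
  if (!is.null(config$gff)) {
    models <- .stage("gene_models", read_gene_models(config$gff))
    sites <- .stage("classify_regions",
                    classify_regions(sites, models, config$promoter_len))
  }
  if (!is.null(config$fasta))
    genome <- .stage("genome", Biostrings::readDNAStringSet(config$fasta))

  gcall <- list(hom_ref_max = config$hom_ref_max,
                hom_alt_min = config$hom_alt_min,
                min_call_depth = config$min_call_depth)
  f1 <- .stage("filter_depth",
               filter_depth(sites, config$dp_min, config$dp_max,
                            config$per_pool_depth))
  f2 <- .stage("filter_shared_hom_alt",
               do.call(filter_shared_hom_alt, c(list(f1), gcall)))
  f3 <- .stage("filter_shared_het",
               do.call(filter_shared_het, c(list(f2), gcall)))
  attrition <- rbind(attr(f1, "filter_log"), attr(f2, "filter_log"),
                     attr(f3, "filter_log"))

  stats <- .stage("site_stats", site_stats(f3))
  chrom_lengths <- if (!is.null(config$map))
    setNames(config$map$chrom_lengths_bp, config$map$chrom_names)
  windows <- .stage("sliding_window",
                    sliding_window_mean(stats, config$window_bp,
                                        config$step_bp, config$scan_stat,
                                        chrom_lengths))
  regions <- .stage("call_regions",
                    call_candidate_regions(windows,
                                           config$region_quantile,
                                           config$per_chrom_quantile))
  classes <- config$region_classes
  if (is.null(models)) classes <- NULL  # no annotation: rank all sites
  candidates <- .stage("rank_candidates",
                       rank_candidate_sites(stats, regions, classes,
                                            config$top_fraction))

  consequences <- NULL
  if (!is.null(models) && !is.null(genome) && nrow(candidates)) {
    sel <- candidates[candidates$selected, , drop = FALSE]
    consequences <- .stage("annotate", lapply(seq_len(nrow(sel)),
      function(i) {
        v <- sel[i, ]
        hit <- Filter(function(m) m$chrom == v$chrom &&
                        !is.na(genomic_to_cds(m, v$pos)), models)
        if (!length(hit)) return(NULL)
        ann <- annotate_consequence(hit[[1]], genome, v)
        c(list(chrom = v$chrom, pos = v$pos), unclass(ann))
      }))
    consequences <- do.call(rbind, lapply(
      Filter(Negate(is.null), consequences), as.data.frame))
  }

  report <- list(config = config, n_input_sites = n0,
                 attrition = attrition, stats = stats,
                 windows = windows, regions = regions,
                 candidates = candidates, consequences = consequences,
                 truth = truth, files = character(0))
  if (!is.null(config$out_dir))
    report$files <- .write_artifacts(report, config$out_dir)
  report
}

.write_artifacts <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) {
    p <- file.path(out_dir, f)
    write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files <- c(tsv(report$stats, "site_stats.tsv"),
             tsv(report$windows, "windows.tsv"),
             tsv(report$attrition, "filter_report.tsv"),
             tsv(report$candidates, "candidates.tsv"))
  files <- c(files, write_bed(report$windows,
                              file.path(out_dir, "windows.bed")),
             write_bed(report$regions, file.path(out_dir, "regions.bed")))
  if (!is.null(report$consequences))
    files <- c(files, tsv(report$consequences, "consequences.tsv"))
  cfg <- report$config
  # echo only the analysis-defining settings; paths to the artifact
  # directory are environment-specific and excluded
  cfg$map <- NULL; cfg$out_dir <- NULL
  cfg$simulate <- unclass(cfg$simulate)
  summ <- list(config = cfg[!vapply(cfg, is.null, TRUE)],
               n_input_sites = report$n_input_sites,
               attrition = report$attrition,
               regions = report$regions,
               top_candidates = utils::head(
                 report$candidates[, intersect(
                   c("chrom", "pos", "ref", "alt", "ed_ideal", "rank",
                     "selected"), names(report$candidates))], 10))
  p <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summ, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(files, p)
}
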