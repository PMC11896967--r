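#' Define the genetic map of a simulated genome
#'
#' The map carries physical chromosome lengths and a per-chromosome
#' recombination rate in cM/Mb. Optional suppressed intervals scale the
#' local rate by a multiplier, emulating low-recombination (e.g.
#' pericentromeric) blocks that produce large linked regions around a
#' causal locus.
#'
#' @param chrom_names character vector of chromosome labels.
#' @param chrom_lengths_bp integer vector of chromosome lengths in bp.
#' @param recomb_rate cM per Mb, recycled across chromosomes. Default 1.
#' @param suppressed_intervals optional `data.frame` with columns
#'   `chrom`, `start`, `end`, `multiplier` (rate multiplier in the
#'   interval, e.g. 0 for full crossover suppression).
#' @return an object of class `genetic_map`.
#' @examples
#' gmap <- genetic_map(\"chr1\", 2e7)
#' @export
genetic_map <- function(chrom_names, chrom_lengths_bp, recomb_rate = 1,
                        suppressed_intervals = NULL) {
  chrom_names <- as.character(chrom_names)
  if (anyDuplicated(chrom_names)) stop("duplicated chromosome names")
  .check_num(chrom_lengths_bp, "chrom_lengths_bp", min = 1,
             len = length(chrom_names))
  .check_num(recomb_rate, "recomb_rate", min = 0)
  recomb_rate <- rep_len(recomb_rate, length(chrom_names))
  if (!is.null(suppressed_intervals)) {
    si <- as.data.frame(suppressed_intervals)
    stopifnot(all(c("chrom", "start", "end", "multiplier") %in% names(si)))
    if (!all(si$chrom %in% chrom_names))
      stop("suppressed interval on unknown chromosome")
    len <- setNames(chrom_lengths_bp, chrom_names)
    if (any(si$start < 1) || any(si$end > len[si$chrom]) ||
        any(si$start > si$end))
      stop("suppressed interval outside its chromosome")
    .check_num(si$multiplier, "multiplier", min = 0)
    suppressed_intervals <- si
  }
  structure(list(chrom_names = chrom_names,
                 chrom_lengths_bp = as.numeric(chrom_lengths_bp),
                 recomb_rate = recomb_rate,
                 suppressed_intervals = suppressed_intervals),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic_map: %d chromosome(s), %.1f Mb total\n",
              length(x$chrom_names), sum(x$chrom_lengths_bp) / 1e6))
  invisible(x)
}

# cumulative genetic position (cM) of physical positions on one chromosome;
# piecewise-linear: base rate everywhere, scaled inside suppressed intervals
genetic_position <- function(map, chrom, pos_bp) {
  i <- match(chrom, map$chrom_names)
  if (is.na(i)) stop(sprintf("unknown chromosome '%s'", chrom))
  rate <- map$recomb_rate[i]
  cm <- pos_bp
  si <- map$suppressed_intervals
  if (!is.null(si)) {
    si <- si[si$chrom == chrom, , drop = FALSE]
    for (k in seq_len(nrow(si))) {
      ov <- pmax(0, pmin(pos_bp, si$end[k]) - si$start[k] + 1)
      cm <- cm + ov * (si$multiplier[k] - 1)
    }
  }
  rate * cm / 1e6
}

#' Simulation settings for an F2 bulked-segregant experiment
#'
#' Defaults mirror the mapping design the package targets: two bulks of 30
#' F2 individuals each, pooled sequencing at ~30x per pool, and a small
#' per-read error rate. `n_f2` (the size of the F2 population the bulks
#' are drawn from) defaults to 240 so that the recessive class (expected
#' 1/4) comfortably exceeds the bulk size.
#'
#' @param n_f2 number of F2 individuals to simulate.
#' @param bulk_size individuals per phenotypic pool.
#' @param n_sites number of variant sites to place on the map.
#' @param causal_chrom,causal_pos_bp location of the recessive causal locus.
#' @param mean_depth expected pooled read depth per site per pool.
#' @param seq_error per-read probability of reading the other allele.
#' @param depth_law `"poisson"` (depth ~ Poisson(mean_depth)) or `"fixed"`.
#' @param seed integer seed governing the whole simulation.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_f2 = 240, bulk_size = 30, n_sites = 2000,
                       causal_chrom = "chr1", causal_pos_bp = 1e7,
                       mean_depth = 30, seq_error = 0.001,
                       depth_law = c("poisson", "fixed"), seed = 1) {
  depth_law <- match.arg(depth_law)
  stopifnot(.is_count(n_f2), .is_count(bulk_size), .is_count(n_sites))
  if (2 * bulk_size > n_f2)
    stop("2 * bulk_size must not exceed n_f2")
  .check_num(mean_depth, "mean_depth", min = 1)
  .check_num(seq_error, "seq_error", min = 0)
  if (seq_error >= 0.5) stop("seq_error must be < 0.5")
  structure(list(n_f2 = as.integer(n_f2), bulk_size = as.integer(bulk_size),
                 n_sites = as.integer(n_sites),
                 causal_chrom = as.character(causal_chrom),
                 causal_pos_bp = as.numeric(causal_pos_bp),
                 mean_depth = mean_depth, seq_error = seq_error,
                 depth_law = depth_law, seed = as.integer(seed)),
            class = "sim_config")
}

#' Place variant sites uniformly along a genetic map
#'
#' Sites are distributed over chromosomes proportionally to physical
#' length and uniformly within each chromosome; coordinates are unique and
#' sorted. When `causal` is given the causal coordinate is always among
#' the returned sites.
#'
#' @param map a [genetic_map()].
#' @param n_sites number of sites (>= 1).
#' @param seed optional seed; omit to draw from the current RNG stream.
#' @param causal optional `list(chrom=, pos=)` to force-include.
#' @return `data.frame` with columns `chrom`, `pos`, sorted.
#' @export
place_sites <- function(map, n_sites, seed = NULL, causal = NULL) {
  stopifnot(inherits(map, "genetic_map"), .is_count(n_sites), n_sites >= 1)
  .maybe_seed(seed)
  if (n_sites > sum(map$chrom_lengths_bp))
    stop("n_sites exceeds the number of available positions")
  if (!is.null(causal)) {
    ci <- match(causal$chrom, map$chrom_names)
    if (is.na(ci) || causal$pos < 1 || causal$pos > map$chrom_lengths_bp[ci])
      stop("causal position outside its chromosome")
  }
  lens <- map$chrom_lengths_bp
  chrom <- character(0); pos <- numeric(0)
  while (length(pos) < n_sites) {
    k <- n_sites - length(pos)
    ci <- sample.int(length(lens), k, replace = TRUE, prob = lens)
    p <- floor(runif(k) * lens[ci]) + 1
    chrom <- c(chrom, map$chrom_names[ci]); pos <- c(pos, p)
    keep <- !duplicated(paste(chrom, pos))
    chrom <- chrom[keep]; pos <- pos[keep]
  }
  if (!is.null(causal) &&
      !any(chrom == causal$chrom & pos == causal$pos)) {
    drop <- sample.int(length(pos), 1)
    chrom[drop] <- causal$chrom; pos[drop] <- causal$pos
  }
  o <- order(match(chrom, map$chrom_names), pos)
  data.frame(chrom = chrom[o], pos = pos[o], stringsAsFactors = FALSE)
}

#' Simulate an F2 population along placed sites
#'
#' Both parents are fully inbred and opposite-homozygous at every site, so
#' the F1 is heterozygous everywhere. Each F2 individual receives two
#' independent gametes; a gamete is a Markov walk along each chromosome
#' whose switch probability between adjacent sites is the Haldane
#' recombination fraction r = (1 - exp(-2 d / 100)) / 2 for map distance
#' d in cM. Phenotype is recessive: `GT` (glossy/mutant class) iff the
#' individual carries two mutant-parent alleles at the causal site.
#'
#' @param map a [genetic_map()].
#' @param sites `data.frame(chrom, pos)` as from [place_sites()].
#' @param causal `list(chrom=, pos=)`; must be one of `sites`.
#' @param n_f2 number of individuals.
#' @param seed optional seed.
#' @return an `f2_population`: list with `dosage` (n_f2 x n_sites integer
#'   matrix counting mutant-parent alleles), `phenotype` (`"WT"`/`"GT"`),
#'   `sites`, `causal_index`.
#' @export
simulate_f2 <- function(map, sites, causal, n_f2, seed = NULL) {
  stopifnot(inherits(map, "genetic_map"), .is_count(n_f2), n_f2 >= 1)
  .maybe_seed(seed)
  ci <- which(sites$chrom == causal$chrom & sites$pos == causal$pos)
  if (length(ci) != 1L) stop("causal site must be exactly one of 'sites'")
  n_gam <- 2L * n_f2
  S <- nrow(sites)
  gam <- matrix(0L, n_gam, S)
  for (chr in unique(sites$chrom)) {
    idx <- which(sites$chrom == chr)
    cm <- genetic_position(map, chr, sites$pos[idx])
    r <- 0.5 * (1 - exp(-2 * diff(cm) / 100))
    col <- rbinom(n_gam, 1L, 0.5)
    gam[, idx[1]] <- col
    for (j in seq_along(r)) {
      sw <- rbinom(n_gam, 1L, r[j])
      col <- as.integer(xor(col, sw))
      gam[, idx[j + 1]] <- col
    }
  }
  dosage <- gam[seq_len(n_f2), , drop = FALSE] +
    gam[n_f2 + seq_len(n_f2), , drop = FALSE]
  phenotype <- ifelse(dosage[, ci] == 2L, "GT", "WT")
  structure(list(dosage = dosage, phenotype = phenotype, sites = sites,
                 causal_index = ci),
            class = "f2_population")
}

#' @export
print.f2_population <- function(x, ...) {
  cat(sprintf("f2_population: %d individuals x %d sites (%.1f%% GT)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(x$phenotype == "GT")))
  invisible(x)
}

#' Select the two phenotypic bulks from an F2 population
#'
#' Samples `bulk_size` individuals without replacement from each
#' phenotype class.
#'
#' @param pop an `f2_population`.
#' @param bulk_size individuals per bulk.
#' @param seed optional seed.
#' @return list with integer index vectors `wt` and `gt`.
#' @export
form_bulks <- function(pop, bulk_size = 30, seed = NULL) {
  stopifnot(inherits(pop, "f2_population"), .is_count(bulk_size))
  .maybe_seed(seed)
  out <- lapply(c(WT = "WT", GT = "GT"), function(cls) {
    avail <- which(pop$phenotype == cls)
    if (length(avail) < bulk_size)
      stop(sprintf("insufficient %s individuals: have %d, need %d",
                   cls, length(avail), bulk_size))
    sort(sample(avail, bulk_size))
  })
  list(wt = out$WT, gt = out$GT)
}

#' Simulate pooled read counts for one bulk
#'
#' At each site the true pool alt frequency is the mean allele dosage of
#' the bulk members divided by 2. Depth is Poisson(`mean_depth`) or fixed;
#' alt reads are Binomial(depth, p(1-e) + (1-p)e) with symmetric per-read
#' error e.
#'
#' @param dosage integer matrix (bulk members x sites) of mutant-allele
#'   dosages in 0..2, e.g. `pop$dosage[bulks$wt, ]`.
#' @param mean_depth expected pooled depth per site.
#' @param seq_error per-read error probability.
#' @param depth_law `"poisson"` or `"fixed"`.
#' @param seed optional seed.
#' @return `data.frame(ref, alt)` of read counts, one row per site.
#' @export
simulate_pool_reads <- function(dosage, mean_depth = 30, seq_error = 0.001,
                                depth_law = c("poisson", "fixed"),
                                seed = NULL) {
  depth_law <- match.arg(depth_law)
  stopifnot(is.matrix(dosage), nrow(dosage) >= 1)
  .check_num(seq_error, "seq_error", min = 0)
  if (seq_error >= 0.5) stop("seq_error must be < 0.5")
  .maybe_seed(seed)
  S <- ncol(dosage)
  p <- colMeans(dosage) / 2
  depth <- if (depth_law == "poisson") rpois(S, mean_depth)
           else rep.int(as.integer(round(mean_depth)), S)
  p_read <- p * (1 - seq_error) + (1 - p) * seq_error
  alt <- rbinom(S, depth, p_read)
  data.frame(ref = depth - alt, alt = alt)
}

# pool genotype string for VCF emission, from the same fraction thresholds
# the filters use
.gt_string <- function(ref, alt, hom_ref_max = 0.1, hom_alt_min = 0.9,
                       min_call_depth = 5) {
  call <- call_pool_genotype(ref, alt, hom_ref_max, hom_alt_min,
                             min_call_depth)
  c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", nocall = "./.")[call$call]
}

#' Write simulated pool counts as a two-sample VCF
#'
#' Emits a minimal but valid VCF 4.2 with samples `WT_pool` and `GT_pool`
#' and `GT:AD:DP` FORMAT fields, plus (optionally) a tab-separated truth
#' record.
#'
#' @param sites `data.frame` with `chrom`, `pos` and optionally `ref`,
#'   `alt` allele columns (defaults A/T).
#' @param wt_counts,gt_counts `data.frame(ref, alt)` aligned to `sites`.
#' @param path output VCF path.
#' @param chrom_lengths optional named lengths for `##contig` headers.
#' @param truth optional truth record list (see [simulate_bsa()]); written
#'   as TSV to `truth_path`.
#' @param truth_path path for the truth TSV (default `<path>.truth.tsv`).
#' @return `path`, invisibly.
#' @export
emit_vcf <- function(sites, wt_counts, gt_counts, path,
                     chrom_lengths = NULL, truth = NULL,
                     truth_path = paste0(path, ".truth.tsv")) {
  stopifnot(nrow(sites) == nrow(wt_counts),
            nrow(sites) == nrow(gt_counts))
  ref <- sites$ref %||% rep("A", nrow(sites))
  alt <- sites$alt %||% rep("T", nrow(sites))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=bsamap-simulator")
  if (!is.null(chrom_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(chrom_lengths),
                          as.integer(chrom_lengths)))
  hdr <- c(hdr,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "WT_pool", "GT_pool", sep = "\t"))
  fmt <- function(cnt) sprintf("%s:%d,%d:%d",
                               .gt_string(cnt$ref, cnt$alt),
                               cnt$ref, cnt$alt, cnt$ref + cnt$alt)
  body <- paste(sites$chrom, format(sites$pos, scientific = FALSE,
                                    trim = TRUE),
                ".", ref, alt, ".", "PASS", ".", "GT:AD:DP",
                fmt(wt_counts), fmt(gt_counts), sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  if (!is.null(truth)) write_truth(truth, truth_path)
  invisible(path)
}

#' @rdname emit_vcf
#' @param x a truth record list.
#' @export
write_truth <- function(x, truth_path) {
  df <- data.frame(chrom = x$sites$chrom, pos = x$sites$pos,
                   p_wt = x$p_wt, p_gt = x$p_gt,
                   causal = seq_len(nrow(x$sites)) == x$causal_index)
  write.table(df, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(truth_path)
}

#' Simulate a complete F2 bulked-segregant sequencing experiment
#'
#' Runs the full generative model under one seed with a fixed stream
#' order (site placement, F2 genotypes, bulk membership, WT-pool reads,
#' GT-pool reads): place sites, simulate the F2, select the bulks, sample
#' pooled reads for both bulks, and assign alleles. The causal variant is
#' emitted as a 2-bp "AA" insertion, matching the kind of frameshift
#' lesion a recessive glossy-wax locus carries; all other sites are SNVs.
#'
#' @param map a [genetic_map()].
#' @param config a [sim_config()].
#' @param vcf_path optional; when given, the dataset is also written with
#'   [emit_vcf()].
#' @return list with `sites` (chrom, pos, ref, alt, wt_ref, wt_alt,
#'   gt_ref, gt_alt), `pop`, `bulks`, `truth`, `config`.
#' @export
simulate_bsa <- function(map, config, vcf_path = NULL) {
  stopifnot(inherits(map, "genetic_map"), inherits(config, "sim_config"))
  set.seed(config$seed)
  causal <- list(chrom = config$causal_chrom, pos = config$causal_pos_bp)
  sites <- place_sites(map, config$n_sites, causal = causal)
  pop <- simulate_f2(map, sites, causal, config$n_f2)
  bulks <- form_bulks(pop, config$bulk_size)
  wt_counts <- simulate_pool_reads(pop$dosage[bulks$wt, , drop = FALSE],
                                   config$mean_depth, config$seq_error,
                                   config$depth_law)
  gt_counts <- simulate_pool_reads(pop$dosage[bulks$gt, , drop = FALSE],
                                   config$mean_depth, config$seq_error,
                                   config$depth_law)
  ci <- pop$causal_index
  base <- c("A", "C", "G", "T")
  ref <- sample(base, nrow(sites), replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(base, b), 1), "")
  alt[ci] <- paste0(ref[ci], "AA")  # causal lesion: AA insertion
  tab <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    ref = ref, alt = unname(alt),
                    wt_ref = wt_counts$ref, wt_alt = wt_counts$alt,
                    gt_ref = gt_counts$ref, gt_alt = gt_counts$alt,
                    stringsAsFactors = FALSE)
  truth <- list(sites = sites, causal_index = ci,
                causal_chrom = causal$chrom, causal_pos = causal$pos,
                p_wt = colMeans(pop$dosage[bulks$wt, , drop = FALSE]) / 2,
                p_gt = colMeans(pop$dosage[bulks$gt, , drop = FALSE]) / 2,
                phenotypes = pop$phenotype)
  if (!is.null(vcf_path))
    emit_vcf(tab, wt_counts, gt_counts, vcf_path,
             chrom_lengths = setNames(map$chrom_lengths_bp,
                                      map$chrom_names),
             truth = truth)
  list(sites = tab, pop = pop, bulks = bulks, truth = truth,
       config = config)
}
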