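#' Read a two-pool VCF into the pipeline site table
#'
#' Parses a VCF with per-pool allelic depths (`AD`) for a wild-type and a
#' mutant bulk into one row per biallelic site. Multi-allelic records are
#' dropped (default) or split per alternate allele; records with missing
#' `AD` are dropped. Counts of dropped records are attached as the
#' `"dropped"` attribute.
#'
#' @param path VCF path (plain or gzipped).
#' @param wt_sample,gt_sample sample column names for the two pools.
#' @param multiallelic `"drop"` (default) or `"split"`.
#' @return `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `wt_ref`, `wt_alt`, `gt_ref`, `gt_alt` and attribute `dropped`
#'   (named counts `multiallelic`, `missing_ad`).
#' @export
read_pool_vcf <- function(path, wt_sample = "WT_pool",
                          gt_sample = "GT_pool",
                          multiallelic = c("drop", "split")) {
  multiallelic <- match.arg(multiallelic)
  vcf <- VariantAnnotation::readVcf(path)
  if (nrow(vcf) == 0L) stop("read_vcf: no variant records in ", path)
  sm <- colnames(vcf)
  missing_sm <- setdiff(c(wt_sample, gt_sample), sm)
  if (length(missing_sm))
    stop("read_vcf: sample column(s) absent from VCF: ",
         paste(missing_sm, collapse = ", "))
  if (!"AD" %in% rownames(VariantAnnotation::geno(
        VariantAnnotation::header(vcf))))
    stop("read_vcf: VCF has no AD FORMAT field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  n_alt <- S4Vectors::elementNROWS(rr$ALT)
  ad <- VariantAnnotation::geno(vcf)$AD

  parse_ad <- function(x, nalt, id) {
    if (length(x) == 0L || all(is.na(x))) return(NULL)   # missing
    if (length(x) != nalt + 1L)
      stop("read_vcf: malformed AD at record ", id,
           " (length ", length(x), ", expected ", nalt + 1L, ")")
    x
  }
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  ids <- paste0(chrom, ":", pos)

  rows <- vector("list", nrow(vcf))
  n_multi <- 0L; n_missing <- 0L
  for (i in seq_len(nrow(vcf))) {
    nalt <- n_alt[i]
    alt_i <- as.character(rr$ALT[[i]])
    wt <- parse_ad(ad[[i, wt_sample]], nalt, ids[i])
    gt <- parse_ad(ad[[i, gt_sample]], nalt, ids[i])
    if (is.null(wt) || is.null(gt) || anyNA(wt) || anyNA(gt)) {
      n_missing <- n_missing + 1L
      next
    }
    if (nalt != 1L) {
      if (multiallelic == "drop") { n_multi <- n_multi + 1L; next }
      rows[[i]] <- data.frame(chrom = chrom[i], pos = pos[i], ref = ref[i],
                              alt = alt_i,
                              wt_ref = wt[1], wt_alt = wt[-1],
                              gt_ref = gt[1], gt_alt = gt[-1],
                              stringsAsFactors = FALSE)
      next
    }
    rows[[i]] <- data.frame(chrom = chrom[i], pos = pos[i], ref = ref[i],
                            alt = alt_i, wt_ref = wt[1], wt_alt = wt[2],
                            gt_ref = gt[1], gt_alt = gt[2],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out) || nrow(out) == 0L)
    stop("read_vcf: no usable biallelic records in ", path)
  rownames(out) <- NULL
  attr(out, "dropped") <- c(multiallelic = n_multi, missing_ad = n_missing)
  out
}

#' Construct a gene model
#'
#' A minimal gene model: sorted, non-overlapping CDS intervals (1-based
#' inclusive, genomic coordinates) on one strand. The start codon sits at
#' the 5'-most CDS base on the coding strand.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome.
#' @param strand `"+"` or `"-"`.
#' @param cds_start,cds_end parallel vectors of CDS interval bounds.
#' @return object of class `gene_model` with fields `gene_id`, `chrom`,
#'   `strand`, `cds` (data.frame), `start_codon`, `cds_length`.
#' @export
gene_model <- function(gene_id, chrom, strand, cds_start, cds_end) {
  stopifnot(strand %in% c("+", "-"), length(cds_start) == length(cds_end),
            all(cds_start <= cds_end))
  o <- order(cds_start)
  cds <- data.frame(start = cds_start[o], end = cds_end[o])
  if (nrow(cds) > 1 && any(cds$start[-1] <= cds$end[-nrow(cds)]))
    stop("CDS intervals overlap in gene ", gene_id)
  structure(list(gene_id = as.character(gene_id),
                 chrom = as.character(chrom), strand = strand, cds = cds,
                 start_codon = if (strand == "+") cds$start[1]
                               else cds$end[nrow(cds)],
                 cds_length = sum(cds$end - cds$start + 1)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s:%s) %d CDS segment(s), %d nt\n",
              x$gene_id, x$chrom, x$strand, nrow(x$cds), x$cds_length))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Collects `CDS` features grouped by their `Parent` (falling back to
#' `ID`/`gene_id`) into [gene_model()] objects.
#'
#' @param path GFF3 path (plain or gzipped).
#' @return named list of `gene_model`s.
#' @export
read_gene_models <- function(path) {
  g <- rtracklayer::import(path)
  cds <- g[g$type == "CDS"]
  if (length(cds) == 0L) stop("no CDS features in ", path)
  pr <- S4Vectors::mcols(cds)$Parent
  parent <- if (!is.null(pr))
    vapply(as.list(pr), function(v)
      if (length(v)) as.character(v)[1] else NA_character_, "")
  else as.character(S4Vectors::mcols(cds)$ID)
  if (is.null(parent) || all(is.na(parent)))
    stop("CDS features carry neither Parent nor ID attributes")
  if (anyNA(parent))
    parent[is.na(parent)] <- as.character(
      S4Vectors::mcols(cds)$ID)[is.na(parent)]
  split_idx <- split(seq_along(cds), parent)
  models <- lapply(names(split_idx), function(id) {
    sub <- cds[split_idx[[id]]]
    gene_model(id,
               as.character(GenomicRanges::seqnames(sub))[1],
               as.character(GenomicRanges::strand(sub))[1],
               GenomicRanges::start(sub), GenomicRanges::end(sub))
  })
  names(models) <- names(split_idx)
  models
}

# strand-aware promoter window: promoter_len bases immediately 5' of the
# start codon (start codon itself excluded)
.promoter_range <- function(model, promoter_len) {
  if (model$strand == "+")
    c(max(1, model$start_codon - promoter_len), model$start_codon - 1)
  else
    c(model$start_codon + 1, model$start_codon + promoter_len)
}

#' Classify variant sites by functional region
#'
#' Assigns each site one of `exonic` (inside any CDS interval),
#' `promoter` (within `promoter_len` bases 5' of a start codon,
#' strand-aware), `intronic` (inside a gene body but neither of the
#' above) or `intergenic`, with precedence in that order.
#'
#' @param sites site table with `chrom`, `pos`.
#' @param models list of [gene_model()]s.
#' @param promoter_len promoter window size in bp (default 2000).
#' @return `sites` with a `region_class` column filled.
#' @export
classify_regions <- function(sites, models, promoter_len = 2000) {
  known <- unique(sites$chrom)
  keep <- vapply(models, function(m) m$chrom %in% known, TRUE)
  if (any(!keep)) {
    warning("skipping ", sum(!keep), " gene model(s) on chromosomes ",
            "absent from the site table")
    models <- models[keep]
  }
  mk <- function(chrom, start, end)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(pmax(1, start), end))
  exon <- promo <- body <- GenomicRanges::GRanges()
  if (length(models)) {
    models <- unname(models)  # named args break S4 c() dispatch
    exon <- do.call(c, lapply(models, function(m)
      mk(m$chrom, m$cds$start, m$cds$end)))
    promo <- do.call(c, lapply(models, function(m) {
      pr <- .promoter_range(m, promoter_len)
      mk(m$chrom, pr[1], pr[2])
    }))
    body <- do.call(c, lapply(models, function(m)
      mk(m$chrom, min(m$cds$start), max(m$cds$end))))
  }
  q <- GenomicRanges::GRanges(sites$chrom,
                              IRanges::IRanges(sites$pos, sites$pos))
  cls <- rep("intergenic", nrow(sites))
  hit <- function(subject) IRanges::overlapsAny(q, subject)
  if (length(body)) cls[hit(body)] <- "intronic"
  if (length(promo)) cls[hit(promo)] <- "promoter"
  if (length(exon)) cls[hit(exon)] <- "exonic"
  sites$region_class <- cls
  sites
}
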