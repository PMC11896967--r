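# Independent oracles and fixture builders shared across test files.
# Oracles deliberately use different formulations from the package code.

# 2x2 likelihood-ratio G via the entropy decomposition
# G = 2 * (sum o ln o - sum r ln r - sum c ln c + N ln N)
g_oracle <- function(wt_ref, wt_alt, gt_ref, gt_alt) {
  o <- c(wt_ref, wt_alt, gt_ref, gt_alt)
  n <- sum(o)
  r <- c(wt_ref + wt_alt, gt_ref + gt_alt)
  cl <- c(wt_ref + gt_ref, wt_alt + gt_alt)
  xlx <- function(x) sum(ifelse(x > 0, x * log(x), 0))
  2 * (xlx(o) - xlx(r) - xlx(cl) + xlx(n))
}

# brute-force per-window rescan: enumerate every window start and average
# the sites falling inside it by direct comparison
window_oracle <- function(df, window_bp, step_bp, stat = "ed") {
  out <- NULL
  for (chr in unique(df$chrom)) {
    sub <- df[df$chrom == chr, ]
    k_max <- floor((max(sub$pos) - 1) / step_bp)
    for (k in 0:k_max) {
      lo <- k * step_bp + 1
      hi <- k * step_bp + window_bp
      inside <- sub$pos >= lo & sub$pos <= hi
      if (!any(inside)) next
      out <- rbind(out, data.frame(chrom = chr, start = lo, end = hi,
                                   n_sites = sum(inside),
                                   mean_stat = mean(sub[[stat]][inside])))
    }
  }
  rownames(out) <- NULL
  out
}

# write a raw two-pool VCF without going through emit_vcf()
write_toy_vcf <- function(path, body_lines,
                          samples = c("WT_pool", "GT_pool")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body_lines), path)
  path
}

# toy single-gene fixture: plus-strand gene whose CDS is ATGGATTTAAAGTGA
# placed at chr1:101-115; returns model, genome and FASTA/GFF writers
toy_gene_fixture <- function(dir = withr::local_tempdir()) {
  flank5 <- paste(rep("C", 100), collapse = "")
  cds <- "ATGGATTTAAAGTGA"
  flank3 <- paste(rep("G", 85), collapse = "")
  chr_seq <- paste0(flank5, cds, flank3)
  genome <- Biostrings::DNAStringSet(chr_seq)
  names(genome) <- "chr1"
  model <- gene_model("g1", "chr1", "+", 101, 115)
  fasta <- file.path(dir, "toy.fa")
  Biostrings::writeXStringSet(genome, fasta)
  gff <- file.path(dir, "toy.gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttoy\tgene\t101\t115\t.\t+\t.\tID=g1",
               "chr1\ttoy\tmRNA\t101\t115\t.\t+\t.\tID=m1;Parent=g1",
               "chr1\ttoy\tCDS\t101\t115\t.\t+\t0\tID=c1;Parent=m1"),
             gff)
  list(model = model, genome = genome, fasta = fasta, gff = gff,
       cds = cds)
}

# minimal f2_population stand-in with chosen phenotype labels
fake_population <- function(phenotypes) {
  n <- length(phenotypes)
  structure(list(dosage = matrix(0L, n, 1),
                 phenotype = phenotypes,
                 sites = data.frame(chrom = "chr1", pos = 1),
                 causal_index = 1L),
            class = "f2_population")
}

# simulated null site table: both pools draw reads at p = 1/2, fixed depth
null_sites <- function(n, depth = 30, start_pos = 1, spacing = 1000,
                       chrom = "chr1") {
  data.frame(chrom = chrom,
             pos = start_pos + spacing * (seq_len(n) - 1),
             ref = "A", alt = "T",
             wt_ref = depth - (a1 <- rbinom(n, depth, 0.5)), wt_alt = a1,
             gt_ref = depth - (a2 <- rbinom(n, depth, 0.5)), gt_alt = a2,
             stringsAsFactors = FALSE)
}
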