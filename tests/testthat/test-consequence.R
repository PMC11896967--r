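# plus-strand toy gene: CDS ATGGATTTAAAGTGA at chr1:101-115 (toy_gene_fixture)

test_that("variant splicing matches the worked insertion example", {
  fx <- toy_gene_fixture(withr::local_tempdir())
  cds <- extract_cds_sequence(fx$model, fx$genome)
  expect_equal(as.character(cds), "ATGGATTTAAAGTGA")

  # "AA" inserted after spliced CDS position 6: VCF pos 106, T -> TAA
  mut <- apply_variant_to_cds(fx$model, cds,
                              list(pos = 106, ref = "T", alt = "TAA"))
  expect_equal(mut, "ATGGATAATTAAAGTGA")

  expect_error(apply_variant_to_cds(fx$model, cds,
                                    list(pos = 106, ref = "G", alt = "GAA")),
               "mismatch")
  expect_error(apply_variant_to_cds(fx$model, cds,
                                    list(pos = 50, ref = "C", alt = "CA")),
               "CDS")
})

test_that("minus-strand genes reverse-complement the alleles before splicing", {
  # same coding sequence on the minus strand: genomic 201-215 carries
  # revcomp(ATGGATTTAAAGTGA) = TCACTTTAAATCCAT
  chr <- paste0(paste(rep("C", 200), collapse = ""), "TCACTTTAAATCCAT")
  genome <- Biostrings::DNAStringSet(chr); names(genome) <- "chr1"
  m <- gene_model("gm", "chr1", "-", 201, 215)
  cds <- extract_cds_sequence(m, genome)
  expect_equal(as.character(cds), "ATGGATTTAAAGTGA")
  # genomic A -> ATT at pos 209 is the same coding-strand AA insertion
  mut <- apply_variant_to_cds(m, cds, list(pos = 209, ref = "A",
                                           alt = "ATT"))
  expect_equal(mut, "ATGGATAATTAAAGTGA")
})

test_that("translation truncates at the first stop with hand-checked results", {
  t1 <- translate_and_truncate("ATGGATTTAAAGTGA")
  expect_equal(t1$protein, "MDLK")
  expect_equal(t1$protein_len, 4)
  expect_true(t1$stop_found)
  expect_equal(t1$stop_codon_index, 5)

  t2 <- translate_and_truncate("ATGGATAATTAAAGTGA")
  expect_equal(t2$protein, "MDN")
  expect_equal(t2$protein_len, 3)
  expect_equal(t2$stop_codon_index, 4)

  # ATG TAA: one residue (M) precedes the stop at codon 2
  t3 <- translate_and_truncate("ATGTAA")
  expect_equal(t3$protein_len, 1)
  expect_equal(t3$protein, "M")
  expect_equal(t3$stop_codon_index, 2)

  t4 <- translate_and_truncate("ATGAAAG")   # no stop, trailing base ignored
  expect_equal(t4$protein_len, 2)
  expect_false(t4$stop_found)
  expect_true(is.na(t4$stop_codon_index))

  expect_error(translate_and_truncate("ATGNNN"), "non-ACGT")
  expect_warning(translate_and_truncate("TTGAAA"), "ATG")
})

test_that("annotate_consequence composes extraction, splice and translation", {
  fx <- toy_gene_fixture(withr::local_tempdir())
  fs <- annotate_consequence(fx$model, fx$genome,
                             list(pos = 106, ref = "T", alt = "TAA"))
  expect_equal(fs$effect, "frameshift")
  expect_equal(fs$original_protein_len, 4)
  expect_equal(fs$mutant_protein_len, 3)
  expect_true(fs$stop_found)
  expect_equal(fs$stop_codon_index, 4)

  # 3-base insertion at a codon boundary: in-frame, +1 residue, no new stop
  inf <- annotate_consequence(fx$model, fx$genome,
                              list(pos = 106, ref = "T", alt = "TAAA"))
  expect_equal(inf$effect, "inframe_indel")
  expect_equal(inf$mutant_protein_len, inf$original_protein_len + 1)
  expect_equal(inf$stop_codon_index, 6)

  up <- annotate_consequence(fx$model, fx$genome,
                             list(pos = 50, ref = "C", alt = "CA"))
  expect_equal(up$effect, "noncoding")

  sub <- annotate_consequence(fx$model, fx$genome,
                              list(pos = 104, ref = "G", alt = "C"))
  expect_equal(sub$effect, "substitution")
})

test_that("in-frame codon-boundary indels shift length by len/3 absent new stops", {
  set.seed(401)
  safe <- setdiff(names(Biostrings::GENETIC_CODE),
                  names(which(Biostrings::GENETIC_CODE == "*")))
  # avoid codons that could seed a stop across junctions: exhaustive
  # checking below relies on no-stop inserts at exact codon boundaries,
  # where no new junction codons arise
  for (i in 1:20) {
    n_cod <- sample(5:30, 1)
    cds <- paste0("ATG", paste(sample(safe, n_cod, replace = TRUE),
                               collapse = ""), "TAA")
    orig <- translate_and_truncate(cds)
    expect_equal(orig$protein_len, n_cod + 1)
    k <- sample(1:3, 1)                      # insert k codons
    at <- 3 * sample.int(n_cod, 1)           # codon boundary (after ATG+...)
    ins <- paste(sample(safe, k, replace = TRUE), collapse = "")
    mut <- paste0(substr(cds, 1, at), ins,
                  substr(cds, at + 1, nchar(cds)))
    expect_equal(translate_and_truncate(mut)$protein_len,
                 orig$protein_len + k)
    # deletion of one whole codon (never the ATG)
    del_at <- 3 * sample.int(n_cod, 1)
    mutd <- paste0(substr(cds, 1, del_at),
                   substr(cds, del_at + 4, nchar(cds)))
    expect_equal(translate_and_truncate(mutd)$protein_len,
                 orig$protein_len - 1)
  }
})

test_that("the simulated causal AA insertion annotates as a frameshift", {
  gmap <- genetic_map("chr1", 1e6)
  cfg <- sim_config(n_f2 = 240, n_sites = 50, causal_chrom = "chr1",
                    causal_pos_bp = 5e5, seed = 5)
  sim <- simulate_bsa(gmap, cfg)
  causal <- sim$sites[sim$sites$pos == 5e5, ]
  expect_equal(nchar(causal$alt) - nchar(causal$ref), 2)

  # synthetic gene whose CDS spans the causal position, in frame 493..516
  set.seed(6)
  chr <- paste(sample(c("A", "C", "G", "T"), 6e5, replace = TRUE),
               collapse = "")
  cds_start <- 5e5 - 7   # causal falls mid-CDS
  body <- sample(c("A", "C", "G", "T"), 24, replace = TRUE)
  body[1:3] <- c("A", "T", "G")
  body[5e5 - cds_start + 1] <- causal$ref  # reference allele must match
  substr(chr, cds_start, cds_start + 23) <- paste(body, collapse = "")
  genome <- Biostrings::DNAStringSet(chr); names(genome) <- "chr1"
  model <- gene_model("sim_gene", "chr1", "+", cds_start, cds_start + 23)
  ann <- suppressWarnings(
    annotate_consequence(model, genome, causal))
  expect_equal(ann$effect, "frameshift")
})
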