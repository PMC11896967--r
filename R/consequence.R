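#' Extract the spliced coding sequence of a gene model
#'
#' Concatenates the CDS intervals in genomic order and reverse-complements
#' the result for minus-strand genes, yielding the coding-strand sequence.
#'
#' @param model a [gene_model()].
#' @param genome a named `Biostrings::DNAStringSet` (names = chromosomes)
#'   or a FASTA path.
#' @return a `Biostrings::DNAString` of the coding sequence.
#' @export
extract_cds_sequence <- function(model, genome) {
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  nm <- sub("\\s.*", "", names(genome))  # FASTA headers may carry comments
  i <- match(model$chrom, nm)
  if (is.na(i)) stop("chromosome ", model$chrom, " absent from genome")
  chrom_seq <- genome[[i]]
  pieces <- mapply(function(s, e) as.character(chrom_seq[s:e]),
                   model$cds$start, model$cds$end)
  cds <- Biostrings::DNAString(paste(pieces, collapse = ""))
  if (model$strand == "-") cds <- Biostrings::reverseComplement(cds)
  cds
}

# spliced CDS coordinate (1-based on the coding strand) of a genomic
# position; NA when the position is not inside any CDS interval
genomic_to_cds <- function(model, pos) {
  cds <- model$cds
  hit <- which(pos >= cds$start & pos <= cds$end)
  if (length(hit) != 1L) return(NA_integer_)
  before <- if (hit > 1) sum(cds$end[seq_len(hit - 1)] -
                             cds$start[seq_len(hit - 1)] + 1) else 0L
  plus_coord <- before + (pos - cds$start[hit]) + 1L
  if (model$strand == "+") as.integer(plus_coord)
  else as.integer(model$cds_length - plus_coord + 1L)
}

#' Apply a variant to a spliced coding sequence
#'
#' Replaces the reference allele with the alternate at the variant's
#' spliced CDS coordinate, VCF-anchored (the first REF base is shared
#' context for indels). For minus-strand genes both alleles are
#' reverse-complemented and the anchor flips to the allele's 3'-most
#' genomic base. The reference allele must match the coding sequence at
#' the target position; a mismatch is a hard error, as it indicates a
#' coordinate bug rather than biology.
#'
#' @param model a [gene_model()].
#' @param cds_sequence coding sequence (string or `DNAString`) from
#'   [extract_cds_sequence()].
#' @param variant list or one-row data.frame with `pos`, `ref`, `alt`
#'   (genomic, plus-strand alleles).
#' @return the mutant coding-strand sequence as a character string.
#' @export
apply_variant_to_cds <- function(model, cds_sequence, variant) {
  cds <- as.character(cds_sequence)
  ref <- as.character(variant$ref); alt <- as.character(variant$alt)
  if (model$strand == "+") {
    cpos <- genomic_to_cds(model, variant$pos)
    c_ref <- ref; c_alt <- alt
  } else {
    # anchor at the genomic end of REF, which is 5'-most on the coding strand
    cpos <- genomic_to_cds(model, variant$pos + nchar(ref) - 1L)
    rc <- function(s) as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    c_ref <- rc(ref); c_alt <- rc(alt)
  }
  if (is.na(cpos)) stop("variant does not overlap a CDS interval")
  found <- substr(cds, cpos, cpos + nchar(c_ref) - 1L)
  if (!identical(found, c_ref))
    stop(sprintf("reference mismatch at CDS position %d: model has '%s', variant claims '%s'",
                 cpos, found, c_ref))
  paste0(substr(cds, 1L, cpos - 1L), c_alt,
         substr(cds, cpos + nchar(c_ref), nchar(cds)))
}

#' Translate a coding sequence and locate the first stop
#'
#' Standard nuclear genetic code, codon by codon. The protein length
#' counts residues strictly before the first stop codon; when no stop is
#' present the length is `floor(n/3)` and `stop_found` is `FALSE`. A
#' sequence not starting with ATG triggers a warning, not an error.
#'
#' @param coding_sequence string or `DNAString` (A/C/G/T only).
#' @return list: `protein`, `protein_len`, `stop_found`,
#'   `stop_codon_index` (1-based codon number of the first stop, `NA` if
#'   none).
#' @export
translate_and_truncate <- function(coding_sequence) {
  s <- toupper(as.character(coding_sequence))
  if (grepl("[^ACGT]", s)) stop("non-ACGT character in coding sequence")
  if (substr(s, 1, 3) != "ATG")
    warning("coding sequence does not start with ATG")
  n_cod <- nchar(s) %/% 3L
  codons <- substring(s, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stop_at <- which(aa == "*")[1]
  if (is.na(stop_at)) {
    list(protein = paste(aa, collapse = ""), protein_len = n_cod,
         stop_found = FALSE, stop_codon_index = NA_integer_)
  } else {
    list(protein = paste(head(aa, stop_at - 1L), collapse = ""),
         protein_len = stop_at - 1L, stop_found = TRUE,
         stop_codon_index = as.integer(stop_at))
  }
}

#' Annotate the coding consequence of a variant
#'
#' Composes CDS extraction, variant application and translation. Effect
#' classes: `frameshift` (indel length not a multiple of 3 inside CDS),
#' `inframe_indel`, `substitution` (equal-length alleles), `noncoding`
#' (variant outside every CDS interval of the model).
#'
#' @param model a [gene_model()].
#' @param genome named `DNAStringSet` or FASTA path.
#' @param variant list/one-row data.frame with `pos`, `ref`, `alt`.
#' @return object of class `coding_consequence`: list with `effect`,
#'   `original_protein_len`, `mutant_protein_len`, `stop_found`,
#'   `stop_codon_index`, `gene_id`.
#' @export
annotate_consequence <- function(model, genome, variant) {
  anchor_in <- !is.na(genomic_to_cds(model, variant$pos))
  end_in <- !is.na(genomic_to_cds(model,
                                  variant$pos + nchar(variant$ref) - 1L))
  if (!anchor_in || !end_in) {
    return(structure(list(effect = "noncoding",
                          original_protein_len = NA_integer_,
                          mutant_protein_len = NA_integer_,
                          stop_found = NA, stop_codon_index = NA_integer_,
                          gene_id = model$gene_id),
                     class = "coding_consequence"))
  }
  cds <- extract_cds_sequence(model, genome)
  orig <- translate_and_truncate(cds)
  mut_seq <- apply_variant_to_cds(model, cds, variant)
  mut <- suppressWarnings(translate_and_truncate(mut_seq))
  dlen <- nchar(as.character(variant$alt)) -
          nchar(as.character(variant$ref))
  effect <- if (dlen == 0L) "substitution"
            else if (dlen %% 3L != 0L) "frameshift"
            else "inframe_indel"
  structure(list(effect = effect,
                 original_protein_len = orig$protein_len,
                 mutant_protein_len = mut$protein_len,
                 stop_found = mut$stop_found,
                 stop_codon_index = mut$stop_codon_index,
                 gene_id = model$gene_id),
            class = "coding_consequence")
}

#' @export
print.coding_consequence <- function(x, ...) {
  cat(sprintf("coding_consequence [%s] %s: protein %s -> %s aa%s\n",
              x$gene_id, x$effect,
              x$original_protein_len, x$mutant_protein_len,
              if (isTRUE(x$stop_found))
                sprintf(" (stop at codon %d)", x$stop_codon_index)
              else ""))
  invisible(x)
}
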