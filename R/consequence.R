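#' Annotate the coding consequence of a small variant
#'
#' Translates the reference and mutated codon with the standard nuclear
#' genetic code (the yeast nuclear code) and emits a protein-change string in
#' the conventional style: reference amino acid, 1-based codon index, then
#' the alternate amino acid or \code{"*"} for a gained stop (e.g.
#' \code{"W142*"}, \code{"T357S"}); synonymous changes are reported as
#' \code{"silent"}. Indels whose length change is not a multiple of 3 are
#' frameshifts; in-frame indels are reported as structural.
#'
#' @param pos 1-based genomic position of the variant (first affected base).
#' @param ref,alt alleles on the forward genomic strand.
#' @param cds_seq CDS sequence in coding (sense) orientation; length must be
#'   a multiple of 3.
#' @param cds_range length-2 vector, 1-based inclusive genomic span of the
#'   CDS.
#' @param strand \code{"+"} or \code{"-"}: genomic strand carrying the CDS.
#' @param gene optional gene name carried into the result.
#' @return a \code{consequence_call}: list with \code{gene},
#'   \code{protein_change} and \code{class} (one of nonsense, missense,
#'   silent, frameshift, structural, noncoding).
#' @export
annotate_consequence <- function(pos, ref, alt, cds_seq, cds_range,
                                 strand = c("+", "-"), gene = NA_character_) {
  strand <- match.arg(strand)
  cds_seq <- toupper(as.character(cds_seq))
  n <- nchar(cds_seq)
  if (n %% 3 != 0) stop_taqmap("CDS length %d is not a multiple of 3", n)
  if (cds_range[2] - cds_range[1] + 1 != n)
    stop_taqmap("cds_range span does not match CDS length")
  out <- function(change, class)
    structure(list(gene = gene, protein_change = change, class = class),
              class = "consequence_call")

  if (pos < cds_range[1] || pos > cds_range[2])
    return(out(NA_character_, "noncoding"))

  if (nchar(ref) != nchar(alt)) {
    shift <- abs(nchar(ref) - nchar(alt)) %% 3
    return(out(if (shift) "frameshift" else "inframe indel",
               if (shift) "frameshift" else "structural"))
  }
  if (nchar(ref) != 1L)
    return(out("multi-nucleotide substitution", "structural"))

  if (strand == "+") {
    cpos <- pos - cds_range[1] + 1L
    c_ref <- ref; c_alt <- alt
  } else {
    cpos <- cds_range[2] - pos + 1L
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    c_ref <- comp[[toupper(ref)]]; c_alt <- comp[[toupper(alt)]]
  }
  codon_i <- (cpos - 1L) %/% 3L + 1L
  in_codon <- (cpos - 1L) %% 3L + 1L
  codon <- substr(cds_seq, (codon_i - 1L) * 3L + 1L, codon_i * 3L)
  if (substr(codon, in_codon, in_codon) != toupper(c_ref))
    stop_taqmap("reference allele '%s' does not match CDS at codon %d",
                ref, codon_i)
  alt_codon <- codon
  substr(alt_codon, in_codon, in_codon) <- toupper(c_alt)
  gc <- Biostrings::GENETIC_CODE
  ref_aa <- gc[[codon]]; alt_aa <- gc[[alt_codon]]
  if (identical(ref_aa, alt_aa)) return(out("silent", "silent"))
  if (alt_aa == "*")
    return(out(sprintf("%s%d*", ref_aa, codon_i), "nonsense"))
  out(sprintf("%s%d%s", ref_aa, codon_i, alt_aa), "missense")
}

#' @export
print.consequence_call <- function(x, ...) {
  cat(sprintf("consequence_call: %s %s (%s)\n",
              if (is.na(x$gene)) "" else x$gene,
              x$protein_change %||% "", x$class))
  invisible(x)
}
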