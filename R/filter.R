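FILTER_FIELDS <- c("DP", "MQM", "QUAL", "AO", "SAF", "SAR", "RPR", "RPL", "AF")

#' Construct a small-variant record
#'
#' One called small variant with the annotation fields the filter chain
#' consumes (Freebayes-style INFO tags). Internal consistency is enforced:
#' forward plus reverse alt observations must equal \code{AO}, as must
#' right- plus left-placed reads, and \code{DP >= AO >= 0}.
#'
#' @param chrom,pos,ref,alt site and alleles (\code{pos} 1-based, VCF
#'   convention).
#' @param DP total depth. @param MQM mean mapping quality of alt reads.
#' @param QUAL call quality. @param AO alt observation count.
#' @param SAF,SAR alt observations on forward / reverse strand.
#' @param RPR,RPL reads placing the alt right / left.
#' @param AF alt allele frequency in \code{[0, 1]}.
#' @return a one-row data.frame of class \code{variant_record}.
#' @export
variant_record <- function(chrom = "chr", pos = 1L, ref = "A", alt = "C",
                           DP, MQM, QUAL, AO, SAF, SAR, RPR, RPL, AF) {
  if (SAF + SAR != AO) stop_taqmap("SAF + SAR must equal AO")
  if (RPR + RPL != AO) stop_taqmap("RPR + RPL must equal AO")
  if (DP < AO || AO < 0) stop_taqmap("DP >= AO >= 0 violated")
  structure(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                       DP = DP, MQM = MQM, QUAL = QUAL, AO = AO, SAF = SAF,
                       SAR = SAR, RPR = RPR, RPL = RPL, AF = AF,
                       stringsAsFactors = FALSE),
            class = c("variant_record", "data.frame"))
}

#' Apply the nine-clause small-variant filter chain
#'
#' The filter used to retain only reliable homozygous small variants:
#' \code{DP > 15 & MQM > 30 & QUAL/AO > 10 & SAF > 0 & SAR > 0 & RPR > 1 &
#' RPL > 1 & QUAL > 100 & AF = 1}. All inequalities are strict, exactly as
#' written; the equality on \code{AF} absorbs text-float round-trip with a
#' 1e-9 tolerance. \code{QUAL/AO} fails by definition when \code{AO = 0}
#' (no division is attempted).
#'
#' @param record a \code{variant_record}, a one-row data.frame or a named
#'   list carrying the nine fields.
#' @return list with \code{pass} (logical) and \code{failed_clauses}
#'   (character vector of every violated clause, empty when passing).
#' @export
apply_filter_chain <- function(record) {
  record <- as.list(record)
  missing_f <- setdiff(FILTER_FIELDS, names(record))
  if (length(missing_f))
    stop_taqmap("malformed variant record: missing field(s) %s",
                paste(missing_f, collapse = ", "))
  v <- lapply(record[FILTER_FIELDS], as.numeric)
  if (anyNA(v))
    stop_taqmap("malformed variant record: NA in field(s) %s",
                paste(FILTER_FIELDS[is.na(unlist(v))], collapse = ", "))
  failed <- character(0)
  if (!(v$DP > 15)) failed <- c(failed, "DP")
  if (!(v$MQM > 30)) failed <- c(failed, "MQM")
  if (!(v$AO > 0 && v$QUAL / v$AO > 10)) failed <- c(failed, "QUAL/AO")
  if (!(v$SAF > 0)) failed <- c(failed, "SAF")
  if (!(v$SAR > 0)) failed <- c(failed, "SAR")
  if (!(v$RPR > 1)) failed <- c(failed, "RPR")
  if (!(v$RPL > 1)) failed <- c(failed, "RPL")
  if (!(v$QUAL > 100)) failed <- c(failed, "QUAL")
  if (!(abs(v$AF - 1) <= 1e-9)) failed <- c(failed, "AF")
  list(pass = length(failed) == 0, failed_clauses = failed)
}

#' Filter a table of variant records
#'
#' Vectorized wrapper over \code{\link{apply_filter_chain}}: the filter is a
#' pure per-record predicate, so record order never affects results.
#'
#' @param variants data.frame with the nine filter fields (plus any others).
#' @return the input with added columns \code{pass} (logical) and
#'   \code{failed_clauses} (comma-separated clause names, \code{""} when
#'   passing).
#' @export
filter_variants <- function(variants) {
  stopifnot(is.data.frame(variants))
  res <- lapply(seq_len(nrow(variants)),
                function(i) apply_filter_chain(variants[i, , drop = FALSE]))
  variants$pass <- vapply(res, `[[`, TRUE, "pass")
  variants$failed_clauses <- vapply(res, function(r)
    paste(r$failed_clauses, collapse = ","), "")
  variants
}

#' Read Freebayes-style variant records from a VCF
#'
#' Uses \pkg{VariantAnnotation} to parse VCF 4.x and extracts the nine
#' filter fields. Multi-allelic records are decomposed to one row per
#' alternate allele, taking the per-allele (Number=A) INFO entries.
#'
#' @param path VCF file.
#' @return data.frame with chrom, pos, ref, alt and the nine fields.
#' @export
read_variant_table <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop_taqmap("package 'VariantAnnotation' is required to read VCF")
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- lengths(alt)
  idx <- rep(seq_along(n_alt), n_alt)       # expand multi-allelic rows
  k <- sequence(n_alt)                      # which alt within the record

  pick <- function(field, per_allele) {
    x <- info[[field]]
    if (is.null(x)) stop_taqmap("VCF lacks INFO field %s", field)
    if (per_allele && methods::is(x, "List")) {
      as.numeric(unlist(x)[cumsum(c(0, n_alt))[idx] + k])
    } else if (methods::is(x, "List")) {
      as.numeric(vapply(x, `[`, numeric(1), 1L))[idx]
    } else as.numeric(x)[idx]
  }
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[idx],
    pos = BiocGenerics::start(rr)[idx],
    ref = as.character(VariantAnnotation::ref(vcf))[idx],
    alt = as.character(unlist(alt)),
    DP = pick("DP", FALSE),
    MQM = pick("MQM", TRUE),
    QUAL = as.numeric(VariantAnnotation::qual(vcf))[idx],
    AO = pick("AO", TRUE), SAF = pick("SAF", TRUE), SAR = pick("SAR", TRUE),
    RPR = pick("RPR", TRUE), RPL = pick("RPL", TRUE), AF = pick("AF", TRUE),
    stringsAsFactors = FALSE)
}

#' Write a clause-level filter audit table
#'
#' @param variants output of \code{\link{filter_variants}}.
#' @param path TSV destination.
#' @return the path, invisibly.
#' @export
write_filter_audit <- function(variants, path) {
  stopifnot(all(c("pass", "failed_clauses") %in% names(variants)))
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
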