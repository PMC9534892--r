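#' Write genome haplotypes as FASTA plus a marker table
#'
#' Emits \code{parent_A.fasta}, \code{parent_B.fasta} and
#' \code{markers.tsv} (chrom, pos0, allele_A, allele_B) into \code{dir}.
#' FASTA round-trips losslessly through
#' \code{\link[Biostrings]{readDNAStringSet}}.
#'
#' @param genome a \code{hybrid_genome}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(genome$seq_A, file.path(dir, "parent_A.fasta"))
  seq_B <- Biostrings::DNAStringSet(lapply(
    genome$chromosomes$name, function(ch) haplotype_seq(genome, ch, "B")))
  names(seq_B) <- genome$chromosomes$name
  Biostrings::writeXStringSet(seq_B, file.path(dir, "parent_B.fasta"))
  mk <- do.call(rbind, lapply(names(genome$markers), function(ch) {
    m <- genome$markers[[ch]]
    if (nrow(m) == 0) return(NULL)
    data.frame(chrom = ch, pos0 = m$pos, allele_A = m$a_A, allele_B = m$a_B,
               stringsAsFactors = FALSE)
  }))
  write.table(mk %||% data.frame(), file.path(dir, "markers.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write an evidence bundle as TSV tracks
#'
#' Files: \code{marker_depths.tsv} (chrom, pos, allele_A, allele_B,
#' depth_A, depth_B), \code{window_coverage.tsv} (chrom, start, end, total,
#' depth_A, depth_B), \code{junctions.tsv}, and \code{meta.json}
#' (chromosomes, mean depth, window size). \code{\link{read_evidence}}
#' restores the bundle losslessly for the fields the caller uses.
#'
#' @param evidence an \code{evidence_bundle}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_evidence <- function(evidence, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  md <- do.call(rbind, lapply(names(evidence$marker_depths), function(ch) {
    m <- evidence$marker_depths[[ch]]
    if (nrow(m) == 0) return(NULL)
    data.frame(chrom = ch, pos = m$pos, allele_A = m$a_A, allele_B = m$a_B,
               depth_A = m$depth_A, depth_B = m$depth_B,
               stringsAsFactors = FALSE)
  }))
  write.table(md, file.path(dir, "marker_depths.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  wc <- do.call(rbind, lapply(names(evidence$window_coverage), function(ch)
    cbind(chrom = ch, evidence$window_coverage[[ch]],
          stringsAsFactors = FALSE)))
  write.table(wc, file.path(dir, "window_coverage.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(evidence$junctions, file.path(dir, "junctions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(chromosomes = evidence$chromosomes,
                            mean_depth = evidence$mean_depth,
                            window_size = evidence$window_size),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read an evidence bundle written by \code{\link{write_evidence}}
#'
#' @param dir directory holding the TSV tracks.
#' @return an \code{evidence_bundle}.
#' @export
read_evidence <- function(dir) {
  need <- c("marker_depths.tsv", "window_coverage.tsv", "junctions.tsv",
            "meta.json")
  missing_f <- need[!file.exists(file.path(dir, need))]
  if (length(missing_f))
    stop_taqmap("evidence directory %s lacks %s", dir,
                paste(missing_f, collapse = ", "))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  chroms <- as.data.frame(meta$chromosomes, stringsAsFactors = FALSE)
  md <- read.table(file.path(dir, "marker_depths.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
  wc <- read.table(file.path(dir, "window_coverage.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
  jn <- read.table(file.path(dir, "junctions.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(chrom1 = "character",
                                  chrom2 = "character"))
  marker_depths <- lapply(chroms$name, function(ch) {
    m <- md[md$chrom == ch, ]
    data.frame(pos = m$pos, a_A = m$allele_A, a_B = m$allele_B,
               depth_A = m$depth_A, depth_B = m$depth_B,
               stringsAsFactors = FALSE)
  })
  names(marker_depths) <- chroms$name
  window_coverage <- lapply(chroms$name, function(ch) {
    w <- wc[wc$chrom == ch, c("start", "end", "total", "depth_A", "depth_B")]
    rownames(w) <- NULL
    w
  })
  names(window_coverage) <- chroms$name
  structure(list(marker_depths = marker_depths,
                 window_coverage = window_coverage, junctions = jn,
                 chromosomes = chroms, mean_depth = meta$mean_depth,
                 window_size = meta$window_size),
            class = "evidence_bundle")
}

#' Write called or truth events as BED and TSV
#'
#' BED intervals are already 0-based half-open internally, so coordinates
#' pass through unchanged; the TSV carries the full event table including
#' class, homolog and support columns.
#'
#' @param events event data.frame (kind, chrom, start, end, ...).
#' @param prefix file prefix; writes \code{<prefix>.bed} and
#'   \code{<prefix>.tsv}.
#' @return the prefix, invisibly.
#' @export
write_events <- function(events, prefix) {
  bed <- data.frame(chrom = events$chrom,
                    start = as.integer(round(events$start)),
                    end = as.integer(round(pmax(events$end,
                                                events$start + 1))),
                    name = paste0(events$kind, "_", events$homolog))
  write.table(bed, paste0(prefix, ".bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(events, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}

#' Gene annotation for the simulated genome
#'
#' Places the three causal genes of the phenotype model at their loci and
#' scatters non-causal decoy genes uniformly over the genome (2 kb each),
#' for use by \code{\link{candidate_genes}} and GFF3 export.
#'
#' @param genome a \code{hybrid_genome}.
#' @param model a \code{phenotype_model}.
#' @param n_decoys decoy gene count (default 30).
#' @param seed integer seed.
#' @return data.frame: gene, chrom, start, end, causal.
#' @export
model_gene_annotation <- function(genome, model, n_decoys = 30, seed = 99) {
  str <- model$structural; act <- model$activator; rep_ <- model$repressor
  causal <- data.frame(
    gene = c(str$gene %||% "STRUCT", act$gene %||% "ACT",
             rep_$gene %||% "REP"),
    chrom = c(str$chrom, act$chrom, rep_$chrom),
    start = c(str$interval[1], act$pos - 1000, rep_$pos - 1000),
    end = c(str$interval[2], act$pos + 1000, rep_$pos + 1000),
    causal = TRUE, stringsAsFactors = FALSE)
  dec <- with_seed(seed, {
    ci <- sample.int(nrow(genome$chromosomes), n_decoys, replace = TRUE,
                     prob = genome$chromosomes$length)
    st <- floor(runif(n_decoys) *
                  (genome$chromosomes$length[ci] - 2000))
    data.frame(gene = sprintf("GENE%03d", seq_len(n_decoys)),
               chrom = genome$chromosomes$name[ci], start = st,
               end = st + 2000, causal = FALSE, stringsAsFactors = FALSE)
  })
  rbind(causal, dec)
}

#' Write gene annotation as GFF3
#'
#' Converts the internal 0-based half-open intervals to the 1-based
#' inclusive GFF3 convention via \pkg{rtracklayer}.
#'
#' @param annotation data.frame (gene, chrom, start, end).
#' @param path GFF3 destination.
#' @return the path, invisibly.
#' @export
write_genes_gff3 <- function(annotation, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop_taqmap("package 'rtracklayer' is required to write GFF3")
  gr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(start = annotation$start + 1L, end = annotation$end),
    type = "gene", gene = annotation$gene, ID = annotation$gene)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene annotation from GFF3
#'
#' @param path GFF3 file.
#' @return data.frame: gene, chrom, start (0-based), end (half-open).
#' @export
read_genes_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop_taqmap("package 'rtracklayer' is required to read GFF3")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  nm <- S4Vectors::mcols(gr)
  gene <- nm$gene %||% nm$ID %||% nm$Name
  data.frame(gene = as.character(gene),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             stringsAsFactors = FALSE)
}
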