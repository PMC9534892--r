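#' Build a hybrid diploid genome with a dense SNV marker map
#'
#' Simulates the fusion of two divergent haploid parents (called parent A and
#' parent B, mirroring an SK1-like x S288C-like yeast fusion) into a diploid
#' whose two haplotypes are identical except at single-nucleotide marker
#' positions. The marker density defaults to 0.7\% of positions, the divergence
#' reported for such inter-strain fusions. A recognition-site index of the
#' endonuclease motif (default \code{"TCGA"}, the TaqI site) is built over the
#' parent-A haplotype; simulated double-strand breaks are anchored at these
#' sites.
#'
#' @param chrom_lengths named integer vector of chromosome lengths in bp
#'   (names become chromosome names; unnamed lengths get \code{chrI},
#'   \code{chrII}, ...). Each length must be at least 10 kb.
#' @param snv_density fraction of positions carrying an inter-parent SNV
#'   (in \code{[0, 0.05)}; default 0.007).
#' @param motif recognition motif of the break-inducing endonuclease.
#' @param seed integer seed; the same seed yields a byte-identical genome.
#' @return An object of class \code{hybrid_genome}: a list with
#'   \code{chromosomes} (data.frame of name and length), \code{seq_A}
#'   (\code{\link[Biostrings]{DNAStringSet}} of the parent-A haplotype),
#'   \code{markers} (per chromosome, data.frame of 0-based \code{pos},
#'   \code{a_A}, \code{a_B}), \code{sites} (per chromosome, sorted 0-based
#'   motif positions), \code{motif} and \code{snv_density}.
#' @examples
#' g <- build_hybrid_genome(c(chrI = 50000), snv_density = 0.007, seed = 1)
#' nrow(g$markers$chrI)
#' @export
build_hybrid_genome <- function(chrom_lengths, snv_density = 0.007,
                                motif = "TCGA", seed) {
  if (missing(seed)) stop_taqmap("a 'seed' is required")
  if (length(chrom_lengths) < 1L) stop_taqmap("at least one chromosome needed")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    names(chrom_lengths) <- paste0("chr", as.roman(seq_along(chrom_lengths)))
  chrom_lengths <- round(chrom_lengths)
  bad <- names(chrom_lengths)[chrom_lengths <= 0]
  if (length(bad))
    stop_taqmap("zero-length chromosome rejected: %s", paste(bad, collapse = ", "))
  short <- names(chrom_lengths)[chrom_lengths < 10000]
  if (length(short))
    stop_taqmap("chromosomes shorter than 10 kb are not supported: %s",
                paste(short, collapse = ", "))
  assert_scalar_number(snv_density, "snv_density", 0, 0.05, strict_upper = TRUE)

  bases <- c("A", "C", "G", "T")
  res <- with_seed(seed, {
    seqs <- character(length(chrom_lengths))
    markers <- vector("list", length(chrom_lengths))
    for (i in seq_along(chrom_lengths)) {
      L <- chrom_lengths[[i]]
      hap <- sample(bases, L, replace = TRUE)
      n_mark <- rbinom(1L, L, snv_density)
      pos <- sort(sample.int(L, n_mark)) - 1L   # 0-based
      a_A <- hap[pos + 1L]
      # parent-B allele drawn uniformly among the three non-A bases
      shift <- sample.int(3L, n_mark, replace = TRUE)
      a_B <- bases[(match(a_A, bases) - 1L + shift) %% 4L + 1L]
      seqs[i] <- paste(hap, collapse = "")
      markers[[i]] <- data.frame(pos = pos, a_A = a_A, a_B = a_B,
                                 stringsAsFactors = FALSE)
    }
    list(seqs = seqs, markers = markers)
  })

  seq_A <- Biostrings::DNAStringSet(res$seqs)
  names(seq_A) <- names(chrom_lengths)
  names(res$markers) <- names(chrom_lengths)

  sites <- lapply(seq_along(seq_A), function(i) {
    Biostrings::start(Biostrings::matchPattern(motif, seq_A[[i]])) - 1L
  })
  names(sites) <- names(chrom_lengths)

  structure(list(
    chromosomes = data.frame(name = names(chrom_lengths),
                             length = as.integer(chrom_lengths),
                             stringsAsFactors = FALSE),
    seq_A = seq_A,
    markers = res$markers,
    sites = sites,
    motif = motif,
    snv_density = snv_density,
    seed = as.integer(seed)
  ), class = "hybrid_genome")
}

#' Extract one parental haplotype sequence
#'
#' The two haplotypes are identical except at marker positions, so the
#' parent-B sequence is reconstructed from the parent-A sequence by
#' substituting the parent-B alleles.
#'
#' @param genome a \code{hybrid_genome}.
#' @param chrom chromosome name.
#' @param parent \code{"A"} or \code{"B"}.
#' @return a \code{\link[Biostrings]{DNAString}}.
#' @export
haplotype_seq <- function(genome, chrom, parent = c("A", "B")) {
  parent <- match.arg(parent)
  stopifnot(inherits(genome, "hybrid_genome"))
  if (!chrom %in% names(genome$seq_A))
    stop_taqmap("unknown chromosome '%s'", chrom)
  s <- genome$seq_A[[chrom]]
  if (parent == "A") return(s)
  mk <- genome$markers[[chrom]]
  if (nrow(mk) == 0) return(s)
  Biostrings::replaceLetterAt(s, mk$pos + 1L, mk$a_B)
}

#' @export
print.hybrid_genome <- function(x, ...) {
  cat(sprintf("hybrid_genome: %d chromosome(s), %s bp total\n",
              nrow(x$chromosomes),
              format(sum(x$chromosomes$length), big.mark = ",")))
  nm <- sum(vapply(x$markers, nrow, 0L))
  cat(sprintf("  markers: %d (density %.4f; requested %.4f)\n",
              nm, nm / sum(x$chromosomes$length), x$snv_density))
  cat(sprintf("  recognition motif %s: %d sites\n", x$motif,
              sum(lengths(x$sites))))
  invisible(x)
}
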