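#' Three-locus flocculation phenotype model
#'
#' Encodes the regulatory architecture underlying flocculation in the hybrid:
#' a structural adhesin locus whose tandem-repeat length sets adhesion
#' strength (longer repeat arrays flocculate more), a transcriptional
#' activator that is strictly required for adhesin expression, and a
#' repressor whose functional dosage attenuates expression. Each locus
#' carries one allele per parent; alleles differ in repeat count or in
#' functionality (natural nonsense polymorphisms).
#'
#' The score is the product
#' \deqn{f(r_{max}) \times [\text{activator present}] \times \rho^{d}}
#' where \eqn{f} maps the maximum repeat count present to \code{[0,1]}
#' (linear between \code{repeat_zero} and \code{repeat_full}, clamped),
#' the indicator is 1 iff at least one functional activator allele is
#' present, and \eqn{\rho \in (0,1]} is the per-copy repressor penalty with
#' \eqn{d} the functional repressor dosage.
#'
#' @param structural list(chrom, interval = c(start,end), repeat_units =
#'   c(A=,B=), gene).
#' @param activator list(chrom, pos, functional = c(A=,B=), gene).
#' @param repressor list(chrom, pos, functional = c(A=,B=), gene).
#' @param repeat_zero repeat count at/below which adhesion vanishes.
#' @param repeat_full repeat count giving full adhesion.
#' @param repressor_penalty multiplicative penalty per functional repressor
#'   copy, in (0, 1].
#' @return an object of class \code{phenotype_model}.
#' @export
phenotype_model <- function(structural, activator, repressor,
                            repeat_zero = 8, repeat_full = 18,
                            repressor_penalty = 0.4) {
  stopifnot(repeat_full > repeat_zero,
            repressor_penalty > 0, repressor_penalty <= 1)
  structure(list(structural = structural, activator = activator,
                 repressor = repressor, repeat_zero = repeat_zero,
                 repeat_full = repeat_full,
                 repressor_penalty = repressor_penalty),
            class = "phenotype_model")
}

#' Default phenotype model mirroring the hybrid strain's architecture
#'
#' Places the structural locus in the subtelomeric region of the first
#' chromosome (parent A carries the short 10-unit array, parent B the long
#' 18-unit array), the activator mid-arm on the second chromosome
#' (functional in parent A only), and the repressor on the third chromosome
#' (functional in parent B only). With the default penalty the ancestral
#' hybrid scores 0.4: heterozygous at all three loci, one functional
#' activator and one functional repressor, and the long structural array
#' present.
#'
#' @param genome a \code{hybrid_genome} with at least 3 chromosomes.
#' @return a \code{phenotype_model}.
#' @export
default_phenotype_model <- function(genome) {
  ch <- genome$chromosomes
  if (nrow(ch) < 3)
    stop_taqmap("default phenotype model needs >= 3 chromosomes")
  L1 <- ch$length[1]; L2 <- ch$length[2]; L3 <- ch$length[3]
  phenotype_model(
    structural = list(chrom = ch$name[1],
                      interval = c(L1 - 30000, L1 - 25000),
                      repeat_units = c(A = 10, B = 18), gene = "FLO1"),
    activator = list(chrom = ch$name[2], pos = round(L2 * 0.5),
                     functional = c(A = TRUE, B = FALSE), gene = "FLO8"),
    repressor = list(chrom = ch$name[3], pos = round(L3 * 0.4),
                     functional = c(A = FALSE, B = TRUE), gene = "SFL1")
  )
}

# parental origin of a homolog at a position: state of the nearest marker
state_at <- function(gt, chrom, homolog, pos) {
  mk <- gt$genome$markers[[chrom]]$pos
  st <- gt$states[[chrom]][[homolog]]
  if (length(mk) == 0) return(homolog)  # no markers: ancestral origin
  st[which.min(abs(mk - pos))]
}

#' Flocculation phenotype score of a genotype
#'
#' Resolves the three causal loci of \code{model} against the genotype's
#' marker states and copy-number tracks and evaluates the multiplicative
#' score. The score is always in \code{[0, 1]}, zero whenever no functional
#' activator allele is present, non-decreasing in the maximum repeat count
#' present and non-increasing in functional repressor dosage.
#'
#' @param gt a \code{taq_genotype}.
#' @param model a \code{phenotype_model}.
#' @return numeric score in \code{[0, 1]}.
#' @export
phenotype_score <- function(gt, model) {
  stopifnot(inherits(gt, "taq_genotype"), inherits(model, "phenotype_model"))
  str <- model$structural; act <- model$activator; rep_ <- model$repressor
  str_pos <- mean(str$interval)

  max_rep <- 0; act_present <- FALSE; rep_dose <- 0
  for (h in c("A", "B")) {
    c_str <- min(cn_at(gt$cn[[str$chrom]][[h]],
                       c(str$interval[1], str_pos, str$interval[2] - 1)))
    if (c_str >= 1) {
      p <- state_at(gt, str$chrom, h, str_pos)
      max_rep <- max(max_rep, str$repeat_units[[p]])
    }
    c_act <- cn_at(gt$cn[[act$chrom]][[h]], act$pos)
    if (c_act >= 1) {
      p <- state_at(gt, act$chrom, h, act$pos)
      if (isTRUE(act$functional[[p]])) act_present <- TRUE
    }
    c_rep <- cn_at(gt$cn[[rep_$chrom]][[h]], rep_$pos)
    if (c_rep >= 1) {
      p <- state_at(gt, rep_$chrom, h, rep_$pos)
      if (isTRUE(rep_$functional[[p]])) rep_dose <- rep_dose + c_rep
    }
  }
  f <- (max_rep - model$repeat_zero) / (model$repeat_full - model$repeat_zero)
  f <- min(max(f, 0), 1)
  f * as.numeric(act_present) * model$repressor_penalty ^ rep_dose
}
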