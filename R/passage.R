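#' Default gene panel for the spontaneous-mutagenesis arm
#'
#' Small panel of loci at which de novo mutations can alter the flocculation
#' phenotype of a haploid strain carrying a functional activator and a long
#' adhesin repeat array, plus phenotypically neutral bystander genes. Roles:
#' \code{structural} (the adhesin itself), \code{activator} (activator
#' complex members; loss abolishes adhesin expression),
#' \code{repressor_inhibitor} (genes restraining the repressor; loss
#' increases effective repression), \code{neutral}.
#'
#' @return data.frame with columns \code{gene}, \code{role}, \code{weight}
#'   (relative mutational target size), \code{cds_codons}.
#' @export
default_gene_panel <- function() {
  data.frame(
    gene = c("FLO1", "FLO8", "MSS11", "MFG1", "TPK2", "MRN1",
             "GUA1", "VPS13", "HOG1", "KAP123", "CWC25"),
    role = c("structural", "activator", "activator", "activator",
             "repressor_inhibitor", "repressor_inhibitor",
             "neutral", "neutral", "neutral", "neutral", "neutral"),
    weight = c(2, 1, 1.2, 0.9, 0.8, 1.1, 1, 3, 0.9, 1.1, 0.6),
    cds_codons = c(1537, 799, 758, 462, 380, 548, 525, 3144, 435, 1113, 179),
    stringsAsFactors = FALSE)
}

SENSE_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
})

# one random coding SNV in `gene`: returns (substitution, consequence, damaging)
draw_point_mutation <- function(gene, cds_codons) {
  codon_i <- sample.int(cds_codons, 1L)
  ref_codon <- sample(SENSE_CODONS, 1L)
  pos <- sample.int(3L, 1L)
  bases <- c("A", "C", "G", "T")
  ref_b <- substr(ref_codon, pos, pos)
  alt_b <- sample(setdiff(bases, ref_b), 1L)
  alt_codon <- ref_codon
  substr(alt_codon, pos, pos) <- alt_b
  gc <- Biostrings::GENETIC_CODE
  ref_aa <- gc[[ref_codon]]; alt_aa <- gc[[alt_codon]]
  if (alt_aa == "*") {
    list(substitution = sprintf("%s%d*", ref_aa, codon_i),
         consequence = "nonsense", damaging = TRUE)
  } else if (alt_aa == ref_aa) {
    list(substitution = "silent", consequence = "silent", damaging = FALSE)
  } else {
    list(substitution = sprintf("%s%d%s", ref_aa, codon_i, alt_aa),
         consequence = "missense",
         damaging = runif(1) < 0.3)  # a minority of missense changes disable
  }
}

haploid_score <- function(ind, repeat_zero = 8, repeat_full = 18,
                          repressor_penalty = 0.4) {
  f <- (ind$repeat_units - repeat_zero) / (repeat_full - repeat_zero)
  f <- min(max(f, 0), 1)
  f * as.numeric(ind$activator_ok) *
    repressor_penalty ^ ind$repressor_activity
}

#' Serial-passage evolution of a flocculent haploid under planktonic selection
#'
#' Emulates repeated daily transfers of the planktonic fraction: each cycle
#' every individual may acquire spontaneous point mutations (drawn over a
#' gene panel and classified as nonsense / missense / silent) and rare
#' structural events at the adhesin locus (intra-array repeat contraction or
#' subtelomeric deletion); survival into the next cycle is then weighted by
#' \code{1 - sel_strength * score}, so strongly flocculent cells settle out
#' and are lost. The ancestor is a haploid with a functional activator and
#' the long (18-unit) repeat array, scoring 1.
#'
#' @param panel gene panel (see \code{\link{default_gene_panel}}).
#' @param point_mutation_rate expected coding point mutations per individual
#'   per cycle over the panel (default 0.15).
#' @param structural_rate expected structural events at the adhesin locus per
#'   individual per cycle (default 0.02).
#' @param cycles number of transfer cycles (default 20).
#' @param n_pop population size carried between cycles (default 100).
#' @param n_clones number of final single-colony clones reported (default 18).
#' @param sel_strength selection intensity in \code{[0, 1)} against
#'   flocculent cells (default 0.9).
#' @param repeat_zero,repeat_full,repressor_penalty phenotype parameters as
#'   in \code{\link{phenotype_model}}.
#' @param seed integer seed.
#' @return object of class \code{passage_result}: \code{clones} (list; each
#'   has \code{mutations} — a data.frame of gene / substitution /
#'   consequence —, \code{repeat_units}, \code{score}),
#'   \code{cycle_mean_score} (length \code{cycles}), and the call
#'   parameters.
#' @export
simulate_serial_passage <- function(panel = default_gene_panel(),
                                    point_mutation_rate = 0.15,
                                    structural_rate = 0.02,
                                    cycles = 20, n_pop = 100, n_clones = 18,
                                    sel_strength = 0.9,
                                    repeat_zero = 8, repeat_full = 18,
                                    repressor_penalty = 0.4, seed = 1) {
  stopifnot(cycles >= 1, n_pop >= 2, sel_strength >= 0, sel_strength < 1)
  ancestor <- list(
    mutations = data.frame(gene = character(), substitution = character(),
                           consequence = character(), stringsAsFactors = FALSE),
    repeat_units = repeat_full, activator_ok = TRUE, repressor_activity = 0)

  with_seed(seed, {
    pop <- rep(list(ancestor), n_pop)
    cycle_mean <- numeric(cycles)
    for (cy in seq_len(cycles)) {
      # mutation
      n_pt <- rpois(n_pop, point_mutation_rate)
      n_st <- rpois(n_pop, structural_rate)
      for (i in which(n_pt + n_st > 0)) {
        ind <- pop[[i]]
        if (n_pt[i] > 0) {
          gi <- sample.int(nrow(panel), n_pt[i], replace = TRUE,
                           prob = panel$weight)
          for (g in gi) {
            m <- draw_point_mutation(panel$gene[g], panel$cds_codons[g])
            ind$mutations <- rbind(ind$mutations, data.frame(
              gene = panel$gene[g], substitution = m$substitution,
              consequence = m$consequence, stringsAsFactors = FALSE))
            if (m$damaging) {
              role <- panel$role[g]
              if (role == "activator") ind$activator_ok <- FALSE
              if (role == "repressor_inhibitor")
                ind$repressor_activity <- ind$repressor_activity + 1
              if (role == "structural") ind$repeat_units <- 0
            }
          }
        }
        if (n_st[i] > 0) {
          for (k in seq_len(n_st[i])) {
            struct_gene <- panel$gene[panel$role == "structural"][1]
            if (runif(1) < 0.7 && ind$repeat_units > repeat_zero) {
              new_r <- sample(seq(4, ind$repeat_units - 1), 1L)
              ind$mutations <- rbind(ind$mutations, data.frame(
                gene = struct_gene, substitution = "Contraction of repeat units",
                consequence = "structural", stringsAsFactors = FALSE))
              ind$repeat_units <- new_r
            } else {
              ind$mutations <- rbind(ind$mutations, data.frame(
                gene = struct_gene, substitution = "Subtelomeric deletion",
                consequence = "structural", stringsAsFactors = FALSE))
              ind$repeat_units <- 0
            }
          }
        }
        pop[[i]] <- ind
      }
      sc <- vapply(pop, haploid_score, 0, repeat_zero = repeat_zero,
                   repeat_full = repeat_full,
                   repressor_penalty = repressor_penalty)
      cycle_mean[cy] <- mean(sc)
      # planktonic survival and regrowth to constant population size
      w <- pmax(1 - sel_strength * sc, 1e-9)
      pop <- pop[sample.int(n_pop, n_pop, replace = TRUE, prob = w)]
    }
    idx <- sample.int(n_pop, min(n_clones, n_pop))
    clones <- lapply(pop[idx], function(ind) {
      ind$score <- haploid_score(ind, repeat_zero, repeat_full,
                                 repressor_penalty)
      ind
    })
    structure(list(clones = clones, cycle_mean_score = cycle_mean,
                   cycles = cycles, n_pop = n_pop,
                   point_mutation_rate = point_mutation_rate,
                   structural_rate = structural_rate,
                   sel_strength = sel_strength, seed = seed),
              class = "passage_result")
  })
}

#' @export
print.passage_result <- function(x, ...) {
  cat(sprintf("passage_result: %d cycles, %d clones\n", x$cycles,
              length(x$clones)))
  cat(sprintf("  mean score cycle 1: %.3f; cycle %d: %.3f\n",
              x$cycle_mean_score[1], x$cycles,
              x$cycle_mean_score[x$cycles]))
  invisible(x)
}

#' Tabulate de novo mutations across evolved clones
#'
#' Flattens clone truth lists into one table (clone, gene, substitution,
#' consequence), the layout used to report mutations found in experimentally
#' evolved lines.
#'
#' @param res a \code{passage_result}.
#' @return data.frame.
#' @export
mutation_table <- function(res) {
  stopifnot(inherits(res, "passage_result"))
  out <- lapply(seq_along(res$clones), function(i) {
    m <- res$clones[[i]]$mutations
    if (nrow(m) == 0) return(NULL)
    cbind(clone = sprintf("clone%d", i), m, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(clone = character(), gene = character(),
                      substitution = character(), consequence = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
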