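#' Default mixture of repair outcomes per induced break
#'
#' Weighted toward homologous-recombination outcomes (gene conversion and
#' break-induced repair), which dominate observed event spectra; whole
#' chromosome aneuploidy, Ty-like ectopic translocation, circularization and
#' interstitial deletion are rarer.
#' @export
default_event_mix <- function() {
  c(SGC = 0.35, BIR = 0.35, ANEUPLOIDY_LOSS = 0.10, ANEUPLOIDY_GAIN = 0.05,
    TL = 0.09, CIRCULARIZATION = 0.035, DELETION = 0.025)
}

snap_to_site <- function(genome, chrom, pos) {
  s <- genome$sites[[chrom]]
  if (length(s) == 0) return(round(pos))
  s[which.min(abs(s - pos))]
}

# nearest recognition site to `pos` within [lo, hi]; NULL when none exists
snap_to_site_within <- function(genome, chrom, pos, lo, hi) {
  s <- genome$sites[[chrom]]
  s <- s[s >= lo & s <= hi]
  if (length(s) == 0) return(NULL)
  s[which.min(abs(s - pos))]
}

# one random event; breakpoints snapped to the nearest recognition site.
# break-derived events hit chromosomes in proportion to length (target size);
# whole-chromosome aneuploidy instead weights chromosomes by 1/length, since
# mis-segregation of gene-rich large chromosomes is rarely tolerated
draw_random_event <- function(genome, mix) {
  ch <- genome$chromosomes
  kind <- sample(names(mix), 1L, prob = mix)
  w <- if (kind %in% c("ANEUPLOIDY_LOSS", "ANEUPLOIDY_GAIN"))
    1 / ch$length else ch$length
  ci <- sample.int(nrow(ch), 1L, prob = w)
  chrom <- ch$name[ci]; L <- ch$length[ci]
  h <- sample(c("A", "B"), 1L)
  snap <- function(p) snap_to_site(genome, chrom, p)
  if (kind == "BIR") {
    bp <- snap(runif(1, 0.05, 0.95) * L)
    rearrangement_event("BIR", chrom, h, breakpoint = bp,
                        end = sample(c("left", "right"), 1L))
  } else if (kind == "SGC") {
    # keep interstitial tracts clear of chromosome ends so distal markers
    # exist to witness that the tract does not reach the telomere
    s <- snap_to_site_within(genome, chrom, runif(1, 0.05, 0.9) * L,
                             2500, L - 5000)
    if (is.null(s)) return(NULL)
    e <- snap_to_site_within(genome, chrom, s + runif(1, 2000, 30000),
                             s + 1000, L - 2500)
    if (is.null(e)) return(NULL)
    rearrangement_event("SGC", chrom, h, interval = c(s, e))
  } else if (kind == "DELETION") {
    s <- snap_to_site_within(genome, chrom, runif(1, 0.1, 0.8) * L,
                             2500, L - 5000)
    if (is.null(s)) return(NULL)
    e <- snap_to_site_within(genome, chrom, s + runif(1, 5000, 50000),
                             s + 2000, L - 2500)
    if (is.null(e)) return(NULL)
    rearrangement_event("DELETION", chrom, h, interval = c(s, e))
  } else if (kind == "CIRCULARIZATION") {
    x <- snap(runif(1, 0.05, 0.30) * L)
    y <- snap(runif(1, 0.70, 0.95) * L)
    if (x <= 0 || y >= L || y <= x) return(NULL)
    rearrangement_event("CIRCULARIZATION", chrom, h, breakpoints = c(x, y))
  } else if (kind == "TL") {
    cj <- sample.int(nrow(ch), 1L, prob = ch$length)
    if (cj == ci && nrow(ch) > 1) cj <- sample(setdiff(seq_len(nrow(ch)), ci), 1L)
    p1 <- snap(runif(1, 0.1, 0.9) * L)
    p2 <- snap_to_site(genome, ch$name[cj], runif(1, 0.1, 0.9) * ch$length[cj])
    if (identical(chrom, ch$name[cj]) && p1 == p2) return(NULL)
    rearrangement_event("TL", chrom, h, breakpoint = p1,
                        partner_chrom = ch$name[cj], partner_pos = p2,
                        partner_homolog = sample(c("A", "B"), 1L))
  } else {
    rearrangement_event(kind, chrom, h)
  }
}

#' Simulate a selected cohort of endonuclease-treated mutants
#'
#' Repeatedly draws mutants carrying random recognition-site-anchored
#' rearrangements, scores each against the flocculation phenotype model, and
#' keeps only mutants whose score falls below \code{selection_threshold} —
#' emulating recovery of non-flocculent cells from the planktonic fraction.
#' Draws continue until \code{n_mutants} are accepted or the draw cap is hit.
#'
#' @param genome a \code{hybrid_genome}.
#' @param model a \code{phenotype_model} (default
#'   \code{\link{default_phenotype_model}}).
#' @param n_mutants number of accepted mutants required (default 30).
#' @param events_per_mutant mean event count per mutant (Poisson), or a
#'   function \code{function(n)} returning counts.
#' @param selection_threshold phenotype score below which a mutant survives
#'   planktonic selection (default 0.2; the ancestral hybrid scores 0.4 under
#'   the default model).
#' @param event_mix named probability vector over event kinds.
#' @param max_draws cap on total draws before declaring the threshold
#'   unreachable.
#' @param seed root seed; per-draw child seeds are derived deterministically.
#' @return object of class \code{taq_cohort}: list with \code{mutants}
#'   (accepted \code{taq_genotype}s), \code{scores}, \code{draw_scores}
#'   (scores of all draws, accepted or not), \code{n_draws},
#'   \code{acceptance_rate}, \code{model}, \code{genome},
#'   \code{selection_threshold}.
#' @export
simulate_taq_cohort <- function(genome, model = default_phenotype_model(genome),
                                n_mutants = 30, events_per_mutant = 6,
                                selection_threshold = 0.2,
                                event_mix = default_event_mix(),
                                max_draws = 400 * n_mutants, seed = 1) {
  stopifnot(inherits(genome, "hybrid_genome"), n_mutants >= 1)
  event_mix <- event_mix / sum(event_mix)
  n_events_fun <- if (is.function(events_per_mutant)) events_per_mutant
                  else function(n) rpois(n, events_per_mutant)

  mutants <- vector("list", n_mutants)
  scores <- numeric(n_mutants)
  draw_scores <- numeric(0)
  accepted <- 0L; draws <- 0L
  while (accepted < n_mutants) {
    draws <- draws + 1L
    if (draws > max_draws)
      stop_taqmap(paste0("selection threshold %.3g appears unreachable: ",
                         "%d accepted after %d draws"),
                  selection_threshold, accepted, draws - 1L)
    gt <- with_seed(derive_seed(seed, draws), {
      k <- n_events_fun(1L)
      evs <- list()
      guard <- 0L
      lens <- setNames(genome$chromosomes$length, genome$chromosomes$name)
      # events must be non-interacting to stay attributable in the read
      # evidence: same-homolog footprint overlaps are contradictory (as in
      # plant_events), and copy/state-altering footprints may not come close
      # on a chromosome even across homologs — overlapping conversions on
      # opposite homologs cancel, loss + gain on one chromosome is
      # indistinguishable from copy-neutral LOH, and adjacent tracts with no
      # heterozygous markers between them fuse into one segment. Clashing
      # draws are redrawn; a 5 kb gap keeps tracts separable.
      dosage_kinds <- setdiff(EVENT_KINDS, "TL")
      gap <- 5000
      while (length(evs) < k && guard < 50L) {
        guard <- guard + 1L
        ev <- draw_random_event(genome, event_mix)
        if (is.null(ev)) next
        fp <- event_footprint(ev, lens[[ev$chrom]])
        both_dosage <- ev$kind %in% dosage_kinds
        clash <- any(vapply(evs, function(e) {
          if (!identical(e$chrom, ev$chrom)) return(FALSE)
          if (!identical(e$homolog, ev$homolog) &&
              !(both_dosage && e$kind %in% dosage_kinds)) return(FALSE)
          efp <- event_footprint(e, lens[[e$chrom]])
          fp[1] < efp[2] + gap && efp[1] < fp[2] + gap
        }, TRUE))
        if (!clash) evs <- c(evs, list(ev))
      }
      plant_events(genome, evs)
    })
    sc <- phenotype_score(gt, model)
    draw_scores <- c(draw_scores, sc)
    if (sc < selection_threshold) {
      accepted <- accepted + 1L
      mutants[[accepted]] <- gt
      scores[accepted] <- sc
    }
  }
  structure(list(mutants = mutants, scores = scores,
                 draw_scores = draw_scores, n_draws = draws,
                 acceptance_rate = n_mutants / draws,
                 model = model, genome = genome,
                 selection_threshold = selection_threshold, seed = seed),
            class = "taq_cohort")
}

#' @export
print.taq_cohort <- function(x, ...) {
  cat(sprintf("taq_cohort: %d mutants accepted in %d draws (rate %.2f)\n",
              length(x$mutants), x$n_draws, x$acceptance_rate))
  cat(sprintf("  score of accepted: mean %.3f; of all draws: mean %.3f\n",
              mean(x$scores), mean(x$draw_scores)))
  invisible(x)
}

#' Simulate evidence bundles for every mutant of a cohort
#'
#' @param cohort a \code{taq_cohort}.
#' @param seed root seed for per-mutant evidence noise.
#' @param ... passed to \code{\link{simulate_evidence}}.
#' @return list of \code{evidence_bundle}, one per mutant.
#' @export
simulate_cohort_evidence <- function(cohort, seed = 1, ...) {
  stopifnot(inherits(cohort, "taq_cohort"))
  lapply(seq_along(cohort$mutants), function(i)
    simulate_evidence(cohort$mutants[[i]], seed = derive_seed(seed, i), ...))
}
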