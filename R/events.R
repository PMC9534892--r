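EVENT_KINDS <- c("BIR", "SGC", "TL", "ANEUPLOIDY_LOSS", "ANEUPLOIDY_GAIN",
                 "CIRCULARIZATION", "DELETION")

#' Construct a rearrangement event
#'
#' Tagged record for one induced rearrangement. Coordinates are 0-based;
#' intervals are half-open. Junction \code{side} records where the retained
#' sequence lies relative to the breakpoint (\code{"right"} means the sequence
#' to the right of the position survives at that junction end).
#'
#' @param kind one of \code{BIR}, \code{SGC}, \code{TL},
#'   \code{ANEUPLOIDY_LOSS}, \code{ANEUPLOIDY_GAIN}, \code{CIRCULARIZATION},
#'   \code{DELETION}.
#' @param chrom chromosome name.
#' @param homolog \code{"A"} or \code{"B"}: the parental homolog the event
#'   acts on.
#' @param breakpoint single breakpoint (BIR, TL).
#' @param end for BIR: which chromosome end the conversion runs to
#'   (\code{"right"} or \code{"left"}).
#' @param interval length-2 vector \code{c(start, end)} (SGC, DELETION).
#' @param breakpoints length-2 vector \code{c(x, y)}, \code{x < y}
#'   (CIRCULARIZATION: the retained arc).
#' @param donor_homolog homolog copied from (BIR, SGC); defaults to the other
#'   homolog.
#' @param partner_chrom,partner_pos,partner_homolog the second locus (TL).
#' @return an object of class \code{rearrangement_event}.
#' @export
rearrangement_event <- function(kind, chrom, homolog = c("A", "B"),
                                breakpoint = NULL, end = c("right", "left"),
                                interval = NULL, breakpoints = NULL,
                                donor_homolog = NULL,
                                partner_chrom = NULL, partner_pos = NULL,
                                partner_homolog = NULL) {
  kind <- match.arg(kind, EVENT_KINDS)
  homolog <- match.arg(homolog)
  end <- match.arg(end)
  if (is.null(donor_homolog)) donor_homolog <- setdiff(c("A", "B"), homolog)
  ev <- list(kind = kind, chrom = chrom, homolog = homolog)
  if (kind == "BIR") {
    stopifnot(length(breakpoint) == 1L)
    ev$breakpoint <- as.numeric(breakpoint); ev$end <- end
    ev$donor_homolog <- donor_homolog
  } else if (kind == "SGC") {
    stopifnot(length(interval) == 2L, interval[1] < interval[2])
    ev$interval <- as.numeric(interval); ev$donor_homolog <- donor_homolog
  } else if (kind == "DELETION") {
    stopifnot(length(interval) == 2L, interval[1] < interval[2])
    ev$interval <- as.numeric(interval)
  } else if (kind == "CIRCULARIZATION") {
    stopifnot(length(breakpoints) == 2L, breakpoints[1] < breakpoints[2])
    ev$breakpoints <- as.numeric(breakpoints)
  } else if (kind == "TL") {
    stopifnot(length(breakpoint) == 1L, !is.null(partner_chrom),
              length(partner_pos) == 1L)
    if (identical(chrom, partner_chrom) && breakpoint == partner_pos)
      stop_taqmap("TL must reference two distinct loci")
    ev$breakpoint <- as.numeric(breakpoint)
    ev$partner_chrom <- partner_chrom
    ev$partner_pos <- as.numeric(partner_pos)
    ev$partner_homolog <- partner_homolog %||% homolog
  }
  structure(ev, class = "rearrangement_event")
}

#' @export
print.rearrangement_event <- function(x, ...) {
  loc <- if (!is.null(x$interval))
    sprintf("[%d,%d)", x$interval[1], x$interval[2])
  else if (!is.null(x$breakpoints))
    sprintf("arc [%d,%d)", x$breakpoints[1], x$breakpoints[2])
  else if (!is.null(x$breakpoint)) sprintf("@%d", x$breakpoint)
  else ""
  cat(sprintf("%s %s:%s homolog %s\n", x$kind, x$chrom, loc, x$homolog))
  invisible(x)
}

# interval of marker state / copy-number consequence, for overlap vetting
event_footprint <- function(ev, chrom_len) {
  switch(ev$kind,
    BIR = if (ev$end == "right") c(ev$breakpoint, chrom_len)
          else c(0, ev$breakpoint),
    SGC = ev$interval,
    DELETION = ev$interval,
    CIRCULARIZATION = c(0, chrom_len),
    ANEUPLOIDY_LOSS = c(0, chrom_len),
    ANEUPLOIDY_GAIN = c(0, chrom_len),
    TL = c(ev$breakpoint, chrom_len))
}

# full-coverage copy-number track: one row per constant-cn run, half-open
flat_cn <- function(len, cn = 1) data.frame(start = 0, end = len, cn = cn)

set_cn <- function(track, start, end, cn) {
  keep <- track[track$end <= start | track$start >= end, , drop = FALSE]
  cut_l <- track[track$start < start & track$end > start, , drop = FALSE]
  if (nrow(cut_l)) cut_l$end <- start
  cut_r <- track[track$start < end & track$end > end, , drop = FALSE]
  if (nrow(cut_r)) cut_r$start <- end
  out <- rbind(keep, cut_l, cut_r, data.frame(start = start, end = end, cn = cn))
  out <- out[out$start < out$end, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

cn_at <- function(track, pos) {
  i <- findInterval(pos, track$start)
  track$cn[pmax(i, 1L)]
}

#' Convert a hybrid genome to its ancestral (unrearranged) genotype
#'
#' The genotype tracks, per chromosome and per physical homolog, the parental
#' origin of every marker plus a copy-number track, the novel junction list
#' and the truth set of planted events.
#'
#' @param genome a \code{hybrid_genome}.
#' @return an object of class \code{taq_genotype}.
#' @export
as_genotype <- function(genome) {
  stopifnot(inherits(genome, "hybrid_genome"))
  chroms <- genome$chromosomes$name
  states <- lapply(chroms, function(ch) {
    n <- nrow(genome$markers[[ch]])
    list(A = rep("A", n), B = rep("B", n))
  })
  names(states) <- chroms
  cn <- lapply(genome$chromosomes$length,
               function(L) list(A = flat_cn(L), B = flat_cn(L)))
  names(cn) <- chroms
  structure(list(genome = genome, states = states, cn = cn,
                 junctions = empty_junctions(), truth = list()),
            class = "taq_genotype")
}

empty_junctions <- function() {
  data.frame(chrom1 = character(), pos1 = numeric(), side1 = character(),
             chrom2 = character(), pos2 = numeric(), side2 = character(),
             stringsAsFactors = FALSE)
}

add_junction <- function(j, chrom1, pos1, side1, chrom2, pos2, side2) {
  rbind(j, data.frame(chrom1 = chrom1, pos1 = pos1, side1 = side1,
                      chrom2 = chrom2, pos2 = pos2, side2 = side2,
                      stringsAsFactors = FALSE))
}

#' Plant rearrangement events into a genotype
#'
#' Applies a list of \code{\link{rearrangement_event}}s to a genome (or an
#' already-rearranged genotype), updating marker parental states, per-homolog
#' copy-number tracks and the junction list, and appending each event to the
#' retained truth set.
#'
#' Semantics: BIR converts marker states from the breakpoint to the chosen
#' chromosome end of the recipient homolog to the donor homolog's current
#' alleles (terminal loss of heterozygosity); SGC converts only its
#' interstitial interval; aneuploidy sets the homolog's copy number to 0 or 2
#' chromosome-wide; CIRCULARIZATION zeroes copy number outside its two
#' interior breakpoints and records the joining junction; DELETION zeroes its
#' interval and records the bridging junction; a reciprocal TL records the two
#' novel junctions and the exchange of distal marker assignment between the
#' partner loci (allele content at each reference coordinate is unchanged, as
#' it is for mapped short reads).
#'
#' @param x a \code{hybrid_genome} or \code{taq_genotype}.
#' @param events list of \code{rearrangement_event}s.
#' @param seed unused for the deterministic planting itself; accepted for
#'   interface symmetry.
#' @return an updated \code{taq_genotype}; planted events are appended to
#'   \code{$truth}.
#' @export
plant_events <- function(x, events, seed = NULL) {
  gt <- if (inherits(x, "hybrid_genome")) as_genotype(x) else x
  stopifnot(inherits(gt, "taq_genotype"))
  if (length(events) == 0) return(gt)
  if (inherits(events, "rearrangement_event")) events <- list(events)

  lens <- setNames(gt$genome$chromosomes$length, gt$genome$chromosomes$name)
  # validate bounds
  for (ev in events) {
    if (!ev$chrom %in% names(lens))
      stop_taqmap("event on unknown chromosome '%s'", ev$chrom)
    fp <- event_footprint(ev, lens[[ev$chrom]])
    pts <- c(ev$breakpoint, ev$interval, ev$breakpoints)
    if (length(pts) && (any(pts < 0) || any(pts > lens[[ev$chrom]])))
      stop_taqmap("%s breakpoint outside %s bounds", ev$kind, ev$chrom)
    if (ev$kind == "CIRCULARIZATION" &&
        (ev$breakpoints[1] <= 0 || ev$breakpoints[2] >= lens[[ev$chrom]]))
      stop_taqmap("circularization breakpoints must be interior")
    if (ev$kind == "SGC" &&
        (ev$interval[1] <= 0 || ev$interval[2] >= lens[[ev$chrom]]))
      stop_taqmap("SGC interval must be interstitial")
  }
  # reject contradictory (overlapping) events on one chromosome+homolog
  if (length(events) > 1) {
    key <- vapply(events, function(e) paste(e$chrom, e$homolog), "")
    for (k in unique(key)) {
      idx <- which(key == k)
      if (length(idx) < 2) next
      fps <- lapply(events[idx], function(e)
        event_footprint(e, lens[[e$chrom]]))
      for (a in seq_along(idx)) for (b in seq_len(a - 1)) {
        if (fps[[a]][1] < fps[[b]][2] && fps[[b]][1] < fps[[a]][2])
          stop_taqmap("overlapping contradictory events on %s: %s and %s",
                      k, events[[idx[b]]]$kind, events[[idx[a]]]$kind)
      }
    }
  }

  for (ev in events) {
    ch <- ev$chrom; h <- ev$homolog; L <- lens[[ch]]
    pos <- gt$genome$markers[[ch]]$pos
    if (ev$kind %in% c("BIR", "SGC")) {
      fp <- event_footprint(ev, L)
      idx <- which(pos >= fp[1] & pos < fp[2])
      gt$states[[ch]][[h]][idx] <- gt$states[[ch]][[ev$donor_homolog]][idx]
    } else if (ev$kind == "ANEUPLOIDY_LOSS") {
      gt$cn[[ch]][[h]] <- flat_cn(L, 0)
    } else if (ev$kind == "ANEUPLOIDY_GAIN") {
      gt$cn[[ch]][[h]] <- flat_cn(L, 2)
    } else if (ev$kind == "CIRCULARIZATION") {
      x1 <- ev$breakpoints[1]; y1 <- ev$breakpoints[2]
      tr <- gt$cn[[ch]][[h]]
      tr <- set_cn(tr, 0, x1, 0)
      tr <- set_cn(tr, y1, L, 0)
      gt$cn[[ch]][[h]] <- tr
      gt$junctions <- add_junction(gt$junctions, ch, x1, "right", ch, y1, "left")
    } else if (ev$kind == "DELETION") {
      gt$cn[[ch]][[h]] <- set_cn(gt$cn[[ch]][[h]], ev$interval[1],
                                 ev$interval[2], 0)
      gt$junctions <- add_junction(gt$junctions, ch, ev$interval[1], "left",
                                   ch, ev$interval[2], "right")
    } else if (ev$kind == "TL") {
      gt$junctions <- add_junction(gt$junctions, ch, ev$breakpoint, "left",
                                   ev$partner_chrom, ev$partner_pos, "right")
      gt$junctions <- add_junction(gt$junctions, ch, ev$breakpoint, "right",
                                   ev$partner_chrom, ev$partner_pos, "left")
    }
    gt$truth <- c(gt$truth, list(ev))
  }
  gt
}

#' @export
print.taq_genotype <- function(x, ...) {
  cat(sprintf("taq_genotype: %d chromosome(s), %d planted event(s), %d junction(s)\n",
              length(x$states), length(x$truth), nrow(x$junctions)))
  for (ev in x$truth) print(ev)
  invisible(x)
}
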