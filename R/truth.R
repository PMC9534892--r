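#' Flatten a genotype's planted truth set to a comparable table
#'
#' One row per planted event with the same coordinate conventions the caller
#' reports: BIR rows carry the converted terminal interval, SGC and DELETION
#' their interval, CIRCULARIZATION the retained arc, aneuploidy the whole
#' chromosome, TL its two loci.
#'
#' @param gt a \code{taq_genotype}.
#' @return data.frame with kind, chrom, homolog, start, end, partner_chrom,
#'   partner_pos.
#' @export
truth_events_df <- function(gt) {
  stopifnot(inherits(gt, "taq_genotype"))
  lens <- setNames(gt$genome$chromosomes$length, gt$genome$chromosomes$name)
  rows <- lapply(gt$truth, function(ev) {
    L <- lens[[ev$chrom]]
    fp <- switch(ev$kind,
      CIRCULARIZATION = ev$breakpoints,
      TL = c(ev$breakpoint, ev$breakpoint),
      event_footprint(ev, L))
    data.frame(kind = ev$kind, chrom = ev$chrom, homolog = ev$homolog,
               start = fp[1], end = fp[2],
               partner_chrom = ev$partner_chrom %||% NA_character_,
               partner_pos = ev$partner_pos %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(kind = character(), chrom = character(),
                      homolog = character(), start = numeric(),
                      end = numeric(), partner_chrom = character(),
                      partner_pos = numeric(), stringsAsFactors = FALSE)
  out
}

# tolerance (bp) at a boundary: the local inter-marker gap, times `k`
marker_gap_at <- function(genome, chrom, pos, k = 1) {
  mk <- genome$markers[[chrom]]$pos
  if (length(mk) < 2) return(Inf)
  i <- findInterval(pos, mk)
  lo <- mk[max(i, 1L)]; hi <- mk[min(i + 1L, length(mk))]
  k * max(hi - lo, mean(diff(mk)))
}

#' Match called events against a planted truth set
#'
#' For each truth event, finds a called event of the same kind on the same
#' chromosome (homolog compared when both sides report one) whose
#' non-terminal boundaries lie within \code{tol_markers} local inter-marker
#' gaps of the truth boundaries; TL events match on their unordered locus
#' pair. Reports per-truth matches and the count of unmatched called events.
#'
#' @param gt the \code{taq_genotype} carrying the truth set.
#' @param called the \code{events} data.frame from \code{\link{call_events}}.
#' @param tol_markers breakpoint tolerance in local marker spacings.
#' @return list: \code{matched} logical per truth event, \code{bp_error}
#'   worst boundary error (bp) per matched truth event, \code{n_extra}
#'   called events not explained by any truth event.
#' @export
match_events <- function(gt, called, tol_markers = 1) {
  truth <- truth_events_df(gt)
  lens <- setNames(gt$genome$chromosomes$length, gt$genome$chromosomes$name)
  matched <- logical(nrow(truth))
  bp_error <- rep(NA_real_, nrow(truth))
  taken <- logical(nrow(called))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    cand <- which(!taken & called$kind == tr$kind & called$chrom == tr$chrom)
    if (tr$kind != "TL" && length(cand)) {
      hom_ok <- is.na(called$homolog[cand]) |
        called$homolog[cand] == tr$homolog
      cand <- cand[hom_ok]
    }
    if (length(cand) == 0) next
    if (tr$kind %in% c("ANEUPLOIDY_LOSS", "ANEUPLOIDY_GAIN")) {
      matched[i] <- TRUE; bp_error[i] <- 0; taken[cand[1]] <- TRUE; next
    }
    if (tr$kind == "TL") {
      for (j in cand) {
        loci_t <- c(paste(tr$chrom, tr$start), paste(tr$partner_chrom,
                                                     tr$partner_pos))
        loci_c <- c(paste(called$chrom[j], called$start[j]),
                    paste(called$partner_chrom[j], called$partner_pos[j]))
        if (setequal(loci_t, loci_c)) {
          matched[i] <- TRUE; bp_error[i] <- 0; taken[j] <- TRUE; break
        }
      }
      next
    }
    L <- lens[[tr$chrom]]
    for (j in cand) {
      errs <- numeric(0)
      for (side in c("start", "end")) {
        tp <- tr[[side]]
        if (tp <= 0 || tp >= L) next          # terminal boundary: exact
        tol <- marker_gap_at(gt$genome, tr$chrom, tp, tol_markers)
        errs <- c(errs, abs(called[[side]][j] - tp))
        if (abs(called[[side]][j] - tp) > tol) { errs <- NULL; break }
      }
      if (!is.null(errs)) {
        matched[i] <- TRUE
        bp_error[i] <- if (length(errs)) max(errs) else 0
        taken[j] <- TRUE
        break
      }
    }
  }
  list(matched = matched, bp_error = bp_error, truth = truth,
       n_extra = sum(!taken))
}
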