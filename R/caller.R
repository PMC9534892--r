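#' Caller configuration
#'
#' One block holding every threshold of the rearrangement caller; defaults
#' are recorded in output provenance. The heterozygosity band and minimum
#' depth formalize marker genotyping from allele depths; smoothing and the
#' minimum segment size control loss-of-heterozygosity segmentation;
#' coverage bands separate copy-neutral (reciprocal) from copy-lost
#' segments; whole-chromosome thresholds call aneuploidy; junction support
#' gates breakpoint refinement and translocation calls.
#'
#' @param min_depth marker depth below which no genotype is called.
#' @param het_band B-allele-fraction interval called heterozygous.
#' @param smooth_w majority-vote smoothing window (markers).
#' @param min_segment_markers minimum markers per retained segment.
#' @param recip_lo relative total coverage at/above which a LOH segment is
#'   treated as copy-neutral ("reciprocal").
#' @param loss_threshold,gain_threshold per-homolog relative coverage bounds
#'   for whole-chromosome loss / gain (defaults 0.25 / 1.5 of single copy).
#' @param min_support junction reads needed to use a junction.
#' @param snap_window bp window for snapping coverage boundaries to
#'   junctions.
#' @export
caller_config <- function(min_depth = 10, het_band = c(0.15, 0.85),
                          smooth_w = 5, min_segment_markers = 5,
                          recip_lo = 0.75, loss_threshold = 0.25,
                          gain_threshold = 1.5, min_support = 5,
                          snap_window = 5000) {
  stopifnot(min_depth >= 1, length(het_band) == 2, het_band[1] < het_band[2],
            smooth_w >= 1, min_segment_markers >= 1)
  as.list(environment())
}

#' Genotype markers from parental allele depths
#'
#' @param evidence an \code{evidence_bundle}.
#' @param min_depth,het_band see \code{\link{caller_config}}.
#' @return data.frame with chrom, pos, state (HET / HOM_A / HOM_B / NOCALL),
#'   depth_A, depth_B.
#' @export
call_markers <- function(evidence, min_depth = 10, het_band = c(0.15, 0.85)) {
  stopifnot(inherits(evidence, "evidence_bundle"))
  out <- lapply(names(evidence$marker_depths), function(ch) {
    md <- evidence$marker_depths[[ch]]
    tot <- md$depth_A + md$depth_B
    baf <- ifelse(tot > 0, md$depth_B / tot, NA_real_)
    state <- ifelse(tot < min_depth, "NOCALL",
             ifelse(baf <= het_band[1], "HOM_A",
             ifelse(baf >= het_band[2], "HOM_B", "HET")))
    data.frame(chrom = ch, pos = md$pos, state = state,
               depth_A = md$depth_A, depth_B = md$depth_B,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# centred majority vote over w markers; ties and edges keep the raw call
smooth_states <- function(states, w) {
  if (w <= 1 || length(states) < w) return(states)
  lv <- c("HET", "HOM_A", "HOM_B")
  cnt <- vapply(lv, function(st)
    as.numeric(stats::filter(states == st, rep(1, w), sides = 2)),
    numeric(length(states)))
  maxc <- apply(cnt, 1, max)
  n_at_max <- rowSums(cnt == maxc)
  winner <- lv[max.col(cnt, ties.method = "first")]
  out <- ifelse(is.na(maxc) | n_at_max > 1, states, winner)
  out
}

#' Segment marker genotype calls into runs of constant state
#'
#' Maximal runs of a common genotype state (after majority smoothing) become
#' segments; boundaries are placed midway between the flanking markers of a
#' state change; runs shorter than \code{min_segment_markers} are merged
#' into their larger neighbor. NOCALL markers are excluded before
#' segmentation.
#'
#' @param marker_calls output of \code{\link{call_markers}}.
#' @param chromosomes data.frame with \code{name}, \code{length}.
#' @param min_segment_markers,smooth_w see \code{\link{caller_config}}.
#' @return data.frame with chrom, start, end (half-open bp), state,
#'   n_markers, terminal, first_marker, last_marker.
#' @export
segment_states <- function(marker_calls, chromosomes,
                           min_segment_markers = 5, smooth_w = 5) {
  out <- list()
  for (i in seq_len(nrow(chromosomes))) {
    ch <- chromosomes$name[i]; L <- chromosomes$length[i]
    mc <- marker_calls[marker_calls$chrom == ch & marker_calls$state != "NOCALL", ]
    if (nrow(mc) == 0) {
      warning(sprintf("chromosome %s has no callable markers", ch))
      next
    }
    st <- smooth_states(mc$state, smooth_w)
    # merge short runs into neighbors until all runs are large enough
    repeat {
      r <- rle(st)
      if (length(r$lengths) <= 1) break
      short <- which(r$lengths < min_segment_markers)
      if (length(short) == 0) break
      j <- short[which.min(r$lengths[short])]
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      nb <- if (j == 1) 2L
            else if (j == length(r$lengths)) j - 1L
            else if (r$lengths[j - 1] >= r$lengths[j + 1]) j - 1L else j + 1L
      st[starts[j]:ends[j]] <- r$values[nb]
    }
    r <- rle(st)
    ends_i <- cumsum(r$lengths); starts_i <- ends_i - r$lengths + 1
    n_seg <- length(r$lengths)
    seg_start <- numeric(n_seg); seg_end <- numeric(n_seg)
    for (j in seq_len(n_seg)) {
      seg_start[j] <- if (j == 1) 0 else
        floor((mc$pos[ends_i[j - 1]] + mc$pos[starts_i[j]]) / 2)
      seg_end[j] <- if (j == n_seg) L else
        floor((mc$pos[ends_i[j]] + mc$pos[starts_i[j + 1]]) / 2)
    }
    out[[ch]] <- data.frame(
      chrom = ch, start = seg_start, end = seg_end, state = r$values,
      n_markers = r$lengths,
      terminal = seg_start == 0 | seg_end == L,
      first_marker = mc$pos[starts_i], last_marker = mc$pos[ends_i],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), state = character(),
                      n_markers = integer(), terminal = logical(),
                      first_marker = numeric(), last_marker = numeric(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Snap a coverage-derived boundary to nearby junction evidence
#'
#' If a junction end with support at least \code{min_support} lies within
#' \code{window} bp of the boundary, the breakpoint snaps to the junction
#' position (read-level resolution); otherwise the coverage-derived boundary
#' stands, flagged approximate. Among several candidates the nearest wins;
#' ties go to higher support, then to the lower coordinate.
#'
#' @param boundary approximate position (bp).
#' @param chrom chromosome of the boundary.
#' @param junctions junction data.frame (chrom1, pos1, side1, chrom2, pos2,
#'   side2, support).
#' @param window search window in bp.
#' @param min_support minimum supporting reads.
#' @return list(pos, approximate, support).
#' @export
refine_breakpoint <- function(boundary, chrom, junctions, window = 5000,
                              min_support = 5) {
  stopifnot(window > 0)
  cand <- rbind(
    data.frame(pos = junctions$pos1, support = junctions$support,
               chrom = junctions$chrom1),
    data.frame(pos = junctions$pos2, support = junctions$support,
               chrom = junctions$chrom2))
  cand <- cand[cand$chrom == chrom & cand$support >= min_support &
                 abs(cand$pos - boundary) <= window, , drop = FALSE]
  if (nrow(cand) == 0)
    return(list(pos = boundary, approximate = TRUE, support = 0))
  cand <- cand[order(abs(cand$pos - boundary), -cand$support, cand$pos), ]
  list(pos = cand$pos[1], approximate = FALSE, support = cand$support[1])
}

empty_called_events <- function() {
  data.frame(kind = character(), chrom = character(), homolog = character(),
             start = numeric(), end = numeric(), donor_homolog = character(),
             partner_chrom = character(), partner_pos = numeric(),
             n_markers = numeric(), junction_support = numeric(),
             coverage_ratio = numeric(), approximate = logical(),
             ambiguous = logical(), stringsAsFactors = FALSE)
}

called_event_row <- function(kind, chrom, homolog = NA_character_,
                             start = NA_real_, end = NA_real_,
                             donor_homolog = NA_character_,
                             partner_chrom = NA_character_,
                             partner_pos = NA_real_, n_markers = NA_real_,
                             junction_support = NA_real_,
                             coverage_ratio = NA_real_, approximate = FALSE,
                             ambiguous = FALSE) {
  data.frame(kind = kind, chrom = chrom, homolog = homolog, start = start,
             end = end, donor_homolog = donor_homolog,
             partner_chrom = partner_chrom, partner_pos = partner_pos,
             n_markers = n_markers, junction_support = junction_support,
             coverage_ratio = coverage_ratio, approximate = approximate,
             ambiguous = ambiguous, stringsAsFactors = FALSE)
}

#' Detect whole-chromosome aneuploidy from window coverage
#'
#' Uses the median per-parental-homolog window coverage across each
#' chromosome relative to the expected single-copy depth. A homolog below
#' \code{loss_threshold} is a loss, above \code{gain_threshold} a gain; the
#' chromosome-wide total must move with it (below 0.75 / above 1.25 of the
#' diploid expectation), which separates true copy-number change from
#' copy-neutral loss of heterozygosity that also shifts allele-specific
#' coverage.
#'
#' @param evidence an \code{evidence_bundle}.
#' @param loss_threshold,gain_threshold see \code{\link{caller_config}}.
#' @param exclude optional data.frame (chrom, homolog) pairs to skip.
#' @return data.frame of called events (possibly empty).
#' @export
detect_aneuploidy <- function(evidence, loss_threshold = 0.25,
                              gain_threshold = 1.5, exclude = NULL) {
  out <- empty_called_events()
  exp1 <- evidence$mean_depth / 2
  for (i in seq_len(nrow(evidence$chromosomes))) {
    ch <- evidence$chromosomes$name[i]; L <- evidence$chromosomes$length[i]
    wc <- evidence$window_coverage[[ch]]
    if (nrow(wc) < 5) next
    r_tot <- median(wc$total) / evidence$mean_depth
    for (h in c("A", "B")) {
      if (!is.null(exclude) &&
          any(exclude$chrom == ch & exclude$homolog == h)) next
      r_h <- median(wc[[paste0("depth_", h)]]) / exp1
      if (r_h < loss_threshold && r_tot < 0.75) {
        out <- rbind(out, called_event_row("ANEUPLOIDY_LOSS", ch, h, 0, L,
                                           coverage_ratio = r_h))
      } else if (r_h > gain_threshold && r_tot > 1.25) {
        out <- rbind(out, called_event_row("ANEUPLOIDY_GAIN", ch, h, 0, L,
                                           coverage_ratio = r_h))
      }
    }
  }
  out
}

#' Detect chromosome circularization
#'
#' Reports circularization when one homolog's coverage is lost on both
#' terminal stretches of a chromosome, retained between two interior
#' breakpoints, and a junction with sufficient support joins the two
#' interior breakpoints (retained-arc right end to left end). Terminal
#' losses without the joining junction are reported as two terminal
#' deletions instead. Breakpoints are annotated with the distance to the
#' nearest recognition site when a site index is supplied.
#'
#' @param evidence an \code{evidence_bundle}.
#' @param min_support minimum junction support.
#' @param sites optional recognition-site index (named list of 0-based
#'   positions).
#' @return list(events = called-event data.frame, used_junctions = integer
#'   row indices into \code{evidence$junctions}, flagged = data.frame of
#'   (chrom, homolog) whose coverage pattern was consumed).
#' @export
detect_circularization <- function(evidence, min_support = 5, sites = NULL) {
  events <- empty_called_events()
  used <- integer(0)
  flagged <- data.frame(chrom = character(), homolog = character(),
                        stringsAsFactors = FALSE)
  exp1 <- evidence$mean_depth / 2
  jn <- evidence$junctions
  snap <- 2 * evidence$window_size
  for (i in seq_len(nrow(evidence$chromosomes))) {
    ch <- evidence$chromosomes$name[i]; L <- evidence$chromosomes$length[i]
    wc <- evidence$window_coverage[[ch]]
    n_w <- nrow(wc)
    if (n_w < 5) next
    for (h in c("A", "B")) {
      dep <- wc[[paste0("depth_", h)]]
      # the arc's complement must be physically absent: allele coverage lost
      # AND total coverage down (terminal LOH by BIR keeps total coverage)
      lost <- dep < 0.25 * exp1 & wc$total < 0.75 * evidence$mean_depth
      if (!lost[1] || !lost[n_w]) next
      ret <- which(!lost)
      if (length(ret) == 0) next               # whole-chromosome loss
      i1 <- ret[1]; i2 <- ret[length(ret)]
      if (i2 - i1 < 2) next
      # windows straddling a breakpoint are mixed; judge purity without them
      interior <- dep[(i1 + 1):(i2 - 1)]
      outer_idx <- setdiff(seq_len(n_w), (i1 - 1):(i2 + 1))
      if (mean(interior >= 0.6 * exp1) < 0.8) next
      if (length(outer_idx) && mean(lost[outer_idx]) < 0.8) next
      x_est <- wc$start[i1]; y_est <- wc$end[i2]
      hit <- which(jn$chrom1 == ch & jn$chrom2 == ch &
                     jn$support >= min_support &
                     ((jn$side1 == "right" & jn$side2 == "left" &
                         abs(jn$pos1 - x_est) <= snap &
                         abs(jn$pos2 - y_est) <= snap) |
                      (jn$side2 == "right" & jn$side1 == "left" &
                         abs(jn$pos2 - x_est) <= snap &
                         abs(jn$pos1 - y_est) <= snap)))
      if (length(hit)) {
        j <- hit[1]
        if (jn$side1[j] == "right") { x <- jn$pos1[j]; y <- jn$pos2[j] }
        else { x <- jn$pos2[j]; y <- jn$pos1[j] }
        ev <- called_event_row("CIRCULARIZATION", ch, h, x, y,
                               junction_support = jn$support[j])
        if (!is.null(sites) && length(sites[[ch]])) {
          ev$site_dist_start <- min(abs(sites[[ch]] - x))
          ev$site_dist_end <- min(abs(sites[[ch]] - y))
        }
        events <- merge_event_rows(events, ev)
        used <- c(used, j)
      } else {
        events <- merge_event_rows(events, rbind(
          called_event_row("DELETION", ch, h, 0, x_est, approximate = TRUE),
          called_event_row("DELETION", ch, h, y_est, L, approximate = TRUE)))
      }
      flagged <- rbind(flagged, data.frame(chrom = ch, homolog = h,
                                           stringsAsFactors = FALSE))
    }
  }
  list(events = events, used_junctions = used, flagged = flagged)
}

# rbind that tolerates extra annotation columns
merge_event_rows <- function(a, b) {
  for (cc in setdiff(names(b), names(a))) a[[cc]] <- rep(NA, nrow(a))
  for (cc in setdiff(names(a), names(b))) b[[cc]] <- rep(NA, nrow(b))
  rbind(a, b[names(a)])
}

#' Classify a loss-of-heterozygosity segment
#'
#' Applies the coverage-reciprocity rule: a LOH segment whose total coverage
#' is preserved (the donor homolog's allele coverage rises as the
#' recipient's falls — a reciprocal change) is a homologous-recombination
#' event, break-induced repair if the segment touches a chromosome end and a
#' short gene conversion if interstitial. A segment whose coverage is lost
#' with no reciprocal gain is a deletion, or a translocation when junction
#' evidence links its boundary to another locus. Contradictory evidence
#' (reciprocal coverage plus a junction to elsewhere) is classified by the
#' junction and flagged ambiguous.
#'
#' @param seg one row of \code{\link{segment_states}} output with state
#'   HOM_A or HOM_B.
#' @param evidence the \code{evidence_bundle}.
#' @param config a \code{\link{caller_config}}.
#' @return one called-event row (plus \code{used_junction} attribute).
#' @export
classify_segment <- function(seg, evidence, config = caller_config()) {
  stopifnot(seg$state %in% c("HOM_A", "HOM_B"))
  retained <- sub("HOM_", "", seg$state)
  lost <- setdiff(c("A", "B"), retained)
  ch <- seg$chrom
  md <- evidence$marker_depths[[ch]]
  in_seg <- md$pos >= seg$start & md$pos < seg$end
  cov_ratio <- mean(md$depth_A[in_seg] + md$depth_B[in_seg]) /
    evidence$mean_depth
  L <- evidence$chromosomes$length[evidence$chromosomes$name == ch]

  jn <- evidence$junctions
  boundaries <- c(if (seg$start > 0) seg$start, if (seg$end < L) seg$end)
  near_boundary <- function(p, chr)
    chr == ch & vapply(p, function(q) any(abs(q - boundaries) <=
                                            config$snap_window), TRUE)
  j_idx <- which(jn$support >= config$min_support &
                   (near_boundary(jn$pos1, jn$chrom1) |
                      near_boundary(jn$pos2, jn$chrom2)))
  # junction to "another locus": other end not at this segment's boundaries
  elsewhere <- j_idx[vapply(j_idx, function(j) {
    !(near_boundary(jn$pos1[j], jn$chrom1[j]) &&
        near_boundary(jn$pos2[j], jn$chrom2[j]))
  }, TRUE)]
  bridging <- setdiff(j_idx, elsewhere)

  reciprocal <- cov_ratio >= config$recip_lo
  used <- integer(0)

  if (reciprocal) {
    # copy-neutral reciprocal change: homologous repair; a junction to
    # elsewhere near a boundary is attributed to an independent event but
    # flagged as ambiguous evidence
    kind <- if (seg$terminal) "BIR" else "SGC"
    ev <- called_event_row(kind, ch, lost, seg$start, seg$end,
                           donor_homolog = retained,
                           n_markers = seg$n_markers,
                           coverage_ratio = cov_ratio, approximate = TRUE,
                           ambiguous = length(elsewhere) > 0)
  } else if (length(elsewhere) > 0 && length(bridging) == 0) {
    # coverage lost and a junction links a boundary to another locus; a
    # bridging junction joining the segment's own two boundaries is the
    # stronger (deletion) explanation and takes precedence below
    j <- elsewhere[which.max(jn$support[elsewhere])]
    on_this <- jn$chrom1[j] == ch &&
      any(abs(jn$pos1[j] - boundaries) <= config$snap_window)
    ev <- called_event_row("TL", ch, lost,
                           start = if (on_this) jn$pos1[j] else jn$pos2[j],
                           end = if (on_this) jn$pos1[j] else jn$pos2[j],
                           partner_chrom = if (on_this) jn$chrom2[j] else jn$chrom1[j],
                           partner_pos = if (on_this) jn$pos2[j] else jn$pos1[j],
                           n_markers = seg$n_markers,
                           junction_support = jn$support[j],
                           coverage_ratio = cov_ratio,
                           ambiguous = reciprocal)
    used <- j
  } else {
    s <- seg$start; e <- seg$end; approx <- TRUE; supp <- NA_real_
    if (length(bridging)) {
      j <- bridging[which.max(jn$support[bridging])]
      s <- min(jn$pos1[j], jn$pos2[j]); e <- max(jn$pos1[j], jn$pos2[j])
      approx <- FALSE; supp <- jn$support[j]; used <- j
    }
    ev <- called_event_row("DELETION", ch, lost, s, e,
                           n_markers = seg$n_markers,
                           junction_support = supp,
                           coverage_ratio = cov_ratio, approximate = approx,
                           ambiguous = length(elsewhere) > 0)
  }
  attr(ev, "used_junction") <- used
  ev
}

#' Call and classify all rearrangement events from an evidence bundle
#'
#' Full caller: genotypes markers, detects circularization and aneuploidy
#' from coverage, segments loss of heterozygosity, classifies each LOH
#' segment by the reciprocity rule, and calls translocations from remaining
#' reciprocal high-support junction pairs. Copy-neutral reciprocal
#' translocations leave marker states and coverage unchanged, so their
#' parental homolog is not identifiable from this evidence and is reported
#' as NA.
#'
#' @param evidence an \code{evidence_bundle}.
#' @param config a \code{\link{caller_config}}.
#' @param sites optional recognition-site index for breakpoint annotation.
#' @return list of class \code{called_events}: \code{events} (data.frame),
#'   \code{segments}, \code{marker_calls}, \code{config}.
#' @export
call_events <- function(evidence, config = caller_config(), sites = NULL) {
  stopifnot(inherits(evidence, "evidence_bundle"))
  mc <- call_markers(evidence, config$min_depth, config$het_band)
  circ <- detect_circularization(evidence, config$min_support, sites)
  events <- circ$events
  used_j <- circ$used_junctions

  aneu <- detect_aneuploidy(evidence, config$loss_threshold,
                            config$gain_threshold, exclude = circ$flagged)
  events <- merge_event_rows(events, aneu)

  segs <- suppressWarnings(
    segment_states(mc, evidence$chromosomes,
                   config$min_segment_markers, config$smooth_w))
  loh <- segs[segs$state %in% c("HOM_A", "HOM_B"), , drop = FALSE]
  if (nrow(loh)) {
    skip <- logical(nrow(loh))
    for (i in seq_len(nrow(loh))) {
      lost <- setdiff(c("A", "B"), sub("HOM_", "", loh$state[i]))
      # explained by whole-chromosome loss of the missing homolog?
      if (any(aneu$kind == "ANEUPLOIDY_LOSS" & aneu$chrom == loh$chrom[i] &
                aneu$homolog == lost)) skip[i] <- TRUE
      # explained by a circularization / terminal-deletion pattern?
      if (any(circ$flagged$chrom == loh$chrom[i] &
                circ$flagged$homolog == lost)) {
        arc <- events[events$kind == "CIRCULARIZATION" &
                        events$chrom == loh$chrom[i], , drop = FALSE]
        if (nrow(arc) == 0 ||
            loh$end[i] <= arc$start[1] + config$snap_window ||
            loh$start[i] >= arc$end[1] - config$snap_window)
          skip[i] <- TRUE
      }
    }
    for (i in which(!skip)) {
      ev <- classify_segment(loh[i, ], evidence, config)
      used_j <- c(used_j, attr(ev, "used_junction"))
      events <- merge_event_rows(events, ev)
    }
  }

  # reciprocal junction pairs not consumed above -> translocations
  jn <- evidence$junctions
  avail <- setdiff(which(jn$support >= config$min_support), used_j)
  if (length(avail)) {
    key <- vapply(avail, function(j) {
      ends <- rbind(c(jn$chrom1[j], jn$pos1[j]), c(jn$chrom2[j], jn$pos2[j]))
      ends <- ends[order(ends[, 1], as.numeric(ends[, 2])), , drop = FALSE]
      paste(t(ends), collapse = ":")
    }, "")
    for (k in unique(key)) {
      js <- avail[key == k]
      # skip junctions already explained by a called event breakpoint
      expl <- FALSE
      for (j in js) {
        d1 <- events$chrom == jn$chrom1[j] &
          (abs(events$start - jn$pos1[j]) <= config$snap_window |
             abs(events$end - jn$pos1[j]) <= config$snap_window)
        d2 <- events$chrom == jn$chrom2[j] &
          (abs(events$start - jn$pos2[j]) <= config$snap_window |
             abs(events$end - jn$pos2[j]) <= config$snap_window)
        if (any(d1 & d2 & events$kind %in%
                  c("DELETION", "CIRCULARIZATION"))) expl <- TRUE
      }
      if (expl) next
      j <- js[1]
      events <- merge_event_rows(events, called_event_row(
        "TL", jn$chrom1[j], NA_character_, jn$pos1[j], jn$pos1[j],
        partner_chrom = jn$chrom2[j], partner_pos = jn$pos2[j],
        junction_support = max(jn$support[js])))
    }
  }
  rownames(events) <- NULL
  structure(list(events = events, segments = segs, marker_calls = mc,
                 config = config),
            class = "called_events")
}

#' @export
print.called_events <- function(x, ...) {
  cat(sprintf("called_events: %d event(s)\n", nrow(x$events)))
  if (nrow(x$events)) print(x$events[, c("kind", "chrom", "homolog",
                                         "start", "end")])
  invisible(x)
}
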