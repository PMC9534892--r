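#' Windowed homozygosity of one mutant
#'
#' Counts homozygous (either parent) versus heterozygous marker calls per
#' fixed-width tiling window (default 10 kb, last window truncated) and
#' reports the bounded fraction \code{n_hom / (n_hom + n_het)} (NA when the
#' window has no callable marker). The literal hom/het odds ratio is emitted
#' as a secondary column, NA when \code{n_het = 0}. NOCALL markers count
#' toward neither.
#'
#' @param marker_calls output of \code{\link{call_markers}}.
#' @param chromosomes data.frame with \code{name}, \code{length}.
#' @param window_size window width in bp (>= 1000).
#' @return data.frame: chrom, start, end, n_hom, n_het, hom_fraction,
#'   hom_het_odds.
#' @export
window_homozygosity <- function(marker_calls, chromosomes,
                                window_size = 10000) {
  stopifnot(window_size >= 1000)
  out <- lapply(seq_len(nrow(chromosomes)), function(i) {
    ch <- chromosomes$name[i]; L <- chromosomes$length[i]
    ws <- seq(0, L - 1, by = window_size)
    we <- pmin(ws + window_size, L)
    mc <- marker_calls[marker_calls$chrom == ch &
                         marker_calls$state != "NOCALL", ]
    wi <- pmin(mc$pos %/% window_size + 1L, length(ws))
    f <- factor(wi, levels = seq_along(ws))
    n_hom <- as.integer(tapply(mc$state %in% c("HOM_A", "HOM_B"), f, sum,
                               default = 0L))
    n_het <- as.integer(tapply(mc$state == "HET", f, sum, default = 0L))
    tot <- n_hom + n_het
    data.frame(chrom = ch, start = ws, end = we, n_hom = n_hom,
               n_het = n_het,
               hom_fraction = ifelse(tot > 0, n_hom / tot, NA_real_),
               hom_het_odds = ifelse(n_het > 0, n_hom / n_het, NA_real_),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate windowed homozygosity across a mutant cohort
#'
#' A mutant counts toward a window when its homozygous fraction there is at
#' least \code{cutoff} (default 0.9), or — when per-mutant loss of
#' heterozygosity segments are supplied — when an LOH segment covers at
#' least half of the window. All mutants must share one window tiling;
#' the aggregation is invariant to mutant order.
#'
#' @param window_stats list of \code{\link{window_homozygosity}} outputs,
#'   one per mutant.
#' @param cutoff homozygous-fraction cutoff.
#' @param segments optional list of LOH segment data.frames (chrom, start,
#'   end, state), one per mutant.
#' @return data.frame: chrom, start, end, k (mutants with LOH), M (cohort
#'   size).
#' @export
aggregate_cohort <- function(window_stats, cutoff = 0.9, segments = NULL) {
  stopifnot(length(window_stats) >= 1)
  ref <- window_stats[[1]][, c("chrom", "start", "end")]
  k <- integer(nrow(ref))
  for (m in seq_along(window_stats)) {
    ws <- window_stats[[m]]
    if (!identical(ws[, c("chrom", "start", "end")], ref))
      stop_taqmap("mutant %d uses a different window tiling", m)
    hit <- !is.na(ws$hom_fraction) & ws$hom_fraction >= cutoff
    if (!is.null(segments)) {
      seg <- segments[[m]]
      seg <- seg[seg$state %in% c("HOM_A", "HOM_B"), , drop = FALSE]
      if (nrow(seg)) {
        for (s in seq_len(nrow(seg))) {
          same <- ref$chrom == seg$chrom[s]
          ov <- pmin(ref$end, seg$end[s]) - pmax(ref$start, seg$start[s])
          hit <- hit | (same & ov >= 0.5 * (ref$end - ref$start))
        }
      }
    }
    k <- k + hit
  }
  cbind(ref, data.frame(k = k, M = length(window_stats)))
}

#' Test windows for loss-of-heterozygosity hotspots
#'
#' The background LOH rate \code{p0} is the genome-wide mean of \code{k/M}
#' after excluding the top 5\% of windows (so true hotspots do not inflate
#' their own background); each window is then tested with the one-sided
#' binomial tail \eqn{P(X \ge k \mid M, p_0)}, corrected across windows by
#' Benjamini-Hochberg. Windows with \code{q <= alpha} are hotspots; adjacent
#' significant windows are merged into intervals. Note the formal test is
#' this package's addition — peak calling in the source experiments was
#' visual.
#'
#' @param agg output of \code{\link{aggregate_cohort}}.
#' @param alpha FDR level (default 0.05).
#' @param p0 optional fixed background rate; estimated when NULL.
#' @return object of class \code{hotspot_report}: \code{windows} (with p,
#'   q, hotspot columns), \code{hotspots} (merged intervals with min q),
#'   \code{p0}, \code{alpha}, \code{degenerate}.
#' @export
test_hotspots <- function(agg, alpha = 0.05, p0 = NULL) {
  M <- unique(agg$M)
  stopifnot(length(M) == 1, M >= 2)
  rate <- agg$k / agg$M
  degenerate <- length(unique(agg$k)) == 1
  if (is.null(p0)) {
    keep <- rate <= quantile(rate, 0.95)
    p0 <- mean(rate[keep])
    # stabilizer: never report an exactly-zero background
    p0 <- max(p0, 0.5 / (M * nrow(agg)))
  }
  p <- pbinom(agg$k - 1, M, p0, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  agg$p <- p; agg$q <- q
  agg$hotspot <- !degenerate & q <= alpha & agg$k > 0

  hs <- agg[agg$hotspot, , drop = FALSE]
  merged <- NULL
  if (nrow(hs)) {
    hs <- hs[order(hs$chrom, hs$start), ]
    grp <- cumsum(c(TRUE, hs$chrom[-1] != hs$chrom[-nrow(hs)] |
                      hs$start[-1] != hs$end[-nrow(hs)]))
    merged <- do.call(rbind, lapply(split(hs, grp), function(g)
      data.frame(chrom = g$chrom[1], start = min(g$start), end = max(g$end),
                 min_q = min(g$q), max_k = max(g$k),
                 stringsAsFactors = FALSE)))
    rownames(merged) <- NULL
  } else {
    merged <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), min_q = numeric(),
                         max_k = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(windows = agg, hotspots = merged, p0 = p0, alpha = alpha,
                 degenerate = degenerate),
            class = "hotspot_report")
}

#' @export
print.hotspot_report <- function(x, ...) {
  cat(sprintf("hotspot_report: %d window(s), background p0 = %.4f, alpha = %g\n",
              nrow(x$windows), x$p0, x$alpha))
  if (x$degenerate) cat("  degenerate background: all windows identical\n")
  cat(sprintf("  %d merged hotspot interval(s)\n", nrow(x$hotspots)))
  if (nrow(x$hotspots)) print(x$hotspots)
  invisible(x)
}

#' Tabulate aneuploidy frequency across a cohort
#'
#' Counts whole-chromosome gains and losses per chromosome and parental
#' homolog over the cohort's called (or truth) event tables.
#'
#' @param event_tables list of event data.frames (one per mutant) with
#'   columns kind, chrom, homolog.
#' @param chromosomes optional chromosome data.frame to fix row order.
#' @return data.frame: chrom, homolog, type (gain / loss), count.
#' @export
aneuploidy_frequency <- function(event_tables, chromosomes = NULL) {
  ev <- do.call(rbind, lapply(event_tables, function(e)
    e[e$kind %in% c("ANEUPLOIDY_LOSS", "ANEUPLOIDY_GAIN"),
      c("kind", "chrom", "homolog"), drop = FALSE]))
  chroms <- if (!is.null(chromosomes)) chromosomes$name
            else sort(unique(ev$chrom))
  grid <- expand.grid(chrom = chroms, homolog = c("A", "B"),
                      type = c("gain", "loss"), stringsAsFactors = FALSE)
  grid$count <- 0L
  if (!is.null(ev) && nrow(ev)) {
    ev$type <- ifelse(ev$kind == "ANEUPLOIDY_GAIN", "gain", "loss")
    tab <- table(paste(ev$chrom, ev$homolog, ev$type))
    key <- paste(grid$chrom, grid$homolog, grid$type)
    hit <- match(key, names(tab))
    grid$count <- ifelse(is.na(hit), 0L, as.integer(tab[hit]))
  }
  grid
}

#' Genes overlapping loss-of-heterozygosity hotspots
#'
#' Ranks genes overlapping any merged hotspot interval by the hotspot's q
#' value, then by decreasing overlap fraction of the gene, with a
#' chromosome/coordinate tie-break for a deterministic ordering.
#'
#' @param report a \code{\link{test_hotspots}} result.
#' @param annotation data.frame with gene, chrom, start, end (0-based
#'   half-open), or a GRanges with a \code{gene} metadata column.
#' @return data.frame: gene, chrom, start, end, q, overlap_fraction.
#' @export
candidate_genes <- function(report, annotation) {
  stopifnot(inherits(report, "hotspot_report"))
  if (methods::is(annotation, "GRanges")) {
    annotation <- data.frame(
      gene = S4Vectors::mcols(annotation)$gene,
      chrom = as.character(GenomicRanges::seqnames(annotation)),
      start = BiocGenerics::start(annotation) - 1L,
      end = BiocGenerics::end(annotation),
      stringsAsFactors = FALSE)
  }
  if (nrow(annotation) == 0) {
    warning("empty gene annotation; no candidates reported")
    return(data.frame(gene = character(), chrom = character(),
                      start = numeric(), end = numeric(), q = numeric(),
                      overlap_fraction = numeric(), stringsAsFactors = FALSE))
  }
  hs <- report$hotspots
  rows <- list()
  for (i in seq_len(nrow(hs))) {
    same <- annotation$chrom == hs$chrom[i]
    ov <- pmin(annotation$end, hs$end[i]) - pmax(annotation$start, hs$start[i])
    hit <- which(same & ov > 0)
    for (g in hit) {
      rows[[length(rows) + 1]] <- data.frame(
        gene = annotation$gene[g], chrom = annotation$chrom[g],
        start = annotation$start[g], end = annotation$end[g],
        q = hs$min_q[i],
        overlap_fraction = ov[g] / (annotation$end[g] - annotation$start[g]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene = character(), chrom = character(),
                      start = numeric(), end = numeric(), q = numeric(),
                      overlap_fraction = numeric(), stringsAsFactors = FALSE))
  # a gene hit by several hotspots keeps its best entry
  out <- out[order(out$q, -out$overlap_fraction, out$chrom, out$start), ]
  out <- out[!duplicated(out$gene), ]
  rownames(out) <- NULL
  out
}
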