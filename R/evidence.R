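#' Simulate sequencing evidence for a rearranged genotype
#'
#' Produces the evidence tracks a short-read workflow would yield for one
#' mutant: per-marker parental allele depths, per-window total and
#' per-parental-allele coverage, and junction-supporting read records.
#'
#' Depth model: each homolog copy contributes reads at rate
#' \code{mean_depth/2 * copy_number}; those reads carry the parental allele
#' the homolog holds at the marker, so loss of heterozygosity shows up as all
#' depth on one allele while total coverage is preserved, and copy-number
#' change shows up in total coverage. With \code{dispersion = 0} depths equal
#' their expectations exactly (noiseless mode); \code{dispersion = 1} draws
#' independent Poisson depths per homolog; \code{dispersion > 1} uses a
#' negative binomial with variance \code{dispersion * mean}. Window coverage
#' is the window mean of the same marker draws (expected values where a
#' window contains no marker). Every true junction emits supporting reads at
#' \code{junction_support_rate} per sequenced fragment; a Poisson background
#' of spurious low-support junctions is added at \code{false_junction_rate}
#' per genome (none in noiseless mode).
#'
#' @param gt a \code{taq_genotype}.
#' @param mean_depth mean total read depth at a diploid site (default 50).
#' @param dispersion 0 = noiseless, 1 = Poisson, >1 = overdispersed.
#' @param junction_support_rate expected fraction of \code{mean_depth}
#'   supporting a true junction.
#' @param false_junction_rate expected count of spurious junctions per genome.
#' @param window_size coverage window width in bp (default 10000).
#' @param seed integer seed.
#' @return an object of class \code{evidence_bundle} with components
#'   \code{marker_depths}, \code{window_coverage}, \code{junctions},
#'   \code{chromosomes}, \code{mean_depth}, \code{window_size}.
#' @export
simulate_evidence <- function(gt, mean_depth = 50, dispersion = 1,
                              junction_support_rate = 0.3,
                              false_junction_rate = 0.5,
                              window_size = 10000, seed = 1) {
  stopifnot(inherits(gt, "taq_genotype"))
  assert_scalar_number(mean_depth, "mean_depth", 0, Inf, strict_lower = TRUE)
  assert_scalar_number(dispersion, "dispersion", 0, Inf)
  chroms <- gt$genome$chromosomes

  draw_depth <- function(mu) {
    if (dispersion == 0) return(mu)
    if (dispersion <= 1) return(rpois(length(mu), mu))
    out <- numeric(length(mu))
    pos <- mu > 0
    out[pos] <- rnbinom(sum(pos), size = mu[pos] / (dispersion - 1),
                        mu = mu[pos])
    out
  }

  with_seed(seed, {
    marker_depths <- vector("list", nrow(chroms))
    window_cov <- vector("list", nrow(chroms))
    names(marker_depths) <- names(window_cov) <- chroms$name

    for (i in seq_len(nrow(chroms))) {
      ch <- chroms$name[i]; L <- chroms$length[i]
      mk <- gt$genome$markers[[ch]]
      pos <- mk$pos
      dA <- numeric(length(pos)); dB <- numeric(length(pos))
      for (h in c("A", "B")) {
        tr <- gt$cn[[ch]][[h]]
        cnv <- if (length(pos)) cn_at(tr, pos) else numeric(0)
        d <- draw_depth(mean_depth / 2 * cnv)
        st <- gt$states[[ch]][[h]]
        isA <- st == "A"
        dA[isA] <- dA[isA] + d[isA]
        dB[!isA] <- dB[!isA] + d[!isA]
      }
      marker_depths[[ch]] <- data.frame(pos = pos, a_A = mk$a_A, a_B = mk$a_B,
                                        depth_A = dA, depth_B = dB,
                                        stringsAsFactors = FALSE)

      ws <- seq(0, L - 1, by = window_size)
      we <- pmin(ws + window_size, L)
      wi <- if (length(pos)) pmin(pos %/% window_size + 1L, length(ws))
            else integer(0)
      n_w <- length(ws)
      tot <- numeric(n_w); wA <- numeric(n_w); wB <- numeric(n_w)
      cnt <- tabulate(wi, n_w)
      if (length(pos)) {
        f <- factor(wi, levels = seq_len(n_w))
        wA <- vapply(split(dA, f), sum, 0)
        wB <- vapply(split(dB, f), sum, 0)
        wA <- ifelse(cnt > 0, wA / pmax(cnt, 1), NA_real_)
        wB <- ifelse(cnt > 0, wB / pmax(cnt, 1), NA_real_)
      } else {
        wA[] <- NA_real_; wB[] <- NA_real_
      }
      # windows without markers: fall back to expected coverage at midpoint
      mid <- (ws + we) / 2
      expA <- mean_depth / 2 * cn_at(gt$cn[[ch]]$A, mid)
      expB <- mean_depth / 2 * cn_at(gt$cn[[ch]]$B, mid)
      # parental-allele expectation: homolog A carries allele A unless its
      # state says otherwise; use marker states when present, cn otherwise
      na_w <- is.na(wA)
      wA[na_w] <- expA[na_w]; wB[na_w] <- expB[na_w]
      tot <- wA + wB
      window_cov[[ch]] <- data.frame(start = ws, end = we, total = tot,
                                     depth_A = wA, depth_B = wB)
    }

    jn <- gt$junctions
    if (nrow(jn)) {
      mu <- mean_depth * junction_support_rate
      jn$support <- if (dispersion == 0) round(mu) else rpois(nrow(jn), mu)
      jn <- jn[jn$support > 0, , drop = FALSE]
    } else jn$support <- numeric(0)
    if (dispersion > 0 && false_junction_rate > 0) {
      n_false <- rpois(1, false_junction_rate)
      if (n_false > 0) {
        ci <- sample.int(nrow(chroms), n_false, replace = TRUE)
        cj <- sample.int(nrow(chroms), n_false, replace = TRUE)
        fj <- data.frame(
          chrom1 = chroms$name[ci],
          pos1 = floor(runif(n_false) * chroms$length[ci]),
          side1 = sample(c("left", "right"), n_false, replace = TRUE),
          chrom2 = chroms$name[cj],
          pos2 = floor(runif(n_false) * chroms$length[cj]),
          side2 = sample(c("left", "right"), n_false, replace = TRUE),
          support = sample(1:3, n_false, replace = TRUE),
          stringsAsFactors = FALSE)
        jn <- rbind(jn, fj)
      }
    }
    rownames(jn) <- NULL

    structure(list(marker_depths = marker_depths,
                   window_coverage = window_cov,
                   junctions = jn,
                   chromosomes = chroms,
                   mean_depth = mean_depth,
                   window_size = window_size),
              class = "evidence_bundle")
  })
}

#' @export
print.evidence_bundle <- function(x, ...) {
  cat(sprintf("evidence_bundle: %d chromosome(s), %d markers, depth %g, %d junction record(s)\n",
              nrow(x$chromosomes),
              sum(vapply(x$marker_depths, nrow, 0L)),
              x$mean_depth, nrow(x$junctions)))
  invisible(x)
}
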