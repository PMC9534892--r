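#' Flocculation score from optical densities
#'
#' The fraction of cells in flocs: \code{1 - OD(P)/OD(T)}, where OD(P) is
#' the OD600 of the planktonic supernatant after settling and OD(T) that of
#' the fully dispersed culture. Scores are clipped to \code{[0, 1]}; raw
#' measurements with \code{od_p > od_t} are allowed but flagged.
#'
#' @param od_p OD600 of the planktonic supernatant (>= 0).
#' @param od_t OD600 of the dispersed total culture (> 0).
#' @return numeric score(s) in \code{[0, 1]}, with attribute
#'   \code{"flagged"} (logical) marking clipped measurements.
#' @examples
#' flocculation_score(0.25, 1.0)  # 0.75
#' @export
flocculation_score <- function(od_p, od_t) {
  if (any(od_t <= 0)) stop_taqmap("od_t must be positive")
  if (any(od_p < 0)) stop_taqmap("od_p must be non-negative")
  raw <- 1 - od_p / od_t
  flagged <- od_p > od_t
  if (any(flagged))
    warning(sprintf("%d measurement(s) with od_p > od_t clipped to 0",
                    sum(flagged)))
  score <- pmin(pmax(raw, 0), 1)
  attr(score, "flagged") <- flagged
  score
}

#' Welch's unequal-variance t-test
#'
#' Direct evaluation of the Welch statistic
#' \eqn{t = (\bar a - \bar b)/\sqrt{s_a^2/n_a + s_b^2/n_b}} with the
#' Welch-Satterthwaite degrees of freedom and a two-sided p value from the
#' t distribution — the comparison used for phenotype scores and expression
#' levels against the ancestral strain.
#'
#' @param a,b numeric samples, each with at least 2 values; at least one
#'   must have nonzero variance.
#' @return list(t, df, p).
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop_taqmap("each sample needs n >= 2")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2,
                                        p = 1))
    stop_taqmap("both samples have zero variance")
  }
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

#' Significance stars for a p value
#'
#' The figure-legend convention: \code{***} p < 0.001, \code{**} p < 0.01,
#' \code{*} p < 0.05, \code{""} otherwise.
#' @param p p value(s).
#' @return character vector.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, \code{dCt = ct_target - ct_reference} (reference is the
#' housekeeping gene, e.g. ACT1); per strain the fold change relative to the
#' control strain is \code{2^-(mean dCt_strain - mean dCt_control)}, so the
#' control is 1 by construction. Replicates lacking a reference Ct are
#' dropped with a warning. The result is invariant to adding a constant to
#' all Ct values.
#'
#' @param samples data.frame with columns strain, ct_target, ct_reference
#'   (one row per replicate).
#' @param control control strain name (must be present).
#' @return data.frame: strain, n, mean_dct, fold.
#' @export
relative_expression <- function(samples, control) {
  stopifnot(all(c("strain", "ct_target", "ct_reference") %in% names(samples)))
  bad <- is.na(samples$ct_reference) | is.na(samples$ct_target)
  if (any(bad)) {
    warning(sprintf("%d replicate(s) dropped for missing Ct", sum(bad)))
    samples <- samples[!bad, , drop = FALSE]
  }
  if (!control %in% samples$strain)
    stop_taqmap("control strain '%s' not present", control)
  if (any(samples$ct_target <= 0 | samples$ct_reference <= 0) ||
      any(!is.finite(samples$ct_target) | !is.finite(samples$ct_reference)))
    stop_taqmap("Ct values must be positive and finite")
  dct <- samples$ct_target - samples$ct_reference
  mean_dct <- tapply(dct, samples$strain, mean)
  ddct <- mean_dct - mean_dct[[control]]
  data.frame(strain = names(mean_dct),
             n = as.integer(table(samples$strain)[names(mean_dct)]),
             mean_dct = as.numeric(mean_dct),
             fold = 2^(-as.numeric(ddct)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Replicate summary: mean, sample SD, n
#'
#' Sample SD uses the n-1 denominator and is NA for a single replicate.
#'
#' @param x numeric replicate values (n >= 1).
#' @return list(mean, sd, n).
#' @export
score_summary <- function(x) {
  stopifnot(length(x) >= 1)
  list(mean = mean(x), sd = if (length(x) > 1) sd(x) else NA_real_,
       n = length(x))
}
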