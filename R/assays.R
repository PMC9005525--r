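# Closed-form immune-assay scores and the small-sample paired comparisons
# used on them.

#' Treg percent suppression
#'
#' `100 - 100 * pct_with_treg / pct_without_treg`, where the percentages are
#' of proliferating (or cytokine-secreting) responder cells with and without
#' Tregs. Negative values (enhancement) are returned as-is.
#'
#' @param pct_with_treg percentage (0-100) with Tregs present.
#' @param pct_without_treg percentage (0-100) without Tregs; must be > 0.
#' @return percent suppression (may be negative).
#' @export
percent_suppression <- function(pct_with_treg, pct_without_treg) {
  if (!all(pct_with_treg >= 0 & pct_with_treg <= 100) ||
      !all(pct_without_treg >= 0 & pct_without_treg <= 100)) {
    stopf("percentages must be in [0, 100]")
  }
  if (any(pct_without_treg == 0)) {
    stopf("percent suppression undefined when pct_without_treg is 0")
  }
  100 - 100 * pct_with_treg / pct_without_treg
}

#' Bead-standardized migration ratio
#'
#' Migrated-cell event counts are standardized by the bead events spiked
#' into each tube; the ratio is
#' `(events_chemokine / beads_chemokine) / (events_control / beads_control)`.
#' The ratio is invariant to rescaling both bead counts by a common factor.
#'
#' @param events_chemokine,events_control migrated-cell event counts.
#' @param beads_chemokine,beads_control bead event counts (> 0).
#' @return the migration ratio.
#' @export
migration_ratio <- function(events_chemokine, events_control,
                            beads_chemokine, beads_control) {
  if (any(c(events_chemokine, events_control) < 0)) {
    stopf("event counts must be nonnegative")
  }
  if (any(c(beads_chemokine, beads_control) <= 0)) {
    stopf("bead counts must be positive")
  }
  if (any(events_control == 0)) {
    stopf("migration ratio undefined when events_control is 0")
  }
  (events_chemokine / beads_chemokine) / (events_control / beads_control)
}

#' Clinical disease activity index (CDAI)
#'
#' Total = patient global assessment (0-10) + physician global assessment
#' (0-10) + swollen joint count (0-28) + tender joint count (0-28); the
#' attainable maximum is therefore 76. Activity bands use half-open
#' intervals: remission \[0, 2.8\], low (2.8, 10.0\], moderate (10.0, 22.0\],
#' high (22, Inf).
#'
#' @param patient_global,physician_global global assessments, 0-10.
#' @param swollen,tender 28-joint counts, 0-28.
#' @return a `cdai_score` list with `total` and `band`.
#' @export
cdai <- function(patient_global, physician_global, swollen, tender) {
  chk <- function(x, lo, hi, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
      stopf("%s must be in [%g, %g]", nm, lo, hi)
    }
  }
  chk(patient_global, 0, 10, "patient_global")
  chk(physician_global, 0, 10, "physician_global")
  chk(swollen, 0, 28, "swollen")
  chk(tender, 0, 28, "tender")
  total <- patient_global + physician_global + swollen + tender
  band <- if (total <= 2.8) "remission" else if (total <= 10) "low" else
    if (total <= 22) "moderate" else "high"
  structure(list(patient_global = patient_global,
                 physician_global = physician_global,
                 swollen = swollen, tender = tender,
                 total = total, band = band),
            class = "cdai_score")
}

#' @export
print.cdai_score <- function(x, ...) {
  cat(sprintf("CDAI %.1f (%s)\n", x$total, x$band))
  invisible(x)
}

# Exact Wilcoxon signed-rank p by enumeration of all 2^n sign assignments
# over midranks of |d| (ties handled exactly). W+ = sum of ranks with
# positive sign.
signed_rank_exact <- function(d, alternative) {
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- matrix(bitwAnd(rep(0:(2^n - 1), each = n),
                          2^(seq_len(n) - 1)) > 0, nrow = n)
  ws <- colSums(signs * r)
  switch(alternative,
         greater = mean(ws >= w_obs - 1e-9),
         less = mean(ws <= w_obs + 1e-9),
         two.sided = min(1, 2 * min(mean(ws >= w_obs - 1e-9),
                                    mean(ws <= w_obs + 1e-9))))
}

signed_rank_normal <- function(d, alternative) {
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ew <- n * (n + 1) / 4
  ties <- table(r)
  varw <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- 0.5
  z_g <- (w - ew - cc) / sqrt(varw)
  z_l <- (w - ew + cc) / sqrt(varw)
  switch(alternative,
         greater = pnorm(z_g, lower.tail = FALSE),
         less = pnorm(z_l),
         two.sided = {
           z <- (w - ew - sign(w - ew) * cc) / sqrt(varw)
           min(1, 2 * pnorm(-abs(z)))
         })
}

#' Paired comparison: Wilcoxon signed-rank or paired t test
#'
#' Differences are `after - before`. For the Wilcoxon signed-rank test,
#' zero differences are dropped (classic Wilcoxon handling) and the p-value
#' is exact -- full enumeration of the 2^n sign assignments -- for n <= 15
#' untied-from-zero pairs, with a tie-corrected normal approximation above.
#' The paired t test is the standard two-sided closed form.
#'
#' @param before,after equal-length paired measurement vectors.
#' @param test `"wilcoxon_one_sided"` or `"t_paired_two_sided"`.
#' @param alternative direction for the one-sided Wilcoxon test, on
#'   `after - before`: `"less"` (default; a decrease after treatment) or
#'   `"greater"`.
#' @param exact_max largest n for which the exact Wilcoxon null is
#'   enumerated.
#' @return list with `statistic`, `p_value`, `n` (pairs used), `method`.
#' @export
paired_compare <- function(before, after,
                           test = c("wilcoxon_one_sided", "t_paired_two_sided"),
                           alternative = c("less", "greater"),
                           exact_max = 15) {
  test <- match.arg(test)
  if (length(before) != length(after)) stopf("before and after must have equal length")
  d <- after - before
  if (test == "wilcoxon_one_sided") {
    alternative <- match.arg(alternative)
    d <- d[d != 0]
    n <- length(d)
    if (n == 0) stopf("all differences are zero; Wilcoxon test degenerate")
    if (length(before) < 3) stopf("need at least 3 pairs")
    w <- sum(rank(abs(d))[d > 0])
    p <- if (n <= exact_max) signed_rank_exact(d, alternative)
    else signed_rank_normal(d, alternative)
    list(statistic = w, p_value = p, n = n,
         method = sprintf("Wilcoxon signed-rank, one-sided (%s), %s",
                          alternative,
                          if (n <= exact_max) "exact" else "normal approximation"))
  } else {
    n <- length(d)
    if (n < 2) stopf("need at least 2 pairs")
    if (sd(d) == 0) {
      return(list(statistic = NA_real_, p_value = 1, n = n,
                  method = "paired t test, two-sided (degenerate: zero-variance differences)"))
    }
    tstat <- mean(d) / (sd(d) / sqrt(n))
    p <- 2 * pt(-abs(tstat), df = n - 1)
    list(statistic = tstat, p_value = p, n = n,
         method = "paired t test, two-sided")
  }
}
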