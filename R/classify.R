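# Synoptic trend classification: combine per-group medians, permutation
# verdicts and Hettmansperger-Norton results into interpretable labels.

#' Strength band of a correlation magnitude
#'
#' Bands: negligible `|r| < 0.2`, weak `[0.2, 0.4)`, medium `[0.4, 0.6)`,
#' strong `>= 0.6` (the medium-strong boundary of 0.4 marks correlations
#' considered clinically relevant).
#'
#' @param r Numeric vector of correlations.
#' @return Character vector of band labels.
#' @export
strength_band <- function(r) {
  cut(abs(r), breaks = c(0, 0.2, 0.4, 0.6, 1),
      labels = c("negligible", "weak", "medium", "strong"),
      include.lowest = TRUE, right = FALSE)
}

endpoint_label <- function(median_r, perm_p, alpha) {
  if (perm_p >= alpha) "~0" else if (median_r > 0) "+" else "-"
}

#' Classify monotonic and umbrella trends per comparison
#'
#' For each of the 14 comparisons: the monotonic label reports a
#' significant increasing or decreasing pattern (whichever
#' Hettmansperger-Norton p-value is smaller, if below `alpha`), with the
#' Nt and Ht endpoints described as `+`, `-` or `~0` using the within-group
#' permutation verdicts; the umbrella label is `concave` or `convex` when
#' the corresponding test is significant (larger z wins if both),
#' otherwise `none`; the strongest group is the argmax of the absolute
#' within-group medians (`tie` when equal), with the strength band of the
#' strongest median.
#'
#' @param medians Numeric matrix `comparison x scope` of ensemble medians
#'   (as from [ensemble_median()]); group columns `Nt`, `preHt`, `Ht` used.
#' @param perm_p Numeric matrix `comparison x scope` of permutation
#'   p-values.
#' @param hn List per comparison: named list of `hn_trend_test` results for
#'   the four patterns of [trend_scores()].
#' @param alpha Significance level (default 0.05).
#' @return Data frame, one row per comparison: `comparison`, `monotonic`,
#'   `monotonic_p`, `umbrella`, `umbrella_p`, `strongest`, `band`, plus the
#'   endpoint labels `nt_end`, `ht_end`.
#' @export
classify_trends <- function(medians, perm_p, hn, alpha = 0.05) {
  comps <- rownames(medians)
  groups <- sap_groups()
  out <- lapply(comps, function(cm) {
    med <- medians[cm, groups]
    h <- hn[[cm]]
    # monotonic
    pm <- c(increasing = h$increasing$p_value, decreasing = h$decreasing$p_value)
    mono <- if (min(pm) < alpha) names(pm)[which.min(pm)] else "none"
    nt_end <- endpoint_label(med["Nt"], perm_p[cm, "Nt"], alpha)
    ht_end <- endpoint_label(med["Ht"], perm_p[cm, "Ht"], alpha)
    # umbrella
    pu <- c(concave = h$concave$p_value, convex = h$convex$p_value)
    zu <- c(concave = h$concave$z, convex = h$convex$z)
    sig_u <- pu < alpha
    umb <- if (!any(sig_u)) "none" else names(zu)[sig_u][which.max(zu[sig_u])]
    # strongest group (never silently break an exact tie)
    am <- abs(med)
    top <- which(am == max(am))
    strongest <- if (length(top) > 1L) "tie" else groups[top]
    data.frame(comparison = cm,
               monotonic = mono,
               monotonic_p = unname(min(pm)),
               nt_end = nt_end, ht_end = ht_end,
               umbrella = umb,
               umbrella_p = unname(min(pu)),
               strongest = strongest,
               band = as.character(strength_band(max(am))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
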