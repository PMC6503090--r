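# Stratified balanced bootstrap: plan construction and per-replicate
# recomputation of adjustment, ANSI and Winsorized correlations.

#' Build a stratified (balanced) bootstrap plan
#'
#' For each stratum of size `m`, the balanced scheme concatenates `B` copies
#' of the stratum's subject indices, applies one uniform random permutation
#' to the `m * B` entries, and cuts the result into `B` consecutive blocks
#' of size `m`; block `b` is replicate `b`'s draw for that stratum. Every
#' replicate therefore has exactly the original stratum counts, and across
#' all `B` replicates every subject appears exactly `B` times.
#'
#' With `balanced = FALSE` an ordinary stratified bootstrap is drawn
#' (independent within-stratum resampling with replacement per replicate);
#' it preserves stratum counts but not the per-subject balance, and is
#' provided for comparing simulation error.
#'
#' @param stratum_labels Character/factor vector, one label per subject.
#' @param B Number of replicates (>= 1).
#' @param seed RNG seed for the plan.
#' @param balanced Use the balanced scheme (default `TRUE`).
#' @return Object of class `bootstrap_plan`: list with `index` (integer
#'   matrix `n x B`, column `b` = subject rows of replicate `b`), `B`,
#'   `seed`, `balanced` and `stratum_labels`.
#' @export
balanced_stratified_plan <- function(stratum_labels, B, seed, balanced = TRUE) {
  if (B < 1L) bt_stop("B must be >= 1", "barotrend_param_error")
  if (anyNA(stratum_labels)) {
    bt_stop("every subject needs a stratum label", "barotrend_config_error")
  }
  f <- factor(stratum_labels)
  if (any(tabulate(f, nlevels(f)) == 0L)) {
    bt_stop("empty stratum in plan", "barotrend_config_error")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(f)
  index <- matrix(NA_integer_, n, B)
  for (lev in levels(f)) {
    rows <- which(f == lev)
    m <- length(rows)
    draw <- if (balanced) {
      matrix(rep(rows, B)[sample.int(m * B)], nrow = m)
    } else {
      matrix(rows[sample.int(m, m * B, replace = TRUE)], nrow = m)
    }
    index[rows, ] <- draw
  }
  structure(list(index = index, B = as.integer(B), seed = seed,
                 balanced = balanced, stratum_labels = as.character(f)),
            class = "bootstrap_plan")
}

# fast per-replicate engine: adjusted correlations of alpha vs 13 proxies +
# ANSI, in the 4 scopes, for one row index vector
replicate_wincorr <- function(V, gender, age_class, group, idx, gamma) {
  g <- group[idx]
  f <- cell_id(gender[idx], age_class[idx])
  A <- adjust_matrix(V[idx, , drop = FALSE], f)
  comps <- ansi_components()
  ansi <- pct_rank((pct_rank(A[, comps[1]]) + pct_rank(A[, comps[2]]) +
                      pct_rank(A[, comps[3]])) / 3)
  Y <- cbind(A[, proxy_names(), drop = FALSE], ansi = ansi)
  x <- A[, "alpha"]
  out <- matrix(NA_real_, ncol(Y), length(analysis_scopes()),
                dimnames = list(comparison_names(), analysis_scopes()))
  for (sc in analysis_scopes()) {
    rows <- if (sc == "overall") seq_along(x) else which(g == sc)
    xs <- x[rows]
    wx <- winsorize(xs, gamma)
    if (sd(wx) == 0) next  # whole scope degenerate; cells stay flagged
    for (j in seq_len(ncol(Y))) {
      wy <- winsorize(Y[rows, j], gamma)
      if (sd(wy) == 0) next
      out[j, sc] <- max(-1, min(1, cor(wx, wy)))
    }
  }
  out
}

#' Bootstrap ensemble of Winsorized correlations
#'
#' For every replicate of the plan the resampled cohort is materialized, the
#' gender x age-class adjustment is refitted on the replicate, ANSI is
#' recomputed on the replicate, and the gamma-Winsorized correlation of
#' adjusted alpha with each of the 14 comparisons (13 adjusted proxies +
#' ANSI) is computed overall and within each SAP group (group membership
#' travels with the resampled subjects; because groups are unions of strata,
#' per-replicate group counts are exact).
#'
#' Cells whose winsorized variance is degenerate within a replicate scope
#' are flagged `NA` and counted in the `flagged` attribute; they are
#' excluded from aggregation.
#'
#' @param cohort Cohort data frame.
#' @param plan A `bootstrap_plan` built on this cohort's strata.
#' @param gamma Winsorizing proportion (default 0.1).
#' @return Object of class `bootstrap_ensemble`: numeric array
#'   `B x 14 x 4` with dimnames (replicate, comparison, scope), attributes
#'   `gamma`, `seed`, `B`, `flagged` (count of degenerate cells).
#' @export
bootstrap_wincorr_ensemble <- function(cohort, plan, gamma = 0.1) {
  if (!identical(plan$stratum_labels, as.character(cohort$stratum))) {
    bt_stop("plan was not built on this cohort's strata", "barotrend_config_error")
  }
  V <- as.matrix(cohort[c("alpha", proxy_names())])
  B <- plan$B
  ens <- array(NA_real_, dim = c(B, length(comparison_names()),
                                 length(analysis_scopes())),
               dimnames = list(NULL, comparison_names(), analysis_scopes()))
  for (b in seq_len(B)) {
    ens[b, , ] <- replicate_wincorr(V, cohort$gender, cohort$age_class,
                                    cohort$group, plan$index[, b], gamma)
  }
  structure(ens, gamma = gamma, seed = plan$seed, B = B,
            flagged = sum(is.na(ens)), class = "bootstrap_ensemble")
}

#' Componentwise median of a bootstrap ensemble
#'
#' The median (midpoint convention for even counts) over replicates, per
#' comparison and scope, excluding flagged cells; a cell with no valid
#' replicate raises an error.
#'
#' @param ensemble A `bootstrap_ensemble`.
#' @return Numeric matrix `14 x 4` (comparison x scope).
#' @export
ensemble_median <- function(ensemble) {
  out <- apply(unclass(ensemble), c(2, 3), function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    median(v)
  })
  if (anyNA(out)) {
    bt_stop("ensemble cell with no valid replicate", "barotrend_degenerate_error")
  }
  out
}
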