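# Age/gender adjustment by saturated two-way ANOVA residuals, and the
# composite ANSI index.

# Percent rank on 0-100, midrank convention: 100 * (rank - 0.5) / n.
# A full tie maps every subject to exactly 50.
pct_rank <- function(x) 100 * (rank(x) - 0.5) / length(x)

cell_id <- function(gender, age_class) paste(gender, age_class, sep = ":")

#' Fit a gender x age-class cell-means model
#'
#' The saturated two-way ANOVA model (main effects of gender and age class
#' plus their interaction) fits each cell's mean exactly, so the residual of
#' a subject is its value minus its cell's mean. No design matrix is needed.
#'
#' @param values Numeric vector of a proxy.
#' @param gender,age_class Categorical vectors, same length as `values`.
#' @return Object of class `cell_means_model`: list with `means` (named
#'   vector of cell means), `grand_mean`, and the cell levels.
#' @export
fit_cell_means <- function(values, gender, age_class) {
  n <- length(values)
  if (length(gender) != n || length(age_class) != n) {
    bt_stop("values, gender and age_class must have equal length",
            "barotrend_param_error")
  }
  f <- cell_id(gender, age_class)
  m <- tapply(values, f, mean)
  means <- setNames(as.vector(m), dimnames(m)[[1]])
  structure(list(means = means, grand_mean = mean(values)),
            class = "cell_means_model")
}

#' Fitted values of a cell-means model
#' @param object A `cell_means_model`.
#' @param gender,age_class Cells to predict for.
#' @param ... Unused.
#' @return Numeric vector of cell means; an unseen cell raises an error of
#'   class `barotrend_missing_cell_error`.
#' @export
predict.cell_means_model <- function(object, gender, age_class, ...) {
  f <- cell_id(gender, age_class)
  fit <- object$means[f]
  if (anyNA(fit)) {
    bt_stop(sprintf("no fitted mean for cell(s): %s",
                    paste(unique(f[is.na(fit)]), collapse = ", ")),
            "barotrend_missing_cell_error")
  }
  unname(fit)
}

# residual matrix of V (n x p) against one cell factor; vectorized via rowsum
adjust_matrix <- function(V, cell_f) {
  f <- factor(cell_f)
  counts <- tabulate(f, nbins = nlevels(f))
  means <- rowsum(V, f, reorder = TRUE) / counts
  V - means[as.integer(f), , drop = FALSE]
}

#' Compute the composite ANSI index
#'
#' ANSI synthesizes three proxies (mean RR, total RR power, rest-stand
#' change in normalized LF). Each component is first freed of age and gender
#' effects (cell-means residuals), converted to a percentile rank (midrank,
#' 0-100 scale), the three ranks are averaged with equal weight, and the
#' average is re-expressed as a percentile rank on 0-100.
#'
#' @param cohort Data frame holding the component columns plus `gender` and
#'   `age_class`.
#' @return Numeric vector of ANSI values in \[0, 100\].
#' @export
compute_ansi <- function(cohort) {
  comps <- ansi_components()
  if (!all(comps %in% names(cohort))) {
    bt_stop("cohort misses ANSI component columns", "barotrend_param_error")
  }
  if (nrow(cohort) < 2L) bt_stop("ANSI undefined for n < 2", "barotrend_param_error")
  f <- cell_id(cohort$gender, cohort$age_class)
  A <- adjust_matrix(as.matrix(cohort[comps]), f)
  m <- (pct_rank(A[, 1]) + pct_rank(A[, 2]) + pct_rank(A[, 3])) / 3
  pct_rank(m)
}

#' Adjust a cohort for age and gender effects
#'
#' Replaces alpha and the 13 proxies by their residuals from per-variable
#' gender x age-class cell-means fits over the whole cohort, and appends
#' ANSI. Demographic, stratum and group columns are carried over unchanged.
#'
#' @param cohort A cohort data frame (see [generate_cohort()]).
#' @return Data frame with columns `subject_id`, `gender`, `age_class`,
#'   `sap_clinic`, `stratum`, `group`, then `alpha_adj`, `<proxy>_adj` for
#'   the 13 proxies, and `ansi`.
#' @export
adjust_cohort <- function(cohort) {
  vars <- c("alpha", proxy_names())
  if (!all(vars %in% names(cohort))) {
    bt_stop("cohort misses variable columns", "barotrend_param_error")
  }
  f <- cell_id(cohort$gender, cohort$age_class)
  A <- adjust_matrix(as.matrix(cohort[vars]), f)
  out <- cohort[intersect(c("subject_id", "age", "gender", "age_class",
                            "sap_clinic", "stratum", "group"), names(cohort))]
  colnames(A) <- paste0(vars, "_adj")
  out <- cbind(out, as.data.frame(A))
  out$ansi <- compute_ansi(cohort)
  out
}
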