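# Synthetic cohort generator: demographic scaffold from the design, a
# single-factor correlation structure per SAP group, and optional
# contamination with outlying subjects.

#' Draw standardized scores with a single-factor correlation structure
#'
#' Column 1 is the latent alpha factor (standard normal); proxy `i` is
#' `L_i * alpha + sqrt(1 - L_i^2) * eps_i` with independent standard normal
#' noise, so the population correlation of alpha with proxy `i` is exactly
#' `L_i` and between proxies `i`, `j` is `L_i * L_j` -- a joint correlation
#' matrix that is positive semi-definite by construction.
#'
#' @param loadings Numeric vector in \[-1, 1\], one per proxy.
#' @param n Number of rows (>= 2).
#' @return Numeric matrix `n x (k+1)`; column names `alpha`, then the names
#'   of `loadings` (or `p1..pk`).
#' @export
sample_single_factor <- function(loadings, n) {
  if (any(abs(loadings) > 1) || anyNA(loadings)) {
    bt_stop("loadings must lie in [-1, 1]", "barotrend_calibration_error")
  }
  if (n < 2L) bt_stop("n must be >= 2", "barotrend_param_error")
  k <- length(loadings)
  a <- rnorm(n)
  E <- matrix(rnorm(n * k), nrow = n)
  X <- a %o% loadings + sweep(E, 2L, sqrt(1 - loadings^2), `*`)
  out <- cbind(alpha = a, X)
  colnames(out) <- c("alpha",
                     if (is.null(names(loadings))) paste0("p", seq_len(k))
                     else names(loadings))
  out
}

# named independent substreams derived from one master seed
spawn_seeds <- function(seed, streams) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, length(streams)), streams)
}

#' Generate a synthetic cohort
#'
#' Builds a cohort whose gender x age-class x group cell counts and SAP
#' stratum counts equal the design exactly. Clinic SAP is uniform within
#' each stratum's interval and ages are uniform integers within each class.
#' Within each SAP group, standardized (alpha, proxies) are drawn by
#' [sample_single_factor()] with that group's calibration loadings, rescaled
#' to each variable's location/scale and shifted by the additive
#' (gender, age-class) cell effect. A fraction of subjects is contaminated:
#' a random subset of their proxies is displaced by `contamination_scale`
#' standard deviations (random sign), emulating subjects with outlying
#' values on several but not all measures.
#'
#' @param design A `cohort_design` (default [default_design()]).
#' @param effects A `factor_effects` (default [default_effects()]).
#' @param calib A `correlation_calibration` (default [default_calibration()]).
#' @param contamination_fraction Proportion of contaminated subjects in
#'   \[0, 0.5) (default 0.01).
#' @param contamination_scale Displacement in SD units (default 6).
#' @param seed Master seed; three named substreams (demographics, factors,
#'   contamination) are derived from it so components are reproducible in
#'   isolation.
#' @return Data frame with columns `subject_id`, `age`, `gender`,
#'   `age_class`, `sap_clinic`, `stratum`, `group`, `alpha`, and the 13
#'   proxies; exactly `design$total_n` rows.
#' @export
#' @examples
#' co <- generate_cohort(seed = 1)
#' table(co$group)
generate_cohort <- function(design = default_design(),
                            effects = default_effects(),
                            calib = default_calibration(),
                            contamination_fraction = 0.01,
                            contamination_scale = 6,
                            seed = 1L) {
  validate_design(design)
  if (contamination_fraction < 0 || contamination_fraction >= 0.5) {
    bt_stop("contamination_fraction must lie in [0, 0.5)", "barotrend_param_error")
  }
  if (!all(sap_groups() %in% calib$group)) {
    bt_stop("calibration misses a SAP group", "barotrend_config_error")
  }
  seeds <- spawn_seeds(seed, c("demographics", "factors", "contamination"))
  vars <- c("alpha", proxy_names())
  sc <- effects$scales
  loc <- setNames(sc$location, sc$variable)[vars]
  scl <- setNames(sc$scale, sc$variable)[vars]

  # --- demographic scaffold, per group ---------------------------------------
  set.seed(seeds[["demographics"]])
  rows <- list()
  for (g in sap_groups()) {
    st <- design$strata[design$strata$group == g, , drop = FALSE]
    cc <- design$cell_counts[design$cell_counts$group == g, , drop = FALSE]
    n_g <- sum(st$count)
    stratum <- rep(st$stratum, st$count)
    sap <- unlist(lapply(seq_len(nrow(st)), function(i) {
      runif(st$count[i], st$lower[i], st$upper[i])
    }), use.names = FALSE)
    cell_rows <- cc[rep(seq_len(nrow(cc)), cc$count), c("gender", "age_class")]
    # pair demographics with strata at random within the group
    ord <- sample.int(n_g)
    gender <- cell_rows$gender[ord]
    age_class <- cell_rows$age_class[ord]
    br <- design$age_breaks
    age <- vapply(age_class, function(cl) {
      b <- br[[cl]]
      sample(seq.int(b[1], b[2]), 1L)
    }, integer(1))
    rows[[g]] <- data.frame(age = age, gender = gender, age_class = age_class,
                            sap_clinic = sap, stratum = stratum, group = g,
                            stringsAsFactors = FALSE)
  }
  co <- do.call(rbind, rows)
  rownames(co) <- NULL
  co$subject_id <- sprintf("S%04d", seq_len(nrow(co)))

  # --- correlated standardized scores per group ------------------------------
  set.seed(seeds[["factors"]])
  Z <- matrix(NA_real_, nrow(co), length(vars), dimnames = list(NULL, vars))
  for (g in sap_groups()) {
    idx <- which(co$group == g)
    L <- unlist(calib[calib$group == g, proxy_names()])
    Z[idx, ] <- sample_single_factor(L, length(idx))
  }

  # --- rescale to units and add cell effects ---------------------------------
  shift <- effects$shift
  key <- cell_id(co$gender, co$age_class)
  skey <- cell_id(shift$gender, shift$age_class)
  for (v in vars) {
    cell_shift <- setNames(shift[[v]], skey)[key]
    co[[v]] <- loc[v] + scl[v] * Z[, v] + unname(cell_shift)
  }

  # --- contamination ---------------------------------------------------------
  set.seed(seeds[["contamination"]])
  m <- round(contamination_fraction * nrow(co))
  if (m > 0) {
    subj <- sample.int(nrow(co), m)
    for (i in subj) {
      # a random subset of proxies (at least one, never all 13)
      k <- sample.int(length(proxy_names()) - 1L, 1L)
      hit <- sample(proxy_names(), k)
      sgn <- sample(c(-1, 1), k, replace = TRUE)
      co[i, hit] <- co[i, hit] + sgn * contamination_scale * scl[hit]
    }
  }
  co <- co[c("subject_id", "age", "gender", "age_class", "sap_clinic",
             "stratum", "group", vars)]
  attr(co, "design") <- design
  co
}

# -- cohort CSV interface ------------------------------------------------------

#' Write a cohort to CSV
#'
#' UTF-8, header row, decimal point, no thousands separators; column order
#' `subject_id, age, gender, sap_clinic, stratum, group, alpha, <13 proxies>`.
#' `age_class` is derivable from `age` and is not stored.
#'
#' @param cohort Cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- c("subject_id", "age", "gender", "sap_clinic", "stratum", "group",
            "alpha", proxy_names())
  utils::write.csv(cohort[cols], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Restores `age_class` from `age` and validates stratum and group labels
#' against the clinic SAP values.
#'
#' @param path CSV file path.
#' @param design A `cohort_design` used for validation and age classes.
#' @return Cohort data frame.
#' @export
read_cohort_csv <- function(path, design = default_design()) {
  co <- utils::read.csv(path, stringsAsFactors = FALSE)
  co$age_class <- age_class_of(co$age, design)
  validate_cohort(co, design)
  co <- co[c("subject_id", "age", "gender", "age_class", "sap_clinic",
             "stratum", "group", "alpha", proxy_names())]
  attr(co, "design") <- design
  co
}

#' Validate a cohort against its design
#'
#' Checks label consistency (stratum vs SAP bounds, group vs the SAP group
#' definition) and completeness (no missing values).
#'
#' @param cohort Cohort data frame.
#' @param design A `cohort_design`; defaults to the design attached to the
#'   cohort by [generate_cohort()], falling back to [default_design()].
#' @return The cohort, invisibly.
#' @export
validate_cohort <- function(cohort, design = NULL) {
  if (is.null(design)) {
    design <- attr(cohort, "design")
    if (is.null(design)) design <- default_design()
  }
  vars <- c("alpha", proxy_names())
  need <- c("subject_id", "age", "gender", "age_class", "sap_clinic",
            "stratum", "group", vars)
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    bt_stop(paste("cohort misses columns:", paste(miss, collapse = ", ")),
            "barotrend_param_error")
  }
  if (anyNA(cohort[need])) bt_stop("cohort contains missing values",
                                   "barotrend_param_error")
  if (!identical(unname(sap_group_of(cohort$sap_clinic)), unname(cohort$group))) {
    bt_stop("group labels inconsistent with clinic SAP", "barotrend_param_error")
  }
  if (!identical(unname(stratum_of(cohort$sap_clinic, design)),
                 unname(cohort$stratum))) {
    bt_stop("stratum labels inconsistent with clinic SAP", "barotrend_param_error")
  }
  invisible(cohort)
}
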