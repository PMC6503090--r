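# Cohort design: SAP strata and gender x age-class x group cell counts.

#' Default cohort design: 1154 subjects in seven SAP strata
#'
#' The reference design mirrors a large healthy-subject cohort: three SAP
#' groups (normotensive 778, pre-hypertensive 144, hypertensive 232; total
#' 1154), with the Nt and Ht groups further subdivided into SAP-homogeneous
#' strata used for stratified resampling, and a gender x age-class
#' composition per group.
#'
#' Strata (SAP in mmHg): Nt1 \[80,100) n=84, Nt2 \[100,110) n=158,
#' Nt3 \[110,120) n=282, Nt4 \[120,130) n=254, preHt \[130,140) n=144,
#' Ht1 \[140,160) n=167, Ht2 \[160,220\] n=65 (the last stratum is closed
#' above).
#'
#' @return An object of class `cohort_design`: a list with elements
#'   `strata` (data frame: `stratum`, `lower`, `upper`, `closed_upper`,
#'   `count`, `group`), `cell_counts` (data frame: `gender`, `age_class`,
#'   `group`, `count`), `age_breaks` (named list of inclusive age ranges per
#'   class) and `total_n`.
#' @export
#' @examples
#' d <- default_design()
#' d$total_n
#' subset(d$strata, group == "preHt")
default_design <- function() {
  strata <- data.frame(
    stratum      = c("Nt1", "Nt2", "Nt3", "Nt4", "preHt", "Ht1", "Ht2"),
    lower        = c(80, 100, 110, 120, 130, 140, 160),
    upper        = c(100, 110, 120, 130, 140, 160, 220),
    closed_upper = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    count        = c(84L, 158L, 282L, 254L, 144L, 167L, 65L),
    group        = c("Nt", "Nt", "Nt", "Nt", "preHt", "Ht", "Ht"),
    stringsAsFactors = FALSE
  )
  cell_counts <- data.frame(
    gender    = rep(c("F", "M"), each = 9L),
    age_class = rep(rep(c("17-30", "31-49", "50-86"), each = 3L), 2L),
    group     = rep(c("Nt", "preHt", "Ht"), 6L),
    count     = c(204L, 8L, 4L,
                  204L, 28L, 32L,
                  80L, 20L, 66L,
                  124L, 17L, 14L,
                  118L, 38L, 60L,
                  48L, 33L, 56L),
    stringsAsFactors = FALSE
  )
  design <- structure(
    list(strata = strata,
         cell_counts = cell_counts,
         age_breaks = list(`17-30` = c(17L, 30L),
                           `31-49` = c(31L, 49L),
                           `50-86` = c(50L, 86L)),
         total_n = 1154L),
    class = "cohort_design"
  )
  validate_design(design)
  design
}

#' Validate a cohort design
#'
#' Checks the structural invariants: stratum counts sum to `total_n`,
#' cell counts per group agree with the group's stratum-count sum, all
#' counts are non-negative, and SAP intervals are disjoint and ordered.
#'
#' @param design A `cohort_design`.
#' @return The design, invisibly, if valid; otherwise an error of class
#'   `barotrend_design_error`.
#' @export
validate_design <- function(design) {
  s <- design$strata
  cc <- design$cell_counts
  if (any(s$count < 0) || any(cc$count < 0)) {
    bt_stop("counts must be non-negative", "barotrend_design_error")
  }
  if (sum(s$count) != design$total_n) {
    bt_stop("stratum counts do not sum to total_n", "barotrend_design_error")
  }
  by_group_strata <- tapply(s$count, s$group, sum)
  by_group_cells <- tapply(cc$count, cc$group, sum)
  for (g in names(by_group_strata)) {
    if (is.na(by_group_cells[g]) || by_group_cells[g] != by_group_strata[g]) {
      bt_stop(sprintf("cell counts for group %s do not match stratum counts", g),
              "barotrend_design_error")
    }
  }
  # intervals ordered and disjoint (strata are listed in SAP order)
  if (is.unsorted(s$lower) || any(s$upper <= s$lower) ||
      any(utils::head(s$upper, -1) > utils::tail(s$lower, -1))) {
    bt_stop("SAP intervals must be disjoint and ordered", "barotrend_design_error")
  }
  invisible(design)
}

#' Assign SAP group labels from clinic SAP values
#'
#' Nt: SAP < 130; preHt: 130 <= SAP < 140; Ht: SAP >= 140 (mmHg).
#'
#' @param sap Numeric vector of clinic systolic pressures (mmHg).
#' @return Character vector of group labels.
#' @export
sap_group_of <- function(sap) {
  ifelse(sap < 130, "Nt", ifelse(sap < 140, "preHt", "Ht"))
}

#' Assign stratum labels from clinic SAP values under a design
#'
#' @param sap Numeric vector (mmHg).
#' @param design A `cohort_design`.
#' @return Character vector of stratum labels; values outside every interval
#'   raise an error.
#' @export
stratum_of <- function(sap, design = default_design()) {
  s <- design$strata
  lab <- rep(NA_character_, length(sap))
  for (i in seq_len(nrow(s))) {
    hit <- sap >= s$lower[i] &
      (if (s$closed_upper[i]) sap <= s$upper[i] else sap < s$upper[i])
    lab[hit] <- s$stratum[i]
  }
  if (anyNA(lab)) {
    bt_stop("SAP value outside all design strata", "barotrend_design_error")
  }
  lab
}

#' Age class of an age in years
#' @param age Numeric vector of ages (years).
#' @param design A `cohort_design` (for the class boundaries).
#' @return Character vector of age-class labels.
#' @export
age_class_of <- function(age, design = default_design()) {
  br <- design$age_breaks
  lab <- rep(NA_character_, length(age))
  for (cl in names(br)) {
    lab[age >= br[[cl]][1] & age <= br[[cl]][2]] <- cl
  }
  if (anyNA(lab)) bt_stop("age outside all design classes", "barotrend_design_error")
  lab
}
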