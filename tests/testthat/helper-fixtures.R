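# Shared fixtures: a scaled-down cohort design for fast tests, enumeration
# utilities used as independent oracles, and a cached default cohort.

# Miniature design: same three SAP groups, three strata, 72 subjects.
mini_design <- function() {
  strata <- data.frame(
    stratum      = c("NtA", "preHt", "HtA"),
    lower        = c(80, 130, 140),
    upper        = c(130, 140, 220),
    closed_upper = c(FALSE, FALSE, TRUE),
    count        = c(30L, 24L, 18L),
    group        = c("Nt", "preHt", "Ht"),
    stringsAsFactors = FALSE
  )
  cell_counts <- data.frame(
    gender    = rep(c("F", "M"), each = 9L),
    age_class = rep(rep(c("17-30", "31-49", "50-86"), each = 3L), 2L),
    group     = rep(c("Nt", "preHt", "Ht"), 6L),
    count     = c(6L, 4L, 3L,  5L, 4L, 3L,  4L, 4L, 3L,
                  5L, 4L, 3L,  5L, 4L, 3L,  5L, 4L, 3L),
    stringsAsFactors = FALSE
  )
  structure(list(strata = strata, cell_counts = cell_counts,
                 age_breaks = list(`17-30` = c(17L, 30L),
                                   `31-49` = c(31L, 49L),
                                   `50-86` = c(50L, 86L)),
                 total_n = 72L),
            class = "cohort_design")
}

mini_cohort <- function(seed = 5, ...) {
  generate_cohort(design = mini_design(), seed = seed,
                  contamination_fraction = 0, ...)
}

# one default-design cohort reused across expensive tests
default_cohort_cached <- local({
  co <- NULL
  function() {
    if (is.null(co)) co <<- generate_cohort(seed = 101)
    co
  }
})

# all permutations of 1..n (tiny n only) -- oracle utility
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

# all allocations of N pooled items into 3 labelled groups of sizes n --
# returns a list of index-triples; oracle for the HN permutation null
all_allocations <- function(n) {
  N <- sum(n)
  out <- list()
  for (g1 in asplit(utils::combn(N, n[1]), 2)) {
    rest <- setdiff(seq_len(N), g1)
    for (g2 in asplit(utils::combn(rest, n[2]), 2)) {
      out[[length(out) + 1L]] <- list(as.integer(g1), as.integer(g2),
                                      setdiff(rest, g2))
    }
  }
  out
}

# exact permutation-null standardization of the HN statistic by full
# enumeration: returns z = (T_obs - mean(T)) / sd(T) over all allocations
hn_exact_z <- function(samples, scores) {
  n <- lengths(samples)
  N <- sum(n)
  pooled <- unlist(samples, use.names = FALSE)
  R <- rank(pooled)
  cc <- scores - sum(n * scores) / N
  t_of <- function(alloc) {
    sum(cc * vapply(seq_len(3), function(i) mean(R[alloc[[i]]]), numeric(1)))
  }
  obs <- t_of(list(seq_len(n[1]), n[1] + seq_len(n[2]), n[1] + n[2] + seq_len(n[3])))
  ts <- vapply(all_allocations(n), t_of, numeric(1))
  # population sd over the allocation null (allocations are equiprobable)
  (obs - mean(ts)) / sqrt(mean((ts - mean(ts))^2))
}
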