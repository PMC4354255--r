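#' Kruskal-Wallis rank test with exact small-sample p-value
#'
#' Tie-corrected Kruskal-Wallis H with the chi-square approximation
#' (df = groups - 1), as appropriate for partial-consumption proportions
#' whose distribution violates normality and homoscedasticity. For small
#' samples (total N <= 10) the p-value is computed exactly by enumerating
#' every assignment of the observations to the group sizes. When all
#' observations are identical the statistic is taken as H = 0, p = 1 (the
#' degenerate complete-tie convention; the tie-correction denominator
#' vanishes there).
#'
#' @param values numeric observations.
#' @param groups group labels (coerced to factor), >= 2 nonempty groups.
#' @param exact_n largest total N for which the exact permutation p-value
#'   is computed (default 10).
#' @return object of class \code{"kw_result"}: \code{H}, \code{df},
#'   \code{p} (exact if computed, else chi-square), \code{p_chisq},
#'   \code{p_exact} (NA unless computed), \code{group_sizes}.
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("x", "y"), each = 3))  # H = 3.857
#' @export
kruskal_wallis <- function(values, groups, exact_n = 10) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(tabulate(groups) == 0)) stop("every group must be nonempty")
  if (length(values) != length(groups)) stop("values/groups length mismatch")
  sizes <- table(groups)
  k <- nlevels(groups)
  N <- length(values)

  if (length(unique(values)) == 1L) {
    return(structure(list(H = 0, df = k - 1L, p = 1, p_chisq = 1,
                          p_exact = NA_real_, group_sizes = sizes),
                     class = "kw_result"))
  }
  kt <- stats::kruskal.test(values, groups)
  H <- unname(kt$statistic)
  df <- unname(kt$parameter)
  p_chisq <- unname(kt$p.value)
  p_exact <- NA_real_
  if (N <= exact_n) {
    r <- rank(values)
    stats_all <- kw_enumerate(r, as.integer(sizes))
    p_exact <- mean(stats_all >= H - 1e-10)
  }
  structure(list(H = H, df = df,
                 p = if (!is.na(p_exact)) p_exact else p_chisq,
                 p_chisq = p_chisq, p_exact = p_exact, group_sizes = sizes),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g%s\n",
              x$H, x$df, x$p,
              if (!is.na(x$p_exact)) " (exact permutation)" else ""))
  invisible(x)
}

# tie-corrected H from ranks of the pooled sample
kw_stat_from_ranks <- function(r, g_sizes, assignment) {
  N <- length(r)
  ends <- cumsum(g_sizes)
  starts <- c(1, head(ends, -1) + 1)
  ssq <- 0
  for (j in seq_along(g_sizes)) {
    rj <- sum(r[assignment[starts[j]:ends[j]]])
    ssq <- ssq + rj^2 / g_sizes[j]
  }
  H <- 12 / (N * (N + 1)) * ssq - 3 * (N + 1)
  t_counts <- table(r)
  corr <- 1 - sum(t_counts^3 - t_counts) / (N^3 - N)
  if (corr <= 0) return(0)
  H / corr
}

# H over every distinct assignment of N observations to the group sizes
kw_enumerate <- function(r, g_sizes) {
  N <- length(r)
  out <- numeric(0)
  recurse <- function(remaining, chosen, sizes_left) {
    if (!length(sizes_left)) {
      out[[length(out) + 1L]] <<- kw_stat_from_ranks(r, g_sizes, chosen)
      return(invisible(NULL))
    }
    cmb <- utils::combn(remaining, sizes_left[1], simplify = FALSE)
    for (cc in cmb) recurse(setdiff(remaining, cc), c(chosen, cc), sizes_left[-1])
  }
  recurse(seq_len(N), integer(0), g_sizes)
  unlist(out)
}

#' Aggregate partial-consumption proportions by group
#'
#' Per-group proportion of killed prey that were only partially consumed:
#' sum(partially_eaten) / sum(killed) within each level combination of
#' \code{by}. Groups with no kills are reported as missing.
#'
#' @param records trial records.
#' @param by character vector of grouping columns (default
#'   \code{"density"}).
#' @return data.frame of the grouping columns plus \code{n} (replicates),
#'   \code{killed}, \code{partially_eaten}, \code{proportion}.
#' @export
partial_proportion_table <- function(records, by = "density") {
  key <- interaction(records[, by, drop = FALSE], drop = TRUE, sep = "|")
  rows <- lapply(levels(key), function(lv) {
    sel <- key == lv
    kil <- sum(records$killed[sel])
    cbind(records[which(sel)[1L], by, drop = FALSE],
          data.frame(n = sum(sel), killed = kil,
                     partially_eaten = sum(records$partially_eaten[sel]),
                     proportion = if (kil > 0)
                       sum(records$partially_eaten[sel]) / kil else NA_real_))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[do.call(order, out[, by, drop = FALSE]), , drop = FALSE]
}

#' Partial-consumption analysis across density and treatment factors
#'
#' The observation unit is the per-replicate proportion of killed prey
#' that were partially eaten, restricted to replicates with two or more
#' kills (the recording rule: a single part-eaten prey at the end of a
#' trial is not evidence of partial consumption). For each prey species
#' and for the pooled data, a Kruskal-Wallis test is run against each
#' factor: density (as a multi-level factor), predator species,
#' parasitism and fish presence. Strata with no qualifying replicate are
#' skipped with an explicit flag.
#'
#' @param records trial records.
#' @param factors factors to test (default density, predator species,
#'   parasitism, fish presence).
#' @return list: \code{observations} (replicate-level proportions),
#'   \code{proportions} (per prey x density aggregate table),
#'   \code{tests} (data.frame prey / factor / H / df / p / n / skipped).
#' @export
partial_consumption_analysis <- function(records,
    factors = c("density", "predator_species", "parasitised", "fish_present")) {
  eligible <- records[records$killed >= 2, , drop = FALSE]
  eligible$proportion <- eligible$partially_eaten / eligible$killed

  prey_sets <- c(as.list(unique(records$prey_species)), list("pooled"))
  tests <- do.call(rbind, lapply(prey_sets, function(prey) {
    sub <- if (identical(prey, "pooled")) eligible
           else eligible[eligible$prey_species == prey, , drop = FALSE]
    do.call(rbind, lapply(factors, function(fac) {
      if (nrow(sub) == 0 || length(unique(sub[[fac]])) < 2) {
        return(data.frame(prey = unlist(prey), factor = fac, H = NA_real_,
                          df = NA_integer_, p = NA_real_, n = nrow(sub),
                          skipped = TRUE))
      }
      kw <- kruskal_wallis(sub$proportion, sub[[fac]])
      data.frame(prey = unlist(prey), factor = fac, H = kw$H, df = kw$df,
                 p = kw$p, n = nrow(sub), skipped = FALSE)
    }))
  }))
  rownames(tests) <- NULL

  props <- partial_proportion_table(records, by = c("prey_species", "density"))
  list(observations = eligible, proportions = props, tests = tests)
}
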