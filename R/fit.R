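#' Model specification for indicator-variable functional-response fits
#'
#' Defines which treatment factors (and interactions) modify the attack
#' rate and the handling time, under treatment coding: every parameter is
#' an intercept (the base treatment cell) plus offsets for non-base levels,
#' with interaction indicators equal to the product of their main-effect
#' indicators. Terms use the factor names \code{"prey"}, \code{"predator"},
#' \code{"parasitised"}, \code{"fish"}, with interactions written
#' \code{"predator:fish"} etc. An empty term vector means intercept only —
#' the "simplified model" used for attack rate in within-module fits.
#'
#' @param a_terms character vector of terms modifying the attack rate
#'   (default none: intercept only).
#' @param h_terms character vector of terms modifying the handling time.
#' @param base named list of base levels (defaults: prey
#'   \code{"A_aquaticus"}, predator \code{"G_d_celticus"} — the native
#'   amphipod — unparasitised, no fish).
#' @param variant response variant (only \code{"II"} is fit with treatment
#'   coding).
#' @param T trial duration in experiment-duration units (default 1).
#' @return an object of class \code{"fr_spec"}.
#' @examples
#' # between-module model: a and h both coded by prey
#' fr_spec(a_terms = "prey", h_terms = "prey")
#' # within-module model: intercept-only a, fully factorial h
#' fr_spec(h_terms = c("predator", "fish", "parasitised",
#'                     "predator:fish", "predator:parasitised",
#'                     "parasitised:fish", "predator:parasitised:fish"))
#' @export
fr_spec <- function(a_terms = character(), h_terms = character(),
                    base = list(), variant = "II", T = 1) {
  base_default <- list(prey = "A_aquaticus", predator = "G_d_celticus",
                       parasitised = FALSE, fish = FALSE)
  base <- utils::modifyList(base_default, base)
  variant <- match.arg(variant, "II")
  known <- c("prey", "predator", "parasitised", "fish")
  for (term in c(a_terms, h_terms)) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (any(!parts %in% known))
      stop("unknown factor in term '", term, "'; known: ",
           paste(known, collapse = ", "))
  }
  structure(list(a_terms = a_terms, h_terms = h_terms, base = base,
                 variant = variant, T = T),
            class = "fr_spec")
}

unit_factors <- function(units, base, used = character()) {
  lv <- function(x, base_level, name) {
    x <- as.character(x)
    base_level <- as.character(base_level)
    # a coded factor must contain its base (intercept) level in the data
    if (name %in% used && !base_level %in% x)
      stop("base level '", base_level, "' of factor '", name,
           "' not present in the data")
    factor(x, levels = unique(c(base_level, sort(setdiff(unique(x), base_level)))))
  }
  data.frame(prey = lv(units$prey_species, base$prey, "prey"),
             predator = lv(units$predator_species, base$predator, "predator"),
             parasitised = lv(units$parasitised, base$parasitised, "parasitised"),
             fish = lv(units$fish_present, base$fish, "fish"))
}

#' Build indicator (design) matrices for a functional-response model
#'
#' Expands the treatment coding of an \code{\link{fr_spec}} over a set of
#' experimental units into design matrices for the attack rate and the
#' handling time. The base cell maps to the all-zero indicator row (plus
#' intercept); multi-level factors expand to one column per non-base
#' level; interaction columns are products of their main-effect columns.
#' Column order is deterministic: intercept, then terms in the order given
#' in the spec, levels alphabetical within term.
#'
#' @param units trial records or design units.
#' @param spec an \code{\link{fr_spec}}.
#' @return list with matrices \code{Xa}, \code{Xh} (first column the
#'   intercept).
#' @export
build_indicator_rows <- function(units, spec) {
  used <- unique(unlist(strsplit(c(spec$a_terms, spec$h_terms), ":", fixed = TRUE)))
  fac <- unit_factors(units, spec$base, used)
  build_one <- function(terms) {
    if (!length(terms)) {
      X <- matrix(1, nrow(fac), 1, dimnames = list(NULL, "intercept"))
      return(X)
    }
    form <- stats::reformulate(terms)
    X <- stats::model.matrix(form, fac)
    colnames(X)[1] <- "intercept"
    X
  }
  list(Xa = build_one(spec$a_terms), Xh = build_one(spec$h_terms))
}

split_theta <- function(theta, X) {
  pa <- ncol(X$Xa)
  list(a = theta[seq_len(pa)], h = theta[pa + seq_len(ncol(X$Xh))])
}

#' Negative binomial log-likelihood of a Rogers indicator-variable model
#'
#' The fitting objective: each trial's kill count is Binomial(N0, p) with
#' p the Rogers Type II expectation divided by N0 (clamped to
#' [1e-9, 1 - 1e-9]), where the cell's attack rate and handling time come
#' from the indicator coding. Parameter vectors implying a nonpositive
#' attack rate or negative handling time in any observed cell return
#' \code{+Inf}, steering the optimiser away from infeasible regions.
#'
#' @param theta parameter vector: attack-rate coefficients (intercept
#'   first) followed by handling-time coefficients, on the natural scale.
#' @param records trial records.
#' @param spec an \code{\link{fr_spec}}.
#' @param X optional precomputed result of
#'   \code{\link{build_indicator_rows}} (hot-loop use).
#' @return scalar negative log-likelihood (0 for an empty record set).
#' @export
nll_binomial <- function(theta, records, spec, X = NULL) {
  if (nrow(records) == 0) return(0)
  if (is.null(X)) X <- build_indicator_rows(records, spec)
  th <- split_theta(theta, X)
  a <- drop(X$Xa %*% th$a)
  h <- drop(X$Xh %*% th$h)
  if (any(a <= 0) || any(h < 0)) return(Inf)
  ne <- rogers_expected_eaten(a, h, records$density, spec$T)
  p <- pmin(pmax(ne / records$density, 1e-9), 1 - 1e-9)
  -sum(stats::dbinom(records$killed, records$density, p, log = TRUE))
}

# finite penalty version for optimisers that dislike Inf
nll_safe <- function(theta, records, spec, X) {
  v <- nll_binomial(theta, records, spec, X)
  if (!is.finite(v)) 1e10 + sum(pmax(-theta, 0)) else v
}

# central-difference observed Hessian, step 1e-5 * max(|theta|, 1)
fd_hessian <- function(fn, theta) {
  p <- length(theta)
  hstep <- 1e-5 * pmax(abs(theta), 1)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(theta)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- ej <- numeric(p); ei[i] <- hstep[i]; ej[j] <- hstep[j]
      if (i == j) {
        H[i, i] <- (fn(theta + ei) - 2 * f0 + fn(theta - ei)) / hstep[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (fn(theta + ei + ej) - fn(theta + ei - ej) -
             fn(theta - ei + ej) + fn(theta - ei - ej)) /
          (4 * hstep[i] * hstep[j])
      }
    }
  }
  H
}

default_starts <- function(records, X, spec) {
  T <- spec$T
  # attack rate from the depletion-consistent linearisation on the lower
  # half of the density ladder; handling time from the observed ceiling
  low <- records$density <= stats::median(records$density)
  if (!any(low)) low <- rep(TRUE, nrow(records))
  pbar <- sum(records$killed[low]) / sum(records$density[low])
  a0 <- max(-log(max(1 - pbar, 1e-3)) / T, 0.05)
  h0 <- 1 / max(max(records$killed), 1)
  theta <- c(a0, rep(0, ncol(X$Xa) - 1), max(h0, 1e-3), rep(0, ncol(X$Xh) - 1))
  names(theta) <- c(paste0("a_", colnames(X$Xa)), paste0("h_", colnames(X$Xh)))
  theta
}

jitter_start <- function(theta, X) {
  ints <- c(1, ncol(X$Xa) + 1)
  out <- theta
  out[ints] <- theta[ints] * stats::runif(2, 0.5, 1.5)
  eff <- setdiff(seq_along(theta), ints)
  out[eff] <- theta[eff] + stats::rnorm(length(eff), 0, 0.02)
  out
}

#' Fit a Rogers functional-response model by maximum likelihood
#'
#' Maximum-likelihood estimation of the indicator-variable Rogers model:
#' a derivative-free Nelder-Mead pass refined by quasi-Newton (BFGS), run
#' from several jittered starts (attack rate from a disc-equation
#' linearisation on low densities, handling time from 1/max(kills),
#' treatment effects from zero). Parameters are optimised on the natural
#' scale so effects can be negative; infeasible cells carry an infinite
#' penalty. Standard errors come from the inverse finite-difference
#' observed Hessian at the optimum; a singular Hessian yields estimates
#' with SEs flagged unavailable rather than an error.
#'
#' @param records validated trial records spanning >= 2 distinct densities.
#' @param spec an \code{\link{fr_spec}}.
#' @param starts optional start vector (replaces the automatic start).
#' @param n_starts number of jittered restarts (default 5).
#' @param refine run the BFGS refinement after Nelder-Mead (default TRUE;
#'   turned off for speed in bootstrap refits).
#' @param optim_control control list for the Nelder-Mead pass.
#' @param hessian compute the observed Hessian and Wald quantities
#'   (default TRUE; bootstrap refits skip it).
#' @return object of class \code{"fr_fit"}: \code{theta}, \code{vcov},
#'   \code{se}, \code{z}, \code{p}, \code{logLik}, \code{AIC},
#'   \code{converged}, \code{boundary}, \code{se_available},
#'   \code{starts}, \code{spec}, \code{n}.
#' @export
fit_fr <- function(records, spec, starts = NULL, n_starts = 5, refine = TRUE,
                   optim_control = list(maxit = 2000, reltol = 1e-10),
                   hessian = TRUE) {
  validate_records_minimal(records)
  if (length(unique(records$density)) < 2)
    stop("need >= 2 distinct densities to fit a functional response")
  X <- build_indicator_rows(records, spec)
  obj <- function(th) nll_safe(th, records, spec, X)

  base_start <- if (is.null(starts)) default_starts(records, X, spec) else starts
  start_list <- list(base_start)
  if (n_starts > 1) {
    for (k in seq_len(n_starts - 1))
      start_list[[k + 1]] <- jitter_start(base_start, X)
  }

  best <- NULL
  for (st in start_list) {
    opt <- tryCatch(
      stats::optim(st, obj, method = "Nelder-Mead", control = optim_control),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (refine) {
      opt2 <- tryCatch(
        stats::optim(opt$par, obj, method = "BFGS",
                     control = list(maxit = 200, reltol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(opt2) && is.finite(opt2$value) && opt2$value <= opt$value)
        opt <- opt2
    }
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e9)
    stop("fit_fr: all starts failed to reach a feasible optimum")

  theta <- best$par
  names(theta) <- names(base_start)
  boundary <- all(records$killed == records$density) || all(records$killed == 0)

  vc <- NULL
  if (hessian) {
    H <- fd_hessian(obj, theta)
    vc <- tryCatch(solve(H), error = function(e) NULL)
  }
  se_available <- !is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) > 0)
  if (se_available) {
    se <- sqrt(diag(vc))
    z <- theta / se
    p <- 2 * stats::pnorm(-abs(z))
    dimnames(vc) <- list(names(theta), names(theta))
  } else {
    vc <- NULL
    se <- z <- p <- rep(NA_real_, length(theta))
  }
  names(se) <- names(z) <- names(p) <- names(theta)

  ll <- -nll_binomial(theta, records, spec, X)
  structure(list(theta = theta, vcov = vc, se = se, z = z, p = p,
                 logLik = ll, AIC = 2 * length(theta) - 2 * ll,
                 converged = best$convergence == 0 && !boundary &&
                   (!hessian || se_available),
                 boundary = boundary, se_available = se_available,
                 starts = base_start, spec = spec, X_names = lapply(X, colnames),
                 n = nrow(records)),
            class = "fr_fit")
}

# fitting needs only the columns it touches; full schema not required
validate_records_minimal <- function(records) {
  need <- c("prey_species", "predator_species", "parasitised", "fish_present",
            "density", "killed")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (any(records$killed > records$density | records$killed < 0))
    stop("killed counts outside [0, density]")
  invisible(records)
}

#' @export
print.fr_fit <- function(x, ...) {
  cat(sprintf("Rogers functional-response fit (n = %d, logLik = %.2f, AIC = %.1f)\n",
              x$n, x$logLik, x$AIC))
  if (!x$converged) cat("  [warning: not converged",
                        if (x$boundary) " (boundary data)", "]\n", sep = "")
  print(contrast_table(x), digits = 3)
  invisible(x)
}

#' Wald z-score and two-sided p-value
#'
#' The reporting arithmetic used throughout the summary tables:
#' z = estimate / SE, p = 2(1 - Phi(|z|)).
#'
#' @param estimate,se numeric (vectorized).
#' @return data.frame with columns \code{z} and \code{p}.
#' @examples
#' wald_z(0.992, 0.155)  # z = 6.4
#' @export
wald_z <- function(estimate, se) {
  z <- estimate / se
  data.frame(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Parameter and contrast table for a functional-response fit
#'
#' By default, one row per fitted coefficient (estimate, SE, z, two-sided
#' p). Custom contrasts are supplied as weight vectors over the parameter
#' vector: the estimate is \eqn{c'\theta} and its SE the delta-method
#' quadratic form \eqn{\sqrt{c' V c}} — e.g. intercept + effect weights
#' recover group-level parameter values with correct uncertainty.
#'
#' @param fit an \code{\link{fr_fit}} with available covariance.
#' @param contrasts optional named list of numeric weight vectors, each of
#'   length \code{length(fit$theta)}.
#' @return data.frame: \code{parameter}, \code{estimate}, \code{se},
#'   \code{z}, \code{p}.
#' @export
contrast_table <- function(fit, contrasts = NULL) {
  if (is.null(contrasts)) {
    out <- data.frame(parameter = names(fit$theta), estimate = unname(fit$theta),
                      se = unname(fit$se), z = unname(fit$z), p = unname(fit$p))
    return(out)
  }
  if (!fit$se_available) stop("fit covariance unavailable; cannot form contrasts")
  rows <- lapply(names(contrasts), function(lab) {
    w <- contrasts[[lab]]
    if (length(w) != length(fit$theta))
      stop(sprintf("contrast '%s' has length %d, expected %d",
                   lab, length(w), length(fit$theta)))
    est <- sum(w * fit$theta)
    se <- sqrt(drop(t(w) %*% fit$vcov %*% w))
    cbind(data.frame(parameter = lab, estimate = est, se = se), wald_z(est, se))
  })
  do.call(rbind, rows)
}

# unique treatment cells present in the records, with display labels
unique_cells <- function(records) {
  cells <- unique(records[, c("prey_species", "predator_species",
                              "parasitised", "fish_present")])
  cells <- cells[do.call(order, cells), , drop = FALSE]
  rownames(cells) <- NULL
  cells$cell <- paste0(cells$prey_species, "/", cells$predator_species,
                       ifelse(cells$parasitised, "/parasitised", "/unparasitised"),
                       ifelse(cells$fish_present, "/fish", "/no_fish"))
  cells
}

cell_params <- function(fit, cells, theta = fit$theta) {
  X <- build_indicator_rows(cells, fit$spec)
  th <- split_theta(theta, X)
  data.frame(cell = cells$cell,
             a = drop(X$Xa %*% th$a),
             h = drop(X$Xh %*% th$h))
}

#' Bootstrap confidence envelope for fitted functional responses
#'
#' Nonparametric case bootstrap: whole pots are resampled with
#' replacement, stratified by treatment cell so every resample preserves
#' the factorial design, and the model is refit to each resample
#' (warm-started from the point estimate, single Nelder-Mead
#' pass). Stratification stops at the treatment-cell level rather than
#' treatment-by-density: resampling within strata of only a few pots
#' deflates bootstrap variance by the factor (n - 1)/n per stratum, which
#' would make the envelope systematically anti-conservative.
#' Failed or non-converged refits are dropped and counted; a
#' warning is attached when more than 20\% fail. The envelope is the
#' per-density equi-tailed quantile band of the predicted number eaten,
#' per treatment cell.
#'
#' @param records trial records.
#' @param spec an \code{\link{fr_spec}}.
#' @param n_boot number of bootstrap resamples (default 1500).
#' @param seed integer seed; identical seeds give identical envelopes.
#' @param grid density grid for the envelope (default: the distinct
#'   densities in the data).
#' @param level coverage of the equi-tailed interval (default 0.95).
#' @param fit optional precomputed point fit (saves one fit).
#' @return object of class \code{"fr_boot"}: \code{envelope} (data.frame
#'   cell / density / lower / upper), \code{draws} (parameter matrix,
#'   one row per retained resample), \code{n_boot}, \code{n_failed},
#'   \code{level}, \code{fit}, \code{warning}.
#' @export
bootstrap_fr <- function(records, spec, n_boot = 1500, seed = 1L, grid = NULL,
                         level = 0.95, fit = NULL) {
  if (is.null(fit)) fit <- fit_fr(records, spec)
  if (!fit$converged && !fit$se_available)
    stop("bootstrap requires a converged base fit")
  if (is.null(grid)) grid <- sort(unique(records$density))
  # strata are treatment cells, not treatment x density: every resample keeps
  # the factorial design intact, while strata stay large enough that the
  # within-stratum variance deflation factor (n_s - 1)/n_s is negligible
  # (density-level strata of 4 pots would deflate bootstrap variance by 25%
  # and the envelope could never attain nominal coverage)
  strata <- interaction(records$prey_species, records$predator_species,
                        records$parasitised, records$fish_present, drop = TRUE)
  idx_by_stratum <- split(seq_len(nrow(records)), strata)
  X <- build_indicator_rows(records, spec)

  old <- local_rng(seed)
  on.exit(restore_rng(old), add = TRUE)

  draws <- matrix(NA_real_, n_boot, length(fit$theta),
                  dimnames = list(NULL, names(fit$theta)))
  keep <- logical(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(idx_by_stratum, function(ix)
      ix[sample.int(length(ix), length(ix), replace = TRUE)]), use.names = FALSE)
    # resampled rows reuse the point fit's indicator rows
    res <- data.frame(density = records$density[idx],
                      killed = records$killed[idx])
    Xb <- list(Xa = X$Xa[idx, , drop = FALSE], Xh = X$Xh[idx, , drop = FALSE])
    opt <- tryCatch(
      stats::optim(fit$theta, nll_safe, records = res, spec = spec, X = Xb,
                   method = "Nelder-Mead",
                   control = list(maxit = max(800, 500 * length(fit$theta)),
                                  reltol = 1e-8)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) && opt$value < 1e9 &&
        opt$convergence == 0) {
      draws[b, ] <- opt$par
      keep[b] <- TRUE
    }
  }
  n_failed <- sum(!keep)
  draws <- draws[keep, , drop = FALSE]

  cells <- unique_cells(records)
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  Xc <- build_indicator_rows(cells, spec)
  pa <- ncol(Xc$Xa)
  env_rows <- lapply(seq_len(nrow(cells)), function(ci) {
    a_d <- drop(draws[, seq_len(pa), drop = FALSE] %*% Xc$Xa[ci, ])
    h_d <- drop(draws[, pa + seq_len(ncol(Xc$Xh)), drop = FALSE] %*% Xc$Xh[ci, ])
    ng <- length(grid)
    pred <- matrix(rogers_expected_eaten(rep(a_d, each = ng),
                                         rep(h_d, each = ng),
                                         rep(grid, times = length(a_d)), spec$T),
                   nrow = ng)
    data.frame(cell = cells$cell[ci], density = grid,
               lower = apply(pred, 1, stats::quantile, qs[1]),
               upper = apply(pred, 1, stats::quantile, qs[2]))
  })
  envelope <- do.call(rbind, env_rows)
  rownames(envelope) <- NULL
  warn <- if (n_failed > 0.2 * n_boot)
    sprintf("%d of %d bootstrap refits failed (> 20%%)", n_failed, n_boot) else NULL
  if (!is.null(warn)) warning(warn)
  structure(list(envelope = envelope, draws = draws, n_boot = n_boot,
                 n_failed = n_failed, level = level, grid = grid, fit = fit,
                 warning = warn),
            class = "fr_boot")
}

#' Predicted response curve with bootstrap interval
#'
#' Joins the point-fit prediction (the Rogers expectation at each cell's
#' fitted parameters) with the bootstrap envelope on a density grid,
#' producing the plot-ready table behind a functional-response figure.
#' A collapsed fit (zero attack rate everywhere, flat zero curve with a
#' zero-width interval) is flagged via the \code{"collapsed"} attribute.
#'
#' @param fit an \code{\link{fr_fit}}.
#' @param envelope an \code{\link{bootstrap_fr}} result (optional; without
#'   it the interval columns are NA).
#' @param grid density grid (default: the envelope's grid, else 1..30).
#' @param cells optional cell table (default: the envelope's cells, or the
#'   base cell of the spec).
#' @return data.frame: \code{cell}, \code{density}, \code{mean},
#'   \code{lower}, \code{upper}.
#' @export
predict_curve_ci <- function(fit, envelope = NULL, grid = NULL, cells = NULL) {
  if (is.null(grid))
    grid <- if (!is.null(envelope)) envelope$grid else seq_len(30)
  if (any(grid <= 0)) stop("density grid must be positive")
  if (is.null(cells)) {
    if (!is.null(envelope)) {
      cells <- unique(do.call(rbind, lapply(strsplit(unique(envelope$envelope$cell), "/"),
        function(pp) data.frame(prey_species = pp[1], predator_species = pp[2],
                                parasitised = pp[3] == "parasitised",
                                fish_present = pp[4] == "fish"))))
      cells$cell <- unique(envelope$envelope$cell)
    } else {
      b <- fit$spec$base
      cells <- data.frame(prey_species = b$prey, predator_species = b$predator,
                          parasitised = as.logical(b$parasitised),
                          fish_present = as.logical(b$fish))
      cells$cell <- "base"
    }
  }
  cp <- cell_params(fit, cells)
  out <- do.call(rbind, lapply(seq_len(nrow(cp)), function(i) {
    data.frame(cell = cp$cell[i], density = grid,
               mean = rogers_expected_eaten(cp$a[i], cp$h[i], grid, fit$spec$T))
  }))
  if (!is.null(envelope)) {
    out <- merge(out, envelope$envelope, by = c("cell", "density"),
                 all.x = TRUE, sort = FALSE)
  } else {
    out$lower <- NA_real_; out$upper <- NA_real_
  }
  out <- out[order(out$cell, out$density), ]
  rownames(out) <- NULL
  attr(out, "collapsed") <- all(out$mean == 0)
  out
}
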