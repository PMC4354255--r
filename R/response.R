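#' Functional-response parameter sets
#'
#' Container for the parameters of a predator functional response in a
#' non-replacement (prey-depletion) design. Time is expressed in
#' experiment-duration units: a 40-h trial is mapped to \code{T = 1} by
#' default, and the attack rate \code{a} (per duration unit) and handling
#' time \code{h} (duration units per prey) are scaled accordingly.
#'
#' Three variants are supported:
#' \describe{
#'   \item{\code{"II"}}{Rogers random-predator (Type II with depletion):
#'     constant attack rate \code{a}, handling time \code{h}.}
#'   \item{\code{"I"}}{the \code{h = 0} limit of the Rogers model,
#'     \eqn{N_e = N_0 (1 - e^{-aT})} — a depletion-consistent linear
#'     response (not Holling's rectilinear form), so that all variants
#'     share one likelihood.}
#'   \item{\code{"III"}}{density-dependent attack rate
#'     \eqn{a(N_0) = b N_0 / (1 + c N_0)} substituted into the Rogers
#'     solution; with \code{c = 0} this is the two-parameter Hassell form.}
#' }
#'
#' @param a attack rate (per duration unit), \code{>= 0}; ignored for
#'   variant \code{"III"}.
#' @param h handling time (duration units per prey), \code{>= 0}.
#' @param T trial duration (duration units), \code{> 0}.
#' @param variant one of \code{"I"}, \code{"II"}, \code{"III"}.
#' @param b,c Type III attack-rate coefficients (\code{b >= 0},
#'   \code{c >= 0}); only used when \code{variant = "III"}.
#' @return an object of class \code{"fr_params"}.
#' @examples
#' fr_params(a = 0.981, h = 0.307)            # Type II
#' fr_params(a = 0.5, h = 0, variant = "I")   # linear (depletion) limit
#' @export
fr_params <- function(a = NULL, h = 0, T = 1, variant = "II", b = NULL, c = NULL) {
  variant <- match.arg(variant, c("I", "II", "III"))
  if (!is.numeric(T) || length(T) != 1L || T <= 0) stop("`T` must be a single positive number")
  if (variant %in% c("I", "II")) {
    if (is.null(a) || a < 0) stop("`a` must be supplied and >= 0 for variants I and II")
  }
  if (variant == "I" && h != 0) stop("variant I has h = 0 by definition")
  if (h < 0) stop("`h` must be >= 0")
  if (variant == "III") {
    if (is.null(b) || b < 0) stop("`b` must be supplied and >= 0 for variant III")
    if (is.null(c)) c <- 0
    if (c < 0) stop("`c` must be >= 0")
  }
  structure(list(a = a, h = h, T = T, variant = variant, b = b, c = c),
            class = "fr_params")
}

#' @export
print.fr_params <- function(x, ...) {
  cat("Functional-response parameters (Type ", x$variant, ")\n", sep = "")
  if (x$variant == "III") {
    cat(sprintf("  b = %g, c = %g, h = %g, T = %g\n", x$b, x$c, x$h, x$T))
  } else {
    cat(sprintf("  a = %g, h = %g, T = %g\n", x$a, x$h, x$T))
  }
  invisible(x)
}

#' Expected prey eaten under the Rogers random-predator model
#'
#' Expected number of prey eaten \eqn{N_e} out of an initial density
#' \eqn{N_0} over a trial of duration \eqn{T}, under a Type II response
#' with prey depletion and no replacement:
#' \deqn{N_e = N_0 \{1 - \exp(a (N_e h - T))\},}
#' solved explicitly on the principal Lambert branch as
#' \deqn{N_e = N_0 - W_0\!\big(a h N_0 e^{-a (T - h N_0)}\big) / (a h).}
#'
#' Degenerate cases: \code{a = 0} or \code{N0 = 0} return exactly 0;
#' \code{h = 0} (or \code{a*h < 1e-12}, where the Lambert form is 0/0)
#' returns the closed form \eqn{N_0 (1 - e^{-aT})}. Very large Lambert
#' arguments are handled in log space, so deep handling-limited regimes
#' (\eqn{h N_0 \gg T}) do not overflow.
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param a attack rate(s), \code{>= 0}. May also be an
#'   \code{\link{fr_params}} object of variant \code{"II"}, in which case
#'   \code{h} and \code{T} are taken from it.
#' @param h handling time(s), \code{>= 0}.
#' @param N0 initial prey density (count, \code{>= 0}).
#' @param T trial duration(s), \code{> 0}.
#' @return expected number of prey eaten, in \code{[0, N0]}.
#' @examples
#' rogers_expected_eaten(a = 1, h = 0, N0 = 10, T = 1)      # 10 * (1 - exp(-1))
#' rogers_expected_eaten(a = 0.981, h = 0.307, N0 = 30)
#' @export
rogers_expected_eaten <- function(a, h = NULL, N0, T = 1) {
  if (inherits(a, "fr_params")) {
    p <- a
    if (p$variant != "II") stop("rogers_expected_eaten expects variant II parameters")
    if (is.null(h)) h <- p$h
    if (missing(T)) T <- p$T
    a <- p$a
  }
  if (any(a < 0, na.rm = TRUE)) stop("`a` must be >= 0")
  if (any(h < 0, na.rm = TRUE)) stop("`h` must be >= 0")
  if (any(N0 < 0, na.rm = TRUE)) stop("`N0` must be >= 0")
  if (any(T <= 0, na.rm = TRUE)) stop("`T` must be > 0")
  n <- max(length(a), length(h), length(N0), length(T))
  a <- rep_len(a, n); h <- rep_len(h, n); N0 <- rep_len(N0, n); T <- rep_len(T, n)

  ne <- numeric(n)
  zero <- a == 0 | N0 == 0
  lin <- !zero & a * h < 1e-12      # h -> 0 limit; Lambert form degenerates to 0/0
  ne[lin] <- N0[lin] * (1 - exp(-a[lin] * T[lin]))

  full <- !zero & !lin
  if (any(full)) {
    af <- a[full]; hf <- h[full]; nf <- N0[full]; tf <- T[full]
    lz <- log(af * hf * nf) + af * (hf * nf - tf)
    w <- numeric(sum(full))
    big <- lz > 500
    if (any(big)) w[big] <- lambert_w0_log(lz[big])
    if (any(!big)) w[!big] <- lambert_w0(exp(lz[!big]))
    ne[full] <- pmin(pmax(nf - w / (af * hf), 0), nf)
  }
  ne
}

type1_expected <- function(a, N0, T) N0 * (1 - exp(-a * T))

type3_expected <- function(b, c, h, N0, T) {
  a_eff <- b * N0 / (1 + c * N0)
  rogers_expected_eaten(a_eff, h, N0, T)
}

#' Expected prey eaten under Type I and Type III responses
#'
#' Alternatives to the Rogers Type II model, sharing its depletion
#' (non-replacement) structure. Variant \code{"I"} is the linear limit
#' \eqn{N_e = N_0(1 - e^{-aT})}; variant \code{"III"} replaces the constant
#' attack rate with \eqn{a(N_0) = b N_0/(1 + c N_0)} inside the Rogers
#' solution, giving the sigmoid low-density refuge.
#'
#' @param params an \code{\link{fr_params}} object of variant \code{"I"}
#'   or \code{"III"}.
#' @param N0 initial prey density (vectorized).
#' @param T trial duration; defaults to \code{params$T}.
#' @return expected number of prey eaten, in \code{[0, N0]}.
#' @examples
#' alt_response_expected(fr_params(a = 0.5, variant = "I"), N0 = 10)
#' @export
alt_response_expected <- function(params, N0, T = params$T) {
  if (!inherits(params, "fr_params")) stop("`params` must be an fr_params object")
  switch(params$variant,
         I   = type1_expected(params$a, N0, T),
         III = type3_expected(params$b, params$c, params$h, N0, T),
         stop("`params` must have variant I or III; use rogers_expected_eaten for II"))
}

#' Expected prey eaten for any response variant
#'
#' Dispatches on the variant of \code{params}: the Rogers solution for
#' Type II, and \code{\link{alt_response_expected}} otherwise.
#'
#' @inheritParams alt_response_expected
#' @return expected number of prey eaten.
#' @export
expected_response <- function(params, N0, T = params$T) {
  if (params$variant == "II") rogers_expected_eaten(params$a, params$h, N0, T)
  else alt_response_expected(params, N0, T)
}
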