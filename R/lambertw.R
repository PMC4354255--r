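#' Principal branch of the Lambert W function
#'
#' Computes \eqn{W_0(z)}, the principal-branch solution of \eqn{w e^w = z},
#' for \eqn{z \ge -1/e}. This is the branch on which the Rogers
#' random-predator equation has its physically admissible solution
#' (number of prey eaten between 0 and the initial density).
#'
#' Vectorized. Uses a Halley iteration from a branch-aware starting point:
#' a square-root expansion near the branch point \eqn{z = -1/e}, the
#' identity start \eqn{w_0 = z} near 0, and \eqn{\log z - \log\log z} for
#' large arguments. Values of \code{z} within \code{1e-12} below \eqn{-1/e}
#' are clamped to the branch point.
#'
#' @param z numeric vector, each element \eqn{\ge -1/e} (tolerance
#'   \code{1e-12} below, clamped).
#' @return numeric vector \code{w} with \code{w * exp(w) == z} to at most
#'   \code{1e-10} relative error.
#' @examples
#' lambert_w0(0)           # 0
#' lambert_w0(-exp(-1))    # -1 (branch point)
#' lambert_w0(1)           # 0.5671433...
#' @export
lambert_w0 <- function(z) {
  if (!is.numeric(z)) stop("`z` must be numeric")
  brk <- -exp(-1)
  bad <- !is.na(z) & z < brk - 1e-12
  if (any(bad)) {
    stop(sprintf("lambert_w0: z = %.15g is below the branch point -1/e",
                 z[which(bad)[1L]]))
  }
  z <- pmax(z, brk)
  w <- numeric(length(z))
  w[] <- NA_real_

  at_brk <- !is.na(z) & z <= brk + 1e-15
  w[at_brk] <- -1

  todo <- !is.na(z) & !at_brk
  if (any(todo)) {
    zi <- z[todo]
    w0 <- numeric(length(zi))
    near_branch <- zi < -0.25
    small <- !near_branch & zi < 1
    large <- !near_branch & !small
    # series about the branch point: w = -1 + p - p^2/3, p = sqrt(2(e z + 1))
    p <- sqrt(2 * (exp(1) * zi[near_branch] + 1))
    w0[near_branch] <- -1 + p - p^2 / 3
    w0[small] <- zi[small] * exp(-pmin(zi[small], 1))
    lz <- log(zi[large])
    w0[large] <- lz - log(pmax(lz, 1e-12))
    w0 <- pmax(w0, -1 + 1e-12)
    for (iter in 1:50) {
      ew <- exp(w0)
      f  <- w0 * ew - zi
      # Halley step
      denom <- ew * (w0 + 1) - (w0 + 2) * f / (2 * w0 + 2)
      dw <- f / denom
      w0 <- w0 - dw
      if (all(abs(dw) <= 1e-12 * pmax(abs(w0), 1e-3))) break
    }
    w[todo] <- w0
  }
  w[is.na(z)] <- NA_real_
  w
}

# Solve w + log(w) = lz (w > 0) for very large Lambert arguments supplied in
# log space; avoids overflow of exp() in the Rogers solution when a*h*N0 and
# the exponent are jointly large.
lambert_w0_log <- function(lz) {
  w <- pmax(lz - log(pmax(lz, 2)), 1)
  for (iter in 1:50) {
    f <- w + log(w) - lz
    dw <- f / (1 + 1 / w)
    w <- w - dw
    if (all(abs(dw) <= 1e-12 * w)) break
  }
  w
}
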