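#' Polynomial logistic regression of proportion killed on density
#'
#' The phenomenological response-type test: a binomial GLM (logit link) of
#' killed out of initial density against a raw polynomial in density
#' (degree 2 by default — first- and second-order terms are what the sign
#' rules use). Density is entered untransformed and uncentred because the
#' classification rules refer to the raw-density terms. Kills here include
#' partially as well as completely eaten prey, which is what the
#' \code{killed} count records.
#'
#' @param records trial records of one community module (or any subset
#'   over >= 3 distinct densities).
#' @param degree polynomial degree (default 2).
#' @return list of class \code{"fr_type_fit"}: \code{coefficients}
#'   (data.frame term / estimate / se / z / p), \code{converged},
#'   \code{logLik}, \code{aic}, and the underlying \code{glm} object.
#' @export
fit_logistic_poly <- function(records, degree = 2) {
  if (length(unique(records$density)) < 3)
    stop("need >= 3 distinct densities")
  if (any(records$killed > records$density)) stop("killed exceeds density")
  df <- data.frame(killed = records$killed,
                   alive = records$density - records$killed,
                   N0 = records$density)
  form <- stats::as.formula(paste(
    "cbind(killed, alive) ~", paste(sprintf("I(N0^%d)", seq_len(degree)), collapse = " + ")))
  sep_flag <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_flag <<- TRUE
      invokeRestart("muffleWarning")
    })
  # quasi-separation can converge to a perfect fit with runaway
  # coefficients and no warning; treat saturated linear predictors as
  # non-convergence too
  if (any(abs(stats::predict(fit, type = "link")) > 15)) sep_flag <- TRUE
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = c("intercept", paste0("order", seq_len(degree))),
                      estimate = sm[, 1], se = sm[, 2], z = sm[, 3], p = sm[, 4],
                      row.names = NULL)
  structure(list(coefficients = coefs,
                 converged = fit$converged && !sep_flag,
                 logLik = as.numeric(stats::logLik(fit)),
                 aic = stats::AIC(fit),
                 glm = fit),
            class = "fr_type_fit")
}

#' Classify the functional-response type from the logistic-regression fit
#'
#' Sign/significance rules on the polynomial terms: a significant negative
#' first-order term indicates Type II; a significant positive first-order
#' term followed by a significant negative second-order term indicates
#' Type III; anything else is inconclusive (and, in the full workflow,
#' falls through to AIC comparison).
#'
#' @param fit an \code{fr_type_fit}, or a data.frame shaped like its
#'   \code{coefficients} component.
#' @param alpha significance level (default 0.05).
#' @return \code{"TypeII"}, \code{"TypeIII"} or \code{"inconclusive"}.
#' @export
classify_response <- function(fit, alpha = 0.05) {
  coefs <- if (inherits(fit, "fr_type_fit")) fit$coefficients else fit
  b1 <- coefs[coefs$term == "order1", ]
  b2 <- coefs[coefs$term == "order2", ]
  if (nrow(b1) == 0) stop("no first-order term in fit")
  if (b1$p < alpha && b1$estimate < 0) return("TypeII")
  if (nrow(b2) == 1 && b1$p < alpha && b1$estimate > 0 &&
      b2$p < alpha && b2$estimate < 0) return("TypeIII")
  "inconclusive"
}

# no-treatment binomial MLE of one response variant; used by the AIC fallback
fit_variant_nll <- function(theta, records, variant, T) {
  par <- switch(variant,
                I   = list(a = theta[1], h = 0),
                II  = list(a = theta[1], h = theta[2]),
                III = list(b = theta[1], c = theta[2], h = theta[3]))
  if (any(unlist(par) < 0)) return(1e10)
  ne <- switch(variant,
               I   = type1_expected(par$a, records$density, T),
               II  = rogers_expected_eaten(par$a, par$h, records$density, T),
               III = type3_expected(par$b, par$c, par$h, records$density, T))
  p <- pmin(pmax(ne / records$density, 1e-9), 1 - 1e-9)
  -sum(stats::dbinom(records$killed, records$density, p, log = TRUE))
}

fit_variant <- function(records, variant, T = 1) {
  start <- switch(variant,
                  I   = c(a = 0.5),
                  II  = c(a = 0.5, h = 0.1),
                  III = c(b = 0.05, c = 0.05, h = 0.1))
  opt <- tryCatch(
    if (length(start) == 1L)
      stats::optim(start, fit_variant_nll, records = records, variant = variant,
                   T = T, method = "Brent", lower = 0, upper = 1e3)
    else
      stats::optim(start, fit_variant_nll, records = records, variant = variant,
                   T = T, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e9)
    return(list(converged = FALSE, logLik = NA_real_, k = length(start),
                theta = NULL))
  list(converged = opt$convergence == 0, logLik = -opt$value,
       k = length(start), theta = opt$par)
}

#' AIC comparison of Type I, II and III response fits
#'
#' The fallback when the sign rules are inconclusive: fits each variant
#' with no treatment terms by binomial maximum likelihood and compares
#' AIC = 2k - 2 logLik. Variants that fail to converge are recorded with
#' missing logLik and excluded from selection.
#'
#' @param records trial records of one module.
#' @param variants which variants to compare (default I, II, III).
#' @param T trial duration (default 1).
#' @return list: \code{aic_table} (data.frame variant / logLik / k / AIC)
#'   and \code{selected_variant}.
#' @export
aic_model_comparison <- function(records, variants = c("I", "II", "III"), T = 1) {
  fits <- lapply(variants, function(v) fit_variant(records, v, T))
  tab <- data.frame(variant = variants,
                    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
                    k = vapply(fits, `[[`, numeric(1), "k"))
  tab$AIC <- 2 * tab$k - 2 * tab$logLik
  ok <- vapply(fits, `[[`, logical(1), "converged") & is.finite(tab$AIC)
  sel <- if (any(ok)) tab$variant[ok][which.min(tab$AIC[ok])] else NA_character_
  list(aic_table = tab, selected_variant = sel)
}

#' Full response-type test for one module
#'
#' Runs the polynomial logistic regression, applies the sign rules, and —
#' when they are inconclusive — falls through to the AIC comparison across
#' Type I/II/III, mirroring the phenomenological workflow.
#'
#' @inheritParams fit_logistic_poly
#' @param alpha significance level for the sign rules.
#' @return list: \code{fit}, \code{classification} (from the sign rules),
#'   \code{aic} (NULL unless invoked), \code{selected_variant} (sign-rule
#'   type, or the AIC choice when inconclusive).
#' @export
type_test <- function(records, degree = 2, alpha = 0.05) {
  fit <- fit_logistic_poly(records, degree)
  cls <- classify_response(fit, alpha)
  aic <- NULL
  selected <- switch(cls, TypeII = "II", TypeIII = "III", NA_character_)
  if (cls == "inconclusive") {
    aic <- aic_model_comparison(records)
    selected <- aic$selected_variant
  }
  list(fit = fit, classification = cls, aic = aic, selected_variant = selected)
}
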