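# Mixture chi-square likelihood-ratio test and derived variance ratios.

#' Boundary-corrected likelihood-ratio test for the dominance variance
#'
#' Tests the additive + dominance model against the additive model. Because
#' the null value of the dominance variance lies on the boundary of the
#' parameter space, the reference distribution of the statistic
#' `2 (logL_AD - logL_A)` is the 50:50 mixture of a point mass at zero
#' (chi-square with 0 df) and a chi-square with 1 df:
#' `p = 0.5 Pr(chisq_1 >= statistic)` for a positive statistic and `p = 1`
#' when the statistic is zero. The chi-square(1) critical value at `P = 0.01`
#' therefore marks the top 0.005 of the mixture null.
#'
#' @param logl_a Restricted log-likelihood of the additive model.
#' @param logl_ad Restricted log-likelihood of the additive + dominance model.
#' @return List of class `mixture_lrt` with `statistic`, `p_value`, and the
#'   two log-likelihoods.
#' @export
mixture_lrt <- function(logl_a, logl_ad) {
  stopifnot(is.finite(logl_a), is.finite(logl_ad))
  stat <- max(0, 2 * (logl_ad - logl_a))
  p <- if (stat > 0) 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE) else 1
  structure(list(statistic = stat, p_value = p,
                 logl_a = logl_a, logl_ad = logl_ad),
            class = "mixture_lrt")
}

#' @export
print.mixture_lrt <- function(x, ...) {
  cat("Likelihood-ratio test of the dominance variance\n")
  cat(sprintf("  logL additive     : %.4f\n", x$logl_a))
  cat(sprintf("  logL add+dominance: %.4f\n", x$logl_ad))
  cat(sprintf("  statistic = %.4f, p = %.4g (50:50 chisq(0)/chisq(1) mixture)\n",
              x$statistic, x$p_value))
  invisible(x)
}

#' Heritabilities and variance ratios from fitted components
#'
#' Computes the total phenotypic variance (sum of all fitted components), the
#' additive and dominance heritabilities, the dominance share of the genetic
#' variance \eqn{\sigma^2_d / (\sigma^2_a + \sigma^2_d)}, and the
#' repeatability \eqn{(\sigma^2_a + \sigma^2_d + \sigma^2_{pe}) / \sigma^2_p}.
#'
#' @param components A [gblup()] fit, or a named vector with `sigma_a2`,
#'   `sigma_pe2`, `sigma_e2` and optionally `sigma_d2` (absent means zero).
#' @return Named numeric vector `sigma_p2`, `h_a2`, `h_d2`,
#'   `dominance_share`, `repeatability`.
#' @export
variance_ratios <- function(components) {
  th <- if (inherits(components, "gblup")) components$components else components
  if (is.null(names(th))) {
    stop_invalid("components must be named (sigma_a2, [sigma_d2,] sigma_pe2, sigma_e2)")
  }
  need <- c("sigma_a2", "sigma_pe2", "sigma_e2")
  if (!all(need %in% names(th))) {
    stop_invalid("components must include ", paste(need, collapse = ", "))
  }
  a <- th[["sigma_a2"]]
  d <- if ("sigma_d2" %in% names(th)) th[["sigma_d2"]] else 0
  pe <- th[["sigma_pe2"]]
  e <- th[["sigma_e2"]]
  if (any(c(a, d, pe, e) < 0)) stop_invalid("components must be >= 0")
  sp <- a + d + pe + e
  if (sp <= 0) stop_invalid("total phenotypic variance is zero")
  c(sigma_p2 = sp, h_a2 = a / sp, h_d2 = d / sp,
    dominance_share = if (a + d > 0) d / (a + d) else 0,
    repeatability = (a + d + pe) / sp)
}
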