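# S3 methods for fitted gblup objects.

#' @export
print.gblup <- function(x, digits = 4, ...) {
  cat("GBLUP", if (x$include_dominance) "additive + dominance" else "additive",
      "model (repeated records)\n")
  cat(sprintf("  %d records on %d animals; REML %s after %d iterations\n",
              x$n_records, x$n_animals, x$message, x$iterations))
  cat(sprintf("  logL = %.4f, mu = %.*g\n", x$logl, digits, x$mu))
  tab <- format(signif(x$components, digits))
  cat("  components:", paste(names(x$components), tab, sep = " = ",
                             collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a fitted GBLUP model
#'
#' @param object A [gblup()] fit.
#' @param ... Unused.
#' @return List of class `summary.gblup` with the component table (estimate,
#'   SE, boundary flag), derived variance ratios, log-likelihood and
#'   convergence information.
#' @export
summary.gblup <- function(object, ...) {
  tab <- data.frame(component = names(object$components),
                    estimate = unname(object$components),
                    se = unname(object$se),
                    boundary = unname(object$boundary),
                    stringsAsFactors = FALSE)
  structure(list(components = tab, ratios = variance_ratios(object),
                 mu = object$mu, logl = object$logl,
                 converged = object$converged, iterations = object$iterations,
                 include_dominance = object$include_dominance,
                 n_records = object$n_records, n_animals = object$n_animals),
            class = "summary.gblup")
}

#' @export
print.summary.gblup <- function(x, digits = 4, ...) {
  cat("GBLUP", if (x$include_dominance) "additive + dominance" else "additive",
      "model\n")
  cat(sprintf("%d records on %d animals; %s (%d iterations); logL = %.4f\n\n",
              x$n_records, x$n_animals,
              if (x$converged) "converged" else "not converged",
              x$iterations, x$logl))
  tab <- x$components
  tab$estimate <- signif(tab$estimate, digits)
  tab$se <- signif(tab$se, digits)
  print(tab, row.names = FALSE)
  r <- x$ratios
  cat(sprintf("\nsigma_p2 = %.4g, h_a2 = %.3f, h_d2 = %.3f, dominance share = %.3f, repeatability = %.3f\n",
              r[["sigma_p2"]], r[["h_a2"]], r[["h_d2"]],
              r[["dominance_share"]], r[["repeatability"]]))
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) c(mu = object$mu)

#' @export
logLik.gblup <- function(object, ...) {
  structure(object$logl, df = sum(!object$boundary) + 1L,
            nobs = object$n_records, class = "logLik")
}

#' Genetic-value predictions from a fitted GBLUP model
#'
#' Returns per-animal breeding values, dominance deviations, total genetic
#' values and permanent-environmental solutions. Animals that are in the
#' relationship matrices but had no records (e.g. validation animals) are
#' predicted through their genomic covariances with the phenotyped animals.
#'
#' @param object A [gblup()] fit.
#' @param ids Optional animal ids to return (default: all animals in `G`).
#' @param ... Unused.
#' @return Data frame with `animal_id`, `bv`, `dv`, `tgv`, `pe`, `phenotyped`.
#' @export
predict.gblup <- function(object, ids = NULL, ...) {
  gv <- object$genetic_values
  if (is.null(ids)) return(gv)
  j <- match(ids, gv$animal_id)
  if (anyNA(j)) {
    stop_invalid("unknown animal ids: ",
                 paste(ids[is.na(j)][1:5], collapse = ", "))
  }
  out <- gv[j, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
fitted.gblup <- function(object, ...) {
  gv <- object$genetic_values
  j <- match(object$records$animal_id, gv$animal_id)
  object$mu + gv$bv[j] + gv$dv[j] + gv$pe[j]
}

#' @export
residuals.gblup <- function(object, ...) {
  object$records$value - fitted(object)
}

#' Compare additive and additive + dominance fits
#'
#' Likelihood-ratio comparison of a nested pair of [gblup()] fits (one without
#' and one with the dominance term) against the boundary-corrected 50:50
#' mixture of chi-square distributions with 0 and 1 degree of freedom.
#'
#' @param object,... Two `gblup` fits in either order.
#' @return A [mixture_lrt()] result.
#' @export
anova.gblup <- function(object, ...) {
  others <- Filter(function(o) inherits(o, "gblup"), list(...))
  if (length(others) != 1L) {
    stop_invalid("supply exactly two gblup fits (additive and additive + dominance)")
  }
  b <- others[[1]]
  if (object$include_dominance == b$include_dominance) {
    stop_invalid("the two fits must differ in the dominance term")
  }
  fit_a <- if (object$include_dominance) b else object
  fit_ad <- if (object$include_dominance) object else b
  mixture_lrt(fit_a$logl, fit_ad$logl)
}
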