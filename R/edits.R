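# Record-editing rules and fixed-effect pre-adjustment of phenotypes.

#' Default record-edit rules
#'
#' Keep-ranges (and, for calving interval, the cap-range) applied to raw
#' records before analysis. Defaults: calving interval (CI) valid on
#' \[290, 550\] days with values in \[551, 762\] capped at 551; milk yield kept
#' on \[2000, 15000\] L; fat yield on \[50, 800\] kg; protein yield on
#' \[45, 600\] kg.
#'
#' @return Named list of rules, one per trait label; each rule has `keep`
#'   (length-2 inclusive keep-range) and optionally `cap` (inclusive range
#'   whose values are set to `cap_to`).
#' @export
edit_rules <- function() {
  list(CI      = list(keep = c(290, 550), cap = c(551, 762), cap_to = 551),
       milk    = list(keep = c(2000, 15000)),
       fat     = list(keep = c(50, 800)),
       protein = list(keep = c(45, 600)))
}

#' Apply record-edit filters
#'
#' Drops records outside the trait's keep-range; for traits with a cap-range
#' (calving interval), values inside the cap-range are set to the cap value
#' instead of being dropped.
#'
#' @param records Phenotype data frame with a `value` column.
#' @param trait Trait label naming a rule in `rules`.
#' @param rules Rule set, by default [edit_rules()].
#' @return List with `records` (filtered copy), `n_dropped` and `n_capped`.
#' @export
apply_edit_filters <- function(records, trait, rules = edit_rules()) {
  if (!trait %in% names(rules)) {
    stop_invalid("unknown trait label '", trait, "'; known: ",
                 paste(names(rules), collapse = ", "))
  }
  rule <- rules[[trait]]
  v <- records$value
  capped <- if (!is.null(rule$cap)) v >= rule$cap[1] & v <= rule$cap[2] else
    rep(FALSE, length(v))
  keep <- (v >= rule$keep[1] & v <= rule$keep[2]) | capped
  out <- records[keep, , drop = FALSE]
  out$value[capped[keep]] <- rule$cap_to
  rownames(out) <- NULL
  list(records = out, n_dropped = sum(!keep), n_capped = sum(capped))
}

#' Pre-adjust phenotypes for fixed effects
#'
#' Ordinary least-squares fit of the record values on the supplied covariates
#' (plus an intercept); the residuals replace the record values, mirroring the
#' usual two-step genomic evaluation in which contemporary-group and other
#' fixed effects are removed before the genetic model is fitted. Redundant
#' (linearly dependent) covariate columns are dropped with a message.
#'
#' @param records Phenotype data frame with a `value` column.
#' @param design Data frame or matrix of covariates, one row per record;
#'   factors/characters are expanded to dummies. `NULL` fits intercept only
#'   (residuals are the values minus the grand mean).
#' @return `records` with `value` replaced by OLS residuals.
#' @export
adjust_phenotypes <- function(records, design = NULL) {
  y <- records$value
  if (!all(is.finite(y))) stop_invalid("record values must be finite")
  if (is.null(design)) {
    X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    df <- as.data.frame(design)
    if (nrow(df) != length(y)) {
      stop_invalid("design must have one row per record")
    }
    X <- stats::model.matrix(~ ., data = df)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    message("dropping redundant design columns: ",
            paste(drop_cols, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    if (qr(X)$rank < ncol(X)) {
      stop_invalid("design still rank-deficient after pruning: ",
                   paste(colnames(X), collapse = ", "))
    }
  }
  fit <- stats::lm.fit(X, y)
  out <- records
  out$value <- unname(fit$residuals)
  out
}
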