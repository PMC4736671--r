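# REML estimation and BLUP solving for the repeated-records GBLUP model
#
#   y = 1 mu + W u + [W d] + W pe + e,
#   u ~ N(0, G sigma_a2), d ~ N(0, D sigma_d2),
#   pe ~ N(0, I sigma_pe2), e ~ N(0, I sigma_e2),
#
# with W the record -> animal incidence matrix. The restricted likelihood is
# evaluated on an exact orthogonal decomposition of the records into
# within-animal contrasts (n - q of them, iid with variance sigma_e2) and
# animal means ybar ~ N(1 mu, Sigma) with
#   Sigma = sigma_a2 G + sigma_d2 D + sigma_pe2 I + sigma_e2 diag(1/n_i),
# so every iteration works on q x q matrices regardless of record counts.

#' Control parameters for the REML fit
#'
#' @param max_iter Maximum iterations (EM warm-up plus average-information).
#' @param tol_logl Convergence threshold on the relative log-likelihood change.
#' @param tol_comp Convergence threshold on the relative component change
#'   (relative to the phenotypic variance).
#' @param em_iter Number of EM warm-up iterations before switching to
#'   average-information updates.
#' @param ridge Relative ridge added to the covariance diagonal only if a
#'   Cholesky factorization fails (logged via a message when applied).
#' @param pin_after Number of consecutive iterations a component must sit at
#'   the zero boundary before it is fixed there.
#' @param verbose Print per-iteration progress.
#' @return List of class `gblup_control`.
#' @export
gblup_control <- function(max_iter = 200L, tol_logl = 1e-8, tol_comp = 1e-6,
                          em_iter = 5L, ridge = 1e-8, pin_after = 3L,
                          verbose = FALSE) {
  structure(list(max_iter = as.integer(max_iter), tol_logl = tol_logl,
                 tol_comp = tol_comp, em_iter = as.integer(em_iter),
                 ridge = ridge, pin_after = as.integer(pin_after),
                 verbose = isTRUE(verbose)),
            class = "gblup_control")
}

#' Record-to-animal incidence matrix
#'
#' @param records Phenotype data frame with an `animal_id` column.
#' @param ids Animal id order defining the columns.
#' @return records x animals 0/1 matrix; each row selects exactly one animal.
#' @export
incidence_matrix <- function(records, ids) {
  j <- match(records$animal_id, ids)
  if (anyNA(j)) {
    stop_invalid("records refer to animal ids absent from the id list: ",
                 paste(unique(records$animal_id[is.na(j)]), collapse = ", "))
  }
  W <- matrix(0, nrow(records), length(ids), dimnames = list(NULL, ids))
  W[cbind(seq_len(nrow(records)), j)] <- 1
  W
}

# Collapse records to per-animal means, record counts and the within-animal
# residual sum of squares.
collapse_records <- function(records) {
  if (!all(c("animal_id", "value") %in% names(records))) {
    stop_invalid("records must have animal_id and value columns")
  }
  y <- records$value
  if (!all(is.finite(y))) stop_invalid("record values must be finite")
  f <- factor(records$animal_id, levels = unique(records$animal_id))
  ni <- as.numeric(table(f))
  ybar <- as.numeric(tapply(y, f, mean))
  rss_w <- sum((y - ybar[as.integer(f)])^2)
  list(ids = levels(f), ybar = ybar, ni = ni, rss_w = rss_w,
       n = length(y), q = nlevels(f))
}

chol_safe <- function(S, ridge) {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    message("covariance factorization failed; applying ridge of ", ridge)
    R <- chol(S + diag(ridge * mean(diag(S)), nrow(S)))
  }
  R
}

# Evaluate the restricted log-likelihood and its derivative quantities at
# theta (named vector over the active components). Returns NULL if the
# parameters are inadmissible.
reml_eval <- function(theta, dat, ridge = 1e-8, derivs = TRUE) {
  th_e <- theta[["sigma_e2"]]
  if (any(theta < 0)) return(NULL)
  if (dat$n > dat$q && th_e <= 0) return(NULL)
  S <- theta[["sigma_a2"]] * dat$G
  if (!is.null(dat$D)) S <- S + theta[["sigma_d2"]] * dat$D
  diag(S) <- diag(S) + theta[["sigma_pe2"]] + th_e / dat$ni
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    if (is.null(ridge)) return(NULL)
    R <- tryCatch(chol_safe(S, ridge), error = function(e) NULL)
    if (is.null(R)) return(NULL)
  }
  Sinv <- chol2inv(R)
  si1 <- rowSums(Sinv)
  xtSx <- sum(si1)
  mu <- sum(si1 * dat$ybar) / xtSx
  r <- dat$ybar - mu
  w <- drop(Sinv %*% r)
  quad <- sum(r * w)
  within <- if (dat$n > dat$q) {
    (dat$n - dat$q) * log(th_e) + dat$rss_w / th_e
  } else 0
  logl <- -0.5 * ((dat$n - 1) * log(2 * pi) + within + sum(log(dat$ni)) +
                    2 * sum(log(diag(R))) + log(xtSx) + quad)
  out <- list(logl = logl, mu = mu, w = w, Sinv = Sinv)
  if (!derivs) return(out)
  P <- Sinv - tcrossprod(si1) / xtSx
  f <- list(sigma_a2 = drop(dat$G %*% w))
  tr <- c(sigma_a2 = sum(P * dat$G))
  if (!is.null(dat$D)) {
    f$sigma_d2 <- drop(dat$D %*% w)
    tr["sigma_d2"] <- sum(P * dat$D)
  }
  f$sigma_pe2 <- w
  tr["sigma_pe2"] <- sum(diag(P))
  f$sigma_e2 <- w / dat$ni
  tr["sigma_e2"] <- sum(diag(P) / dat$ni)
  nm <- names(theta)
  score <- vapply(nm, function(j) {
    -0.5 * (tr[[j]] - sum(w * f[[j]]))
  }, numeric(1))
  if (dat$n > dat$q) {
    score[["sigma_e2"]] <- score[["sigma_e2"]] -
      0.5 * ((dat$n - dat$q) / th_e - dat$rss_w / th_e^2)
  }
  k <- length(nm)
  AI <- matrix(0, k, k, dimnames = list(nm, nm))
  Pf <- lapply(f, function(v) drop(P %*% v))
  for (i in seq_len(k)) for (j in i:k) {
    AI[i, j] <- AI[j, i] <- 0.5 * sum(f[[nm[i]]] * Pf[[nm[j]]])
  }
  if (dat$n > dat$q) {
    AI["sigma_e2", "sigma_e2"] <- AI["sigma_e2", "sigma_e2"] +
      0.5 * dat$rss_w / th_e^3
  }
  out$P <- P
  out$score <- score
  out$AI <- AI
  out
}

# Denominators for the EM update theta + 2 theta^2 / den * score.
em_denominators <- function(nm, dat) {
  den <- stats::setNames(rep(dat$q, length(nm)), nm)
  den["sigma_e2"] <- dat$n
  den
}

reml_fit_core <- function(dat, control, include_dominance) {
  nm <- c("sigma_a2", if (include_dominance) "sigma_d2", "sigma_pe2",
          "sigma_e2")
  mean_y <- sum(dat$ni * dat$ybar) / dat$n
  vtot <- (dat$rss_w + sum(dat$ni * (dat$ybar - mean_y)^2)) / max(dat$n - 1, 1)
  trace <- data.frame()
  if (vtot <= .Machine$double.eps * (1 + mean_y^2)) {
    theta <- stats::setNames(rep(0, length(nm)), nm)
    na <- stats::setNames(rep(NA_real_, length(nm)), nm)
    return(list(theta = theta, se = na, se_all = na,
                mu = mean_y, logl = NA_real_, converged = TRUE, iter = 0L,
                boundary = theta == 0, trace = trace,
                message = "constant phenotype: all components at the 0 boundary"))
  }
  start <- c(sigma_a2 = 0.3, sigma_d2 = 0.1, sigma_pe2 = 0.2, sigma_e2 = 0.5)
  theta <- stats::setNames(start[nm] * vtot / sum(start[nm]), nm)
  den <- em_denominators(nm, dat)
  floor_e <- 1e-12 * vtot
  zero_run <- stats::setNames(integer(length(nm)), nm)
  fixed <- stats::setNames(rep(FALSE, length(nm)), nm)
  ev <- reml_eval(theta, dat, control$ridge)
  if (is.null(ev)) stop_invalid("restricted likelihood not evaluable at the starting values")
  converged <- FALSE
  iter <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    trace <- rbind(trace, data.frame(iter = iter, logl = ev$logl,
                                     as.list(theta)))
    free <- !fixed
    em_step <- theta
    em_step[free] <- theta[free] + 2 * theta[free]^2 / den[free] * ev$score[free]
    step_ok <- FALSE
    cand <- theta
    ev_new <- ev
    if (iter > control$em_iter) {
      # active set: a component resting on the zero boundary with a negative
      # score stays put (KKT), so the Newton step for the rest is undistorted
      active <- free & !(theta == 0 & ev$score < 0)
      # average-information step with Levenberg-Marquardt damping: escalate
      # the damping until the step is an admissible ascent that improves logL
      if (any(active)) {
        Aact <- ev$AI[active, active, drop = FALSE]
        for (lambda in c(0, 0.1, 1, 10, 100)) {
          Ad <- Aact + lambda * diag(diag(Aact), nrow(Aact))
          delta <- tryCatch(solve(Ad, ev$score[active]),
                            error = function(e) NULL)
          if (is.null(delta) || any(!is.finite(delta)) ||
              sum(ev$score[active] * delta) <= 0) next
          prop <- theta
          prop[active] <- theta[active] + delta
          prop <- clamp_components(prop, floor_e, dat)
          ev_prop <- reml_eval(prop, dat, control$ridge)
          half <- 0L
          while ((is.null(ev_prop) || ev_prop$logl < ev$logl - 1e-10) &&
                 half < 10L) {
            half <- half + 1L
            prop <- clamp_components(theta + (prop - theta) / 2, floor_e, dat)
            ev_prop <- reml_eval(prop, dat, control$ridge)
          }
          if (!is.null(ev_prop) && ev_prop$logl >= ev$logl - 1e-10) {
            cand <- prop
            ev_new <- ev_prop
            step_ok <- TRUE
            break
          }
        }
      }
    }
    if (!step_ok) { # EM warm-up, or the quadratic step failed even damped
      cand <- clamp_components(em_step, floor_e, dat)
      ev_new <- reml_eval(cand, dat, control$ridge)
      if (is.null(ev_new)) break
      if (iter > control$em_iter && ev_new$logl < ev$logl - 1e-10) {
        converged <- TRUE  # cannot improve in any direction
        break
      }
    }
    at_zero <- cand == 0 & free
    zero_run[at_zero] <- zero_run[at_zero] + 1L
    zero_run[!at_zero] <- 0L
    fixed <- fixed | zero_run >= control$pin_after
    dl <- abs(ev_new$logl - ev$logl) / (1 + abs(ev_new$logl))
    dth <- max(abs(cand - theta)) / vtot
    theta <- cand
    ev <- ev_new
    if (control$verbose) {
      cat(sprintf("iter %3d logL %.8f  %s\n", iter, ev$logl,
                  paste(sprintf("%s=%.6g", names(theta), theta), collapse = " ")))
    }
    if (iter > control$em_iter && dl < control$tol_logl &&
        dth < control$tol_comp) {
      converged <- TRUE
      break
    }
  }
  se <- stats::setNames(rep(NA_real_, length(nm)), nm)
  free_se <- theta > 0
  Vth <- tryCatch(solve(ev$AI[free_se, free_se, drop = FALSE]),
                  error = function(e) NULL)
  if (!is.null(Vth)) {
    dse <- diag(Vth)
    dse[dse < 0] <- NA_real_
    se[free_se] <- sqrt(dse)
  }
  # curvature-based uncertainty for every component, boundary ones included
  # (reported se stays NA at the boundary; this feeds recovery diagnostics)
  se_all <- stats::setNames(rep(NA_real_, length(nm)), nm)
  Vall <- tryCatch(solve(ev$AI), error = function(e) NULL)
  if (!is.null(Vall)) {
    dall <- diag(Vall)
    dall[dall < 0] <- NA_real_
    se_all[] <- sqrt(dall)
  }
  list(theta = theta, se = se, se_all = se_all, mu = ev$mu, logl = ev$logl,
       converged = converged, iter = iter, boundary = theta == 0,
       trace = trace, w = ev$w,
       message = if (converged) "converged" else "maximum iterations reached")
}

clamp_components <- function(theta, floor_e, dat) {
  theta[theta < 0] <- 0
  if (dat$n > dat$q && theta[["sigma_e2"]] < floor_e) {
    theta[["sigma_e2"]] <- floor_e
  }
  theta
}

# Align phenotyped animals with the relationship matrices and collapse records.
prepare_gblup_data <- function(records, G, D) {
  ids_all <- rownames(G)
  if (is.null(ids_all)) stop_invalid("G must carry animal ids as row names")
  if (!is.null(D)) {
    if (!identical(rownames(D), ids_all)) {
      stop_invalid("G and D must index the same animals in the same order")
    }
  }
  cr <- collapse_records(records)
  if (!all(cr$ids %in% ids_all)) {
    stop_invalid("phenotyped animals missing from G: ",
                 paste(setdiff(cr$ids, ids_all)[1:5], collapse = ", "))
  }
  idx <- match(cr$ids, ids_all)
  dat <- list(G = unclass(G)[idx, idx, drop = FALSE],
              D = if (!is.null(D)) unclass(D)[idx, idx, drop = FALSE],
              ybar = cr$ybar, ni = cr$ni, rss_w = cr$rss_w,
              n = cr$n, q = cr$q)
  list(dat = dat, cr = cr, idx = idx, ids_all = ids_all, G = G, D = D)
}

#' Fit a GBLUP model with additive (and optionally dominance) effects
#'
#' Estimates the variance components of the repeated-records model
#' `y = 1 mu + W u + [W d] + W pe + e` by restricted maximum likelihood
#' (EM warm-up followed by average-information updates, components floored at
#' zero) and solves the corresponding mixed-model equations for breeding
#' values, dominance deviations, total genetic values and
#' permanent-environmental effects. Animals present in `G` but without
#' records receive genetic-value predictions through their genomic
#' covariances with the phenotyped animals.
#'
#' @param records Phenotype data frame with columns `animal_id` and `value`
#'   (one row per record; animals may repeat).
#' @param G Additive genomic relationship matrix over all animals of interest
#'   (phenotyped and, optionally, prediction-only), from [grm_additive()].
#' @param D Optional dominance relationship matrix from [grm_dominance()],
#'   over the same animals in the same order; include it to fit the
#'   additive + dominance model.
#' @param control A [gblup_control()].
#' @return Object of class `gblup` with components, standard errors (`$se`,
#'   `NA` for components fixed at the zero boundary; `$se_all` carries the
#'   curvature-based uncertainty for every component), fitted mean, restricted
#'   log-likelihood, convergence information, iteration trace, and per-animal
#'   genetic values (`$genetic_values`: `animal_id`, `bv`, `dv`, `tgv`, `pe`,
#'   `phenotyped`).
#' @seealso [summary.gblup()], [predict.gblup()], [anova.gblup()],
#'   [variance_ratios()], [reml_loglik()]
#' @export
gblup <- function(records, G, D = NULL, control = gblup_control()) {
  prep <- prepare_gblup_data(records, G, D)
  fit <- reml_fit_core(prep$dat, control, include_dominance = !is.null(D))
  w <- fit$w %||% rep(0, prep$cr$q)
  gv <- blup_from_w(fit$theta, w, prep)
  structure(list(call = match.call(), components = fit$theta, se = fit$se,
                 se_all = fit$se_all,
                 mu = fit$mu, logl = fit$logl, converged = fit$converged,
                 iterations = fit$iter, boundary = fit$boundary,
                 message = fit$message, trace = fit$trace,
                 include_dominance = !is.null(D),
                 n_records = prep$cr$n, n_animals = prep$cr$q,
                 animal_ids = prep$cr$ids, w = w,
                 genetic_values = gv, records = records, G = G, D = D,
                 control = control),
            class = "gblup")
}

# BLUP solutions for every animal in G from the collapsed projection w = P ybar:
# u_hat = sigma_a2 * G[, phen] w, d_hat = sigma_d2 * D[, phen] w,
# pe_hat = sigma_pe2 * w (phenotyped animals only).
blup_from_w <- function(theta, w, prep) {
  ids_all <- prep$ids_all
  idx <- prep$idx
  bv <- theta[["sigma_a2"]] * drop(unclass(prep$G)[, idx, drop = FALSE] %*% w)
  dv <- if (!is.null(prep$D)) {
    theta[["sigma_d2"]] * drop(unclass(prep$D)[, idx, drop = FALSE] %*% w)
  } else rep(0, length(ids_all))
  pe <- rep(0, length(ids_all))
  pe[idx] <- theta[["sigma_pe2"]] * w
  data.frame(animal_id = ids_all, bv = unname(bv), dv = unname(dv),
             tgv = unname(bv + dv), pe = pe,
             phenotyped = seq_along(ids_all) %in% idx,
             stringsAsFactors = FALSE)
}

#' Solve the mixed-model equations at fixed variance components
#'
#' Computes BLUP solutions for breeding values, dominance deviations and
#' permanent-environmental effects at supplied (e.g. previously estimated)
#' variance components, including predictions for animals that appear in the
#' relationship matrices without records.
#'
#' @param components Named vector with `sigma_a2`, `sigma_pe2`, `sigma_e2`
#'   and, when `D` is supplied, `sigma_d2`.
#' @inheritParams gblup
#' @return Data frame with `animal_id`, `bv`, `dv`, `tgv`, `pe`,
#'   `phenotyped`; attribute `mu` carries the generalized-least-squares mean.
#' @export
solve_blup <- function(components, records, G, D = NULL) {
  prep <- prepare_gblup_data(records, G, D)
  theta <- normalize_components(components, !is.null(D))
  if (theta[["sigma_e2"]] <= 0 && any(prep$dat$ni > 1)) {
    stop_invalid("sigma_e2 = 0 with repeated records: likelihood degenerate")
  }
  ev <- reml_eval(theta, prep$dat, ridge = NULL, derivs = FALSE)
  if (is.null(ev)) stop_invalid("phenotypic covariance not positive definite at these components")
  out <- blup_from_w(theta, ev$w, prep)
  attr(out, "mu") <- ev$mu
  out
}

normalize_components <- function(components, include_dominance) {
  nm <- c("sigma_a2", if (include_dominance) "sigma_d2", "sigma_pe2",
          "sigma_e2")
  if (is.null(names(components))) {
    if (length(components) != length(nm)) {
      stop_invalid("expected ", length(nm), " components (", paste(nm, collapse = ", "), ")")
    }
    components <- stats::setNames(as.numeric(components), nm)
  }
  if (!all(nm %in% names(components))) {
    stop_invalid("components must include ", paste(nm, collapse = ", "))
  }
  th <- components[nm]
  if (any(th < 0) || all(th == 0)) {
    stop_invalid("components must be >= 0 and not all zero")
  }
  th
}

#' Restricted log-likelihood at supplied variance components
#'
#' Evaluates the REML log-likelihood of the repeated-records model at fixed
#' components, with the mean profiled out by generalized least squares. Used
#' for likelihood-ratio comparisons and as an oracle hook.
#'
#' @inheritParams solve_blup
#' @return Scalar restricted log-likelihood.
#' @export
reml_loglik <- function(records, G, D = NULL, components) {
  prep <- prepare_gblup_data(records, G, D)
  theta <- normalize_components(components, !is.null(D))
  ev <- reml_eval(theta, prep$dat, ridge = NULL, derivs = FALSE)
  if (is.null(ev)) stop_invalid("phenotypic covariance singular at these components")
  ev$logl
}
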