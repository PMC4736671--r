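# Half-sib-aware cross-validation of predictive ability.

#' Assign animals to cross-validation folds by sire family
#'
#' Whole paternal half-sib families are allocated to folds so that no
#' validation animal shares a sire with any training animal: families are
#' sorted largest first (ties shuffled from `seed`) and each is placed in the
#' currently smallest fold. When dam metadata is supplied, families linked by
#' dam-daughter pairs are merged first so that no predicted cow can have
#' daughters in the training set.
#'
#' @param animals Animal ids.
#' @param sires Sire id per animal, aligned with `animals`.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed for the tie-break shuffle.
#' @param dams Optional dam id per animal (NA where unknown); dams that are
#'   themselves in `animals` are co-assigned with their daughters.
#' @return Data frame of class `fold_assignment` with columns `animal_id`,
#'   `sire_id`, `fold`; attributes `k` and `seed`.
#' @export
assign_folds <- function(animals, sires, k = 5, seed = 1, dams = NULL) {
  if (length(animals) != length(sires)) {
    stop_invalid("animals and sires must be aligned")
  }
  if (k < 2) stop_invalid("k must be >= 2")
  # group = connected component over shared sire and (optional) dam-daughter links
  group <- match(sires, unique(sires))
  if (!is.null(dams)) {
    parent <- seq_along(unique(sires))
    find <- function(i) { while (parent[i] != i) i <- parent[i] <- parent[parent[i]]; i }
    for (a in seq_along(animals)) {
      if (!is.na(dams[a]) && dams[a] %in% animals) {
        gi <- find(group[a])
        gj <- find(group[match(dams[a], animals)])
        if (gi != gj) parent[gj] <- gi
      }
    }
    group <- vapply(group, find, integer(1))
  }
  fam <- split(seq_along(animals), group)
  if (length(fam) < k) {
    stop_invalid("fewer families (", length(fam), ") than folds (", k, ")")
  }
  sizes <- lengths(fam)
  ord <- with_seed(seed, order(-sizes, sample.int(length(fam))))
  fold_of_fam <- integer(length(fam))
  fold_sizes <- numeric(k)
  for (f in ord) {
    target <- which.min(fold_sizes)
    fold_of_fam[f] <- target
    fold_sizes[target] <- fold_sizes[target] + sizes[f]
  }
  fold <- integer(length(animals))
  for (f in seq_along(fam)) fold[fam[[f]]] <- fold_of_fam[f]
  out <- data.frame(animal_id = animals, sire_id = sires, fold = fold,
                    stringsAsFactors = FALSE)
  attr(out, "k") <- as.integer(k)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("fold_assignment", "data.frame")
  out
}

# Correlation that is NA (not a warning) when either side is constant, as
# happens when a variance component is estimated at the zero boundary.
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# Per-fold predictive-ability metrics against per-animal mean phenotypes.
fold_metrics_row <- function(phen, pred_gv, pred_bv, pred_dv) {
  slope <- if (stats::var(pred_gv) == 0) NA_real_ else
    unname(stats::lm.fit(cbind(1, pred_gv), phen)$coefficients[2])
  data.frame(cor_bv = safe_cor(phen, pred_bv),
             cor_dv = if (is.null(pred_dv)) NA_real_ else
               safe_cor(phen, pred_dv),
             cor_tgv = safe_cor(phen, pred_gv),
             slope = slope,
             mse = mean((phen - pred_gv)^2),
             n_valid = length(phen))
}

#' Run half-sib-aware cross-validation of the two GBLUP models
#'
#' For each fold, both the additive and the additive + dominance model are
#' fitted on the records of the remaining folds; genotypes of validation
#' animals stay in the relationship matrices, but their phenotypes are
#' excluded. Validation animals' breeding values, dominance deviations and
#' total genetic values are then predicted through their genomic covariances
#' and compared with their per-animal mean adjusted phenotypes.
#'
#' @param records Phenotype data frame (`animal_id`, `value`).
#' @param genotypes Allele-count matrix over all phenotyped animals.
#' @param folds A [assign_folds()] result covering the phenotyped animals.
#' @param control A [gblup_control()] used for every fold fit.
#' @param keep_predictions Keep per-fold validation predictions (needed for
#'   rank-correlation tables).
#' @return Data frame of class `cv_metrics`: one row per fold x model
#'   (`model` is `"A"` or `"AD"`) with `cor_bv`, `cor_dv`, `cor_tgv`,
#'   `slope`, `mse` (slope and MSE are on BV for model A and on TGV for model
#'   A + D), and `n_valid`. When `keep_predictions = TRUE` the attribute
#'   `predictions` holds one data frame per fold with validation phenotypes
#'   and both models' predictions.
#' @export
run_cv <- function(records, genotypes, folds, control = gblup_control(),
                   keep_predictions = TRUE) {
  ids_phen <- unique(records$animal_id)
  if (!all(ids_phen %in% folds$animal_id)) {
    stop_invalid("fold assignment does not cover all phenotyped animals")
  }
  freqs <- allele_frequencies(genotypes)
  G <- grm_additive(genotypes, freqs)
  D <- grm_dominance(genotypes, freqs)
  k <- attr(folds, "k")
  metrics <- list()
  preds <- list()
  for (f in seq_len(k)) {
    valid_ids <- folds$animal_id[folds$fold == f]
    train <- records[!records$animal_id %in% valid_ids, , drop = FALSE]
    if (nrow(train) == 0 || length(valid_ids) == 0) {
      stop_invalid("fold ", f, " leaves an empty training or validation set")
    }
    fit_a <- gblup(train, G, control = control)
    fit_ad <- gblup(train, G, D, control = control)
    vrec <- records[records$animal_id %in% valid_ids, , drop = FALSE]
    phen <- tapply(vrec$value, factor(vrec$animal_id, levels = valid_ids), mean)
    obs_ids <- valid_ids[!is.na(phen)]
    phen <- as.numeric(phen[!is.na(phen)])
    pa <- predict(fit_a, obs_ids)
    pad <- predict(fit_ad, obs_ids)
    ma <- fold_metrics_row(phen, pa$bv, pa$bv, NULL)
    mad <- fold_metrics_row(phen, pad$tgv, pad$bv, pad$dv)
    metrics[[length(metrics) + 1L]] <- cbind(fold = f, model = "A", ma)
    metrics[[length(metrics) + 1L]] <- cbind(fold = f, model = "AD", mad)
    if (keep_predictions) {
      preds[[f]] <- data.frame(fold = f, animal_id = obs_ids, phen = phen,
                               bv_a = pa$bv, bv_ad = pad$bv, dv_ad = pad$dv,
                               tgv_ad = pad$tgv, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, metrics)
  rownames(out) <- NULL
  if (keep_predictions) attr(out, "predictions") <- preds
  class(out) <- c("cv_metrics", "data.frame")
  out
}

paired_p <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  d <- x[keep] - y[keep]
  if (length(d) < 2) return(list(p = NA_real_, degenerate = TRUE))
  if (stats::sd(d) == 0) return(list(p = 1, degenerate = TRUE))
  list(p = stats::t.test(x[keep], y[keep], paired = TRUE)$p.value,
       degenerate = FALSE)
}

one_sample_p <- function(x, mu) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(list(p = NA_real_, degenerate = TRUE))
  if (stats::sd(x) == 0) {
    return(list(p = if (isTRUE(all.equal(mean(x), mu))) 1 else 0,
                degenerate = TRUE))
  }
  list(p = stats::t.test(x, mu = mu)$p.value, degenerate = FALSE)
}

#' Summarize cross-validation metrics
#'
#' Averages the per-fold metrics and runs the model-comparison tests: paired
#' two-sample t tests of correlations and MSE between models A and A + D, and
#' one-sample t tests of the regression slopes against 1. Zero-variance
#' paired differences are flagged as degenerate with `p = 1`.
#'
#' @param metrics A [run_cv()] result.
#' @return List of class `cv_summary` with `means` (per model x metric mean
#'   and standard error over folds) and `tests` (comparison, p, degenerate).
#' @export
summarize_cv <- function(metrics) {
  k <- length(unique(metrics$fold))
  if (k < 2) stop_invalid("need at least 2 folds to summarize")
  mean_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  se_na <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2) return(NA_real_)
    stats::sd(v) / sqrt(length(v))
  }
  num_cols <- c("cor_bv", "cor_dv", "cor_tgv", "slope", "mse")
  means <- do.call(rbind, lapply(split(metrics, metrics$model), function(mm) {
    data.frame(model = mm$model[1], metric = num_cols,
               mean = vapply(num_cols, function(cn) mean_na(mm[[cn]]), 0),
               se = vapply(num_cols, function(cn) se_na(mm[[cn]]), 0),
               stringsAsFactors = FALSE)
  }))
  rownames(means) <- NULL
  a <- metrics[metrics$model == "A", ]
  ad <- metrics[metrics$model == "AD", ]
  a <- a[order(a$fold), ]; ad <- ad[order(ad$fold), ]
  t_bv <- paired_p(a$cor_bv, ad$cor_bv)
  t_tgv <- paired_p(a$cor_bv, ad$cor_tgv)
  t_mse <- paired_p(a$mse, ad$mse)
  t_sa <- one_sample_p(a$slope, 1)
  t_sad <- one_sample_p(ad$slope, 1)
  tests <- data.frame(
    comparison = c("cor: BV_A vs BV_AD", "cor: BV_A vs TGV_AD",
                   "mse: A vs AD", "slope_A vs 1", "slope_AD vs 1"),
    p = c(t_bv$p, t_tgv$p, t_mse$p, t_sa$p, t_sad$p),
    degenerate = c(t_bv$degenerate, t_tgv$degenerate, t_mse$degenerate,
                   t_sa$degenerate, t_sad$degenerate),
    stringsAsFactors = FALSE)
  structure(list(means = means, tests = tests, k = k), class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Cross-validation summary over %d folds\n", x$k))
  m <- x$means
  m$mean <- signif(m$mean, digits); m$se <- signif(m$se, digits)
  print(m, row.names = FALSE)
  cat("\n")
  t <- x$tests
  t$p <- signif(t$p, digits)
  print(t, row.names = FALSE)
  invisible(x)
}

#' Rank correlations under hypothetical selection percentages
#'
#' Animals are ranked by the model-A values; for each selection percentage the
#' top animals are retained (deterministic id-order tie-break) and the
#' Spearman rank correlation (midranks for ties) between the two models'
#' values on that subset is computed, quantifying re-ranking among selection
#' candidates.
#'
#' @param values_a Per-animal values from the additive model (e.g. BV).
#' @param values_ad Per-animal values from the additive + dominance model
#'   (e.g. TGV), aligned with `values_a`.
#' @param percentages Selection percentages in (0, 100].
#' @param higher_better Rank direction; set `FALSE` for traits where smaller
#'   is better (e.g. calving interval).
#' @param ids Optional animal ids used for the deterministic tie-break.
#' @return Data frame with `percentage`, `n_selected`, `spearman` (`NA` when
#'   fewer than 3 animals are selected).
#' @export
rank_by_selection <- function(values_a, values_ad,
                              percentages = c(10, 25, 50, 75, 100),
                              higher_better = TRUE, ids = NULL) {
  if (length(values_a) != length(values_ad)) {
    stop_invalid("values_a and values_ad must be aligned")
  }
  if (any(percentages <= 0 | percentages > 100)) {
    stop_invalid("percentages must lie in (0, 100]")
  }
  n <- length(values_a)
  ids <- ids %||% as.character(seq_len(n))
  key <- if (higher_better) -values_a else values_a
  ord <- order(key, ids)
  out <- lapply(percentages, function(pct) {
    n_sel <- max(1L, floor(n * pct / 100))
    sel <- ord[seq_len(n_sel)]
    rho <- if (n_sel < 3 || stats::sd(values_a[sel]) == 0 ||
               stats::sd(values_ad[sel]) == 0) NA_real_ else
      stats::cor(values_a[sel], values_ad[sel], method = "spearman")
    data.frame(percentage = pct, n_selected = n_sel, spearman = rho)
  })
  do.call(rbind, out)
}
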