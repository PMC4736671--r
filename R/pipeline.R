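# End-to-end study orchestration: simulate (or load), build G/D, fit both
# models, model comparison, inbreeding correlations, cross-validation, and an
# internally consistent report.

#' Configuration for a full study run
#'
#' Exactly one input mode: either a [sim_config()] (simulate) or paths to a
#' genotype TSV and phenotype TSV (files).
#'
#' @param sim A [sim_config()], or `NULL` when reading from files.
#' @param genotype_file,phenotype_file Input paths for file mode (genotype
#'   TSV as written by [write_genotypes()]; phenotype TSV as written by
#'   [write_phenotypes()]).
#' @param covariates Optional covariate column names in the phenotype table;
#'   when given, records are pre-adjusted by OLS before fitting.
#' @param k_folds Number of cross-validation folds.
#' @param percentages Selection percentages for the rank-correlation table.
#' @param higher_better Ranking direction for selection.
#' @param seed Master seed for fold assignment (simulation uses the seed
#'   inside `sim`).
#' @param control A [gblup_control()].
#' @return List of class `study_config`.
#' @export
study_config <- function(sim = sim_config(), genotype_file = NULL,
                         phenotype_file = NULL, covariates = NULL,
                         k_folds = 5, percentages = c(10, 25, 50, 75, 100),
                         higher_better = TRUE, seed = 1,
                         control = gblup_control()) {
  simulate_mode <- !is.null(sim)
  file_mode <- !is.null(genotype_file) || !is.null(phenotype_file)
  if (simulate_mode && file_mode) {
    stop_invalid("choose one input mode: sim or genotype_file/phenotype_file")
  }
  if (!simulate_mode && (is.null(genotype_file) || is.null(phenotype_file))) {
    stop_invalid("file mode needs both genotype_file and phenotype_file")
  }
  structure(list(sim = sim, genotype_file = genotype_file,
                 phenotype_file = phenotype_file, covariates = covariates,
                 k_folds = as.integer(k_folds), percentages = percentages,
                 higher_better = isTRUE(higher_better),
                 seed = as.integer(seed), control = control),
            class = "study_config")
}

#' Run the complete genomic-evaluation study
#'
#' Executes the full chain on one dataset: simulate (or load) genotypes and
#' repeated records, optionally pre-adjust phenotypes, build the additive and
#' dominance relationship matrices, fit the additive (A) and additive +
#' dominance (A + D) models by REML, compare them with the mixture chi-square
#' likelihood-ratio test, correlate estimated dominance deviations with the
#' two genomic inbreeding measures, and assess predictive ability by
#' half-sib-aware cross-validation including the selection-percentage rank
#' table. Identical configuration and seed reproduce the report exactly.
#'
#' @param config A [study_config()].
#' @return List of class `study_report` with data-frame tables `components`
#'   (variance components and derived ratios per model), `lrt`,
#'   `inbreeding`, `cv_means`, `cv_tests`, `rank`, and a `provenance` list.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  if (!is.null(config$sim)) {
    pop <- sim_herd(config$sim)
    genotypes <- pop$genotypes
    records <- pop$records
    sires <- attr(genotypes, "sires")
  } else {
    genotypes <- read_genotypes(config$genotype_file)
    records <- read_phenotypes(config$phenotype_file)
    sires <- attr(genotypes, "sires") %||%
      stats::setNames(records$sire_id[match(rownames(genotypes),
                                            records$animal_id)],
                      rownames(genotypes))
  }
  if (!is.null(config$covariates)) {
    records <- adjust_phenotypes(records,
                                 records[, config$covariates, drop = FALSE])
  }

  freqs <- allele_frequencies(genotypes)
  G <- grm_additive(genotypes, freqs)
  D <- grm_dominance(genotypes, freqs)

  fit_a <- gblup(records, G, control = config$control)
  fit_ad <- gblup(records, G, D, control = config$control)
  lrt <- mixture_lrt(fit_a$logl, fit_ad$logl)

  components <- rbind(component_rows(fit_a, "A"), component_rows(fit_ad, "AD"))
  lrt_tab <- data.frame(model = c("A", "AD"),
                        logl = c(lrt$logl_a, lrt$logl_ad),
                        statistic = c(NA, lrt$statistic),
                        p_value = c(NA, lrt$p_value))

  gf <- genomic_inbreeding(genotypes, freqs)
  hom <- homozygosity_fraction(genotypes)
  dv_hat <- predict(fit_ad)$dv
  cor_or_na <- function(m) {
    tryCatch(suppressWarnings(dominance_inbreeding_cor(dv_hat, m)),
             error = function(e) NA_real_)
  }
  inbreeding <- data.frame(measure = c("homozygosity_fraction",
                                       "inbreeding_coefficient"),
                           cor_with_dv = c(cor_or_na(hom), cor_or_na(gf)))

  folds <- assign_folds(rownames(genotypes), unname(sires[rownames(genotypes)]),
                        k = config$k_folds, seed = config$seed)
  cv <- run_cv(records, genotypes, folds, control = config$control)
  cvs <- summarize_cv(cv)
  rank_tab <- rank_table_from_cv(cv, config$percentages, config$higher_better)

  report <- list(components = components, lrt = lrt_tab,
                 inbreeding = inbreeding, cv_means = cvs$means,
                 cv_tests = cvs$tests, rank = rank_tab,
                 provenance = list(package = "gblupd",
                                   version = as.character(utils::packageVersion("gblupd")),
                                   seed = config$seed,
                                   k_folds = config$k_folds,
                                   mode = if (is.null(config$sim)) "files" else "simulate",
                                   config = unclass_config(config)))
  class(report) <- "study_report"
  report
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$control <- unclass(out$control)
  if (!is.null(out$sim)) out$sim <- unclass(out$sim)
  out
}

component_rows <- function(fit, model) {
  ratios <- variance_ratios(fit)
  data.frame(model = model,
             parameter = c(names(fit$components), names(ratios)),
             estimate = unname(c(fit$components, ratios)),
             se = c(unname(fit$se), rep(NA_real_, length(ratios))),
             stringsAsFactors = FALSE)
}

# Average the per-fold selection rank tables from run_cv predictions.
rank_table_from_cv <- function(cv, percentages, higher_better) {
  preds <- attr(cv, "predictions")
  if (is.null(preds)) stop_invalid("run_cv must keep predictions for the rank table")
  per_fold <- lapply(preds, function(p) {
    rank_by_selection(p$bv_a, p$tgv_ad, percentages, higher_better,
                      ids = p$animal_id)$spearman
  })
  m <- do.call(cbind, per_fold)
  se_row <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
  }
  data.frame(percentage = percentages,
             spearman_mean = rowMeans(m, na.rm = TRUE),
             spearman_se = apply(m, 1, se_row))
}

#' @export
print.study_report <- function(x, ...) {
  cat("Genomic evaluation study report\n")
  cat("-- variance components and ratios --\n")
  tab <- x$components; tab$estimate <- signif(tab$estimate, 4)
  tab$se <- signif(tab$se, 3)
  print(tab, row.names = FALSE)
  cat("-- model comparison (mixture chi-square LRT) --\n")
  print(within(x$lrt, { logl <- round(logl, 2) }), row.names = FALSE)
  cat("-- dominance deviation vs inbreeding --\n")
  print(x$inbreeding, row.names = FALSE)
  cat("-- cross-validation --\n")
  print(x$cv_means, row.names = FALSE)
  print(x$cv_tests, row.names = FALSE)
  cat("-- rank correlations by selection percentage --\n")
  print(x$rank, row.names = FALSE)
  invisible(x)
}

#' Write a study report to disk
#'
#' One TSV per table (full numeric precision) plus a `report.yaml` metadata
#' block with the provenance information.
#'
#' @param report A [run_study()] result.
#' @param dir Output directory (created if missing).
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("components", "lrt", "inbreeding", "cv_means", "cv_tests",
               "rank")) {
    utils::write.table(report[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  yaml::write_yaml(report$provenance, file.path(dir, "report.yaml"))
  invisible(dir)
}

#' Verify the internal consistency of a study report
#'
#' Re-derives every ratio (heritabilities, dominance share, repeatability,
#' total phenotypic variance) and the likelihood-ratio p value from the raw
#' components and log-likelihoods in the report and confirms agreement.
#' `ratio_digits` sets the rounding at which ratio agreement is required
#' (e.g. 3 when checking a table printed to 3 decimals; `NULL` for full
#' precision). `logl_rounding` is the rounding half-width of the reported
#' log-likelihoods (e.g. 0.5 for integer-printed values); the p-value check
#' then accepts any p consistent with a statistic in `2*dLogL +/- 4*half`.
#'
#' @param report A `study_report` (or a list with compatible `components` and
#'   `lrt` tables).
#' @param ratio_digits Rounding of the ratio entries, or `NULL` for exact.
#' @param logl_rounding Half-width of log-likelihood rounding (0 for exact).
#' @return Data frame with `check`, `pass`, `detail`; attribute `ok` is TRUE
#'   when every check passes.
#' @export
verify_report <- function(report, ratio_digits = NULL, logl_rounding = 0) {
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(check = name,
                                                 pass = pass, detail = detail,
                                                 stringsAsFactors = FALSE)
  }
  tol <- if (is.null(ratio_digits)) 1e-8 else 0.5 * 10^(-ratio_digits)
  comp <- report$components
  for (model in unique(comp$model)) {
    cm <- comp[comp$model == model, ]
    get <- function(p) {
      v <- cm$estimate[cm$parameter == p]
      if (length(v)) v[1] else NA_real_
    }
    th <- c(sigma_a2 = get("sigma_a2"), sigma_pe2 = get("sigma_pe2"),
            sigma_e2 = get("sigma_e2"))
    if ("sigma_d2" %in% cm$parameter) th["sigma_d2"] <- get("sigma_d2")
    ratios <- variance_ratios(th)
    for (p in intersect(names(ratios), cm$parameter)) {
      ok <- abs(ratios[[p]] - get(p)) <= tol * max(1, abs(ratios[[p]]))
      add(sprintf("%s: %s consistent with components", model, p), ok,
          sprintf("recomputed %.6g, reported %.6g", ratios[[p]], get(p)))
    }
  }
  lrt <- report$lrt
  if (!is.null(lrt) && nrow(lrt) == 2 && !anyNA(lrt$logl)) {
    stat <- max(0, 2 * (lrt$logl[lrt$model == "AD"] -
                          lrt$logl[lrt$model == "A"]))
    p_rep <- lrt$p_value[lrt$model == "AD"]
    stat_rep <- lrt$statistic[lrt$model == "AD"]
    if (!is.na(stat_rep)) {
      add("lrt: statistic consistent with log-likelihoods",
          abs(stat - stat_rep) <= 2e-8 + 4 * logl_rounding,
          sprintf("recomputed %.6g, reported %.6g", stat, stat_rep))
    }
    if (!is.na(p_rep)) {
      half <- 4 * logl_rounding
      p_of <- function(s) if (s > 0) 0.5 * stats::pchisq(s, 1, lower.tail = FALSE) else 1
      p_lo <- p_of(stat + half)
      p_hi <- p_of(max(0, stat - half))
      ok <- (p_rep >= p_lo - 1e-10 && p_rep <= p_hi + 1e-10) ||
        abs(p_rep - p_of(stat)) <= 1e-8
      add("lrt: p value consistent with log-likelihoods", ok,
          sprintf("recomputed %.3g, reported %.3g", p_of(stat), p_rep))
    }
  }
  out <- do.call(rbind, checks)
  attr(out, "ok") <- all(out$pass)
  out
}
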