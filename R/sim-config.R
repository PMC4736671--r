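#' Configuration for the half-sib population simulator
#'
#' Bundles every knob of the simulated dairy population: family structure
#' (paternal half-sib daughters of unrelated sires), marker panel, repeated
#' phenotype records, and the true variance components on the trait scale.
#' Defaults describe the reference design used throughout the package's own
#' calibration studies: 20 sires with 50 daughters each (1000 cows), 2000
#' biallelic SNPs with minor allele frequencies uniform on \[0.05, 0.5\],
#' 2 records per cow, and true components
#' \eqn{(\sigma^2_a, \sigma^2_d, \sigma^2_{pe}, \sigma^2_e) =
#' (0.25, 0.05, 0.10, 0.60)} so the phenotypic variance is 1.
#'
#' @param n_sires Number of unrelated sires.
#' @param daughters_per_sire Daughters per sire; all phenotyped animals are
#'   daughters, so the population size is `n_sires * daughters_per_sire`.
#' @param n_snps Number of biallelic markers.
#' @param maf_range Length-2 numeric in (0, 0.5]: minor allele frequencies are
#'   drawn uniformly on this interval.
#' @param records_per_animal Repeated records per daughter.
#' @param mu Population mean of the trait.
#' @param sigma_a2,sigma_d2,sigma_pe2,sigma_e2 True additive, dominance,
#'   permanent-environmental and residual variances (trait units squared).
#' @param mean_dominance_effect Mean of the per-SNP dominance effects before
#'   spread rescaling. A non-zero value makes dominance directional, which
#'   induces inbreeding depression (dominance deviations negatively correlated
#'   with homozygosity).
#' @param seed Integer seed; every random draw in the simulator flows from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [sim_herd()] which consumes the configuration.
#' @export
sim_config <- function(n_sires = 20, daughters_per_sire = 50, n_snps = 2000,
                       maf_range = c(0.05, 0.5), records_per_animal = 2,
                       mu = 0, sigma_a2 = 0.25, sigma_d2 = 0.05,
                       sigma_pe2 = 0.10, sigma_e2 = 0.60,
                       mean_dominance_effect = 0, seed = 1) {
  cfg <- list(n_sires = as.integer(n_sires),
              daughters_per_sire = as.integer(daughters_per_sire),
              n_snps = as.integer(n_snps),
              maf_range = as.numeric(maf_range),
              records_per_animal = as.integer(records_per_animal),
              mu = as.numeric(mu),
              sigma_a2 = as.numeric(sigma_a2), sigma_d2 = as.numeric(sigma_d2),
              sigma_pe2 = as.numeric(sigma_pe2), sigma_e2 = as.numeric(sigma_e2),
              mean_dominance_effect = as.numeric(mean_dominance_effect),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_sires, cfg$daughters_per_sire, cfg$n_snps,
              cfg$records_per_animal)
  if (any(is.na(counts)) || any(counts < 1L)) {
    stop_invalid("n_sires, daughters_per_sire, n_snps and records_per_animal must all be >= 1")
  }
  vars <- c(cfg$sigma_a2, cfg$sigma_d2, cfg$sigma_pe2, cfg$sigma_e2)
  if (any(!is.finite(vars)) || any(vars < 0)) {
    stop_invalid("all true variance components must be finite and >= 0")
  }
  check_maf_range(cfg$maf_range)
  invisible(cfg)
}

check_maf_range <- function(maf_range) {
  if (length(maf_range) != 2L || any(!is.finite(maf_range)) ||
      maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop_invalid("maf_range must be a pair within (0, 0.5] with lower <= upper")
  }
  invisible(maf_range)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Half-sib simulation configuration\n")
  cat(sprintf("  population : %d sires x %d daughters = %d cows\n",
              x$n_sires, x$daughters_per_sire, x$n_sires * x$daughters_per_sire))
  cat(sprintf("  markers    : %d SNPs, MAF uniform on [%.3g, %.3g]\n",
              x$n_snps, x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  records    : %d per animal, mean %.3g\n",
              x$records_per_animal, x$mu))
  cat(sprintf("  variances  : a2=%.3g d2=%.3g pe2=%.3g e2=%.3g (mean dom effect %.3g)\n",
              x$sigma_a2, x$sigma_d2, x$sigma_pe2, x$sigma_e2,
              x$mean_dominance_effect))
  cat(sprintf("  seed       : %d\n", x$seed))
  invisible(x)
}
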