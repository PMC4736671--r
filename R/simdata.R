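# Simulation of half-sib genotypes, true genetic effects and repeated records.
#
# Each exported generator takes an explicit seed (or a sim_config carrying one)
# and is deterministic given it; the RNG state of the caller is never touched.

#' Draw minor allele frequencies
#'
#' Frequencies are uniform on `maf_range`; the counted (A) allele is the minor
#' allele, so the returned values double as the A-allele frequencies used by
#' the genotype simulator.
#'
#' @param n_snps Number of SNPs.
#' @param maf_range Pair within (0, 0.5].
#' @param seed Integer seed.
#' @return Numeric vector of length `n_snps`.
#' @export
draw_allele_freqs <- function(n_snps, maf_range, seed) {
  if (n_snps < 1) stop_invalid("n_snps must be >= 1")
  check_maf_range(maf_range)
  with_seed(seed, runif(n_snps, maf_range[1], maf_range[2]))
}

animal_ids <- function(n) sprintf("A%05d", seq_len(n))
sire_ids <- function(n) sprintf("S%03d", seq_len(n))
marker_ids <- function(m) sprintf("snp%05d", seq_len(m))

# Unseeded core: draws sires at HWE, then each daughter as one paternal gamete
# sampled from her sire plus one dam gamete drawn at the population frequency.
sim_half_sib_genotypes_core <- function(n_sires, daughters_per_sire, freqs) {
  m <- length(freqs)
  n <- n_sires * daughters_per_sire
  sire_geno <- matrix(rbinom(n_sires * m, 2L, rep(freqs, each = n_sires)),
                      nrow = n_sires, ncol = m)
  sire_of <- rep(seq_len(n_sires), each = daughters_per_sire)
  sg <- sire_geno[sire_of, , drop = FALSE]
  # paternal gamete: homozygote transmits its allele, heterozygote a fair coin
  pat <- (sg == 2L) + (sg == 1L) * matrix(rbinom(n * m, 1L, 0.5), n, m)
  mat <- matrix(rbinom(n * m, 1L, rep(freqs, each = n)), n, m)
  geno <- pat + mat
  storage.mode(geno) <- "integer"
  dimnames(geno) <- list(animal_ids(n), marker_ids(m))
  sires <- sire_ids(n_sires)[sire_of]
  names(sires) <- rownames(geno)
  attr(geno, "sires") <- sires
  attr(geno, "freqs") <- stats::setNames(freqs, colnames(geno))
  list(genotypes = geno, sires = sires, sire_genotypes = sire_geno)
}

#' Simulate paternal half-sib genotypes
#'
#' Sires are drawn at Hardy-Weinberg equilibrium from the supplied allele
#' frequencies; each daughter receives one gamete sampled from her sire and one
#' population gamete drawn at the SNP frequency, yielding the expected additive
#' relationship of 0.25 within paternal half-sib families.
#'
#' @param cfg A [sim_config()].
#' @param freqs A-allele frequencies, strictly inside (0, 1). Defaults to a
#'   fresh draw from `cfg`.
#' @return Integer matrix of allele counts (animals x SNPs, entries 0/1/2) with
#'   row names (animal ids), column names (marker ids), and attributes
#'   `sires` (named sire id per animal) and `freqs` (the generating
#'   frequencies).
#' @export
sim_half_sib_genotypes <- function(cfg, freqs = NULL) {
  validate_sim_config(cfg)
  seeds <- derive_seeds(cfg$seed, 2)
  if (is.null(freqs)) {
    freqs <- draw_allele_freqs(cfg$n_snps, cfg$maf_range, seeds[1])
  }
  if (any(freqs <= 0) || any(freqs >= 1)) {
    stop_invalid("allele frequencies must lie strictly inside (0, 1)")
  }
  with_seed(seeds[2],
            sim_half_sib_genotypes_core(cfg$n_sires, cfg$daughters_per_sire,
                                        freqs))$genotypes
}

#' Draw per-SNP additive and dominance effects
#'
#' Effects are Gaussian with equal variance per SNP, then rescaled so that under
#' Hardy-Weinberg equilibrium the additive genetic variance
#' \eqn{\sum_i 2 p_i q_i a_i^2} equals `target_sigma_a2` and the dominance
#' genetic variance \eqn{\sum_i (2 p_i q_i)^2 d_i^2} equals `target_sigma_d2`.
#' The dominance effects are first centred on `mean_dominance_effect`; the
#' spread around that mean is then rescaled (solving a quadratic in the scale)
#' so the variance target is still met, which makes directional dominance and a
#' fixed dominance variance compatible.
#'
#' @param freqs A-allele frequencies in (0, 1).
#' @param target_sigma_a2,target_sigma_d2 Target variances (>= 0).
#' @param mean_dominance_effect Mean per-SNP dominance effect.
#' @param seed Integer seed.
#' @return List with numeric vectors `a` and `d`.
#' @export
draw_snp_effects <- function(freqs, target_sigma_a2, target_sigma_d2,
                             mean_dominance_effect = 0, seed = 1) {
  if (target_sigma_a2 < 0 || target_sigma_d2 < 0) {
    stop_invalid("variance targets must be >= 0")
  }
  poly <- freqs > 0 & freqs < 1
  if ((target_sigma_a2 > 0 || target_sigma_d2 > 0) && !any(poly)) {
    stop_invalid("positive variance target with zero polymorphic SNPs")
  }
  m <- length(freqs)
  raw <- with_seed(seed, list(a = rnorm(m), d = rnorm(m)))
  wa <- ifelse(poly, 2 * freqs * (1 - freqs), 0)
  wd <- wa^2

  a <- raw$a
  if (target_sigma_a2 == 0) {
    a <- rep(0, m)
  } else {
    a <- a * sqrt(target_sigma_a2 / sum(wa * a^2))
  }

  if (target_sigma_d2 == 0 && mean_dominance_effect == 0) {
    d <- rep(0, m)
  } else {
    eps <- raw$d - mean(raw$d)              # pure spread component
    mu_part <- mean_dominance_effect^2 * sum(wd)
    if (mu_part > target_sigma_d2 + 1e-12) {
      stop_invalid("mean_dominance_effect alone exceeds target_sigma_d2; ",
                   "reduce the mean or raise the target")
    }
    s2 <- sum(wd * eps^2)
    cross <- 2 * mean_dominance_effect * sum(wd * eps)
    # solve s^2*sum(wd eps^2) + s*cross + mu_part - target = 0 for s >= 0
    disc <- cross^2 - 4 * s2 * (mu_part - target_sigma_d2)
    s <- if (s2 > 0) (-cross + sqrt(max(disc, 0))) / (2 * s2) else 0
    d <- mean_dominance_effect + s * eps
  }
  list(a = a, d = d)
}

# True breeding values / dominance deviations from the generating frequencies.
true_genetic_values <- function(genotypes, freqs, a, d) {
  Z <- additive_codes(genotypes, freqs)
  M <- dominance_codes(genotypes, freqs)
  list(bv = drop(Z %*% a), dv = drop(M %*% d))
}

#' Simulate repeated phenotype records
#'
#' Each animal receives `cfg$records_per_animal` records
#' `y = mu + BV + DV + pe + e`, with the permanent-environmental effect drawn
#' once per animal and the residual per record.
#'
#' @param genotypes Genotype matrix from [sim_half_sib_genotypes()].
#' @param truth Truth set as returned in `sim_herd()$truth` (must carry `bv`,
#'   `dv` and `pe` for every animal).
#' @param cfg A [sim_config()].
#' @return Data frame with columns `animal_id`, `sire_id`, `trait`, `value`.
#' @export
sim_records <- function(genotypes, truth, cfg) {
  validate_sim_config(cfg)
  ids <- rownames(genotypes)
  if (!all(ids %in% truth$animal$animal_id)) {
    stop_invalid("truth set does not cover all animals in the genotype table")
  }
  an <- truth$animal[match(ids, truth$animal$animal_id), ]
  seeds <- derive_seeds(cfg$seed, 4)
  sim_records_core(an, cfg, seeds[4])
}

sim_records_core <- function(an, cfg, seed) {
  r <- cfg$records_per_animal
  n <- nrow(an)
  e <- with_seed(seed, rnorm(n * r, 0, sqrt(cfg$sigma_e2)))
  idx <- rep(seq_len(n), each = r)
  data.frame(animal_id = an$animal_id[idx],
             sire_id = an$sire_id[idx],
             trait = "sim",
             value = cfg$mu + an$bv[idx] + an$dv[idx] + an$pe[idx] + e,
             stringsAsFactors = FALSE)
}

#' Simulate a complete half-sib study population
#'
#' One-stop generator: allele frequencies, half-sib genotypes, per-SNP additive
#' and dominance effects, per-animal permanent-environmental effects, and
#' repeated phenotype records, all from the single seed in `cfg`. The returned
#' truth set supports parameter-recovery tests: true breeding values are the
#' additive-code rows times the `a` vector and true dominance deviations the
#' dominance-code rows times `d`, both using the generating frequencies.
#'
#' @param cfg A [sim_config()].
#' @return List with elements
#'   \describe{
#'     \item{genotypes}{integer allele-count matrix with `sires` attribute,}
#'     \item{records}{phenotype data frame (`animal_id`, `sire_id`, `trait`,
#'       `value`),}
#'     \item{truth}{list with `freqs`, per-SNP `a` and `d`, and an `animal`
#'       data frame (`animal_id`, `sire_id`, `bv`, `dv`, `pe`),}
#'     \item{config}{the input configuration.}
#'   }
#' @export
sim_herd <- function(cfg) {
  validate_sim_config(cfg)
  seeds <- derive_seeds(cfg$seed, 4)
  freqs <- draw_allele_freqs(cfg$n_snps, cfg$maf_range, seeds[1])
  gen <- with_seed(seeds[2],
                   sim_half_sib_genotypes_core(cfg$n_sires,
                                               cfg$daughters_per_sire, freqs))
  eff <- draw_snp_effects(freqs, cfg$sigma_a2, cfg$sigma_d2,
                          cfg$mean_dominance_effect, seeds[3])
  gv <- true_genetic_values(gen$genotypes, freqs, eff$a, eff$d)
  n <- nrow(gen$genotypes)
  pe <- with_seed(seeds[3] + 1L, rnorm(n, 0, sqrt(cfg$sigma_pe2)))
  animal <- data.frame(animal_id = rownames(gen$genotypes),
                       sire_id = unname(gen$sires),
                       bv = gv$bv, dv = gv$dv, pe = pe,
                       stringsAsFactors = FALSE)
  truth <- list(freqs = freqs, a = eff$a, d = eff$d, animal = animal)
  records <- sim_records_core(animal, cfg, seeds[4])
  list(genotypes = gen$genotypes, records = records, truth = truth,
       config = cfg)
}
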