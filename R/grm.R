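# Additive (G) and dominance (D) genomic relationship matrices, genotype
# codings, and the two genomic inbreeding measures.

check_genotypes <- function(genotypes) {
  if (is.null(dim(genotypes)) || nrow(genotypes) < 1 || ncol(genotypes) < 1) {
    stop_invalid("genotypes must be a non-empty animals x SNPs matrix")
  }
  if (!all(genotypes %in% c(0L, 1L, 2L))) {
    stop_invalid("genotype cells must be allele counts in {0, 1, 2}")
  }
  invisible(genotypes)
}

#' Estimate allele frequencies from genotypes
#'
#' The frequency of the counted (A) allele at each marker is the mean allele
#' count over all supplied animals divided by 2. Monomorphic markers are
#' flagged; they are excluded from relationship-matrix numerators and
#' denominators and from the inbreeding coefficient.
#'
#' @param genotypes Animals x SNPs matrix of allele counts in \{0, 1, 2\}.
#' @return Data frame of class `allele_freqs` with columns `marker`, `p`
#'   (A-allele frequency) and `monomorphic`.
#' @export
allele_frequencies <- function(genotypes) {
  check_genotypes(genotypes)
  p <- colMeans(genotypes) / 2
  out <- data.frame(marker = colnames(genotypes) %||% as.character(seq_along(p)),
                    p = unname(p),
                    monomorphic = unname(p <= 0 | p >= 1),
                    stringsAsFactors = FALSE)
  class(out) <- c("allele_freqs", "data.frame")
  out
}

# Accept either an allele_freqs frame or a bare numeric vector of p.
freqs_vector <- function(freqs, genotypes) {
  p <- if (is.data.frame(freqs)) {
    if (!is.null(freqs$marker) && !is.null(colnames(genotypes))) {
      if (!all(colnames(genotypes) %in% freqs$marker)) {
        stop_invalid("marker ids of genotypes and frequencies do not align")
      }
      freqs$p[match(colnames(genotypes), freqs$marker)]
    } else freqs$p
  } else as.numeric(freqs)
  if (length(p) != ncol(genotypes)) {
    stop_invalid("need one allele frequency per genotype column")
  }
  p
}

#' Additive genotype codes (Z)
#'
#' Codes aa, Aa and AA genotypes as \eqn{-2p}, \eqn{q - p} and \eqn{2q}
#' (equivalently \eqn{x - 2p} for allele count `x`), so that the
#' Hardy-Weinberg-weighted mean of each column is exactly zero.
#'
#' @param genotypes Animals x SNPs allele-count matrix.
#' @param freqs [allele_frequencies()] output or numeric vector of A-allele
#'   frequencies aligned to the genotype columns.
#' @return Numeric matrix of the same dimension as `genotypes`.
#' @export
additive_codes <- function(genotypes, freqs) {
  p <- freqs_vector(freqs, genotypes)
  sweep(genotypes + 0.0, 2L, 2 * p)
}

#' Dominance genotype codes (M)
#'
#' Codes aa, Aa and AA genotypes as \eqn{-2p^2}, \eqn{2pq} and \eqn{-2q^2}.
#' Under Hardy-Weinberg equilibrium both the column means and the columnwise
#' cross-products with the additive codes are exactly zero, so additive and
#' dominance variance are not confounded.
#'
#' @inheritParams additive_codes
#' @return Numeric matrix of the same dimension as `genotypes`.
#' @export
dominance_codes <- function(genotypes, freqs) {
  p <- freqs_vector(freqs, genotypes)
  q <- 1 - p
  n <- nrow(genotypes)
  M <- matrix(rep(-2 * p^2, each = n), n, ncol(genotypes),
              dimnames = dimnames(genotypes))
  het <- genotypes == 1L
  AA <- genotypes == 2L
  M[het] <- matrix(rep(2 * p * q, each = n), n)[het]
  M[AA] <- matrix(rep(-2 * q^2, each = n), n)[AA]
  M
}

build_grm <- function(genotypes, freqs, kind) {
  check_genotypes(genotypes)
  af <- if (is.data.frame(freqs)) freqs else {
    p <- freqs_vector(freqs, genotypes)
    data.frame(marker = colnames(genotypes) %||% as.character(seq_along(p)),
               p = p, monomorphic = p <= 0 | p >= 1)
  }
  p <- freqs_vector(af, genotypes)
  poly <- !(af$monomorphic %||% (p <= 0 | p >= 1))
  if (!any(poly)) stop_invalid("no polymorphic SNPs; cannot build a relationship matrix")
  g <- genotypes[, poly, drop = FALSE]
  pp <- p[poly]
  het <- 2 * pp * (1 - pp)
  if (kind == "additive") {
    codes <- additive_codes(g, pp)
    denom <- sum(het)
  } else {
    codes <- dominance_codes(g, pp)
    denom <- sum(het^2)
  }
  K <- tcrossprod(codes) / denom
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(genotypes), rownames(genotypes))
  attr(K, "kind") <- kind
  attr(K, "denominator") <- denom
  attr(K, "n_snps") <- sum(poly)
  class(K) <- c("grm", class(K))
  K
}

#' Additive genomic relationship matrix
#'
#' \eqn{G = Z Z' / \sum_i 2 p_i q_i} over the polymorphic markers, with `Z`
#' the additive codes from [additive_codes()]. Monomorphic markers contribute
#' to neither numerator nor denominator.
#'
#' @inheritParams additive_codes
#' @return Symmetric animals x animals matrix of class `grm` with attributes
#'   `kind`, `denominator` and `n_snps`.
#' @export
grm_additive <- function(genotypes, freqs = allele_frequencies(genotypes)) {
  build_grm(genotypes, freqs, "additive")
}

#' Dominance genomic relationship matrix
#'
#' \eqn{D = M M' / \sum_i (2 p_i q_i)^2} with `M` the dominance codes from
#' [dominance_codes()].
#'
#' @inheritParams additive_codes
#' @return Symmetric animals x animals matrix of class `grm`.
#' @export
grm_dominance <- function(genotypes, freqs = allele_frequencies(genotypes)) {
  build_grm(genotypes, freqs, "dominance")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("%s genomic relationship matrix: %d animals, %d SNPs, denominator %.6g\n",
              attr(x, "kind"), nrow(x), attr(x, "n_snps"),
              attr(x, "denominator")))
  cat(sprintf("  diagonal mean %.4f, off-diagonal mean %.4f\n",
              mean(diag(x)), (sum(x) - sum(diag(x))) / (nrow(x) * (nrow(x) - 1))))
  invisible(x)
}

#' Genomic inbreeding coefficient
#'
#' Extracts the inbreeding part of the genomic self-relationship:
#' \deqn{G_F = \frac{1}{N} \sum_i \frac{x_i^2 - (1 + 2 p_i) x_i + 2 p_i^2}
#' {2 p_i (1 - p_i)},}
#' where \eqn{p_i} is the frequency of the most common allele at SNP \eqn{i}
#' and \eqn{x_i} counts that allele (0, 1, 2). Monomorphic SNPs are excluded
#' from the sum and from `N`. A fully heterozygous animal has
#' \eqn{G_F = -1} at \eqn{p = 0.5}; a fully homozygous one \eqn{+1}.
#'
#' @inheritParams additive_codes
#' @return Named numeric vector of per-animal inbreeding coefficients, with
#'   attribute `n_snps` (the `N` used).
#' @export
genomic_inbreeding <- function(genotypes, freqs = allele_frequencies(genotypes)) {
  check_genotypes(genotypes)
  p <- freqs_vector(freqs, genotypes)
  poly <- p > 0 & p < 1
  if (!any(poly)) stop_invalid("all SNPs monomorphic; inbreeding undefined")
  g <- genotypes[, poly, drop = FALSE]
  p <- p[poly]
  # x must count the most common allele: flip columns where A is the minor one
  flip <- p < 0.5
  x <- g + 0.0
  x[, flip] <- 2 - x[, flip]
  pc <- ifelse(flip, 1 - p, p)
  num <- x^2 - sweep(x, 2L, 1 + 2 * pc, `*`)
  num <- sweep(num, 2L, 2 * pc^2, `+`)
  gf <- rowMeans(sweep(num, 2L, 2 * pc * (1 - pc), `/`))
  names(gf) <- rownames(genotypes)
  attr(gf, "n_snps") <- sum(poly)
  gf
}

#' Proportion of homozygous SNPs per animal
#'
#' @param genotypes Animals x SNPs allele-count matrix.
#' @return Named numeric vector in \[0, 1\].
#' @export
homozygosity_fraction <- function(genotypes) {
  check_genotypes(genotypes)
  out <- rowMeans(genotypes != 1L)
  names(out) <- rownames(genotypes)
  out
}

#' Correlation between dominance deviations and an inbreeding measure
#'
#' Pearson correlation of per-animal (estimated or true) dominance deviations
#' with an inbreeding measure such as [genomic_inbreeding()] or
#' [homozygosity_fraction()]. If either vector has zero variance the
#' correlation is undefined and `NA` is returned with a warning.
#'
#' @param dv Per-animal dominance deviations.
#' @param measure Per-animal inbreeding measure, aligned to `dv`.
#' @return Scalar correlation, or `NA` when undefined.
#' @export
dominance_inbreeding_cor <- function(dv, measure) {
  if (length(dv) != length(measure) || length(dv) < 3) {
    stop_invalid("dv and measure must be aligned vectors of length >= 3")
  }
  if (stats::sd(dv) == 0 || stats::sd(measure) == 0) {
    warning("zero variance: correlation undefined, returning NA")
    return(NA_real_)
  }
  stats::cor(dv, measure)
}
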