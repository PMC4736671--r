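# Genotype codings, relationship matrices and inbreeding measures.

test_that("allele frequencies are per-column mean counts over two", {
  g <- matrix(c(0L, 1L, 2L, 2L, 2L, 2L), 3, 2,
              dimnames = list(paste0("A", 1:3), c("m1", "m2")))
  af <- allele_frequencies(g)
  expect_equal(af$p, c(0.5, 1))
  expect_equal(af$monomorphic, c(FALSE, TRUE))
  gr <- hwe_genotypes(50, draw_allele_freqs(200, c(0.05, 0.5), 1), seed = 2)
  af2 <- allele_frequencies(gr)
  brute <- apply(gr, 2, function(col) sum(col) / (2 * length(col)))
  expect_equal(af2$p, unname(brute), tolerance = 1e-15)
  expect_error(allele_frequencies(matrix(integer(0), 0, 0)), "non-empty")
})

test_that("additive and dominance codes match their genotype tables", {
  g <- matrix(0:2, 3, 1, dimnames = list(paste0("A", 1:3), "m"))
  expect_equal(drop(additive_codes(g, 0.5)), c(A1 = -1, A2 = 0, A3 = 1))
  expect_equal(drop(additive_codes(g, 0.9)), c(A1 = -1.8, A2 = -0.8, A3 = 0.2))
  expect_equal(drop(dominance_codes(g, 0.5)), c(A1 = -0.5, A2 = 0.5, A3 = -0.5))
  expect_equal(drop(dominance_codes(g, 0.9)),
               c(A1 = -1.62, A2 = 0.18, A3 = -0.02))
})

test_that("codings are orthogonal under Hardy-Weinberg weights for any p", {
  for (p in seq(0.05, 0.95, by = 0.05)) {
    q <- 1 - p
    wts <- c(q^2, 2 * p * q, p^2)   # P(x = 0, 1, 2) with p the A frequency
    g <- matrix(0:2, 3, 1)
    z <- drop(additive_codes(g, p))
    m <- drop(dominance_codes(g, p))
    expect_equal(sum(wts * z), 0, tolerance = 1e-14)
    expect_equal(sum(wts * m), 0, tolerance = 1e-14)
    expect_equal(sum(wts * z * m), 0, tolerance = 1e-14)
  }
})

test_that("G and D reproduce the worked single-SNP examples", {
  one <- matrix(2L, 1, 1, dimnames = list("A1", "m"))
  expect_equal(unclass(grm_additive(one, 0.5))[1, 1], 2)
  two <- matrix(c(2L, 0L), 2, 1, dimnames = list(c("A1", "A2"), "m"))
  expect_equal(unname(unclass(grm_additive(two, 0.5))),
               matrix(c(2, -2, -2, 2), 2), ignore_attr = TRUE)
  dpair <- matrix(c(1L, 2L), 2, 1, dimnames = list(c("A1", "A2"), "m"))
  expect_equal(unname(unclass(grm_dominance(dpair, 0.5))),
               matrix(c(1, -1, -1, 1), 2), ignore_attr = TRUE)
  het <- matrix(1L, 1, 1, dimnames = list("A1", "m"))
  expect_equal(unclass(grm_dominance(het, 0.5))[1, 1], 1)
})

test_that("G and D equal their brute-force matrix products", {
  g <- hwe_genotypes(10, draw_allele_freqs(50, c(0.1, 0.5), 3), seed = 4)
  af <- allele_frequencies(g)
  p <- af$p[!af$monomorphic]
  gp <- g[, !af$monomorphic, drop = FALSE]
  Z <- sweep(gp + 0, 2, 2 * p)
  G <- grm_additive(g, af)
  expect_equal(unname(unclass(G)), unname(Z %*% t(Z) / sum(2 * p * (1 - p))),
               tolerance = 1e-12, ignore_attr = TRUE)
  M <- matrix(NA_real_, nrow(gp), ncol(gp))
  for (j in seq_along(p)) {
    M[, j] <- c(-2 * p[j]^2, 2 * p[j] * (1 - p[j]),
                -2 * (1 - p[j])^2)[gp[, j] + 1L]
  }
  D <- grm_dominance(g, af)
  expect_equal(unname(unclass(D)),
               unname(M %*% t(M) / sum((2 * p * (1 - p))^2)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unclass(G), t(unclass(G)), tolerance = 1e-12)
  # with frequencies from the same animals the additive codes are centred
  # exactly, so G has zero row sums; the dominance codes are centred only in
  # expectation, so the average off-diagonal of D merely shrinks with n
  expect_lt(abs(mean(unclass(G) %*% rep(1, 10))), 1e-8 * mean(diag(G)))
})

test_that("monomorphic SNPs contribute nothing and alone are an error", {
  g <- cbind(hwe_genotypes(8, rep(0.3, 5), seed = 6),
             mono = rep(2L, 8))
  colnames(g) <- paste0("m", 1:6)
  G_with <- grm_additive(g)
  G_without <- grm_additive(g[, 1:5])
  expect_equal(unclass(G_with), unclass(G_without), tolerance = 1e-14)
  allmono <- matrix(2L, 4, 3, dimnames = list(paste0("A", 1:4), paste0("m", 1:3)))
  expect_error(grm_additive(allmono), "polymorphic")
  expect_error(genomic_inbreeding(allmono), "monomorphic")
})

test_that("inbreeding coefficient hits the +/-1 extremes and a brute force", {
  het <- matrix(1L, 1, 6, dimnames = list("A1", paste0("m", 1:6)))
  expect_equal(as.numeric(genomic_inbreeding(het, rep(0.5, 6))), -1)
  hom <- matrix(c(0L, 2L, 0L, 2L, 2L, 0L), 1, 6,
                dimnames = list("A1", paste0("m", 1:6)))
  expect_equal(as.numeric(genomic_inbreeding(hom, rep(0.5, 6))), 1)
  # random animal against the per-SNP sum with most-common-allele counting
  g <- hwe_genotypes(5, draw_allele_freqs(40, c(0.1, 0.45), 7), seed = 8)
  af <- allele_frequencies(g)
  gf <- genomic_inbreeding(g, af)
  i <- 3
  terms <- vapply(which(!af$monomorphic), function(j) {
    p <- af$p[j]; x <- g[i, j]
    if (p < 0.5) { p <- 1 - p; x <- 2 - x }
    (x^2 - (1 + 2 * p) * x + 2 * p^2) / (2 * p * (1 - p))
  }, numeric(1))
  expect_equal(unname(gf[i]), mean(terms), tolerance = 1e-12)
})

test_that("homozygosity fraction counts non-heterozygous genotypes", {
  g <- matrix(c(0L, 1L, 2L, 2L), 1, 4,
              dimnames = list("A1", paste0("m", 1:4)))
  expect_equal(unname(homozygosity_fraction(g)), 0.75)
  het <- matrix(1L, 2, 5, dimnames = list(c("A1", "A2"), paste0("m", 1:5)))
  expect_equal(unname(homozygosity_fraction(het)), c(0, 0))
  gr <- hwe_genotypes(20, rep(0.4, 30), seed = 9)
  expect_equal(unname(homozygosity_fraction(gr)),
               unname(apply(gr, 1, function(r) mean(r != 1L))))
})

test_that("diag(G) and G_F agree exactly at p = 0.5 and correlate in general", {
  g <- hwe_genotypes(60, rep(0.5, 200), seed = 10)
  G <- grm_additive(g, rep(0.5, 200))
  gf <- genomic_inbreeding(g, rep(0.5, 200))
  expect_equal(unname(diag(G)), as.numeric(1 + gf), tolerance = 1e-12)

  g2 <- hwe_genotypes(500, draw_allele_freqs(2000, c(0.05, 0.5), 11), seed = 12)
  af <- allele_frequencies(g2)
  G2 <- grm_additive(g2, af)
  gf2 <- genomic_inbreeding(g2, af)
  expect_gt(cor(diag(G2) - 1, gf2), 0.8)
  D2 <- grm_dominance(g2, af)
  offdiag_mean <- (sum(D2) - sum(diag(D2))) / (500 * 499)
  expect_lt(abs(offdiag_mean), 0.01)
})

test_that("mean diagonal of G approaches 1 for unrelated HWE animals", {
  g <- hwe_genotypes(500, draw_allele_freqs(5000, c(0.05, 0.5), 13), seed = 14)
  G <- grm_additive(g)
  expect_lt(abs(mean(diag(G)) - 1), 0.02)
})

test_that("additive and dominance codes are empirically uncorrelated", {
  n <- 2000
  freqs <- draw_allele_freqs(50, c(0.1, 0.5), 15)
  g <- hwe_genotypes(n, freqs, seed = 16)
  Z <- additive_codes(g, freqs)
  M <- dominance_codes(g, freqs)
  std_cross <- colMeans(Z * M) /
    (apply(Z, 2, sd) * apply(M, 2, sd))
  expect_lt(abs(mean(std_cross)), 3 / sqrt(n))
})

test_that("dominance-inbreeding correlation handles sign and degeneracy", {
  x <- rnorm(10)
  expect_equal(dominance_inbreeding_cor(-x, x), -1)
  expect_warning(out <- dominance_inbreeding_cor(rep(1, 10), x), "zero variance")
  expect_true(is.na(out))
  set.seed(17)
  dv <- rnorm(10); mh <- rnorm(10)
  byhand <- sum((dv - mean(dv)) * (mh - mean(mh))) /
    sqrt(sum((dv - mean(dv))^2) * sum((mh - mean(mh))^2))
  expect_equal(dominance_inbreeding_cor(dv, mh), byhand, tolerance = 1e-12)
  expect_error(dominance_inbreeding_cor(1:2, 1:2), "length >= 3")
})
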