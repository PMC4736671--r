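# Independent brute-force oracles. These deliberately avoid the package's
# collapsed-likelihood code path: everything is built from the full dense
# record-level covariance matrix V = W K W' + sigma_e2 I.

oracle_V <- function(rec, G, D, theta) {
  phen <- unique(rec$animal_id)
  W <- outer(rec$animal_id, phen, "==") + 0
  K <- theta[["sigma_a2"]] * unclass(G)[phen, phen]
  if (!is.null(D)) K <- K + theta[["sigma_d2"]] * unclass(D)[phen, phen]
  K <- K + diag(theta[["sigma_pe2"]], length(phen))
  list(V = W %*% K %*% t(W) + diag(theta[["sigma_e2"]], nrow(rec)),
       W = W, phen = phen)
}

# Restricted log-likelihood with the mean profiled by GLS.
oracle_reml_loglik <- function(rec, G, D, theta) {
  o <- oracle_V(rec, G, D, theta)
  n <- nrow(rec)
  Vi <- solve(o$V)
  X <- matrix(1, n, 1)
  xvx <- drop(t(X) %*% Vi %*% X)
  mu <- drop(t(X) %*% Vi %*% rec$value) / xvx
  r <- rec$value - mu
  -0.5 * ((n - 1) * log(2 * pi) + as.numeric(determinant(o$V)$modulus) +
            log(xvx) + drop(t(r) %*% Vi %*% r))
}

# Conditional-expectation BLUP by dense inversion, for all animals in G.
oracle_blup <- function(rec, G, D, theta) {
  o <- oracle_V(rec, G, D, theta)
  Vi <- solve(o$V)
  X <- matrix(1, nrow(rec), 1)
  mu <- drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% rec$value))
  r <- drop(Vi %*% (rec$value - mu))
  wtr <- drop(t(o$W) %*% r)
  ids <- rownames(G)
  bv <- theta[["sigma_a2"]] * drop(unclass(G)[, o$phen] %*% wtr)
  dv <- if (is.null(D)) rep(0, length(ids)) else
    theta[["sigma_d2"]] * drop(unclass(D)[, o$phen] %*% wtr)
  pe <- rep(0, length(ids))
  pe[match(o$phen, ids)] <- theta[["sigma_pe2"]] * wtr
  data.frame(animal_id = ids, bv = bv, dv = dv, tgv = bv + dv, pe = pe)
}

# Unrelated Hardy-Weinberg genotypes at given allele frequencies.
hwe_genotypes <- function(n, freqs, seed) {
  set.seed(seed)
  g <- matrix(rbinom(n * length(freqs), 2L, rep(freqs, each = n)),
              n, length(freqs),
              dimnames = list(sprintf("H%05d", seq_len(n)),
                              sprintf("snp%05d", seq_along(freqs))))
  storage.mode(g) <- "integer"
  g
}

# Small simulated half-sib population used by several tests.
small_pop <- function(seed = 42, n_sires = 6, daughters = 4, n_snps = 80,
                      ...) {
  sim_herd(sim_config(n_sires = n_sires, daughters_per_sire = daughters,
                      n_snps = n_snps, seed = seed, ...))
}
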