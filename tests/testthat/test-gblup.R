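# REML fitting, likelihood evaluation, BLUP solutions and derived quantities.

test_that("incidence matrix maps each record to exactly one animal", {
  rec <- data.frame(animal_id = c("A1", "A1", "A3"), value = 1:3)
  W <- incidence_matrix(rec, c("A1", "A2", "A3"))
  expect_equal(rowSums(W), rep(1, 3))
  expect_equal(W[, "A1"], c(1, 1, 0))
  v <- c(A1 = 2.5, A2 = -1, A3 = 0.5)
  expect_equal(drop(W %*% v), v[rec$animal_id], ignore_attr = TRUE)
  expect_error(incidence_matrix(rec, c("A1", "A2")), "absent")
})

test_that("restricted likelihood matches the dense-V oracle", {
  pop <- small_pop(seed = 101)
  G <- grm_additive(pop$genotypes)
  D <- grm_dominance(pop$genotypes)
  rec <- pop$records
  # unbalance the records and hold three animals out of the phenotype set
  ids <- rownames(pop$genotypes)
  rec <- rec[!(rec$animal_id %in% ids[1:3]), ]
  rec <- rec[!(rec$animal_id %in% ids[4:6] & duplicated(rec$animal_id)), ]
  for (theta in list(c(sigma_a2 = 0.3, sigma_d2 = 0.08, sigma_pe2 = 0.12,
                       sigma_e2 = 0.5),
                     c(sigma_a2 = 0.05, sigma_d2 = 0.3, sigma_pe2 = 0.01,
                       sigma_e2 = 1.2))) {
    expect_equal(reml_loglik(rec, G, D, theta),
                 oracle_reml_loglik(rec, G, D, theta), tolerance = 1e-8)
    thA <- theta[c("sigma_a2", "sigma_pe2", "sigma_e2")]
    expect_equal(reml_loglik(rec, G, components = thA),
                 oracle_reml_loglik(rec, G, NULL, thA), tolerance = 1e-8)
  }
  # REML is invariant to a location shift of the records
  rec2 <- rec
  rec2$value <- rec2$value + 123.4
  th <- c(sigma_a2 = 0.2, sigma_d2 = 0.05, sigma_pe2 = 0.1, sigma_e2 = 0.6)
  expect_equal(reml_loglik(rec2, G, D, th), reml_loglik(rec, G, D, th),
               tolerance = 1e-10)
})

test_that("BLUP solutions equal the dense GLS conditional expectation", {
  pop <- small_pop(seed = 102, n_sires = 5, daughters = 5, n_snps = 100)
  G <- grm_additive(pop$genotypes)
  D <- grm_dominance(pop$genotypes)
  ids <- rownames(pop$genotypes)
  rec <- pop$records[!(pop$records$animal_id %in% ids[1:5]), ]
  theta <- c(sigma_a2 = 0.25, sigma_d2 = 0.1, sigma_pe2 = 0.1, sigma_e2 = 0.6)
  got <- solve_blup(theta, rec, G, D)
  want <- oracle_blup(rec, G, D, theta)
  expect_equal(got$bv, want$bv, tolerance = 1e-8)
  expect_equal(got$dv, want$dv, tolerance = 1e-8)
  expect_equal(got$pe, want$pe, tolerance = 1e-8)
  expect_equal(got$tgv, got$bv + got$dv)
  # unphenotyped animals are predicted, with zero permanent-environment part
  expect_false(all(got$phenotyped))
  expect_true(all(got$pe[!got$phenotyped] == 0))
  expect_true(any(got$bv[!got$phenotyped] != 0))
  expect_error(solve_blup(c(sigma_a2 = 1, sigma_d2 = 0, sigma_pe2 = 1,
                            sigma_e2 = 0), rec, G, D), "repeated records")
})

test_that("constant phenotypes put every component at the zero boundary", {
  pop <- small_pop(seed = 103)
  G <- grm_additive(pop$genotypes)
  rec <- pop$records
  rec$value <- 100
  fit <- gblup(rec, G)
  expect_true(all(fit$components == 0))
  expect_true(fit$converged)
  expect_equal(fit$mu, 100)
  sb <- solve_blup(c(sigma_a2 = 0.2, sigma_pe2 = 0.1, sigma_e2 = 0.7), rec, G)
  expect_equal(sb$bv, rep(0, nrow(sb)), tolerance = 1e-10)
  expect_equal(sb$pe, rep(0, nrow(sb)), tolerance = 1e-10)
})

test_that("REML estimates maximize an independently coded likelihood grid", {
  pop <- sim_herd(sim_config(n_sires = 5, daughters_per_sire = 3, n_snps = 150,
                             sigma_d2 = 0, seed = 104))
  G <- grm_additive(pop$genotypes)
  rec <- pop$records   # 15 animals x 2 records = 30 records
  fit <- gblup(rec, G)
  grid <- expand.grid(a = seq(0.02, 1.2, length.out = 14),
                      pe = seq(0.005, 0.8, length.out = 12),
                      e = seq(0.05, 1.2, length.out = 14))
  gl <- apply(grid, 1, function(g) {
    oracle_reml_loglik(rec, G, NULL,
                       c(sigma_a2 = g[["a"]], sigma_pe2 = g[["pe"]],
                         sigma_e2 = g[["e"]]))
  })
  best <- grid[which.max(gl), ]
  # the fit dominates the whole grid and sits within one grid step of its max
  expect_gte(fit$logl, max(gl) - 1e-6)
  expect_lt(abs(fit$components[["sigma_a2"]] - best$a), 1.2 / 13)
  expect_lt(abs(fit$components[["sigma_pe2"]] - best$pe), 0.8 / 11)
  expect_lt(abs(fit$components[["sigma_e2"]] - best$e), 1.2 / 13)
  # and small perturbations of the optimum never beat it
  th <- fit$components
  for (j in names(th)) {
    for (f in c(0.9, 1.1)) {
      pert <- th
      pert[j] <- max(pert[j], 1e-4) * f
      expect_gte(fit$logl + 1e-7, reml_loglik(rec, G, components = pert))
    }
  }
})

test_that("log-likelihood never decreases across the EM warm-up", {
  pop <- small_pop(seed = 105, n_sires = 8, daughters = 5, n_snps = 120)
  G <- grm_additive(pop$genotypes)
  D <- grm_dominance(pop$genotypes)
  fit <- gblup(pop$records, G, D)
  em <- fit$trace$logl[seq_len(min(fit$control$em_iter + 1L, nrow(fit$trace)))]
  expect_true(all(diff(em) >= -1e-9))
})

test_that("nested fits agree when the dominance component is null", {
  pop <- sim_herd(sim_config(n_sires = 10, daughters_per_sire = 20,
                             n_snps = 500, sigma_d2 = 0, seed = 42))
  fr <- allele_frequencies(pop$genotypes)
  G <- grm_additive(pop$genotypes, fr)
  D <- grm_dominance(pop$genotypes, fr)
  fa <- gblup(pop$records, G)
  fad <- gblup(pop$records, G, D)
  expect_true(fa$converged && fad$converged)
  # the additive model is nested: logL can only improve with D
  expect_gte(fad$logl, fa$logl - 1e-6)
  lrt <- anova(fa, fad)
  expect_gte(lrt$statistic, 0)
  expect_true(lrt$p_value > 0 && lrt$p_value <= 1)
  # boundary component reports no standard error
  if (fad$components[["sigma_d2"]] == 0) {
    expect_true(is.na(fad$se[["sigma_d2"]]))
  }
})

test_that("predicted dominance deviations track the simulated truth", {
  pop <- sim_herd(sim_config(n_sires = 10, daughters_per_sire = 50,
                             n_snps = 400, sigma_d2 = 0.3, sigma_pe2 = 0.05,
                             sigma_e2 = 0.4, seed = 106))
  fr <- allele_frequencies(pop$genotypes)
  G <- grm_additive(pop$genotypes, fr)
  D <- grm_dominance(pop$genotypes, fr)
  fit <- gblup(pop$records, G, D)
  gv <- predict(fit)
  truth <- pop$truth$animal
  expect_gt(cor(gv$dv, truth$dv[match(gv$animal_id, truth$animal_id)]), 0)
  expect_gt(cor(gv$bv, truth$bv[match(gv$animal_id, truth$animal_id)]), 0.3)
  # fitted/residuals decompose the records
  expect_equal(fitted(fit) + residuals(fit), pop$records$value)
})

test_that("mixture test follows the 50:50 chi-square reference", {
  eq <- mixture_lrt(-100, -100)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  # decreasing logL is clamped at zero (boundary convention)
  expect_equal(mixture_lrt(-100, -101)$statistic, 0)
  lrt <- mixture_lrt(-105, -100)
  expect_equal(lrt$statistic, 10)
  # independent survival oracle: P(chisq_1 >= s) = 2 (1 - Phi(sqrt(s)))
  expect_equal(lrt$p_value, (1 - pnorm(sqrt(10))), tolerance = 1e-12)
  expect_equal(lrt$p_value, 7.827011e-4, tolerance = 1e-6)
})

test_that("variance ratios follow their definitions", {
  th <- c(sigma_a2 = 2, sigma_d2 = 0, sigma_pe2 = 1, sigma_e2 = 5)
  r <- variance_ratios(th)
  expect_equal(unname(r[["h_d2"]]), 0)
  expect_equal(unname(r[["dominance_share"]]), 0)
  expect_equal(unname(r[["sigma_p2"]]), 8)
  expect_equal(unname(r[["repeatability"]]), 3 / 8)
  expect_error(variance_ratios(c(sigma_a2 = 0, sigma_pe2 = 0, sigma_e2 = 0)),
               "zero")
})
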