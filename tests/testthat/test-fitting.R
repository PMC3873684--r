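test_that("timecourse constructor enforces its invariants", {
  don <- donor_condition(10)
  expect_error(permeation_timecourse(c(1, 2, 2), c(0, 1, 2), don),
               "strictly increasing")
  expect_error(permeation_timecourse(c(1, 2), c(0, -1), don), ">= 0")
  expect_error(permeation_timecourse(c(1, 2), c(0, 1, 2), don),
               "equal length")
  tc <- permeation_timecourse(c(1, 2), c(0, 1e-9), don)
  expect_s3_class(tc, "permeation_timecourse")
  expect_identical(tc$label, "unnamed")
})

test_that("noise-free one-layer fit recovers the generating parameters", {
  mem <- membrane_spec(L = 68e-4, K = 2, D = 1e-6)
  don <- donor_condition(10)
  tt <- hours_to_s(seq(0.1, 6, length.out = 12))
  fit <- fit_onelayer(tc_from_model(mem, don, tt), L_fixed = mem$L, seed = 1)
  expect_true(fit$converged)
  expect_lt(rel_err(fit$params$K, mem$K), 1e-3)
  expect_lt(rel_err(fit$params$D, mem$D), 1e-3)
  expect_lt(rel_err(fit$params$P, permeability(mem)), 1e-3)
  # residual diagnostics on a perfect fit
  gof <- goodness_of_fit(tc_from_model(mem, don, tt), fit)
  expect_lt(gof$ssr / sum(cumulative_amount(mem, don, tt)^2), 1e-20)
  expect_equal(gof$rmse^2 * gof$n, gof$ssr)
})

test_that("degenerate inputs raise informative fitting errors", {
  don <- donor_condition(10)
  zero_tc <- permeation_timecourse(1:6 * 100, rep(0, 6), don)
  expect_error(fit_onelayer(zero_tc, L_fixed = 68e-4), "no signal")
  short_tc <- permeation_timecourse(c(100, 200, 300), c(0, 1e-9, 2e-9), don)
  expect_error(fit_onelayer(short_tc, L_fixed = 68e-4), "at least 4")
})

test_that("noisy one-layer recovery: median K and D land near truth", {
  mem <- membrane_spec(L = 500e-4, K = 2, D = 1e-7) # lag ~1.2 h, identifiable
  don <- donor_condition(10)
  ests <- vapply(1:8, function(r) {
    cell <- franz_cell_config(noise_cv = 0.05, seed = r)
    tc <- reconstruct_cumulative(simulate_experiment(cell, mem, don))
    f <- fit_onelayer(tc, L_fixed = mem$L, seed = r)
    c(f$params$K, f$params$D)
  }, numeric(2))
  expect_lt(rel_err(median(ests[1, ]), mem$K), 0.10)
  expect_lt(rel_err(median(ests[2, ]), mem$D), 0.10)
  # rmse of a noisy fit stays within ~2x the injected noise scale
  cell <- franz_cell_config(noise_cv = 0.05, seed = 3)
  tc <- reconstruct_cumulative(simulate_experiment(cell, mem, don))
  f <- fit_onelayer(tc, L_fixed = mem$L, seed = 3)
  gof <- goodness_of_fit(tc, f)
  expect_lt(gof$rmse, 2 * 0.05 * max(tc$Q))
})

test_that("estimates are equivariant under joint scaling of Cv and Q", {
  mem <- membrane_spec(L = 500e-4, K = 2, D = 1e-7)
  don <- donor_condition(10)
  tt <- hours_to_s(seq(0.25, 8, length.out = 10))
  tc1 <- tc_from_model(mem, don, tt)
  fac <- 7.3
  tc2 <- permeation_timecourse(tt, tc1$Q * fac,
                               donor_condition(10 * fac))
  f1 <- fit_onelayer(tc1, L_fixed = mem$L, seed = 5)
  f2 <- fit_onelayer(tc2, L_fixed = mem$L, seed = 5)
  expect_lt(rel_err(f1$params$K, f2$params$K), 1e-6)
  expect_lt(rel_err(f1$params$D, f2$params$D), 1e-6)
})

test_that("noise-free two-layer joint fit recovers all four parameters", {
  bl <- sc_dominant_bl()
  don <- donor_condition(1)
  ved <- membrane_spec(L = bl$L_ved, K = bl$K_ved, D = bl$D_ved)
  tt <- hours_to_s(seq(0.25, 8, length.out = 10))
  full <- permeation_timecourse(tt, solve_bilayer_pde(bl, don, tt)$Q, don,
                                label = "full")
  strp <- tc_from_model(ved, don, tt, label = "stripped")
  fit <- fit_twolayer(full, strp, L_sc = bl$L_sc, L_ved = bl$L_ved, seed = 1)
  expect_lt(rel_err(fit$params$K_sc, bl$K_sc), 0.01)
  expect_lt(rel_err(fit$params$D_sc, bl$D_sc), 0.01)
  expect_lt(rel_err(fit$params$K_ved, bl$K_ved), 0.01)
  expect_lt(rel_err(fit$params$D_ved, bl$D_ved), 0.01)
  expect_lt(rel_err(fit$params$P_tot, total_permeability(bl)), 0.01)
})

test_that("noisy two-layer fit pins P_tot tightly, SC parameters loosely", {
  bl <- sc_dominant_bl()
  don <- donor_condition(1)
  ved <- membrane_spec(L = bl$L_ved, K = bl$K_ved, D = bl$D_ved)
  sf <- simulate_experiment(franz_cell_config(noise_cv = 0.05, seed = 7),
                            bl, don)
  ss <- simulate_experiment(franz_cell_config(noise_cv = 0.05, seed = 107),
                            ved, don)
  fit <- fit_twolayer(reconstruct_cumulative(sf), reconstruct_cumulative(ss),
                      L_sc = bl$L_sc, L_ved = bl$L_ved, seed = 7)
  expect_lt(rel_err(fit$params$P_tot, total_permeability(bl)), 0.10)
  expect_lt(rel_err(fit$params$K_sc, bl$K_sc), 0.25)
  expect_lt(rel_err(fit$params$D_sc, bl$D_sc), 0.25)
})

test_that("two-layer fitting demands consistent donors and signals", {
  don <- donor_condition(1)
  ved <- membrane_spec(L = 485e-4, K = 2, D = 1e-7)
  tt <- hours_to_s(seq(0.25, 8, length.out = 8))
  tc <- tc_from_model(ved, don, tt)
  tc_other <- permeation_timecourse(tt, tc$Q, donor_condition(2))
  expect_error(fit_twolayer(tc, tc_other), "donor")
  zero <- permeation_timecourse(tt, rep(0, length(tt)), don)
  expect_error(fit_twolayer(zero, tc), "no signal")
})

test_that("the stripped-curve path of the two-layer fit equals a one-layer fit", {
  # sequential method, VED stage: identical data -> identical estimates
  bl <- sc_dominant_bl()
  don <- donor_condition(1)
  ved <- membrane_spec(L = bl$L_ved, K = bl$K_ved, D = bl$D_ved)
  tt <- hours_to_s(seq(0.25, 8, length.out = 10))
  full <- permeation_timecourse(tt, solve_bilayer_pde(bl, don, tt)$Q, don)
  strp <- tc_from_model(ved, don, tt)
  seqfit <- fit_twolayer(full, strp, L_sc = bl$L_sc, L_ved = bl$L_ved,
                         seed = 3, method = "sequential")
  onefit <- fit_onelayer(strp, L_fixed = bl$L_ved, seed = 3)
  expect_equal(seqfit$params$K_ved, onefit$params$K)
  expect_equal(seqfit$params$D_ved, onefit$params$D)
})

test_that("goodness_of_fit rejects mismatched fits and averages replicates", {
  mem <- membrane_spec(L = 68e-4, K = 2, D = 1e-6)
  don <- donor_condition(10)
  tt <- hours_to_s(seq(0.1, 6, length.out = 8))
  tc <- tc_from_model(mem, don, tt)
  fit <- fit_onelayer(tc, L_fixed = mem$L, seed = 1)
  tc_wrong <- permeation_timecourse(tt, tc$Q, donor_condition(3))
  expect_error(goodness_of_fit(tc_wrong, fit), "donor")
  fake <- fit; fake$params$KL <- NULL
  expect_error(goodness_of_fit(tc, fake), "lacks")
  # replicate averaging
  tc2 <- permeation_timecourse(tt, tc$Q * 1.1, don)
  avg <- average_timecourses(list(tc, tc2))
  expect_equal(avg$Q, tc$Q * 1.05)
  expect_error(average_timecourses(list(tc, tc_from_model(mem, don, tt * 2))),
               "sampling times")
})
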