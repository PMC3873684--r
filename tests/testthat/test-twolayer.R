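test_that("series resistances combine like the electrical analogy", {
  # equal layer permeabilities halve
  bl <- bilayer_spec(L_sc = 10e-4, L_ved = 10e-4, K_sc = 1, K_ved = 1,
                     D_sc = 2e-8, D_ved = 2e-8)
  expect_equal(total_permeability(bl), bl$P_sc / 2)
  # rate-limiting layer dominates
  bl2 <- bilayer_spec(L_sc = 10e-4, L_ved = 10e-4, K_sc = 1, K_ved = 1,
                      D_sc = 1e-10, D_ved = 1e-6)
  expect_equal(total_permeability(bl2),
               1 / (1 / bl2$P_sc + 1 / bl2$P_ved))
  expect_lt(total_permeability(bl2), min(bl2$P_sc, bl2$P_ved))
  # harmonic arithmetic: P_sc = 3e-5, P_ved = 6e-5 -> 2e-5
  bl3 <- bilayer_spec(L_sc = 1e-3, L_ved = 1e-3, K_sc = 3, K_ved = 6,
                      D_sc = 1e-8, D_ved = 1e-8)
  expect_equal(bl3$P_sc, 3e-5)
  expect_equal(total_permeability(bl3), 2e-5)
})

test_that("interface concentration splits the drop by resistance ratio", {
  don <- donor_condition(10)
  # equal resistances: half the donor-side SC concentration
  bl <- bilayer_spec(L_sc = 10e-4, L_ved = 10e-4, K_sc = 1, K_ved = 1,
                     D_sc = 2e-8, D_ved = 2e-8)
  expect_equal(interface_conc(bl, don), mM_to_mol_cm3(5))
  # all resistance in the SC: C_b -> 0
  bl_sc <- bilayer_spec(L_sc = 10e-4, L_ved = 10e-4, K_sc = 1, K_ved = 1,
                        D_sc = 1e-12, D_ved = 1e-4)
  expect_lt(interface_conc(bl_sc, don) / mM_to_mol_cm3(10), 1e-7)
  # no SC resistance: full K_sc*Cv at the interface
  bl_v <- bilayer_spec(L_sc = 10e-4, L_ved = 10e-4, K_sc = 1, K_ved = 1,
                       D_sc = 1e-4, D_ved = 1e-12)
  expect_lt(rel_err(interface_conc(bl_v, don), mM_to_mol_cm3(10)), 1e-7)
})

test_that("steady-state amounts: trapezoid algebra, additivity, reductions", {
  don <- donor_condition(10)
  # identical layers must reproduce the one-layer mean K*Cv/2
  bl <- bilayer_spec(L_sc = 50e-4, L_ved = 50e-4, K_sc = 1, K_ved = 1,
                     D_sc = 1e-6, D_ved = 1e-6)
  br <- ss_amounts(bl, don)
  expect_equal(br$C_ss_avg, mM_to_mol_cm3(5))
  expect_identical(br$M_tot, br$M_sc + br$M_ved)
  # vanishing SC resistance: flat SC profile, M_sc -> L_sc*K_sc*Cv
  bl_flat <- bilayer_spec(L_sc = 10e-4, L_ved = 10e-4, K_sc = 2, K_ved = 1,
                          D_sc = 1e-3, D_ved = 1e-12)
  expect_lt(rel_err(ss_amounts(bl_flat, don)$M_sc,
                    bl_flat$L_sc * 2 * don$Cv), 1e-6)
  # degenerate zero-partition SC shuts everything down
  bl0 <- bilayer_spec(L_sc = 10e-4, L_ved = 10e-4, K_sc = 0, K_ved = 1,
                      D_sc = 1e-8, D_ved = 1e-8)
  expect_identical(ss_amounts(bl0, don)$M_tot, 0)
})

test_that("permeability-form average equals the amount-breakdown average", {
  don <- donor_condition(10)
  set.seed(42)
  for (i in 1:1000) {
    bl <- random_bilayer()
    a <- ss_amounts(bl, don)$C_ss_avg
    b <- ss_mean_conc_twolayer(bl, don)
    expect_lt(rel_err(a, b), 1e-12)
  }
})

test_that("PDE solver validates input and starts from an empty membrane", {
  bl <- sc_dominant_bl()
  don <- donor_condition(1)
  expect_error(solve_bilayer_pde(bl, don, c(10, 5)), "sorted")
  expect_error(solve_bilayer_pde(bl, don, c(-1, 5)), ">= 0")
  expect_error(solve_bilayer_pde(bl, don, 10, n_nodes = 11), ">= 51")
  sol0 <- solve_bilayer_pde(bl, don, 0, n_nodes = 51)
  expect_identical(max(abs(sol0$C)), 0)
  expect_identical(sol0$Q, 0)
})

test_that("identical-layer bilayer reproduces the one-layer series Q(t)", {
  L <- 100e-4; D <- 1e-6
  mem <- membrane_spec(L = L, K = 1, D = D)
  don <- donor_condition(10)
  bl <- bilayer_spec(L_sc = L / 2, L_ved = L / 2, K_sc = 1, K_ved = 1,
                     D_sc = D, D_ved = D)
  tau <- L^2 / D
  tt <- exp(seq(log(0.05), log(5), length.out = 20)) * tau
  sol <- solve_bilayer_pde(bl, don, tt)
  expect_lt(max(rel_err(sol$Q, cumulative_amount(mem, don, tt))), 1e-3)
})

test_that("long-time PDE field matches the piecewise-linear steady state", {
  bl <- sc_dominant_bl()
  don <- donor_condition(1)
  t_end <- 20 * max(bl$L_sc^2 / bl$D_sc, bl$L_ved^2 / bl$D_ved)
  sol <- solve_bilayer_pde(bl, don, t_end)
  # spatial average vs the steady-state algebra
  expect_lt(rel_err(sol$mean_conc[1], ss_mean_conc_twolayer(bl, don)), 5e-3)
  # the field itself: linear within the SC through C_b, linear in the VED
  C_b <- interface_conc(bl, don)
  ii <- sol$interface_index
  sc_line <- bl$K_sc * don$Cv +
    (C_b - bl$K_sc * don$Cv) * sol$x[1:ii] / bl$L_sc
  ved_line <- (C_b * bl$K_ved / bl$K_sc) *
    (1 - (sol$x[(ii + 1):length(sol$x)] - bl$L_sc) / bl$L_ved)
  expect_lt(max(abs(sol$C[1, 1:ii] - sc_line)) / (bl$K_sc * don$Cv), 2e-3)
  expect_lt(max(abs(sol$C[1, (ii + 1):length(sol$x)] - ved_line)) /
              (bl$K_sc * don$Cv), 2e-3)
})

test_that("bilayer solver conserves mass and fills monotonically", {
  bl <- sc_dominant_bl()
  don <- donor_condition(1)
  t_char <- max(bl$L_sc^2 / bl$D_sc, bl$L_ved^2 / bl$D_ved)
  tt <- seq(0.05, 10, length.out = 40) * t_char
  sol <- solve_bilayer_pde(bl, don, tt)
  expect_lt(mass_balance_error(sol), 1e-3)
  expect_true(all(diff(sol$mean_conc) >= -1e-9 * max(sol$mean_conc)))
})

test_that("a transparent VED layer reduces the bilayer to the SC alone", {
  don <- donor_condition(1)
  bl <- bilayer_spec(L_sc = 15e-4, L_ved = 100e-4, K_sc = 10, D_sc = 1e-9,
                     K_ved = 1e4, D_ved = 1e-2)
  expect_lt(rel_err(total_permeability(bl), bl$P_sc), 1e-3)
  br <- ss_amounts(bl, don)
  expect_lt(br$M_ved / br$M_tot, 1e-3)
})
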