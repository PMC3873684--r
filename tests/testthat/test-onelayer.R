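test_that("constructors validate their invariants", {
  expect_error(membrane_spec(L = -1, K = 1, D = 1e-6), "must be > 0")
  expect_error(membrane_spec(L = 68e-4, K = -0.1, D = 1e-6), ">= 0")
  expect_error(membrane_spec(L = 68e-4, K = 1, D = 0), "must be > 0")
  expect_error(donor_condition(-1), ">= 0")
  expect_silent(membrane_spec(L = 68e-4, K = 0, D = 1e-6)) # degenerate K ok
})

test_that("transient profile honours initial and boundary conditions exactly", {
  mem <- sil_mem(K = 1)
  don <- donor_condition(10)
  xs <- seq(0.1, 0.9, by = 0.2) * mem$L
  expect_identical(conc_profile(mem, don, xs, 0), rep(0, length(xs)))
  for (t in c(1, 10, 1e3))
    expect_identical(conc_profile(mem, don, 0, t), mem$K * don$Cv)
  for (t in c(0, 1, 1e3))
    expect_identical(conc_profile(mem, don, mem$L, t), 0)
  expect_error(conc_profile(mem, don, -1e-5, 1), "within")
  expect_error(conc_profile(mem, don, mem$L * 1.01, 1), "within")
  expect_error(conc_profile(mem, don, mem$L / 2, -1), ">= 0")
})

test_that("transient profile matches the Crank-Nicolson oracle", {
  mem <- sil_mem(K = 1)
  don <- donor_condition(10)
  t_half <- 0.5 * mem$L^2 / mem$D
  fd <- solve_onelayer_fd(mem, don, t_half, n_nodes = 2001L)
  mid <- (length(fd$x) + 1L) %/% 2L
  expect_lt(rel_err(conc_profile(mem, don, mem$L / 2, t_half),
                    fd$C[1, mid]), 1e-3)
  # full profile at a second time
  t2 <- 0.1 * mem$L^2 / mem$D
  fd2 <- solve_onelayer_fd(mem, don, t2, n_nodes = 2001L)
  ana <- conc_profile(mem, don, fd2$x, t2)
  expect_lt(max(abs(ana - fd2$C[1, ])) / (mem$K * don$Cv), 1e-3)
})

test_that("profile converges pointwise to the linear steady state", {
  mem <- sil_mem(K = 2)
  don <- donor_condition(5)
  t_inf <- 10 * mem$L^2 / mem$D
  xs <- seq(0, mem$L, length.out = 41)
  ana <- conc_profile(mem, don, xs, t_inf)
  ss <- ss_profile(mem, don, xs)
  expect_lt(max(abs(ana - ss)) / max(ss), 1e-6)
  # steady-state boundary values and midpoint linearity
  expect_identical(ss_profile(mem, don, 0), mem$K * don$Cv)
  expect_identical(ss_profile(mem, don, mem$L), 0)
  expect_equal(ss_profile(membrane_spec(68e-4, 2, 1e-6),
                          donor_condition(0.5), 34e-4),
               mM_to_mol_cm3(0.5))
})

test_that("mean concentration integrates the profile and saturates at K*Cv/2", {
  mem <- sil_mem(K = 1)
  don <- donor_condition(10)
  expect_identical(mean_conc(mem, don, 0), 0)
  expect_lt(rel_err(mean_conc(mem, don, 10 * mem$L^2 / mem$D),
                    mem$K * don$Cv / 2), 1e-6)
  # quadrature oracle at an intermediate time
  t_mid <- 0.2 * mem$L^2 / mem$D
  xg <- seq(0, mem$L, length.out = 10001)
  cp <- conc_profile(mem, don, xg, t_mid)
  quad <- sum((cp[-1] + cp[-length(cp)]) / 2 * diff(xg)) / mem$L
  expect_lt(rel_err(mean_conc(mem, don, t_mid), quad), 1e-6)
  # monotone nondecreasing and bounded
  tt <- seq(0, 5, length.out = 60) * mem$L^2 / mem$D
  mc <- mean_conc(mem, don, tt)
  expect_true(all(diff(mc) >= -1e-15))
  expect_true(all(mc <= mem$K * don$Cv / 2 + 1e-15))
})

test_that("steady-state mean depends on K and Cv only", {
  don <- donor_condition(10)
  expect_identical(ss_mean_conc(sil_mem(K = 1), don), mM_to_mol_cm3(5))
  expect_identical(ss_mean_conc(sil_mem(K = 0), don), 0)
  expect_equal(ss_mean_conc(membrane_spec(1, 26, 1e-5), donor_condition(0.5)),
               mM_to_mol_cm3(6.5))
  # bit-identical under perturbation of D and L
  a <- ss_mean_conc(membrane_spec(68e-4, 3, 1e-6), don)
  b <- ss_mean_conc(membrane_spec(12e-4, 3, 7e-9), don)
  expect_identical(a, b)
})

test_that("cumulative amount follows the series and its late-time asymptote", {
  mem <- sil_mem(K = 1)
  don <- donor_condition(10)
  tau <- mem$L^2 / mem$D
  expect_identical(cumulative_amount(mem, don, 0), 0)
  # series terms vanish at 20 tau: asymptote is exact
  q20 <- cumulative_amount(mem, don, 20 * tau)
  asym <- mem$K * mem$L * don$Cv * (20 - 1 / 6)
  expect_lt(rel_err(q20, asym), 1e-9)
  # finite-difference oracle across two decades of time
  tt <- exp(seq(log(0.05), log(5), length.out = 20)) * tau
  fd <- solve_onelayer_fd(mem, don, tt, n_nodes = 2001L)
  expect_lt(max(rel_err(fd$Q, cumulative_amount(mem, don, tt))), 1e-3)
  # nondecreasing
  qq <- cumulative_amount(mem, don, seq(0, 3 * tau, length.out = 50))
  expect_true(all(diff(qq) >= 0))
})

test_that("late-time slope of Q equals P*Cv", {
  mem <- sil_mem(K = 2, D = 1e-6)
  don <- donor_condition(10)
  tau <- mem$L^2 / mem$D
  slope <- (cumulative_amount(mem, don, 6 * tau) -
              cumulative_amount(mem, don, 5 * tau)) / tau
  expect_lt(rel_err(slope, permeability(mem) * don$Cv), 1e-3)
})

test_that("permeability and lag time are the expected closed forms", {
  expect_equal(permeability(membrane_spec(68e-4, 2, 1e-6)), 2 * 1e-6 / 68e-4)
  expect_identical(permeability(membrane_spec(1, 1, 1e-6)), 1e-6)
  expect_identical(permeability(membrane_spec(1, 0, 1e-6)), 0)
  mem <- sil_mem(K = 1)
  expect_equal(lag_time(mem), 68e-4^2 / (6e-6))
  expect_equal(lag_time(membrane_spec(2 * mem$L, 1, mem$D)), 4 * lag_time(mem))
  # asymptote of Q crosses zero at the lag time
  don <- donor_condition(10)
  tau <- mem$L^2 / mem$D
  q5 <- cumulative_amount(mem, don, 5 * tau)
  q6 <- cumulative_amount(mem, don, 6 * tau)
  slope <- (q6 - q5) / tau
  t_int <- 6 * tau - q6 / slope
  expect_lt(rel_err(t_int, lag_time(mem)), 1e-6)
})
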