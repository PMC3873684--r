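#' Overall permeability of a two-layer membrane
#'
#' Layer resistances add in series: `1/P_tot = 1/P_sc + 1/P_ved`, so
#' `P_tot = 1 / (R_sc + R_ved)` and the smaller layer permeability
#' dominates (the rate-limiting layer, usually the stratum corneum).
#'
#' @param bl a [bilayer_spec()].
#' @return Overall permeability coefficient `P_tot` in cm/s.
#' @export
total_permeability <- function(bl) {
  stopifnot(inherits(bl, "bilayer_spec"))
  Rtot <- bl$R_sc + bl$R_ved
  if (!is.finite(Rtot)) return(0)
  1 / Rtot
}

#' Steady-state concentration at the SC/VED interface (SC side)
#'
#' At steady state the concentration drop across each layer is proportional
#' to its resistance (the electrical-circuit analogy), so the
#' stratum-corneum-side interface concentration is
#' `C_b = K_sc * C_v * R_ved / (R_sc + R_ved)`.
#'
#' @param bl a [bilayer_spec()].
#' @param donor a [donor_condition()] or scalar donor concentration in mM.
#' @return Concentration in mol/cm^3.
#' @export
interface_conc <- function(bl, donor) {
  stopifnot(inherits(bl, "bilayer_spec"))
  donor <- as_donor(donor)
  if (bl$K_sc == 0 || donor$Cv == 0) return(0)
  if (!is.finite(bl$R_ved)) return(bl$K_sc * donor$Cv) # no VED transport
  if (!is.finite(bl$R_sc)) return(0)
  bl$K_sc * donor$Cv * bl$R_ved / (bl$R_sc + bl$R_ved)
}

#' Steady-state drug amounts and mean concentration in two-layer skin
#'
#' Integrates the piecewise-linear steady-state profile. In the SC the
#' profile runs from `K_sc * C_v` at the surface down to the interface
#' value `C_b` ([interface_conc()]), giving the trapezoid
#' `M_sc = L_sc * (K_sc C_v + C_b) / 2`. Crossing into the viable
#' epidermis/dermis the concentration jumps by the SC-to-VED partition
#' ratio (equal chemical potential: `C_b' = C_b * K_ved / K_sc`), then
#' falls linearly to the sink: `M_ved = L_ved * C_b' / 2`. The average skin
#' concentration is `M_tot / L_tot`.
#'
#' @inheritParams interface_conc
#' @return A list of class `ss_breakdown` with `C_b`, `C_b_ved` (the
#'   VED-side interface concentration), `M_sc`, `M_ved`, `M_tot`
#'   (mol/cm^2) and `C_ss_avg` (mol/cm^3).
#' @export
ss_amounts <- function(bl, donor) {
  stopifnot(inherits(bl, "bilayer_spec"))
  donor <- as_donor(donor)
  if (bl$K_sc == 0 || donor$Cv == 0) {
    out <- list(C_b = 0, C_b_ved = 0, M_sc = 0, M_ved = 0, M_tot = 0,
                C_ss_avg = 0)
    class(out) <- "ss_breakdown"
    return(out)
  }
  C_b <- interface_conc(bl, donor)
  C_b_ved <- C_b * bl$K_ved / bl$K_sc
  M_sc <- bl$L_sc * (bl$K_sc * donor$Cv + C_b) / 2
  M_ved <- bl$L_ved * C_b_ved / 2
  M_tot <- M_sc + M_ved
  out <- list(C_b = C_b, C_b_ved = C_b_ved, M_sc = M_sc, M_ved = M_ved,
              M_tot = M_tot, C_ss_avg = M_tot / bl$L_tot)
  class(out) <- "ss_breakdown"
  out
}

#' @export
print.ss_breakdown <- function(x, ...) {
  cat(sprintf("<ss_breakdown> C_b = %g mM (SC side), C_b' = %g mM (VED side)\n",
              mol_cm3_to_mM(x$C_b), mol_cm3_to_mM(x$C_b_ved)))
  cat(sprintf("  M_sc = %g, M_ved = %g, M_tot = %g nmol/cm^2\n",
              mol_cm2_to_nmol_cm2(x$M_sc), mol_cm2_to_nmol_cm2(x$M_ved),
              mol_cm2_to_nmol_cm2(x$M_tot)))
  cat(sprintf("  C_ss_avg = %g mM\n", mol_cm3_to_mM(x$C_ss_avg)))
  invisible(x)
}

#' Steady-state mean skin concentration, permeability form
#'
#' The same average skin concentration as `ss_amounts(bl, donor)$C_ss_avg`,
#' expressed directly through layer permeabilities: with
#' `f = P_sc / (P_sc + P_ved)` (the fraction of the total drop occurring in
#' the VED, equal to `R_ved / (R_sc + R_ved)`),
#' \deqn{\bar C_{ss} = \frac{C_v}{2 L_{tot}}
#'   \left[L_{sc} K_{sc} (1 + f) + L_{ved} K_{ved} f\right].}
#' Kept as a separate code path from [ss_amounts()]; the two agree to
#' machine precision and serve as mutual checks.
#'
#' @inheritParams interface_conc
#' @return Concentration in mol/cm^3.
#' @export
ss_mean_conc_twolayer <- function(bl, donor) {
  stopifnot(inherits(bl, "bilayer_spec"))
  donor <- as_donor(donor)
  Psum <- bl$P_sc + bl$P_ved
  if (Psum == 0 || donor$Cv == 0) return(0)
  f <- bl$P_sc / Psum
  donor$Cv * (bl$L_sc * bl$K_sc * (1 + f) + bl$L_ved * bl$K_ved * f) /
    (2 * bl$L_tot)
}

#' Transient two-layer skin diffusion by Crank-Nicolson finite differences
#'
#' Solves the coupled one-dimensional diffusion equations
#' `dC_sc/dt = D_sc d2C_sc/dx2` (0 < x < L_sc) and
#' `dC_ved/dt = D_ved d2C_ved/dx2` (L_sc < x < L_tot) with a constant donor
#' (`C_sc = K_sc C_v` at the surface), a perfect sink at the base, an
#' initially drug-free membrane, and interface conditions of flux
#' continuity plus the equal-chemical-potential partition jump
#' `C_sc / K_sc = C_ved / K_ved`.
#'
#' Internally the solver works on `u = C / K`, which is continuous across
#' the interface; the interface is a shared finite-volume node so the
#' scheme is conservative: cumulative influx minus efflux equals the stored
#' mass to machine precision. Time steps start at the diffusion-number
#' limit (`nu_max * dx^2 / D`) and grow geometrically (fraction `growth` of
#' elapsed time) once the start-up transient is resolved.
#'
#' @inheritParams interface_conc
#' @param times numeric vector of output times (s), sorted, >= 0.
#' @param n_nodes nodes per layer (>= 51; default 201).
#' @param growth relative time-step growth rate (default 0.01).
#' @param nu_max diffusion-number cap for the initial time step (default 5).
#' @return A list of class `bilayer_solution`: `x` (node positions, cm),
#'   `times`, `C` (matrix, one row per time, concentration in mol/cm^3),
#'   `Q` (cumulative amount permeated per area, mol/cm^2, = cumulative
#'   efflux), `Q_in` (cumulative influx), `stored` (mass per area held in
#'   the membrane), `mean_conc` (spatial average concentration) and
#'   `interface_index` (column of `C` at the interface, SC-side value).
#' @export
solve_bilayer_pde <- function(bl, donor, times, n_nodes = 201L,
                              growth = 0.01, nu_max = 5) {
  stopifnot(inherits(bl, "bilayer_spec"))
  donor <- as_donor(donor)
  if (length(times) < 1L || any(!is.finite(times)) || any(times < 0))
    stop("`times` must be finite and >= 0", call. = FALSE)
  if (is.unsorted(times, strictly = FALSE))
    stop("`times` must be sorted increasing", call. = FALSE)
  if (n_nodes < 51L)
    stop("`n_nodes` must be >= 51 per layer", call. = FALSE)
  n_x <- 2L * n_nodes + 1L
  if (bl$K_sc == 0 || bl$K_ved == 0 || donor$Cv == 0) {
    # no transport through a zero-partition layer: field stays zero except
    # the imposed donor boundary value
    C <- matrix(0, nrow = length(times), ncol = n_x)
    C[times > 0, 1] <- bl$K_sc * donor$Cv
    x1 <- seq(0, bl$L_sc, length.out = n_nodes + 1L)
    x2 <- seq(bl$L_sc, bl$L_tot, length.out = n_nodes + 1L)[-1]
    out <- list(x = c(x1, x2), times = times, C = C,
                Q = numeric(length(times)), Q_in = numeric(length(times)),
                stored = numeric(length(times)),
                mean_conc = numeric(length(times)),
                interface_index = n_nodes + 1L)
    class(out) <- "bilayer_solution"
    return(out)
  }
  sol <- cn_bilayer_cpp(bl$L_sc, bl$L_ved, bl$K_sc, bl$K_ved,
                        bl$D_sc, bl$D_ved, donor$Cv, as.numeric(times),
                        n_per = as.integer(n_nodes), growth = growth,
                        nu_max = nu_max)
  # spatial average by the trapezoidal rule, honouring the interface jump:
  # integrate u = C/K (continuous), weight each panel by its layer K
  x <- sol$x
  ii <- sol$interface_index
  avg <- apply(sol$C, 1L, function(Crow) {
    u <- Crow
    u[1:ii] <- Crow[1:ii] / bl$K_sc
    u[(ii + 1):n_x] <- Crow[(ii + 1):n_x] / bl$K_ved
    dx1 <- diff(x[1:ii]); dx2 <- diff(x[ii:n_x])
    m1 <- bl$K_sc * sum(dx1 * (u[1:(ii - 1)] + u[2:ii]) / 2)
    m2 <- bl$K_ved * sum(dx2 * (u[ii:(n_x - 1)] + u[(ii + 1):n_x]) / 2)
    (m1 + m2) / bl$L_tot
  })
  out <- list(x = x, times = times, C = sol$C, Q = sol$Q_out,
              Q_in = sol$Q_in, stored = sol$stored, mean_conc = avg,
              interface_index = ii)
  class(out) <- "bilayer_solution"
  out
}

#' Mass-balance error of a two-layer transient solution
#'
#' For a conservative scheme, cumulative influx at the donor face minus
#' cumulative efflux at the sink must equal the mass stored in the
#' membrane. Returns the largest absolute imbalance over the recorded
#' times, relative to the final cumulative influx.
#'
#' @param sol a `bilayer_solution` from [solve_bilayer_pde()].
#' @return Dimensionless relative imbalance (0 for a perfect balance).
#' @export
mass_balance_error <- function(sol) {
  stopifnot(inherits(sol, "bilayer_solution"))
  qin_end <- sol$Q_in[length(sol$Q_in)]
  if (qin_end <= 0) return(0)
  max(abs(sol$Q_in - sol$Q - sol$stored)) / qin_end
}
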