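#' One-layer diffusion by Crank-Nicolson finite differences
#'
#' Independent numerical route to the one-layer problem solved analytically
#' by [conc_profile()] and [cumulative_amount()]: a Crank-Nicolson
#' discretisation of `dC/dt = D d2C/dx2` with `C(0,t) = K C_v`,
#' `C(L,t) = 0`, `C(x,0) = 0` on a uniform grid. Used throughout the test
#' suite as the finite-difference oracle for the series solutions, and
#' available to users as a consistency check.
#'
#' @inheritParams conc_profile
#' @param times output times (s), sorted, >= 0.
#' @param n_nodes number of spatial nodes (default 2001).
#' @param growth relative time-step growth rate (default 0.01).
#' @param nu_max diffusion-number cap for the initial step (default 5).
#' @return A list of class `onelayer_fd_solution`: `x`, `times`, `C`
#'   (matrix, rows = times, mol/cm^3), `Q` (cumulative efflux per area,
#'   mol/cm^2) and `Q_in` (cumulative influx per area).
#' @export
solve_onelayer_fd <- function(mem, donor, times, n_nodes = 2001L,
                              growth = 0.01, nu_max = 5) {
  stopifnot(inherits(mem, "membrane_spec"))
  donor <- as_donor(donor)
  if (length(times) < 1L || any(!is.finite(times)) || any(times < 0))
    stop("`times` must be finite and >= 0", call. = FALSE)
  if (is.unsorted(times, strictly = FALSE))
    stop("`times` must be sorted increasing", call. = FALSE)
  if (n_nodes < 11L) stop("`n_nodes` must be >= 11", call. = FALSE)
  C0 <- mem$K * donor$Cv
  if (C0 == 0) {
    out <- list(x = seq(0, mem$L, length.out = n_nodes), times = times,
                C = matrix(0, length(times), n_nodes),
                Q = numeric(length(times)), Q_in = numeric(length(times)))
    class(out) <- "onelayer_fd_solution"
    return(out)
  }
  sol <- cn_onelayer_cpp(mem$L, mem$D, C0, as.numeric(times),
                         n_nodes = as.integer(n_nodes), growth = growth,
                         nu_max = nu_max)
  out <- list(x = sol$x, times = times, C = sol$C, Q = sol$Q_out,
              Q_in = sol$Q_in)
  class(out) <- "onelayer_fd_solution"
  out
}
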