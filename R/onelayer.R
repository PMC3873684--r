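#' One-layer membrane diffusion: Fourier-series solutions of Fick's 2nd law
#'
#' Closed-form solutions for a homogeneous membrane of thickness `L` with a
#' constant donor at `x = 0` (`C = K * C_v`), a perfect sink at `x = L`
#' (`C = 0`) and an initially drug-free membrane. `x` is measured from the
#' donor-facing surface. All quantities are in internal units (cm, s,
#' mol/cm^3); construct the donor with [donor_condition()] (mM in).
#'
#' The transient concentration is
#' \deqn{C(x,t) = K C_v \left[1 - \frac{x}{L}
#'   - \frac{2}{\pi}\sum_{n\ge 1}\frac{1}{n}\sin\frac{n\pi x}{L}
#'     \exp\left(-\frac{D n^2 \pi^2 t}{L^2}\right)\right]}
#' and the cumulative amount permeated per unit area is
#' \deqn{Q(t) = K L C_v \left[\frac{D t}{L^2} - \frac{1}{6}
#'   - \frac{2}{\pi^2}\sum_{n\ge 1}\frac{(-1)^n}{n^2}
#'     \exp\left(-\frac{D n^2 \pi^2 t}{L^2}\right)\right].}
#'
#' Series are truncated adaptively: summation stops when the next term is
#' below 1e-12 of the running partial sum, with a hard cap (`n_terms`,
#' default 500). At `t = 0` the exact limiting values are returned instead
#' of summing.
#'
#' @param mem a [membrane_spec()].
#' @param donor a [donor_condition()] or scalar donor concentration in mM.
#' @param x depth within the membrane (cm), in `[0, L]`. May be a vector.
#' @param t time (s), >= 0. May be a vector (but not together with vector
#'   `x`).
#' @param n_terms maximum number of series terms (default 500).
#' @return Concentration(s) in mol/cm^3 for the concentration functions;
#'   amount per area (mol/cm^2) for [cumulative_amount()].
#' @seealso [ss_profile()], [mean_conc()], [ss_mean_conc()],
#'   [cumulative_amount()], [permeability()], [lag_time()]
#' @examples
#' mem <- membrane_spec(L = 68e-4, K = 1, D = 1e-6)
#' don <- donor_condition(10)
#' conc_profile(mem, don, x = mem$L / 2, t = 30)
#' mol_cm3_to_mM(ss_mean_conc(mem, don)) # K * Cv / 2 -> 5 mM
#' @export
conc_profile <- function(mem, donor, x, t, n_terms = 500L) {
  stopifnot(inherits(mem, "membrane_spec"))
  donor <- as_donor(donor)
  if (any(!is.finite(x)) || any(x < 0) || any(x > mem$L))
    stop("`x` must lie within [0, L]", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("`t` must be >= 0", call. = FALSE)
  if (length(x) > 1L && length(t) > 1L)
    stop("only one of `x`, `t` may be a vector", call. = FALSE)
  C0 <- mem$K * donor$Cv
  if (C0 == 0) return(rep(0, max(length(x), length(t))))
  xi <- x / mem$L
  tau <- mem$D * t / mem$L^2
  n_out <- max(length(xi), length(tau))
  xi <- rep_len(xi, n_out)
  tau <- rep_len(tau, n_out)
  out <- numeric(n_out)
  for (i in seq_len(n_out)) {
    if (tau[i] == 0) {           # initial condition, except the donor face
      out[i] <- if (xi[i] == 0) C0 else 0
      next
    }
    if (xi[i] == 0) { out[i] <- C0; next }
    if (xi[i] == 1) { out[i] <- 0; next }
    s <- 0
    for (n in seq_len(n_terms)) {
      term <- sin(n * pi * xi[i]) / n * exp(-n^2 * pi^2 * tau[i])
      s <- s + term
      if (abs(term) < 1e-12 * max(abs(s), .Machine$double.xmin)) break
    }
    out[i] <- C0 * (1 - xi[i] - 2 / pi * s)
  }
  out
}

#' Steady-state concentration profile in a one-layer membrane
#'
#' The infinite-time limit of [conc_profile()]: a straight line from
#' `K * C_v` at the donor face to 0 at the sink, `C_ss(x) = K C_v (1 - x/L)`.
#'
#' @inheritParams conc_profile
#' @return Concentration(s) in mol/cm^3.
#' @export
ss_profile <- function(mem, donor, x) {
  stopifnot(inherits(mem, "membrane_spec"))
  donor <- as_donor(donor)
  if (any(!is.finite(x)) || any(x < 0) || any(x > mem$L))
    stop("`x` must lie within [0, L]", call. = FALSE)
  mem$K * donor$Cv * (1 - x / mem$L)
}

#' Mean membrane concentration over depth at time t
#'
#' Spatial average of the transient profile over `[0, L]`:
#' \deqn{\bar C(t) = K C_v \left[\frac{1}{2}
#'   - \sum_{n\,\mathrm{odd}} \frac{4}{n^2\pi^2}
#'     \exp\left(-\frac{D n^2 \pi^2 t}{L^2}\right)\right],}
#' which rises monotonically from 0 to the steady-state mean `K C_v / 2`.
#'
#' @inheritParams conc_profile
#' @return Mean concentration(s) in mol/cm^3.
#' @export
mean_conc <- function(mem, donor, t, n_terms = 500L) {
  stopifnot(inherits(mem, "membrane_spec"))
  donor <- as_donor(donor)
  if (any(!is.finite(t)) || any(t < 0))
    stop("`t` must be >= 0", call. = FALSE)
  C0 <- mem$K * donor$Cv
  tau <- mem$D * t / mem$L^2
  out <- numeric(length(tau))
  for (i in seq_along(tau)) {
    if (tau[i] == 0 || C0 == 0) { out[i] <- 0; next }
    s <- 0
    n <- 1L
    for (k in seq_len(n_terms)) {
      term <- 4 / (n^2 * pi^2) * exp(-n^2 * pi^2 * tau[i])
      s <- s + term
      if (term < 1e-12 * max(s, .Machine$double.xmin)) break
      n <- n + 2L                 # even terms vanish in the spatial integral
    }
    out[i] <- C0 * (0.5 - s)
  }
  out
}

#' Steady-state mean membrane concentration
#'
#' `K * C_v / 2`: the spatial average of the linear steady-state profile.
#' Notably independent of `D` and `L` — the partition coefficient alone
#' (given the donor concentration) fixes the steady-state membrane load.
#'
#' @inheritParams conc_profile
#' @return Concentration in mol/cm^3.
#' @export
ss_mean_conc <- function(mem, donor) {
  stopifnot(inherits(mem, "membrane_spec"))
  donor <- as_donor(donor)
  mem$K * donor$Cv / 2
}

#' Cumulative amount permeated per unit area
#'
#' The lag-time series solution `Q(t)` (see [conc_profile()] for the
#' formula). For large `t` it approaches the straight asymptote
#' `K L C_v (D t / L^2 - 1/6)`, whose slope is `P * C_v` and whose t-axis
#' intercept is the lag time `L^2 / (6 D)`.
#'
#' @inheritParams conc_profile
#' @return Amount(s) per area in mol/cm^2.
#' @export
cumulative_amount <- function(mem, donor, t, n_terms = 500L) {
  stopifnot(inherits(mem, "membrane_spec"))
  donor <- as_donor(donor)
  if (any(!is.finite(t)) || any(t < 0))
    stop("`t` must be >= 0", call. = FALSE)
  A0 <- mem$K * mem$L * donor$Cv
  tau <- mem$D * t / mem$L^2
  out <- numeric(length(tau))
  for (i in seq_along(tau)) {
    if (tau[i] == 0 || A0 == 0) { out[i] <- 0; next }
    s <- 0
    for (n in seq_len(n_terms)) {
      term <- (-1)^n / n^2 * exp(-n^2 * pi^2 * tau[i])
      s <- s + term
      if (abs(term) < 1e-12 * max(abs(s), .Machine$double.xmin)) break
    }
    q <- A0 * (tau[i] - 1 / 6 - 2 / pi^2 * s)
    out[i] <- max(q, 0)           # guard tiny negative round-off at t -> 0+
  }
  out
}

#' Permeability coefficient of a homogeneous membrane
#'
#' `P = K * D / L` (cm/s): the steady-state flux per unit donor
#' concentration.
#'
#' @param mem a [membrane_spec()].
#' @return Permeability in cm/s.
#' @export
permeability <- function(mem) {
  stopifnot(inherits(mem, "membrane_spec"))
  mem$K * mem$D / mem$L
}

#' Diffusional lag time of a homogeneous membrane
#'
#' `L^2 / (6 D)` (s): the t-axis intercept of the steady-state asymptote of
#' the cumulative-permeation curve.
#'
#' @param mem a [membrane_spec()].
#' @return Lag time in s.
#' @export
lag_time <- function(mem) {
  stopifnot(inherits(mem, "membrane_spec"))
  mem$L^2 / (6 * mem$D)
}
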