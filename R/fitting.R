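#' Cumulative-permeation time course
#'
#' A `(t, Q)` record from a membrane permeation experiment: cumulative
#' amount permeated per unit diffusion area versus time, together with the
#' donor concentration that drove it. This is the quantity the fitting
#' routines consume.
#'
#' @param times_s times (s), strictly increasing, >= 0.
#' @param Q cumulative amount per area (mol/cm^2), >= 0, same length.
#' @param donor a [donor_condition()] or scalar donor concentration (mM).
#' @param area diffusion area (cm^2), metadata only (Q is already per
#'   area).
#' @param label free-text identifier.
#' @return An object of class `permeation_timecourse`.
#' @export
permeation_timecourse <- function(times_s, Q, donor, area = NA_real_,
                                  label = "") {
  if (!is.numeric(times_s) || !is.numeric(Q) || length(times_s) != length(Q))
    stop("`times_s` and `Q` must be numeric vectors of equal length",
         call. = FALSE)
  if (length(times_s) < 1L)
    stop("time course must contain at least one point", call. = FALSE)
  if (any(!is.finite(times_s)) || any(times_s < 0))
    stop("times must be finite and >= 0", call. = FALSE)
  if (is.unsorted(times_s, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(Q)) || any(Q < 0))
    stop("Q must be finite and >= 0", call. = FALSE)
  donor <- as_donor(donor)
  structure(list(times = as.numeric(times_s), Q = as.numeric(Q),
                 donor = donor, area = area,
                 label = if (nzchar(label)) label else "unnamed"),
            class = "permeation_timecourse")
}

#' @export
print.permeation_timecourse <- function(x, ...) {
  cat(sprintf("<permeation_timecourse> '%s': %d points, t = %.3g..%.3g h, donor %g mM\n",
              x$label, length(x$times), s_to_hours(min(x$times)),
              s_to_hours(max(x$times)), x$donor$Cv_mM))
  invisible(x)
}

#' Average replicate time courses
#'
#' Permeation studies typically report the mean curve over several
#' replicate cells or animals; the fitting routines operate on one curve,
#' so replicates are averaged first. All replicates must share the same
#' sampling times and donor concentration.
#'
#' @param tcs a list of [permeation_timecourse()] objects.
#' @return A single averaged `permeation_timecourse`.
#' @export
average_timecourses <- function(tcs) {
  stopifnot(is.list(tcs), length(tcs) >= 1L,
            all(vapply(tcs, inherits, TRUE, "permeation_timecourse")))
  t0 <- tcs[[1]]$times
  cv0 <- tcs[[1]]$donor$Cv
  for (tc in tcs[-1]) {
    if (!isTRUE(all.equal(tc$times, t0)))
      stop("replicates must share sampling times", call. = FALSE)
    if (!isTRUE(all.equal(tc$donor$Cv, cv0)))
      stop("replicates must share the donor concentration", call. = FALSE)
  }
  Qm <- rowMeans(vapply(tcs, function(tc) tc$Q, numeric(length(t0))))
  permeation_timecourse(t0, Qm, tcs[[1]]$donor, tcs[[1]]$area,
                        label = paste0(tcs[[1]]$label, " (mean of ",
                                       length(tcs), ")"))
}

# One-layer forward model in the fitted parameterisation (KL, D/L^2):
# reusing the unit-thickness series, Q = KL * Cv * (D/L^2 * t - 1/6 - ...)
q_onelayer_kl <- function(KL, D_over_L2, Cv_mol_cm3, times_s) {
  mem <- membrane_spec(L = 1, K = KL, D = D_over_L2)
  cumulative_amount(mem, structure(list(Cv = Cv_mol_cm3,
                                        Cv_mM = mol_cm3_to_mM(Cv_mol_cm3)),
                                   class = "donor_condition"), times_s)
}

# heuristic initial values (KL, D/L^2) from the late-time asymptote:
# slope -> P*Cv, t-intercept -> lag = 1/(6 D/L^2)
init_onelayer <- function(tc) {
  n <- length(tc$times)
  idx <- max(1L, n - 2L):n
  sl <- stats::coef(stats::lm(tc$Q[idx] ~ tc$times[idx]))
  slope <- max(sl[[2]], .Machine$double.eps)
  lag <- tc$times[n] - tc$Q[n] / slope
  span <- diff(range(tc$times))
  if (!is.finite(lag) || lag <= span / 1e4 || lag >= tc$times[n])
    lag <- span / 10
  D_over_L2 <- 1 / (6 * lag)
  KL <- slope / (tc$donor$Cv * D_over_L2)
  c(KL = max(KL, 1e-12), D_over_L2 = max(D_over_L2, 1e-16))
}

# seeded Latin-hypercube multistart around log10(init), +/- `decades`/2
multistart_grid <- function(init, n_starts, seed, decades = 4) {
  if (n_starts <= 1L) return(matrix(log(init), nrow = 1L))
  set.seed(seed)
  H <- lhs::randomLHS(n_starts - 1L, length(init))
  offs <- (H - 0.5) * decades           # log10 offsets
  starts <- sweep(offs * log(10), 2L, log(init), "+")
  rbind(matrix(log(init), nrow = 1L), starts)
}

new_fit_result <- function(model, params, ssr, n_iter, converged, seed,
                           donor, n_obs, extra = list()) {
  structure(c(list(model = model, params = params, ssr = ssr,
                   n_iter = n_iter, converged = converged, seed = seed,
                   donor = donor, n_obs = n_obs), extra),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s model, SSR = %.4g, %s after %d iterations\n",
              x$model, x$ssr,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  for (nm in names(x$params))
    cat(sprintf("  %-10s %.6g\n", nm, x$params[[nm]]))
  invisible(x)
}

#' Fit the one-layer permeation model to a cumulative time course
#'
#' Least-squares estimation of the partition parameter `KL` and diffusion
#' parameter `D/L^2` of the one-layer lag-time solution, by
#' Levenberg-Marquardt minimisation of the unweighted squared residuals of
#' cumulative amounts. Parameters are fitted on the log scale (enforcing
#' positivity) with a seeded Latin-hypercube multi-start spanning four
#' decades around a lag-time/steady-slope heuristic. Given the fixed
#' membrane thickness `L_fixed`, the physical `K = KL / L`,
#' `D = (D/L^2) L^2` and `P = K D / L` are reported.
#'
#' @param tc a [permeation_timecourse()] with at least 4 points.
#' @param L_fixed membrane thickness (cm) used to convert the fitted
#'   composite parameters to `K` and `D` (silicone: 68e-4 cm).
#' @param n_starts number of multi-start points (default 8).
#' @param seed integer seed for the multi-start design.
#' @param weights optional per-point residual weights (default unweighted).
#' @return A `fit_result` with `params` `KL`, `D_over_L2`, `K`, `D`, `P`.
#' @export
fit_onelayer <- function(tc, L_fixed, n_starts = 8L, seed = 1L,
                         weights = NULL) {
  stopifnot(inherits(tc, "permeation_timecourse"))
  stopifnot_scalar(L_fixed, "L_fixed")
  if (length(tc$times) < 4L)
    stop("need at least 4 points to fit", call. = FALSE)
  if (all(tc$Q == 0))
    stop("no signal: all cumulative amounts are zero", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(tc$Q))
  Cv <- tc$donor$Cv

  resid_fn <- function(logp) {
    p <- exp(logp)
    sqrt(weights) * (tc$Q - q_onelayer_kl(p[1], p[2], Cv, tc$times))
  }
  starts <- multistart_grid(init_onelayer(tc), n_starts, seed)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    ok <- fit$info %in% 1:3
    better <- is.null(best) || ssr < best$ssr * (1 - 1e-12) ||
      (abs(ssr - best$ssr) <= 1e-12 * max(ssr, best$ssr) &&
         sum(fit$par^2) < sum(best$fit$par^2))
    if (better) best <- list(fit = fit, ssr = ssr, ok = ok)
  }
  if (is.null(best))
    stop("optimisation failed from every start", call. = FALSE)
  if (!best$ok)
    stop(sprintf(
      "no start converged (best SSR %.4g, nls.lm info %d: %s)",
      best$ssr, best$fit$info, best$fit$message), call. = FALSE)
  p <- exp(best$fit$par)
  KL <- p[[1]]; DL2 <- p[[2]]
  new_fit_result(
    model = "one-layer",
    params = list(KL = KL, D_over_L2 = DL2, K = KL / L_fixed,
                  D = DL2 * L_fixed^2, P = KL * DL2),
    ssr = best$ssr, n_iter = best$fit$niter,
    converged = best$ok, seed = seed, donor = tc$donor,
    n_obs = length(tc$times),
    extra = list(L = L_fixed, label = tc$label))
}

# bilayer forward model for the optimizer: Q(t) at observation times
q_bilayer <- function(K_sc, D_sc, K_ved, D_ved, L_sc, L_ved, Cv_mol_cm3,
                      times_s, n_nodes = 101L) {
  bl <- bilayer_spec(L_sc = L_sc, L_ved = L_ved, K_sc = K_sc, D_sc = D_sc,
                     K_ved = K_ved, D_ved = D_ved)
  don <- structure(list(Cv = Cv_mol_cm3, Cv_mM = mol_cm3_to_mM(Cv_mol_cm3)),
                   class = "donor_condition")
  solve_bilayer_pde(bl, don, times_s, n_nodes = n_nodes)$Q
}

#' Fit the two-layer skin model to full-thickness and stripped-skin data
#'
#' Estimates `K_sc`, `D_sc`, `K_ved`, `D_ved` from a pair of cumulative
#' permeation curves: full-thickness skin (both layers) and tape-stripped
#' skin (stratum corneum removed, modelled as the VED layer alone). The
#' stripped curve is fitted with the one-layer series; the full-thickness
#' curve with the two-layer Crank-Nicolson forward model. By default the
#' two residual vectors are minimised jointly over all four
#' log-parameters; `method = "sequential"` first fixes the VED parameters
#' from the stripped curve, then fits only the SC pair.
#'
#' The SC parameters are weakly identified when the stratum corneum is not
#' rate-limiting; the joint fit is initialised sequentially and refined
#' from seeded multi-start jitter.
#'
#' @param full [permeation_timecourse()] through full-thickness skin.
#' @param stripped [permeation_timecourse()] through stripped skin.
#' @param L_sc stratum corneum thickness (cm; default 15e-4).
#' @param L_ved viable epidermis + dermis thickness (cm; default 500e-4).
#' @param n_starts multi-start points for each optimisation stage.
#' @param seed integer seed.
#' @param method `"joint"` (default) or `"sequential"`.
#' @param n_nodes PDE nodes per layer inside the optimiser (default 101;
#'   the reported fit is re-evaluated at 201).
#' @return A `fit_result` with `params` `K_sc`, `D_sc`, `K_ved`, `D_ved`,
#'   `P_sc`, `P_ved`, `P_tot`.
#' @export
fit_twolayer <- function(full, stripped, L_sc = 15e-4, L_ved = 500e-4,
                         n_starts = 8L, seed = 1L,
                         method = c("joint", "sequential"),
                         n_nodes = 101L) {
  method <- match.arg(method)
  stopifnot(inherits(full, "permeation_timecourse"),
            inherits(stripped, "permeation_timecourse"))
  if (!isTRUE(all.equal(full$donor$Cv, stripped$donor$Cv)))
    stop("full and stripped curves must share the donor concentration",
         call. = FALSE)
  if (all(full$Q == 0) || all(stripped$Q == 0))
    stop("no signal: all cumulative amounts are zero", call. = FALSE)
  Cv <- full$donor$Cv

  # stage 1: VED from the stripped curve alone
  fit_ved <- fit_onelayer(stripped, L_fixed = L_ved, n_starts = n_starts,
                          seed = seed)
  K_ved0 <- fit_ved$params$K; D_ved0 <- fit_ved$params$D

  # stage 2: SC pair on the full curve with VED fixed
  resid_sc <- function(logp) {
    p <- exp(logp)
    full$Q - q_bilayer(p[1], p[2], K_ved0, D_ved0, L_sc, L_ved, Cv,
                       full$times, n_nodes)
  }
  # init: series-resistance estimate of P_sc from the full-curve asymptote
  tc1 <- init_onelayer(full)          # KL, D/L^2 of full treated one-layer
  P_tot0 <- tc1[["KL"]] * tc1[["D_over_L2"]]
  P_ved0 <- K_ved0 * D_ved0 / L_ved
  P_sc0 <- if (P_tot0 < P_ved0 * 0.99) 1 / (1 / P_tot0 - 1 / P_ved0)
           else P_tot0
  D_sc0 <- L_sc^2 * tc1[["D_over_L2"]]
  K_sc0 <- max(P_sc0 * L_sc / D_sc0, 1e-9)
  starts_sc <- multistart_grid(c(K_sc0, D_sc0), n_starts, seed + 1L)
  best_sc <- NULL
  for (i in seq_len(nrow(starts_sc))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts_sc[i, ], fn = resid_sc,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 100, ftol = 1e-10, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best_sc) || ssr < best_sc$ssr) best_sc <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best_sc))
    stop("stratum-corneum stage failed from every start", call. = FALSE)
  K_sc1 <- exp(best_sc$fit$par[[1]]); D_sc1 <- exp(best_sc$fit$par[[2]])

  if (method == "sequential") {
    theta <- c(K_sc1, D_sc1, K_ved0, D_ved0)
    n_iter <- fit_ved$n_iter + best_sc$fit$niter
    conv <- fit_ved$converged && best_sc$fit$info %in% 1:3
  } else {
    # stage 3: joint polish of all four parameters on both curves
    resid_joint <- function(logp) {
      p <- exp(logp)
      r1 <- stripped$Q - q_onelayer_kl(p[3] * L_ved, p[4] / L_ved^2, Cv,
                                       stripped$times)
      r2 <- full$Q - q_bilayer(p[1], p[2], p[3], p[4], L_sc, L_ved, Cv,
                               full$times, n_nodes)
      c(r1, r2)
    }
    init <- c(K_sc1, D_sc1, K_ved0, D_ved0)
    starts <- multistart_grid(init, max(2L, n_starts %/% 2L), seed + 2L,
                              decades = 1)
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      fit <- tryCatch(
        minpack.lm::nls.lm(par = starts[i, ], fn = resid_joint,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 150, ftol = 1e-12, ptol = 1e-12)),
        error = function(e) NULL)
      if (is.null(fit)) next
      ssr <- sum(fit$fvec^2)
      if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
    }
    if (is.null(best))
      stop("joint optimisation failed from every start", call. = FALSE)
    theta <- exp(best$fit$par)
    n_iter <- fit_ved$n_iter + best_sc$fit$niter + best$fit$niter
    conv <- best$fit$info %in% 1:3
  }

  bl <- bilayer_spec(L_sc = L_sc, L_ved = L_ved, K_sc = theta[[1]],
                     D_sc = theta[[2]], K_ved = theta[[3]],
                     D_ved = theta[[4]])
  # report SSR from the high-resolution forward model
  Q_hat_full <- q_bilayer(theta[[1]], theta[[2]], theta[[3]], theta[[4]],
                          L_sc, L_ved, Cv, full$times, n_nodes = 201L)
  Q_hat_str <- q_onelayer_kl(theta[[3]] * L_ved, theta[[4]] / L_ved^2, Cv,
                             stripped$times)
  ssr <- sum((full$Q - Q_hat_full)^2) + sum((stripped$Q - Q_hat_str)^2)
  new_fit_result(
    model = "two-layer",
    params = list(K_sc = theta[[1]], D_sc = theta[[2]], K_ved = theta[[3]],
                  D_ved = theta[[4]], P_sc = bl$P_sc, P_ved = bl$P_ved,
                  P_tot = total_permeability(bl)),
    ssr = ssr, n_iter = n_iter, converged = conv, seed = seed,
    donor = full$donor, n_obs = length(full$times) + length(stripped$times),
    extra = list(L_sc = L_sc, L_ved = L_ved, method = method,
                 label = paste(full$label, "+", stripped$label)))
}

#' Residual diagnostics for a fitted permeation model
#'
#' Recomputes the model curve from the stored parameter estimates and
#' returns the residuals, their sum of squares and the RMSE
#' (`rmse^2 * n = ssr`).
#'
#' @param tc the [permeation_timecourse()] the fit refers to.
#' @param fit a `fit_result` from [fit_onelayer()] or [fit_twolayer()].
#' @param role for two-layer fits, whether `tc` is the `"full"` or
#'   `"stripped"` curve.
#' @return A list with `residuals`, `fitted`, `ssr`, `rmse`, `n`.
#' @export
goodness_of_fit <- function(tc, fit, role = c("full", "stripped")) {
  stopifnot(inherits(tc, "permeation_timecourse"),
            inherits(fit, "fit_result"))
  if (!isTRUE(all.equal(tc$donor$Cv, fit$donor$Cv)))
    stop("donor concentration of `tc` does not match the fit", call. = FALSE)
  if (fit$model == "one-layer") {
    need <- c("KL", "D_over_L2")
    if (!all(need %in% names(fit$params)))
      stop("fit result lacks one-layer parameters", call. = FALSE)
    Q_hat <- q_onelayer_kl(fit$params$KL, fit$params$D_over_L2,
                           tc$donor$Cv, tc$times)
  } else if (fit$model == "two-layer") {
    role <- match.arg(role)
    need <- c("K_sc", "D_sc", "K_ved", "D_ved")
    if (!all(need %in% names(fit$params)))
      stop("fit result lacks two-layer parameters", call. = FALSE)
    Q_hat <- if (role == "stripped")
      q_onelayer_kl(fit$params$K_ved * fit$L_ved,
                    fit$params$D_ved / fit$L_ved^2, tc$donor$Cv, tc$times)
    else
      q_bilayer(fit$params$K_sc, fit$params$D_sc, fit$params$K_ved,
                fit$params$D_ved, fit$L_sc, fit$L_ved, tc$donor$Cv,
                tc$times, n_nodes = 201L)
  } else {
    stop("unknown model family in fit result", call. = FALSE)
  }
  r <- tc$Q - Q_hat
  list(residuals = r, fitted = Q_hat, ssr = sum(r^2),
       rmse = sqrt(mean(r^2)), n = length(r))
}
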