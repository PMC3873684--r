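#' Virtual Franz diffusion-cell configuration
#'
#' Geometry, sampling protocol and noise model of a simulated Franz-cell
#' permeation experiment. Defaults follow a typical vertical cell:
#' receiver volume 6.0 mL, effective diffusion area 1.77 cm^2, 400 uL
#' sampled and replaced with fresh buffer at each time point, 8 sampling
#' times log-spaced over 0.25-8 h.
#'
#' @param receiver_volume_mL receiver chamber volume (mL; default 6.0).
#' @param sample_volume_mL volume withdrawn (and replaced) per sampling
#'   event (mL; default 0.4). Must be < receiver volume.
#' @param area_cm2 effective diffusion area (cm^2; default 1.77).
#' @param schedule_h sampling times in hours, strictly increasing, > 0.
#' @param noise_cv relative standard deviation of the assay noise applied
#'   per sample (default 0 = noise-free).
#' @param noise_model `"lognormal"` (multiplicative, mean-1; default) or
#'   `"additive"` (Gaussian with sd = `noise_cv` x true value).
#' @param seed integer seed making the simulated assay deterministic.
#' @param donor_volume_mL donor chamber volume (mL; default 0.5), used only
#'   when `donor_depletion = TRUE`.
#' @param donor_depletion if `TRUE`, deplete the donor quasi-statically as
#'   drug leaves it (the analytical models assume a constant donor; this
#'   switch exists to stress-test fitting bias). Default `FALSE`.
#' @param clamp_negative clamp negative reconstructed concentrations to 0
#'   (with a warning) instead of erroring.
#' @param temperature_note free-text metadata (default "32 C").
#' @return An object of class `franz_cell_config`.
#' @export
franz_cell_config <- function(receiver_volume_mL = 6.0,
                              sample_volume_mL = 0.4,
                              area_cm2 = 1.77,
                              schedule_h = exp(seq(log(0.25), log(8),
                                                   length.out = 8)),
                              noise_cv = 0,
                              noise_model = c("lognormal", "additive"),
                              seed = 1L,
                              donor_volume_mL = 0.5,
                              donor_depletion = FALSE,
                              clamp_negative = TRUE,
                              temperature_note = "32 C") {
  noise_model <- match.arg(noise_model)
  stopifnot_scalar(receiver_volume_mL, "receiver_volume_mL")
  stopifnot_scalar(sample_volume_mL, "sample_volume_mL")
  stopifnot_scalar(area_cm2, "area_cm2")
  stopifnot_scalar(noise_cv, "noise_cv", positive = FALSE, nonneg = TRUE)
  if (sample_volume_mL >= receiver_volume_mL)
    stop("sample volume must be smaller than the receiver volume",
         call. = FALSE)
  if (length(schedule_h) < 1L)
    stop("sampling schedule must contain at least one time", call. = FALSE)
  if (any(!is.finite(schedule_h)) || any(schedule_h <= 0) ||
      is.unsorted(schedule_h, strictly = TRUE))
    stop("sampling schedule must be strictly increasing and > 0",
         call. = FALSE)
  structure(list(receiver_volume_mL = receiver_volume_mL,
                 sample_volume_mL = sample_volume_mL,
                 area_cm2 = area_cm2,
                 schedule_h = as.numeric(schedule_h),
                 noise_cv = noise_cv, noise_model = noise_model,
                 seed = as.integer(seed),
                 donor_volume_mL = donor_volume_mL,
                 donor_depletion = donor_depletion,
                 clamp_negative = clamp_negative,
                 temperature_note = temperature_note),
            class = "franz_cell_config")
}

#' @export
print.franz_cell_config <- function(x, ...) {
  cat(sprintf(
    "<franz_cell_config> V_r = %g mL, V_s = %g mL, A = %g cm^2, %d samples (%.3g-%.3g h)\n",
    x$receiver_volume_mL, x$sample_volume_mL, x$area_cm2,
    length(x$schedule_h), min(x$schedule_h), max(x$schedule_h)))
  cat(sprintf("  noise: %s CV = %g, seed = %d, donor depletion: %s\n",
              x$noise_model, x$noise_cv, x$seed, x$donor_depletion))
  invisible(x)
}

# true cumulative amount per area at the given times for either membrane
model_Q <- function(membrane, donor, times_s) {
  if (inherits(membrane, "membrane_spec"))
    cumulative_amount(membrane, donor, times_s)
  else if (inherits(membrane, "bilayer_spec"))
    solve_bilayer_pde(membrane, donor, times_s, n_nodes = 201L)$Q
  else stop("`membrane` must be a membrane_spec or bilayer_spec",
            call. = FALSE)
}

#' Simulate a Franz-cell permeation experiment
#'
#' Forward-simulates the receiver-concentration time series that a real
#' sampled Franz cell would yield for the given membrane: drug permeates
#' according to the diffusion model, accumulates in the stirred receiver,
#' and at each scheduled time a fixed aliquot is withdrawn for assay and
#' replaced with fresh buffer (diluting the receiver). Multiplicative
#' lognormal assay noise (mean 1, CV = `noise_cv`) is applied per sample;
#' the run is deterministic for a fixed seed.
#'
#' A warning is issued when the receiver concentration exceeds 10% of the
#' donor concentration, because the underlying diffusion models assume a
#' perfect sink.
#'
#' @param cell a [franz_cell_config()].
#' @param membrane a [membrane_spec()] or [bilayer_spec()].
#' @param donor a [donor_condition()] or scalar donor concentration in mM.
#' @return An object of class `franz_samples`: a list with `time_h`,
#'   `conc_mM` (measured receiver concentrations), `conc_true_mM`,
#'   `Q_true` (model cumulative amount per area, mol/cm^2), `cell`,
#'   `donor`, `membrane_label` and `sink_ratio` (max receiver:donor ratio).
#' @export
simulate_experiment <- function(cell, membrane, donor) {
  stopifnot(inherits(cell, "franz_cell_config"))
  donor <- as_donor(donor)
  times_s <- hours_to_s(cell$schedule_h)
  n <- length(times_s)
  Vr <- cell$receiver_volume_mL      # mL == cm^3
  Vs <- cell$sample_volume_mL
  A <- cell$area_cm2

  if (cell$donor_depletion) {
    # quasi-static donor depletion: scale each permeation increment by the
    # current fractional donor concentration
    Q_const <- model_Q(membrane, donor, times_s)
    dQ <- diff(c(0, Q_const))
    Cv_frac <- 1
    Q_true <- numeric(n)
    acc <- 0
    for (i in seq_len(n)) {
      inc <- dQ[i] * Cv_frac
      acc <- acc + inc
      Q_true[i] <- acc
      Cv_frac <- max(0, Cv_frac - inc * A / (donor$Cv * cell$donor_volume_mL))
    }
  } else {
    Q_true <- model_Q(membrane, donor, times_s)
  }

  mass <- 0                          # drug mass in receiver (mol)
  C_true <- numeric(n)
  prevQ <- 0
  for (i in seq_len(n)) {
    mass <- mass + A * (Q_true[i] - prevQ)
    prevQ <- Q_true[i]
    C_true[i] <- mass / Vr
    mass <- mass - C_true[i] * Vs    # aliquot out, buffer in
  }

  if (cell$noise_cv > 0) {
    set.seed(cell$seed)
    C_meas <- if (cell$noise_model == "lognormal") {
      sdlog <- sqrt(log(1 + cell$noise_cv^2))
      C_true * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      pmax(0, C_true + stats::rnorm(n, 0, cell$noise_cv * C_true))
    }
  } else {
    C_meas <- C_true
  }

  sink_ratio <- if (donor$Cv > 0) max(C_true) / donor$Cv else 0
  if (sink_ratio > 0.1)
    warning(sprintf(
      "receiver reached %.1f%% of the donor concentration; sink assumption violated",
      100 * sink_ratio), call. = FALSE)

  structure(list(time_h = cell$schedule_h,
                 conc_mM = mol_cm3_to_mM(C_meas),
                 conc_true_mM = mol_cm3_to_mM(C_true),
                 Q_true = Q_true,
                 cell = cell, donor = donor,
                 membrane_label = class(membrane)[1],
                 sink_ratio = sink_ratio),
            class = "franz_samples")
}

#' @export
print.franz_samples <- function(x, ...) {
  cat(sprintf(
    "<franz_samples> %d samples over %.3g-%.3g h, donor %g mM, max receiver %.4g mM\n",
    length(x$time_h), min(x$time_h), max(x$time_h), x$donor$Cv_mM,
    max(x$conc_mM)))
  invisible(x)
}

#' Reconstruct cumulative permeation from sampled receiver concentrations
#'
#' Inverts the sampling-and-replacement protocol: each withdrawn aliquot
#' removes drug that later samples no longer see, so the cumulative amount
#' permeated per area at the n-th sampling time is
#' \deqn{Q_n = \frac{C_n V_r + V_s \sum_{i<n} C_i}{A}.}
#' This correction is exact for noise-free data.
#'
#' @param samples a `franz_samples` object, or a numeric vector of receiver
#'   concentrations in mM (then `cell`, `times_h` and `donor` must be
#'   given).
#' @param cell a [franz_cell_config()] (taken from `samples` when
#'   available).
#' @param times_h sampling times (h) when `samples` is a bare vector.
#' @param donor donor condition when `samples` is a bare vector.
#' @param label label for the resulting time course.
#' @return A [permeation_timecourse()] (times in s, Q in mol/cm^2).
#' @export
reconstruct_cumulative <- function(samples, cell = NULL, times_h = NULL,
                                   donor = NULL, label = "") {
  if (inherits(samples, "franz_samples")) {
    cell <- samples$cell
    times_h <- samples$time_h
    donor <- samples$donor
    conc_mM <- samples$conc_mM
    if (!nzchar(label)) label <- samples$membrane_label
  } else {
    stopifnot(inherits(cell, "franz_cell_config"),
              is.numeric(samples), !is.null(times_h), !is.null(donor))
    conc_mM <- samples
    donor <- as_donor(donor)
  }
  if (length(conc_mM) != length(times_h))
    stop("samples must align with the sampling schedule", call. = FALSE)
  if (any(conc_mM < 0)) {
    if (cell$clamp_negative) {
      warning("negative receiver concentrations clamped to 0", call. = FALSE)
      conc_mM <- pmax(conc_mM, 0)
    } else {
      stop("negative receiver concentrations", call. = FALSE)
    }
  }
  C <- mM_to_mol_cm3(conc_mM)
  Vr <- cell$receiver_volume_mL
  Vs <- cell$sample_volume_mL
  removed <- c(0, cumsum(C))[seq_along(C)]  # sum over earlier samples
  Q <- (C * Vr + Vs * removed) / cell$area_cm2
  permeation_timecourse(hours_to_s(times_h), pmax(Q, 0), donor,
                        area = cell$area_cm2, label = label)
}

#' Four-compound fixture panel (paraben-like homologous series)
#'
#' Generates a complete synthetic study: four model penetrants of
#' increasing lipophilicity ("MP", "EP", "PP", "BP", echoing the
#' methyl-to-butyl paraben series) permeating three membranes each — a
#' silicone-like homogeneous membrane (L = 68 um), full-thickness skin
#' (two-layer, SC 15 um + VED 500 um) and stripped skin (VED alone).
#' Donor concentrations are 10, 5, 1 and 0.5 mM. Partition coefficients
#' rise monotonically along the series (26-fold for silicone between the
#' first and last compound) while diffusion coefficients vary only 2-3
#' fold, so permeability differences are partition-driven. All parameter
#' values are synthetic: chosen to give silicone permeabilities of order
#' 1e-5 cm/s and a rate-limiting stratum corneum, not taken from any
#' measured dataset.
#'
#' @param seed integer seed for the simulated assays.
#' @param noise_cv assay noise CV for all simulations (default 0).
#' @param schedule_h sampling schedule (h) passed to every cell.
#' @return A list of class `fixture_panel`: `compounds` (data frame of
#'   true parameters), and per-compound entries each holding `silicone`,
#'   `full`, `stripped` (`franz_samples`), the matching specs and the
#'   donor.
#' @export
make_fixture_panel <- function(seed = 1L, noise_cv = 0,
                               schedule_h = exp(seq(log(0.25), log(8),
                                                    length.out = 8))) {
  compounds <- data.frame(
    compound = c("MP", "EP", "PP", "BP"),
    donor_mM = c(10, 5, 1, 0.5),
    K_sil = c(0.8, 2, 5.5, 20.8),
    D_sil = c(3.5e-8, 3.0e-8, 2.5e-8, 1.4e-8),
    K_sc = c(2, 5, 12, 40),
    D_sc = c(5e-10, 4e-10, 3e-10, 2e-10),
    K_ved = c(0.8, 1.0, 1.4, 2.0),
    D_ved = c(1.2e-7, 1.0e-7, 9e-8, 8e-8),
    stringsAsFactors = FALSE)
  L_sil <- 68e-4; L_sc <- 15e-4; L_ved <- 500e-4

  out <- list(compounds = compounds, L_sil = L_sil, L_sc = L_sc,
              L_ved = L_ved, seed = as.integer(seed), noise_cv = noise_cv)
  for (i in seq_len(nrow(compounds))) {
    p <- compounds[i, ]
    donor <- donor_condition(p$donor_mM)
    sil <- membrane_spec(L = L_sil, K = p$K_sil, D = p$D_sil)
    skin <- bilayer_spec(L_sc = L_sc, L_ved = L_ved, K_sc = p$K_sc,
                         D_sc = p$D_sc, K_ved = p$K_ved, D_ved = p$D_ved)
    ved <- membrane_spec(L = L_ved, K = p$K_ved, D = p$D_ved)
    cells <- lapply(0:2, function(k)
      franz_cell_config(schedule_h = schedule_h, noise_cv = noise_cv,
                        seed = seed + 10L * i + k))
    out[[p$compound]] <- list(
      donor = donor,
      silicone_spec = sil, skin_spec = skin, ved_spec = ved,
      silicone = simulate_experiment(cells[[1]], sil, donor),
      full = simulate_experiment(cells[[2]], skin, donor),
      stripped = simulate_experiment(cells[[3]], ved, donor))
  }
  class(out) <- "fixture_panel"
  out
}

#' @export
print.fixture_panel <- function(x, ...) {
  cat(sprintf(
    "<fixture_panel> %d compounds x 3 membranes, seed %d, noise CV %g\n",
    nrow(x$compounds), x$seed, x$noise_cv))
  print(x$compounds)
  invisible(x)
}
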