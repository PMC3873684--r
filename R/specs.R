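#' Homogeneous membrane specification
#'
#' Describes a single homogeneous membrane (e.g. a silicone sheet, or skin
#' treated as one layer) by its thickness `L`, the vehicle-to-membrane
#' partition coefficient `K` and the Fickian diffusion coefficient `D`.
#' The derived permeability coefficient is `P = K * D / L`.
#'
#' @param L membrane thickness (cm). Must be > 0.
#' @param K dimensionless partition coefficient (vehicle to membrane),
#'   >= 0. `K = 0` is permitted and yields identically zero concentration
#'   and flux, which keeps limiting cases well defined.
#' @param D diffusion coefficient (cm^2/s). Must be > 0.
#' @return An object of class `membrane_spec` with fields `L`, `K`, `D`.
#' @examples
#' sil <- membrane_spec(L = 68e-4, K = 2, D = 1e-6)
#' permeability(sil)
#' @export
membrane_spec <- function(L, K, D) {
  stopifnot_scalar(L, "L")
  stopifnot_scalar(K, "K", positive = FALSE, nonneg = TRUE)
  stopifnot_scalar(D, "D")
  structure(list(L = L, K = K, D = D), class = "membrane_spec")
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat(sprintf(
    "<membrane_spec> L = %g cm (%.1f um), K = %g, D = %g cm^2/s, P = %g cm/s\n",
    x$L, x$L * 1e4, x$K, x$D, permeability(x)))
  invisible(x)
}

#' Two-layer (stratum corneum + viable epidermis/dermis) skin specification
#'
#' Describes skin as two stacked homogeneous layers: the stratum corneum
#' (SC, outermost and usually rate-limiting) and the viable epidermis plus
#' dermis (VED) beneath it. Each layer has its own thickness, partition
#' coefficient (both referenced to the vehicle) and diffusion coefficient.
#' Layer permeabilities are `P_i = K_i * D_i / L_i`; layer resistances
#' `R_i = 1 / P_i` add in series.
#'
#' @param L_sc,L_ved layer thicknesses (cm), > 0. Stratum corneum thickness
#'   defaults to 15 um; the VED thickness default of 500 um is a modelling
#'   choice (see the vignette) and should be set from histology when known.
#' @param K_sc,K_ved vehicle-to-layer partition coefficients, >= 0.
#' @param D_sc,D_ved layer diffusion coefficients (cm^2/s), > 0.
#' @return An object of class `bilayer_spec` with the six fields plus
#'   derived `P_sc`, `P_ved`, `R_sc`, `R_ved`, `L_tot`.
#' @examples
#' skin <- bilayer_spec(K_sc = 50, D_sc = 1e-9, K_ved = 2, D_ved = 1e-7)
#' total_permeability(skin)
#' @export
bilayer_spec <- function(L_sc = 15e-4, L_ved = 500e-4, K_sc, D_sc, K_ved, D_ved) {
  stopifnot_scalar(L_sc, "L_sc")
  stopifnot_scalar(L_ved, "L_ved")
  stopifnot_scalar(K_sc, "K_sc", positive = FALSE, nonneg = TRUE)
  stopifnot_scalar(K_ved, "K_ved", positive = FALSE, nonneg = TRUE)
  stopifnot_scalar(D_sc, "D_sc")
  stopifnot_scalar(D_ved, "D_ved")
  P_sc <- K_sc * D_sc / L_sc
  P_ved <- K_ved * D_ved / L_ved
  structure(list(
    L_sc = L_sc, L_ved = L_ved, K_sc = K_sc, K_ved = K_ved,
    D_sc = D_sc, D_ved = D_ved,
    P_sc = P_sc, P_ved = P_ved,
    R_sc = if (P_sc > 0) 1 / P_sc else Inf,
    R_ved = if (P_ved > 0) 1 / P_ved else Inf,
    L_tot = L_sc + L_ved), class = "bilayer_spec")
}

#' @export
print.bilayer_spec <- function(x, ...) {
  cat(sprintf("<bilayer_spec> SC: L = %.1f um, K = %g, D = %g cm^2/s (P = %g cm/s)\n",
              x$L_sc * 1e4, x$K_sc, x$D_sc, x$P_sc))
  cat(sprintf("               VED: L = %.1f um, K = %g, D = %g cm^2/s (P = %g cm/s)\n",
              x$L_ved * 1e4, x$K_ved, x$D_ved, x$P_ved))
  cat(sprintf("               P_tot = %g cm/s\n", total_permeability(x)))
  invisible(x)
}

#' Donor (vehicle) condition
#'
#' The applied-phase drug concentration driving permeation. The analytical
#' solutions assume the donor is an infinite reservoir, so `C_v` is constant
#' in time; finite-donor depletion can only be switched on in the virtual
#' Franz-cell experiment (see [franz_cell_config()]), never in the
#' closed-form models.
#'
#' @param Cv_mM donor concentration in mM (1 mM = 1e-6 mol/cm^3), >= 0.
#' @return An object of class `donor_condition` with `Cv` (mol/cm^3) and
#'   `Cv_mM`.
#' @examples
#' donor_condition(10) # 10 mM, the methyl paraben donor level
#' @export
donor_condition <- function(Cv_mM) {
  stopifnot_scalar(Cv_mM, "Cv_mM", positive = FALSE, nonneg = TRUE)
  structure(list(Cv = mM_to_mol_cm3(Cv_mM), Cv_mM = Cv_mM),
            class = "donor_condition")
}

#' @export
print.donor_condition <- function(x, ...) {
  cat(sprintf("<donor_condition> C_v = %g mM (%g mol/cm^3), constant donor\n",
              x$Cv_mM, x$Cv))
  invisible(x)
}

# coerce a numeric (mM) or donor_condition to donor_condition
as_donor <- function(donor) {
  if (inherits(donor, "donor_condition")) return(donor)
  if (is.numeric(donor) && length(donor) == 1L) return(donor_condition(donor))
  stop("`donor` must be a donor_condition or a scalar concentration in mM",
       call. = FALSE)
}
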