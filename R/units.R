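#' Unit conversion helpers
#'
#' All internal computation uses cm, s and mol/cm^3. User-facing interfaces
#' (file formats, the Franz-cell simulator, the CLI) speak hours, mM and
#' nmol/cm^2 and convert at the boundary.
#'
#' Conversions: 1 mM = 1e-6 mol/cm^3; 1 h = 3600 s; 1 um = 1e-4 cm;
#' 1 nmol/cm^2 = 1e-9 mol/cm^2.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
mM_to_mol_cm3 <- function(x) x * 1e-6

#' @rdname units
#' @export
mol_cm3_to_mM <- function(x) x * 1e6

#' @rdname units
#' @export
hours_to_s <- function(x) x * 3600

#' @rdname units
#' @export
s_to_hours <- function(x) x / 3600

#' @rdname units
#' @export
um_to_cm <- function(x) x * 1e-4

#' @rdname units
#' @export
nmol_cm2_to_mol_cm2 <- function(x) x * 1e-9

#' @rdname units
#' @export
mol_cm2_to_nmol_cm2 <- function(x) x * 1e9

# internal scalar checks
stopifnot_scalar <- function(x, name, positive = TRUE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}
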