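#' Theoretical steady-state membrane or skin concentration from a fit
#'
#' Converts fitted permeation parameters into the predicted steady-state
#' mean concentration in the membrane. For the one-layer model this is
#' `K * C_v / 2` — it depends on the partition coefficient alone, which is
#' why a permeation experiment suffices to predict the membrane load. For
#' the two-layer model it is the thickness-weighted average of the
#' piecewise-linear steady-state profile ([ss_mean_conc_twolayer()]).
#'
#' @param fit a `fit_result` from [fit_onelayer()] or [fit_twolayer()].
#' @param donor a [donor_condition()] or scalar donor concentration (mM);
#'   defaults to the donor stored in the fit.
#' @return A list with `conc` (mol/cm^3) and `normalized`
#'   (`conc / C_v`, the dimensionless quantity used for cross-membrane
#'   comparison and calibration).
#' @export
theoretical_conc <- function(fit, donor = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  donor <- if (is.null(donor)) fit$donor else as_donor(donor)
  if (fit$model == "one-layer") {
    if (is.null(fit$params$K))
      stop("fit result lacks a partition coefficient", call. = FALSE)
    conc <- fit$params$K * donor$Cv / 2
  } else if (fit$model == "two-layer") {
    need <- c("K_sc", "D_sc", "K_ved", "D_ved")
    if (!all(need %in% names(fit$params)))
      stop("fit result lacks two-layer parameters", call. = FALSE)
    bl <- bilayer_spec(L_sc = fit$L_sc, L_ved = fit$L_ved,
                       K_sc = fit$params$K_sc, D_sc = fit$params$D_sc,
                       K_ved = fit$params$K_ved, D_ved = fit$params$D_ved)
    conc <- ss_mean_conc_twolayer(bl, donor)
  } else {
    stop("unknown model family in fit result", call. = FALSE)
  }
  list(conc = conc,
       normalized = if (donor$Cv > 0) conc / donor$Cv else 0)
}

#' Linear calibration between predicted and observed normalized
#' concentrations
#'
#' Ordinary least-squares line (with intercept by default) through pairs of
#' normalized concentrations — typically the theoretical steady-state
#' silicone-membrane concentration on the x-axis and the observed skin
#' concentration on the y-axis, both divided by the donor concentration.
#' Once established for a compound series, the line converts cheap
#' artificial-membrane predictions into skin-concentration estimates.
#'
#' @param predicted numeric vector of predicted normalized concentrations
#'   (x), or a 2-column data frame/matrix of (predicted, observed).
#' @param observed numeric vector of observed normalized concentrations
#'   (y); omit when `predicted` is 2-column.
#' @param through_origin force the intercept to zero (for series that show
#'   a 1:1-type proportionality).
#' @return An object of class `calibration_line` with `slope`, `intercept`,
#'   `r` (Pearson correlation of x and y), `n`, and the underlying `lm`
#'   fit.
#' @export
calibrate <- function(predicted, observed = NULL, through_origin = FALSE) {
  if (is.null(observed)) {
    m <- as.matrix(predicted)
    if (ncol(m) != 2L) stop("need a 2-column (predicted, observed) input",
                            call. = FALSE)
    predicted <- m[, 1]; observed <- m[, 2]
  }
  if (length(predicted) != length(observed) || length(predicted) < 2L)
    stop("need at least 2 (predicted, observed) pairs", call. = FALSE)
  if (length(unique(predicted)) < 2L || stats::var(predicted) == 0)
    stop("degenerate input: predicted values have no variance",
         call. = FALSE)
  df <- data.frame(x = predicted, y = observed)
  fit <- if (through_origin) stats::lm(y ~ x + 0, data = df)
         else stats::lm(y ~ x, data = df)
  cf <- stats::coef(fit)
  structure(list(
    slope = if (through_origin) cf[["x"]] else cf[["x"]],
    intercept = if (through_origin) 0 else cf[["(Intercept)"]],
    r = stats::cor(df$x, df$y),
    n = nrow(df),
    through_origin = through_origin,
    lm = fit), class = "calibration_line")
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf(
    "<calibration_line> y = %.6g x %s %.6g, r = %.4f (n = %d%s)\n",
    x$slope, if (x$intercept >= 0) "+" else "-", abs(x$intercept), x$r,
    x$n, if (x$through_origin) ", through origin" else ""))
  invisible(x)
}

#' Predict the skin concentration from an artificial-membrane prediction
#'
#' Applies a fitted [calibrate()] line to a normalized
#' artificial-membrane (silicone) prediction and rescales by the donor
#' concentration: `C_skin = (slope * x + intercept) * C_v`.
#'
#' @param cal a `calibration_line`.
#' @param silicone_pred_norm normalized predicted concentration(s)
#'   (dimensionless, `conc / C_v`).
#' @param donor a [donor_condition()] or scalar donor concentration (mM).
#' @return Predicted skin concentration(s) in mol/cm^3.
#' @export
predict_skin_conc <- function(cal, silicone_pred_norm, donor) {
  stopifnot(inherits(cal, "calibration_line"))
  donor <- as_donor(donor)
  (cal$slope * silicone_pred_norm + cal$intercept) * donor$Cv
}
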