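#' Write a permeation time course to a delimited text file
#'
#' Deterministic CSV with metadata comment lines (`# key: value`) followed
#' by a header `time_h,cumulative_amount_nmol_per_cm2`. Times are written
#' in hours and amounts in nmol/cm^2 (the figure-friendly units); values
#' carry full double precision so a write/read round trip is lossless.
#' Two writes of the same time course are byte-identical.
#'
#' @param tc a [permeation_timecourse()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "permeation_timecourse"))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop(sprintf("cannot write '%s': %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  on.exit(close(con))
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  writeLines(c(
    sprintf("# donor_mM: %s", fmt(tc$donor$Cv_mM)),
    sprintf("# area_cm2: %s", fmt(tc$area)),
    sprintf("# membrane: %s", tc$label),
    "time_h,cumulative_amount_nmol_per_cm2",
    paste(fmt(s_to_hours(tc$times)),
          fmt(mol_cm2_to_nmol_cm2(tc$Q)), sep = ",")), con)
  invisible(path)
}

#' Read a permeation time course from a delimited text file
#'
#' Parses the format written by [write_timecourse()] and validates it:
#' metadata lines must declare the donor concentration, the header must
#' name both unit-bearing columns, and times must be strictly increasing.
#' Errors name the offending line.
#'
#' @param path input file path.
#' @return A [permeation_timecourse()] in internal units (s, mol/cm^2).
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L)
    stop(sprintf("'%s' is empty", path), call. = FALSE)
  meta_idx <- grep("^#", lines)
  meta <- list()
  for (i in meta_idx) {
    m <- regmatches(lines[i], regexec("^#\\s*([^:]+):\\s*(.*)$", lines[i]))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L)
    stop(sprintf("'%s' has no data rows", path), call. = FALSE)
  header <- strsplit(body[1], ",")[[1]]
  need <- c("time_h", "cumulative_amount_nmol_per_cm2")
  if (!all(need %in% header))
    stop(sprintf(
      "line 1 of data in '%s': header must contain %s (unit-bearing names required)",
      path, paste(need, collapse = ", ")), call. = FALSE)
  if (is.null(meta$donor_mM))
    stop(sprintf("'%s': missing '# donor_mM:' metadata line", path),
         call. = FALSE)
  df <- utils::read.csv(text = body, check.names = FALSE)
  t_h <- df[["time_h"]]
  q_n <- df[["cumulative_amount_nmol_per_cm2"]]
  if (any(!is.finite(t_h)) || any(!is.finite(q_n)))
    stop(sprintf("'%s': non-numeric values in data rows", path),
         call. = FALSE)
  bad <- which(diff(t_h) <= 0)
  if (length(bad) > 0L) {
    body_pos <- setdiff(seq_along(lines), meta_idx)
    body_pos <- body_pos[nzchar(trimws(lines[body_pos]))]
    stop(sprintf("'%s': time not strictly increasing at line %d",
                 path, body_pos[bad[1] + 2L]), call. = FALSE)
  }
  area <- if (!is.null(meta$area_cm2)) suppressWarnings(as.numeric(meta$area_cm2))
          else NA_real_
  permeation_timecourse(hours_to_s(t_h), nmol_cm2_to_mol_cm2(q_n),
                        donor = as.numeric(meta$donor_mM), area = area,
                        label = if (!is.null(meta$membrane)) meta$membrane
                                else "")
}

#' Write/read receiver-concentration samples
#'
#' Raw simulator output: receiver concentration (mM) versus sampling time,
#' with the cell geometry in the metadata header so that
#' [reconstruct_cumulative()] can be applied after reading.
#'
#' @param samples a `franz_samples` object from [simulate_experiment()].
#' @param path file path.
#' @return `write_samples`: `path` invisibly. `read_samples`: a
#'   `franz_samples`-compatible list.
#' @export
write_samples <- function(samples, path) {
  stopifnot(inherits(samples, "franz_samples"))
  con <- file(path, "w"); on.exit(close(con))
  fmt <- function(x) formatC(x, digits = 9, format = "g")
  cell <- samples$cell
  writeLines(c(
    sprintf("# donor_mM: %s", fmt(samples$donor$Cv_mM)),
    sprintf("# area_cm2: %s", fmt(cell$area_cm2)),
    sprintf("# receiver_volume_mL: %s", fmt(cell$receiver_volume_mL)),
    sprintf("# sample_volume_mL: %s", fmt(cell$sample_volume_mL)),
    sprintf("# membrane: %s", samples$membrane_label),
    "time_h,receiver_conc_mM",
    paste(fmt(samples$time_h), fmt(samples$conc_mM), sep = ",")), con)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta_idx <- grep("^#", lines)
  meta <- list()
  for (i in meta_idx) {
    m <- regmatches(lines[i], regexec("^#\\s*([^:]+):\\s*(.*)$", lines[i]))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L)
    stop(sprintf("'%s' has no data rows", path), call. = FALSE)
  if (!all(c("time_h", "receiver_conc_mM") %in% strsplit(body[1], ",")[[1]]))
    stop(sprintf("'%s': header must contain time_h, receiver_conc_mM", path),
         call. = FALSE)
  for (k in c("donor_mM", "receiver_volume_mL", "sample_volume_mL",
              "area_cm2"))
    if (is.null(meta[[k]]))
      stop(sprintf("'%s': missing '# %s:' metadata line", path, k),
           call. = FALSE)
  df <- utils::read.csv(text = body, check.names = FALSE)
  cell <- franz_cell_config(
    receiver_volume_mL = as.numeric(meta$receiver_volume_mL),
    sample_volume_mL = as.numeric(meta$sample_volume_mL),
    area_cm2 = as.numeric(meta$area_cm2),
    schedule_h = df$time_h)
  donor <- donor_condition(as.numeric(meta$donor_mM))
  structure(list(time_h = df$time_h, conc_mM = df$receiver_conc_mM,
                 conc_true_mM = df$receiver_conc_mM, Q_true = NULL,
                 cell = cell, donor = donor,
                 membrane_label = if (!is.null(meta$membrane)) meta$membrane
                                  else "unnamed",
                 sink_ratio = NA_real_),
            class = "franz_samples")
}

#' Read and write calibration pairs
#'
#' Two-column delimited text (`predicted_norm,observed_norm`) holding the
#' normalized concentration pairs consumed by [calibrate()].
#'
#' @param pairs data frame or matrix with columns predicted/observed.
#' @param path file path.
#' @return `read_calibration_pairs`: a 2-column data frame.
#' @export
write_calibration_pairs <- function(pairs, path) {
  m <- as.matrix(pairs)
  stopifnot(ncol(m) == 2L)
  con <- file(path, "w"); on.exit(close(con))
  fmt <- function(x) formatC(x, digits = 9, format = "g")
  writeLines(c("predicted_norm,observed_norm",
               paste(fmt(m[, 1]), fmt(m[, 2]), sep = ",")), con)
  invisible(path)
}

#' @rdname write_calibration_pairs
#' @export
read_calibration_pairs <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("predicted_norm", "observed_norm") %in% names(df)))
    stop(sprintf("'%s': need columns predicted_norm, observed_norm", path),
         call. = FALSE)
  df[, c("predicted_norm", "observed_norm")]
}

#' Read a run configuration file
#'
#' YAML configuration driving the command-line interface: membrane
#' geometry, donor concentration, Franz-cell settings, fitting options and
#' seeds. Unknown keys are rejected so typos surface early. All fields
#' have documented defaults (see the examples in the package vignette).
#'
#' @param path YAML file path.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known <- c("model", "thickness_um", "L_sc_um", "L_ved_um", "K", "D",
             "K_sc", "D_sc", "K_ved", "D_ved", "donor_mM",
             "receiver_volume_mL", "sample_volume_mL", "area_cm2",
             "schedule_h", "noise_cv", "noise_model", "seed", "n_starts",
             "output_dir", "label")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0L)
    stop(sprintf("unknown config keys: %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  defaults <- list(model = "one-layer", thickness_um = 68, L_sc_um = 15,
                   L_ved_um = 500, donor_mM = 10, receiver_volume_mL = 6.0,
                   sample_volume_mL = 0.4, area_cm2 = 1.77,
                   schedule_h = exp(seq(log(0.25), log(8), length.out = 8)),
                   noise_cv = 0, noise_model = "lognormal", seed = 1L,
                   n_starts = 8L, output_dir = ".", label = "run")
  cfg <- utils::modifyList(defaults, cfg)
  if (!cfg$model %in% c("one-layer", "two-layer"))
    stop("config: model must be 'one-layer' or 'two-layer'", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Serialise a fit result to flat key=value text (with a JSON twin)
#'
#' @param fit a `fit_result`.
#' @param path output path for the key=value report; when `json = TRUE` a
#'   sibling `<path>.json` is written too.
#' @param json also write machine-readable JSON (default TRUE).
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, json = TRUE) {
  stopifnot(inherits(fit, "fit_result"))
  kv <- c(model = fit$model,
          vapply(fit$params, function(v) formatC(v, digits = 9, format = "g"),
                 character(1)),
          ssr = formatC(fit$ssr, digits = 9, format = "g"),
          n_iter = as.character(fit$n_iter),
          converged = tolower(as.character(fit$converged)),
          seed = as.character(fit$seed),
          donor_mM = formatC(fit$donor$Cv_mM, digits = 9, format = "g"))
  writeLines(paste(names(kv), kv, sep = "="), path)
  if (json) {
    j <- c(list(model = fit$model), fit$params,
           list(ssr = fit$ssr, n_iter = fit$n_iter,
                converged = fit$converged, seed = fit$seed,
                donor_mM = fit$donor$Cv_mM))
    jsonlite::write_json(j, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
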