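PARAM_NAMES <- c("LpS_V_N", "LpS_V_T", "sigma_N", "sigma_T", "f_N", "f_T",
                 "K_N", "K_T", "P_v", "kd_N", "kd_T", "D")

STEPPED_PARAMS <- c("LpS_V", "sigma", "f", "K", "kd")

#' Tissue and particle parameters of the transport model
#'
#' All coefficients of the liposome transport PDE and of the interstitial
#' pressure equation. Every parameter except the microvascular pressure `P_v`
#' and the diffusivity `D` is a step function with one value in normal tissue
#' (`_N`) and one in tumour tissue (`_T`).
#'
#' @param LpS_V_N,LpS_V_T transvascular fluid exchange rate, 1/(mmHg*s).
#' @param sigma_N,sigma_T reflection coefficient, dimensionless in `[0, 1]`.
#' @param f_N,f_T retardation coefficient, dimensionless in `[0, 1]`.
#' @param K_N,K_T interstitial hydraulic conductivity, cm^2/(mmHg*s).
#' @param P_v microvascular fluid pressure, mmHg (> 0); spatially and
#'   temporally constant, and an upper bound for the interstitial pressure.
#' @param kd_N,kd_T elimination rate, 1/s.
#' @param D liposome diffusivity, cm^2/s; `D = 0` disables the diffusion term.
#' @return an object of class `tissue_params` (a validated named list).
#' @seealso [mouse_parameters()], [baseline_parameters()]
#' @export
tissue_parameters <- function(LpS_V_N, LpS_V_T, sigma_N, sigma_T, f_N, f_T,
                              K_N, K_T, P_v, kd_N, kd_T, D = 0) {
  p <- mget(PARAM_NAMES)
  p <- lapply(p, as.numeric)
  if (any(!vapply(p, is.finite, logical(1)))) stop("parameters must be finite")
  nonneg <- c("LpS_V_N", "LpS_V_T", "K_N", "K_T", "kd_N", "kd_T", "D")
  if (any(unlist(p[nonneg]) < 0)) stop("rates and conductivities must be >= 0")
  unit <- c("sigma_N", "sigma_T", "f_N", "f_T")
  if (any(unlist(p[unit]) < 0 | unlist(p[unit]) > 1))
    stop("sigma and f must lie in [0, 1]")
  if (p$P_v <= 0) stop("P_v must be positive")
  structure(p, class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat("<tissue_params>\n")
  for (nm in PARAM_NAMES) cat(sprintf("  %-8s %.4g\n", nm, x[[nm]]))
  invisible(x)
}

#' Parameter values used for the mouse tumours
#'
#' Step-function values estimated for the xenograft dataset (the diffusion
#' term is not used in that protocol, so `D = 0`).
#'
#' @return a [tissue_parameters()] object.
#' @export
mouse_parameters <- function() {
  tissue_parameters(
    LpS_V_N = 2.52e-6, LpS_V_T = 2.6e-6,
    sigma_N = 1.0, sigma_T = 0.2,
    f_N = 1.0, f_T = 0.5,
    K_N = 8.53e-8, K_T = 4.13e-8,
    P_v = 25,
    kd_N = 1.65e-6, kd_T = 5.10e-6,
    D = 0)
}

#' Baseline parameters of the synthetic sensitivity study
#'
#' Tumour-tissue values of the sensitivity baseline (which differ from the
#' mouse set for `K_T` and `sigma_T` and include a nonzero diffusivity);
#' normal-tissue values are shared with [mouse_parameters()].
#'
#' @return a [tissue_parameters()] object.
#' @export
baseline_parameters <- function() {
  tissue_parameters(
    LpS_V_N = 2.52e-6, LpS_V_T = 2.6e-6,
    sigma_N = 1.0, sigma_T = 0.19,
    f_N = 1.0, f_T = 0.5,
    K_N = 8.53e-8, K_T = 4.13e-9,
    P_v = 25,
    kd_N = 1.65e-6, kd_T = 5.1e-6,
    D = 7.5e-7)
}

#' Sensitivity-study parameter ranges
#'
#' The swept quantities of the synthetic sensitivity analysis: each row gives
#' the baseline value and the minimum/maximum of the explored range. `noise`
#' is the relative voxelwise measurement-noise level; the remaining rows are
#' tumour-tissue transport parameters.
#'
#' @return a data.frame with columns `param`, `baseline`, `min`, `max`.
#' @export
sensitivity_table <- function() {
  data.frame(
    param    = c("D",    "f_T", "K_T",    "LpS_V_T", "noise", "P_v", "sigma_T", "kd_T"),
    baseline = c(7.5e-7, 0.5,   4.13e-9,  2.6e-6,    0.025,   25,    0.19,      5.1e-6),
    min      = c(0,      0.4,   1.0e-9,   1.0e-7,    0,       5,     0,         1.0e-7),
    max      = c(7.5e-6, 0.6,   1.0e-6,   1.0e-4,    0.05,    50,    0.5,       1.0e-5),
    stringsAsFactors = FALSE)
}

#' Voxel field of a stepped parameter
#'
#' Expands one of the two-valued tissue parameters to a per-voxel field: the
#' tumour value on the mask, the normal value elsewhere.
#'
#' @param name one of `"LpS_V"`, `"sigma"`, `"f"`, `"K"`, `"kd"`.
#' @param params a [tissue_parameters()] object.
#' @param geom a [tumour_geometry()].
#' @return a numeric vector with one value per voxel.
#' @export
piecewise_param <- function(name, params, geom) {
  stopifnot(inherits(params, "tissue_params"), inherits(geom, "tumour_geometry"))
  if (!name %in% STEPPED_PARAMS)
    stop(sprintf("unknown stepped parameter '%s' (one of: %s)", name,
                 paste(STEPPED_PARAMS, collapse = ", ")))
  ifelse(geom$mask, params[[paste0(name, "_T")]], params[[paste0(name, "_N")]])
}

#' Read / write a parameter file
#'
#' Flat YAML or JSON with keys named exactly as the fields of
#' [tissue_parameters()] (units as documented there). The format is chosen
#' from the file extension.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return for `read_parameters`, a [tissue_parameters()] object.
#' @export
read_parameters <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  missing <- setdiff(setdiff(PARAM_NAMES, "D"), names(vals))
  if (length(missing))
    stop("parameter file is missing: ", paste(missing, collapse = ", "))
  do.call(tissue_parameters, as.list(vals[intersect(PARAM_NAMES, names(vals))]))
}

#' @rdname read_parameters
#' @param params a [tissue_parameters()] object.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "tissue_params"))
  vals <- unclass(params)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(vals, path)
  } else {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
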