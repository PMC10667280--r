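#' Nondimensionalization scheme
#'
#' Scales used throughout training and the scaled operators: time by
#' `1 / (P_v * mu_T)`, length by `sqrt(eta_T / mu_T)`, pressure by `P_v`.
#' `mu_T` is the tumour transvascular exchange rate (1/(mmHg*s)) and `eta_T`
#' the tumour interstitial hydraulic conductivity (cm^2/(mmHg*s)), so the
#' scaled tumour pressure-screening length is exactly 1.
#'
#' @param params a [tissue_parameters()] object, or `NULL` when supplying the
#'   scales directly.
#' @param mu_T,eta_T,P_v explicit scales (all positive); defaults are taken
#'   from `params` as `LpS_V_T`, `K_T` and `P_v`.
#' @return an object of class `scaling_scheme`.
#' @export
scaling_scheme <- function(params = NULL, mu_T = params$LpS_V_T,
                           eta_T = params$K_T, P_v = params$P_v) {
  s <- list(mu_T = as.numeric(mu_T), eta_T = as.numeric(eta_T), P_v = as.numeric(P_v))
  if (any(!vapply(s, function(v) is.finite(v) && v > 0, logical(1))))
    stop("all scaling factors must be positive and finite")
  structure(s, class = "scaling_scheme")
}

#' Scale physical quantities to dimensionless form (and back)
#'
#' `t~ = t * P_v * mu_T`, `x~ = x * sqrt(mu_T / eta_T)`, `P~ = P / P_v`.
#' `redimensionalize_*` are the exact inverses.
#'
#' @param t time, s. @param x length, cm. @param P pressure, mmHg.
#' @param s a [scaling_scheme()].
#' @return the scaled (or unscaled) quantity.
#' @name nondimensionalize
#' @export
nondim_time <- function(t, s) t * s$P_v * s$mu_T

#' @rdname nondimensionalize
#' @export
redim_time <- function(t, s) t / (s$P_v * s$mu_T)

#' @rdname nondimensionalize
#' @export
nondim_length <- function(x, s) x * sqrt(s$mu_T / s$eta_T)

#' @rdname nondimensionalize
#' @export
redim_length <- function(x, s) x / sqrt(s$mu_T / s$eta_T)

#' @rdname nondimensionalize
#' @export
nondim_pressure <- function(P, s) P / s$P_v

#' @rdname nondimensionalize
#' @export
redim_pressure <- function(P, s) P * s$P_v

#' Dimensionless transport parameters
#'
#' Transforms a parameter set so the transport PDE is form-invariant in the
#' scaled variables: `lambda = (LpS/V) / mu_T`, `kappa = f K / eta_T`,
#' `kd~ = kd / (P_v mu_T)`, `D~ = D / (eta_T P_v)`; the scaled microvascular
#' pressure is 1.
#'
#' @param params a [tissue_parameters()] object.
#' @param s a [scaling_scheme()].
#' @return a named list of dimensionless parameters (class
#'   `nondim_params`).
#' @export
nondimensionalize_params <- function(params, s) {
  stopifnot(inherits(params, "tissue_params"), inherits(s, "scaling_scheme"))
  structure(list(
    lambda_N = params$LpS_V_N / s$mu_T,
    lambda_T = params$LpS_V_T / s$mu_T,
    sigma_N = params$sigma_N, sigma_T = params$sigma_T,
    kappa_N = params$f_N * params$K_N / s$eta_T,
    kappa_T = params$f_T * params$K_T / s$eta_T,
    kd_N = params$kd_N / (s$P_v * s$mu_T),
    kd_T = params$kd_T / (s$P_v * s$mu_T),
    D = params$D / (s$eta_T * s$P_v),
    P_v = 1), class = "nondim_params")
}

# scale a grid's spacing/origin to dimensionless length units
nondim_grid <- function(grid, s) {
  g <- grid
  fac <- sqrt(s$mu_T / s$eta_T)
  g$spacing <- grid$spacing * fac
  g$origin <- grid$origin * fac
  g
}
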