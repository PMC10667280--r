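#' Exponential plasma pharmacokinetic model
#'
#' `C_p(t) = a exp(-b t)`: a single-compartment clearance of the circulating
#' liposome pool.
#'
#' @param a initial plasma concentration, mgI/cm^3 (>= 0).
#' @param b clearance rate, 1/s (>= 0); alternatively give `half_life_h`.
#' @param half_life_h plasma half-life in hours (used when `b` is missing).
#' @return an object of class `plasma_model`.
#' @export
plasma_model <- function(a, b = NULL, half_life_h = NULL) {
  if (is.null(b)) {
    if (is.null(half_life_h)) stop("give either b or half_life_h")
    b <- log(2) / (half_life_h * 3600)
  }
  if (a < 0 || b < 0) stop("a and b must be non-negative")
  structure(list(a = as.numeric(a), b = as.numeric(b)), class = "plasma_model")
}

#' @export
print.plasma_model <- function(x, ...) {
  hl <- if (x$b > 0) sprintf("%.3g h", log(2) / x$b / 3600) else "Inf"
  cat(sprintf("<plasma_model> C_p(t) = %.4g * exp(-%.4g t), half-life %s\n",
              x$a, x$b, hl))
  invisible(x)
}

#' Plasma concentration at given times
#'
#' @param plasma a [plasma_model()].
#' @param t times, seconds.
#' @return concentrations, mgI/cm^3.
#' @export
plasma_concentration <- function(plasma, t) {
  stopifnot(inherits(plasma, "plasma_model"))
  plasma$a * exp(-plasma$b * t)
}

#' Forward transport solve (Crank-Nicolson)
#'
#' Advances the semi-discrete transport system `dC/dt = g(C, t)` with the
#' trapezoidal (Crank-Nicolson) rule on the voxel lattice, with zero-flux
#' boundary faces. The plasma source is evaluated at the half-step. The linear
#' operator is time-independent, so one sparse factorization is reused across
#' equidistant steps.
#'
#' @param P interstitial pressure (mmHg vector or [pressure_field()]).
#' @param params a [tissue_parameters()] object.
#' @param plasma a [plasma_model()].
#' @param geom a [tumour_geometry()].
#' @param t_grid strictly increasing output times, seconds (first entry is the
#'   initial time).
#' @param C0 initial concentration per voxel, mgI/cm^3 (default 0 everywhere:
#'   imaging starts immediately before administration).
#' @return a [concentration_field()] sampled at `t_grid`.
#' @export
solve_transport <- function(P, params, plasma, geom, t_grid, C0 = 0) {
  stopifnot(inherits(geom, "tumour_geometry"), inherits(plasma, "plasma_model"))
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) < 2L || any(diff(t_grid) <= 0))
    stop("t_grid must contain at least two strictly increasing times")
  n <- n_voxels(geom$grid)
  C <- rep_len(as.numeric(C0), n)
  co <- transport_coefficients(P, params, geom)
  A <- assemble_transport_operator(co$P, grid_faces(geom$grid), co$kappa,
                                   co$kd, co$D, n)
  I <- Matrix::Diagonal(n)
  values <- matrix(NA_real_, n, length(t_grid))
  values[, 1] <- C
  dts <- diff(t_grid)
  M_lhs <- NULL
  dt_cur <- NA_real_
  for (j in seq_along(dts)) {
    dt <- dts[j]
    if (is.null(M_lhs) || abs(dt - dt_cur) > 1e-12 * dt) {
      M_lhs <- I - (dt / 2) * A
      M_rhs <- I + (dt / 2) * A
      dt_cur <- dt
    }
    cp_mid <- plasma_concentration(plasma, t_grid[j] + dt / 2)
    rhs <- M_rhs %*% C + dt * co$src * cp_mid
    C <- as.numeric(Matrix::solve(M_lhs, rhs))
    if (any(!is.finite(C)))
      stop(sprintf("transport solve produced non-finite values at step %d (t = %.4g s)",
                   j, t_grid[j + 1]))
    values[, j + 1] <- C
  }
  concentration_field(geom$grid, t_grid, values)
}

#' Voxelwise proportional measurement noise
#'
#' Multiplies each voxel by `1 + eps` with `eps ~ N(0, level^2)` i.i.d.
#' (relative noise); negative results are clipped at zero. With
#' `mode = "additive"` the perturbation is `level * max(u) * eps` instead.
#'
#' @param u concentration map (numeric vector/array).
#' @param level relative noise standard deviation (>= 0).
#' @param seed RNG seed; the same seed reproduces the noise exactly.
#' @param mode `"proportional"` (default) or `"additive"`.
#' @return the noisy map, same shape as `u`.
#' @export
add_noise <- function(u, level, seed = NULL, mode = c("proportional", "additive")) {
  mode <- match.arg(mode)
  if (!is.finite(level) || level < 0) stop("noise level must be >= 0")
  if (level == 0) return(u)
  if (!is.null(seed)) set.seed(seed)
  eps <- stats::rnorm(length(u), 0, level)
  out <- if (mode == "proportional") u * (1 + eps) else u + max(u) * eps
  pmax(out, 0)
}

#' Extract a snapshot pair from a simulated time course
#'
#' Picks the concentration maps at `t1` and `t2` (which must be sampled times
#' of `C`) and applies measurement noise independently to each.
#'
#' @param C a [concentration_field()].
#' @param geom the [tumour_geometry()] of the simulation.
#' @param t1,t2 snapshot times, seconds, with `t2 > t1`.
#' @param noise_level relative noise level (see [add_noise()]).
#' @param seed RNG seed for the noise.
#' @return a [snapshot_pair()].
#' @export
make_snapshots <- function(C, geom, t1, t2, noise_level = 0, seed = NULL) {
  stopifnot(inherits(C, "concentration_field"))
  if (t2 <= t1) stop("t2 must be greater than t1")
  pick <- function(t) {
    j <- which(abs(C$times - t) <= 1e-9 * max(1, abs(t)))
    if (length(j) != 1L) stop(sprintf("t = %.6g s is not a sampled time", t))
    C$values[, j]
  }
  u1 <- pick(t1); u2 <- pick(t2)
  if (noise_level > 0) {
    if (!is.null(seed)) set.seed(seed)
    u1 <- add_noise(u1, noise_level)
    u2 <- add_noise(u2, noise_level)
  }
  snapshot_pair(u1, u2, t1, t2, geom)
}

#' Generate a synthetic tumour case
#'
#' The full forward pipeline of the synthetic validation study: solve the
#' steady pressure equation for the true IFP, advance the transport PDE by
#' Crank-Nicolson from a zero initial image, and extract a noisy snapshot
#' pair. Defaults are the study conditions of the 1D sensitivity analysis: a
#' 10 cm domain with 200 cells and a 2 cm central tumour, 150 equidistant time
#' points over [0, 200] hours, snapshots at 0 and 200 h, relative noise 0.025.
#'
#' @param params a [tissue_parameters()] object (default
#'   [baseline_parameters()]).
#' @param geom a [tumour_geometry()]; default [centred_tumour_1d()] with
#'   `nx` voxels.
#' @param nx voxel count of the default 1D geometry.
#' @param plasma a [plasma_model()]; the default (`a` = 7 mgI/cm^3, 24 h
#'   half-life) is a configuration choice, not a fitted value.
#' @param t_final_h final simulated time, hours.
#' @param nt number of equidistant time points (including 0).
#' @param t1_h,t2_h snapshot times, hours.
#' @param noise_level relative voxelwise noise applied to both snapshots.
#' @param seed RNG seed for the noise.
#' @return a list with elements `pressure` (the true [pressure_field()]),
#'   `conc` (the [concentration_field()]), `pair` (the noisy
#'   [snapshot_pair()]), plus the inputs (`params`, `plasma`, `geom`).
#' @export
synthetic_tumour_case <- function(params = baseline_parameters(),
                                  geom = NULL, nx = 200,
                                  plasma = plasma_model(a = 7, half_life_h = 24),
                                  t_final_h = 200, nt = 150,
                                  t1_h = 0, t2_h = t_final_h,
                                  noise_level = 0.025, seed = NULL) {
  if (is.null(geom)) geom <- centred_tumour_1d(nx = nx)
  truth <- solve_pressure(geom, params)
  t_grid <- seq(0, t_final_h * 3600, length.out = nt)
  conc <- solve_transport(truth, params, plasma, geom, t_grid)
  pair <- make_snapshots(conc, geom, t1_h * 3600, t2_h * 3600,
                         noise_level = noise_level, seed = seed)
  list(pressure = truth, conc = conc, pair = pair,
       params = params, plasma = plasma, geom = geom)
}
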