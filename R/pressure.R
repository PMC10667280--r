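#' Interstitial pressure from the steady pressure equation
#'
#' Solves `lap(P_i) = -alpha(x)^2 (P_e(x) - P_i)` for the interstitial fluid
#' pressure, where `alpha = sqrt((LpS/V) / K)` takes its tumour/normal value
#' voxelwise and the effective pressure `P_e` is `P_v` inside the tumour and 0
#' outside. The zero-at-infinity condition is approximated by extending the
#' computational domain by `extension` cm on every side and imposing zero
#' Dirichlet values there; the solution is returned restricted to the
#' requested grid. The discrete solution satisfies `0 <= P_i <= P_v`.
#'
#' @param geom a [tumour_geometry()].
#' @param params a [tissue_parameters()] object.
#' @param extension extra domain length appended per side, cm; the default is
#'   twice the domain extent (per axis).
#' @return a [pressure_field()] on the grid of `geom`.
#' @export
solve_pressure <- function(geom, params, extension = NULL) {
  stopifnot(inherits(geom, "tumour_geometry"), inherits(params, "tissue_params"))
  grid <- geom$grid
  extent <- grid$shape * grid$spacing
  if (is.null(extension)) extension <- 2 * extent
  extension <- rep_len(as.numeric(extension), grid$ndim)
  ext_cells <- as.integer(round(extension / grid$spacing))

  eshape <- grid$shape + 2L * ext_cells
  egrid <- pde_grid(eshape, grid$spacing, grid$origin - ext_cells * grid$spacing)
  ne <- n_voxels(egrid)

  # embed the mask in the extended lattice (everything appended is normal tissue)
  inner <- array(FALSE, dim = eshape)
  idx <- lapply(seq_len(grid$ndim), function(a) ext_cells[a] + seq_len(grid$shape[a]))
  inner <- do.call(`[<-`, c(list(inner), idx, list(TRUE)))
  emask <- array(FALSE, dim = eshape)
  emask <- do.call(`[<-`, c(list(emask), idx, list(array(geom$mask, dim = grid$shape))))

  alpha_T <- sqrt(params$LpS_V_T / params$K_T)
  alpha_N <- sqrt(params$LpS_V_N / params$K_N)
  if (!is.finite(alpha_T) || !is.finite(alpha_N) || alpha_T <= 0 || alpha_N <= 0)
    stop("alpha must be positive: LpS/V and K must be strictly positive")
  alpha2 <- ifelse(c(emask), alpha_T^2, alpha_N^2)
  Pe <- ifelse(c(emask), params$P_v, 0)

  # -lap(P) + alpha^2 P = alpha^2 Pe; zero Dirichlet half a cell outside the
  # extended domain enters through the constant -2/h^2 diagonal per axis.
  faces <- grid_faces(egrid)
  diag_lap <- sum(2 / egrid$spacing^2)
  ii <- jj <- xx <- vector("list", 2L * length(faces) + 1L)
  k <- 0L
  for (f in faces) {
    k <- k + 1L; ii[[k]] <- f$lo; jj[[k]] <- f$hi; xx[[k]] <- rep(-1 / f$h^2, length(f$lo))
    k <- k + 1L; ii[[k]] <- f$hi; jj[[k]] <- f$lo; xx[[k]] <- rep(-1 / f$h^2, length(f$lo))
  }
  k <- k + 1L
  ii[[k]] <- jj[[k]] <- seq_len(ne); xx[[k]] <- diag_lap + alpha2
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(ne, ne))
  P <- tryCatch(as.numeric(Matrix::solve(M, alpha2 * Pe)),
                error = function(e) stop("pressure system could not be solved: ",
                                         conditionMessage(e)))
  pressure_field(grid, P[c(inner)])
}

#' Closed-form 1D pressure profile for a centred tumour
#'
#' Analytic solution of the steady pressure equation for piecewise-constant
#' coefficients and a single tumour interval of half-width `R` centred at 0:
#' `P_v (1 - A cosh(alpha_T x))` inside, `B exp(-alpha_N (|x| - R))` outside,
#' with `A`, `B` fixed by continuity at `|x| = R`. With `matching =
#' "gradient"` (the condition the plain-Laplacian pressure equation implies,
#' and the profile the discrete solver converges to) the pressure gradient is
#' continuous; `"K-weighted"` instead makes the Darcy flux `K dP/dx`
#' continuous.
#'
#' @param params a [tissue_parameters()] object.
#' @param R tumour half-width, cm (> 0).
#' @param matching interface condition for the derivative.
#' @return a function of the (vector) signed distance `x` from the tumour
#'   centre returning pressure in mmHg, with constants `A`, `B`, `alpha_T`,
#'   `alpha_N` attached as attributes.
#' @export
analytic_pressure_1d <- function(params, R, matching = c("gradient", "K-weighted")) {
  stopifnot(inherits(params, "tissue_params"))
  matching <- match.arg(matching)
  if (R <= 0) stop("R must be positive")
  aT <- sqrt(params$LpS_V_T / params$K_T)
  aN <- sqrt(params$LpS_V_N / params$K_N)
  w <- if (matching == "gradient") 1 else params$K_T / params$K_N
  # continuity of P and of (w * dP/dx) at |x| = R:
  #   P_v (1 - A cosh(aT R)) = B ;  w P_v A aT sinh(aT R) = aN B
  A <- aN / (w * aT * sinh(aT * R) + aN * cosh(aT * R))
  B <- params$P_v * w * aT * sinh(aT * R) * A / aN
  f <- function(x) {
    x <- abs(x)
    ifelse(x <= R,
           params$P_v * (1 - A * cosh(aT * x)),
           B * exp(-aN * (x - R)))
  }
  attr(f, "A") <- A; attr(f, "B") <- B
  attr(f, "alpha_T") <- aT; attr(f, "alpha_N") <- aN
  f
}
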