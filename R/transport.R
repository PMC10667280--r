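# Assemble the linear part of the transport right-hand side as a sparse matrix:
#   (A C)_i = div( kappa C grad P )_i - kd_i C_i + D lap(C)_i
# in conservative (flux) form on the voxel lattice. Face values of kappa*C use
# arithmetic averages of the adjacent cells; boundary faces carry zero flux, so
# with kd = 0 and D contained, columns of A sum to zero (discrete mass balance).
assemble_transport_operator <- function(P, faces, kappa, kd, D, n) {
  ii <- jj <- xx <- vector("list", length(faces) * 4L + 1L)
  k <- 0L
  for (f in faces) {
    dP <- (P[f$hi] - P[f$lo]) / f$h
    clo <- kappa[f$lo] * dP / (2 * f$h)
    chi <- kappa[f$hi] * dP / (2 * f$h)
    dif <- D / f$h^2
    # (A C)_lo += F / h, (A C)_hi -= F / h with
    # F = (kappa_lo C_lo + kappa_hi C_hi)/2 * dP + D (C_hi - C_lo)/h
    k <- k + 1L; ii[[k]] <- f$lo; jj[[k]] <- f$lo; xx[[k]] <- clo - dif
    k <- k + 1L; ii[[k]] <- f$lo; jj[[k]] <- f$hi; xx[[k]] <- chi + dif
    k <- k + 1L; ii[[k]] <- f$hi; jj[[k]] <- f$lo; xx[[k]] <- -clo + dif
    k <- k + 1L; ii[[k]] <- f$hi; jj[[k]] <- f$hi; xx[[k]] <- -chi - dif
  }
  k <- k + 1L
  ii[[k]] <- seq_len(n); jj[[k]] <- seq_len(n); xx[[k]] <- rep_len(-kd, n)
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n))
}

# Dimensional coefficient fields entering the operator and source term.
transport_coefficients <- function(P, params, geom) {
  P <- if (inherits(P, "pressure_field")) P$values else as.numeric(P)
  P <- check_field(P, geom$grid, "pressure")
  list(
    P = P,
    kappa = piecewise_param("f", params, geom) * piecewise_param("K", params, geom),
    kd = piecewise_param("kd", params, geom),
    D = params$D,
    # gain on C_p(t): (LpS/V) (P_v - P_i) (1 - sigma), per voxel
    src = piecewise_param("LpS_V", params, geom) *
      (params$P_v - P) * (1 - piecewise_param("sigma", params, geom)))
}

#' Transport PDE right-hand side
#'
#' Evaluates the rate of change of interstitial liposome concentration,
#' `g(C, t) = (LpS/V)(P_v - P_i)(1 - sigma) C_p + div(f K C grad P_i) - kd C`
#' (plus `D lap C` when `D > 0`), with tumour/normal parameter values selected
#' voxelwise by the mask. Spatial derivatives use second-order conservative
#' finite differences with zero-flux boundary faces.
#'
#' @param C concentration per voxel, mgI/cm^3.
#' @param P interstitial pressure per voxel (mmHg) or a [pressure_field()].
#' @param Cp plasma concentration at the evaluation time, mgI/cm^3 (scalar).
#' @param params a [tissue_parameters()] object.
#' @param geom a [tumour_geometry()].
#' @return the concentration rate per voxel, mgI/cm^3/s.
#' @export
transport_rhs <- function(C, P, Cp, params, geom) {
  stopifnot(inherits(geom, "tumour_geometry"))
  C <- check_field(C, geom$grid, "concentration")
  if (!is.finite(Cp) || length(Cp) != 1L) stop("Cp must be a finite scalar")
  co <- transport_coefficients(P, params, geom)
  A <- assemble_transport_operator(co$P, grid_faces(geom$grid), co$kappa,
                                   co$kd, co$D, n_voxels(geom$grid))
  as.numeric(A %*% C) + co$src * Cp
}
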