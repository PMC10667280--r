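#' @export
print.ifp_pinn <- function(x, ...) {
  mask <- x$pair$geom$mask
  cat("Voxelwise interstitial fluid pressure fit (discrete-time PINN)\n")
  cat(sprintf("  grid: %s voxels (%dD), %d tumour voxels\n",
              paste(x$pair$geom$grid$shape, collapse = " x "),
              x$pair$geom$grid$ndim, sum(mask)))
  cat(sprintf("  snapshots at t1 = %.3g h, t2 = %.3g h; q = %d stages\n",
              x$pair$t1 / 3600, x$pair$t2 / 3600, x$scheme$q))
  cat(sprintf("  mean tumour IFP: %.2f mmHg (P_v = %.4g mmHg)\n",
              mean_ifp(x), x$params$P_v))
  cat(sprintf("  final loss %.4g; %s\n", x$final_loss, x$convergence_reason))
  invisible(x)
}

#' @export
summary.ifp_pinn <- function(object, ...) {
  mask <- object$pair$geom$mask
  P <- object$pressure$values
  res <- residuals(object)
  out <- list(
    mean_ifp = mean(P[mask]),
    range_ifp = range(P[mask]),
    P_v = object$params$P_v,
    n_voxels = length(P), n_tumour = sum(mask),
    q = object$scheme$q,
    final_loss = object$final_loss,
    converged = object$converged,
    convergence_reason = object$convergence_reason,
    rms_residual_u2 = sqrt(mean(res^2)))
  class(out) <- "summary.ifp_pinn"
  out
}

#' @export
print.summary.ifp_pinn <- function(x, ...) {
  cat("Discrete-time PINN pressure fit\n")
  cat(sprintf("  tumour IFP: mean %.2f mmHg, range [%.2f, %.2f] (P_v = %.4g)\n",
              x$mean_ifp, x$range_ifp[1], x$range_ifp[2], x$P_v))
  cat(sprintf("  %d voxels (%d tumour), %d RK stages\n", x$n_voxels, x$n_tumour, x$q))
  cat(sprintf("  final loss %.4g, RMS u2 residual %.4g mgI/cm^3\n",
              x$final_loss, x$rms_residual_u2))
  cat(sprintf("  %s\n", x$convergence_reason))
  invisible(x)
}

#' @export
coef.ifp_pinn <- function(object, ...) object$pressure$values

#' @export
fitted.ifp_pinn <- function(object, ...) object$reconstructed

#' Residuals of the final-snapshot reconstruction
#'
#' @param object an [ifp_pinn()] fit.
#' @param which `"u2"` (default) or `"u1"`.
#' @param ... unused.
#' @return known minus reconstructed snapshot, mgI/cm^3 per voxel.
#' @export
residuals.ifp_pinn <- function(object, which = c("u2", "u1"), ...) {
  which <- match.arg(which)
  object$pair[[which]] - object$reconstructed[[which]]
}

#' Project the concentration time course with the learned pressure
#'
#' Forward-solves the transport PDE from the first snapshot with the fitted
#' pressure field, which is how the model extends its prediction beyond the
#' imaged interval.
#'
#' @param object an [ifp_pinn()] fit.
#' @param times output times, seconds (must start at or after `t1`); default
#'   is 150 points spanning `[t1, t2]`.
#' @param ... unused.
#' @return a [concentration_field()].
#' @export
predict.ifp_pinn <- function(object, times = NULL, ...) {
  if (is.null(times))
    times <- seq(object$pair$t1, object$pair$t2, length.out = 150)
  solve_transport(object$pressure, object$params, object$plasma,
                  object$pair$geom, times, C0 = object$pair$u1)
}

#' @export
plot.ifp_pinn <- function(x, ...) {
  geom <- x$pair$geom
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (geom$grid$ndim == 1L) {
    xc <- grid_coords(geom$grid)[, 1]
    graphics::plot(xc, x$pressure$values, type = "l", xlab = "x [cm]",
                   ylab = "IFP [mmHg]", main = "Learned pressure", ...)
    graphics::abline(h = x$params$P_v, lty = 3)
  } else {
    graphics::hist(x$pressure$values[geom$mask], xlab = "IFP [mmHg]",
                   main = "Tumour IFP", ...)
  }
  ac <- accumulation_curve(x)
  graphics::plot(ac$time / 3600, ac$concentration, type = "l",
                 xlab = "time [h]", ylab = "mean tumour conc. [mgI/cm^3]",
                 main = "Accumulation curve")
  graphics::points(c(x$pair$t1, x$pair$t2) / 3600,
                   c(mean(x$pair$u1[geom$mask]), mean(x$pair$u2[geom$mask])),
                   pch = 19)
  invisible(x)
}

#' Mean tumour accumulation curve of a fit
#'
#' The average concentration over the tumour mask at each intermediate
#' Runge-Kutta stage time, book-ended by the means of the known snapshots:
#' the model's reconstruction of the full liposome accumulation time course
#' from a single post-administration image.
#'
#' @param fit an [ifp_pinn()] fit.
#' @param mask optional logical mask (default: the tumour mask of the fit).
#' @return a data.frame with columns `time` (s) and `concentration`
#'   (mgI/cm^3).
#' @export
accumulation_curve <- function(fit, mask = NULL) {
  stopifnot(inherits(fit, "ifp_pinn"))
  if (is.null(mask)) mask <- fit$pair$geom$mask
  if (!any(mask)) stop("mask is empty")
  data.frame(
    time = c(fit$pair$t1, fit$stage_times, fit$pair$t2),
    concentration = c(mean(fit$pair$u1[mask]),
                      colMeans(fit$stages[mask, , drop = FALSE]),
                      mean(fit$pair$u2[mask])))
}

#' Mean interstitial fluid pressure over the tumour
#'
#' @param x an [ifp_pinn()] fit, a [pressure_field()], or a numeric voxel
#'   field.
#' @param mask logical tumour mask (required unless `x` is a fit).
#' @return mean pressure over the masked voxels, mmHg.
#' @export
mean_ifp <- function(x, mask = NULL) {
  if (inherits(x, "ifp_pinn")) {
    if (is.null(mask)) mask <- x$pair$geom$mask
    x <- x$pressure
  }
  if (inherits(x, "pressure_field")) x <- x$values
  if (is.null(mask)) stop("mask is required")
  if (!any(mask)) stop("mask is empty")
  mean(as.numeric(x)[mask])
}
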