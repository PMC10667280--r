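#' Three-compartment voxel composition model
#'
#' Each tissue voxel is a mixture of a vascular compartment (plasma
#' concentration `C_p`, volume fraction `eps_p`), a cellular compartment
#' (`C_c`, `eps_c`) and the interstitium (`C_i`, `eps_i`):
#' `C_total = eps_p C_p + eps_c C_c + eps_i C_i`. Raw CT signal converts to
#' total iodine concentration through a species-specific linear factor, and
#' aorta (whole-blood) signal converts to plasma concentration through the
#' hematocrit factor.
#'
#' @param eps_p vascular volume fraction (default 0.03).
#' @param eps_i interstitial volume fraction (default 0.30).
#' @param eps_c cellular volume fraction (default 0; liposome uptake by cells
#'   is treated as negligible).
#' @param hu_per_conc CT scaling, HU per mgI/cm^3 (default 50.1).
#' @param hematocrit dimensionless hematocrit factor in (0, 1] (default 0.5).
#' @return an object of class `compartment_model`.
#' @export
compartment_model <- function(eps_p = 0.03, eps_i = 0.30, eps_c = 0,
                              hu_per_conc = 50.1, hematocrit = 0.5) {
  fr <- c(eps_p = eps_p, eps_i = eps_i, eps_c = eps_c)
  if (any(fr < 0 | fr > 1)) stop("volume fractions must lie in [0, 1]")
  if (sum(fr) > 1 + 1e-12) stop("volume fractions must sum to at most 1")
  if (hu_per_conc <= 0) stop("hu_per_conc must be positive")
  if (hematocrit <= 0 || hematocrit > 1) stop("hematocrit must be in (0, 1]")
  structure(list(eps_p = eps_p, eps_i = eps_i, eps_c = eps_c,
                 hu_per_conc = hu_per_conc, hematocrit = hematocrit),
            class = "compartment_model")
}

#' CT signal to total tissue concentration
#'
#' @param hu voxel field of raw CT signal, HU.
#' @param model a [compartment_model()].
#' @return total iodine concentration, mgI/cm^3 (same shape as `hu`).
#' @export
signal_to_total_concentration <- function(hu, model = compartment_model()) {
  if (any(!is.finite(hu))) stop("HU field must be finite")
  hu / model$hu_per_conc
}

#' Plasma concentration from an aorta signal series
#'
#' Converts mean aorta (whole-blood) CT signal to plasma concentration:
#' `C_p = signal / hu_per_conc / hematocrit`.
#'
#' @param times sample times, seconds (strictly increasing).
#' @param mean_signal mean aorta signal at each time, HU.
#' @param model a [compartment_model()].
#' @return a data.frame with columns `time` (s) and `Cp` (mgI/cm^3).
#' @export
plasma_from_aorta <- function(times, mean_signal, model = compartment_model()) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(mean_signal))) stop("signals must be finite")
  data.frame(time = times,
             Cp = mean_signal / model$hu_per_conc / model$hematocrit)
}

#' Fit the exponential plasma model to concentration samples
#'
#' Least-squares fit of `C_p(t) = a exp(-b t)` on the log scale, using the
#' positive samples; a rising or constant trend yields `b = 0` (the clearance
#' rate is not allowed to be negative).
#'
#' @param times sample times, seconds.
#' @param cp plasma concentration samples, mgI/cm^3 (at least two positive).
#' @return a [plasma_model()].
#' @export
fit_plasma <- function(times, cp) {
  keep <- is.finite(cp) & cp > 0
  if (sum(keep) < 2L) stop("need at least two positive samples")
  t <- as.numeric(times)[keep]; y <- log(cp[keep])
  fit <- stats::lm.fit(cbind(1, t), y)
  b <- -fit$coefficients[2]
  if (b < 0) {   # non-decaying samples: best constant model
    return(plasma_model(a = exp(mean(y)), b = 0))
  }
  plasma_model(a = exp(fit$coefficients[1]), b = b)
}

#' Vascular volume fraction from an early-time image
#'
#' Shortly after administration essentially all liposomes are still in the
#' plasma, so `C_i ~ 0` and (with negligible cellular uptake) the compartment
#' model reduces to `C_total = eps_p C_p`: the mean tissue concentration over
#' the early plasma concentration estimates the vascular fraction.
#'
#' @param early_total mean voxel tissue concentration at the early time,
#'   mgI/cm^3.
#' @param early_cp plasma concentration at the same time, mgI/cm^3 (> 0).
#' @return the estimated fraction; values above 1 are unphysical and trigger
#'   a warning.
#' @export
estimate_vascular_fraction <- function(early_total, early_cp) {
  if (!(early_cp > 0)) stop("early plasma concentration must be positive")
  frac <- early_total / early_cp
  if (frac > 1) warning(sprintf("estimated vascular fraction %.3g > 1 is unphysical", frac))
  frac
}

#' Interstitial concentration from total concentration
#'
#' Inverts the compartment model with negligible cellular concentration:
#' `C_i = (C_total - eps_p C_p) / eps_i`, floored at zero. The number of
#' floored voxels is attached as attribute `n_floored`.
#'
#' @param total total tissue concentration field, mgI/cm^3.
#' @param Cp plasma concentration at the acquisition time, mgI/cm^3 (scalar).
#' @param model a [compartment_model()] with `eps_i > 0`.
#' @return interstitial concentration field, mgI/cm^3.
#' @export
interstitial_concentration <- function(total, Cp, model = compartment_model()) {
  if (model$eps_i <= 0) stop("eps_i must be positive")
  ci <- (total - model$eps_p * Cp) / model$eps_i
  n_floored <- sum(ci < 0)
  ci <- pmax(ci, 0)
  attr(ci, "n_floored") <- n_floored
  ci
}

#' Crop an image volume to the tumour area
#'
#' Zeroes all signal outside the tumour mask, then crops both image and mask
#' to the bounding box of the mask dilated by `buffer_voxels` per side
#' (clipped at the array edges).
#'
#' @param image numeric array (any dimensionality).
#' @param mask logical array of the same shape with at least one `TRUE`.
#' @param buffer_voxels non-negative integer buffer per side.
#' @return a list with `image`, `mask` (cropped arrays) and `box` (a
#'   `ndim x 2` matrix of index ranges into the original array).
#' @export
crop_to_tumour <- function(image, mask, buffer_voxels = 0) {
  image <- as.array(image); mask <- as.array(mask)
  if (!identical(dim(image), dim(mask))) stop("image and mask shapes differ")
  if (!any(mask)) stop("mask is empty")
  if (buffer_voxels < 0) stop("buffer must be >= 0")
  buffer_voxels <- as.integer(buffer_voxels)
  image[!mask] <- 0
  idx <- which(mask, arr.ind = TRUE)
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 1)
  box <- t(vapply(seq_len(ncol(idx)), function(a) {
    c(max(1L, min(idx[, a]) - buffer_voxels),
      min(dim(image)[a], max(idx[, a]) + buffer_voxels))
  }, integer(2)))
  sub <- lapply(seq_len(nrow(box)), function(a) box[a, 1]:box[a, 2])
  list(image = do.call(`[`, c(list(image), sub, list(drop = FALSE))),
       mask = do.call(`[`, c(list(mask), sub, list(drop = FALSE))),
       box = box)
}

#' Read / write voxel volumes as NIfTI
#'
#' Thin wrappers around \pkg{RNifti} used by the command-line tools; voxel
#' spacing is taken from (written to) the header in mm and converted to cm.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return for `read_volume`, a list with `values` (array) and `spacing_cm`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(values = as.array(img),
       spacing_cm = RNifti::pixdim(img) / 10)
}

#' @rdname read_volume
#' @param values numeric array. @param spacing_cm voxel spacing per axis, cm.
#' @export
write_volume <- function(values, path, spacing_cm = 0.1) {
  img <- RNifti::asNifti(as.array(values))
  RNifti::pixdim(img) <- rep_len(spacing_cm * 10, length(dim(as.array(values))))
  RNifti::writeNifti(img, path)
  invisible(path)
}
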