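#' Relative mean squared pressure error
#'
#' The accuracy metric of the synthetic validation: the mean squared
#' difference between predicted and true pressure over the masked voxels,
#' normalized by the mean squared true pressure over the same voxels (a
#' single-ratio normalization, robust to near-zero boundary pressures).
#'
#' @param P_pred,P_true [pressure_field()]s or numeric voxel fields on the
#'   same grid.
#' @param mask logical mask over which the error is computed (default: all
#'   voxels).
#' @return a dimensionless fraction (multiply by 100 for %).
#' @export
relative_mse <- function(P_pred, P_true, mask = NULL) {
  if (inherits(P_pred, "pressure_field")) P_pred <- P_pred$values
  if (inherits(P_true, "pressure_field")) P_true <- P_true$values
  if (length(P_pred) != length(P_true)) stop("fields differ in length")
  if (is.null(mask)) mask <- rep(TRUE, length(P_true))
  if (!any(mask)) stop("mask is empty")
  denom <- mean(P_true[mask]^2)
  if (denom == 0) stop("true pressure is identically zero on the mask")
  mean((P_pred[mask] - P_true[mask])^2) / denom
}

#' Build the sensitivity sweep cases
#'
#' One baseline case plus, for every row of [sensitivity_table()], a case
#' with that single quantity set to the minimum and one set to the maximum of
#' its range (all other values at baseline). `noise` alters the snapshot
#' noise level rather than a PDE parameter.
#'
#' @param which optional character vector of case labels to keep (e.g.
#'   `c("baseline", "noise_max")`).
#' @return a named list of cases, each with `label`, `params`
#'   (a [tissue_parameters()]) and `noise_level`.
#' @export
sensitivity_cases <- function(which = NULL) {
  tab <- sensitivity_table()
  base <- baseline_parameters()
  base_noise <- tab$baseline[tab$param == "noise"]
  mk <- function(label, params, noise) list(label = label, params = params,
                                            noise_level = noise)
  cases <- list(baseline = mk("baseline", base, base_noise))
  for (i in seq_len(nrow(tab))) {
    for (ext in c("min", "max")) {
      label <- paste0(tab$param[i], "_", ext)
      val <- tab[[ext]][i]
      if (tab$param[i] == "noise") {
        cases[[label]] <- mk(label, base, val)
      } else {
        p <- unclass(base)
        p[[tab$param[i]]] <- val
        cases[[label]] <- mk(label, do.call(tissue_parameters, p), base_noise)
      }
    }
  }
  if (!is.null(which)) {
    missing <- setdiff(which, names(cases))
    if (length(missing)) stop("unknown case(s): ", paste(missing, collapse = ", "))
    cases <- cases[which]
  }
  cases
}

# deterministic per-replicate seed derivation, kept below 2^31
derive_seed <- function(master, case_index, replicate, stream) {
  (as.numeric(master) * 100003 + case_index * 1009 +
     replicate * 13 + stream) %% 2147483647
}

#' Sensitivity analysis on synthetic tumours
#'
#' For each case: solve the pressure equation for the true IFP, solve the
#' transport PDE forward, extract noisy snapshots, fit the inverse model, and
#' score the recovered pressure by [relative_mse()] over the tumour mask.
#' Each of the `replicates` runs redraws both the measurement noise and the
#' network initialization (seeds derived deterministically from `seed`); the
#' replicate errors are bootstrap-resampled for a mean and percentile 95%
#' confidence interval.
#'
#' @param cases a list from [sensitivity_cases()] (default: all cases).
#' @param replicates training runs per case (default 5).
#' @param bootstrap_n bootstrap resamples (default 1000).
#' @param seed master seed.
#' @param nx voxel count of the 1D synthetic domain (default 100, the
#'   scaled-down profile; the full protocol uses 200).
#' @param q Runge-Kutta stages (default 20; full protocol 100).
#' @param config a [pinn_config()] template (its seed is overridden per
#'   replicate).
#' @param plasma a [plasma_model()] for the synthetic plasma time course.
#' @param verbose print one line per completed case.
#' @return an object of class `sensitivity_result`: a list with `errors`
#'   (data.frame: case, replicate, error, noise_seed, net_seed) and `summary`
#'   (data.frame: case, mean, ci_lo, ci_hi; errors as fractions).
#' @export
run_sensitivity <- function(cases = sensitivity_cases(), replicates = 5,
                            bootstrap_n = 1000, seed = 1, nx = 100, q = 20,
                            config = pinn_config(),
                            plasma = plasma_model(a = 7, half_life_h = 24),
                            verbose = FALSE) {
  scheme <- irk_gauss(q)
  rows <- list(); summ <- list()
  for (ci in seq_along(cases)) {
    case <- cases[[ci]]
    errs <- numeric(replicates)
    for (r in seq_len(replicates)) {
      noise_seed <- derive_seed(seed, ci, r, 1)
      net_seed <- derive_seed(seed, ci, r, 2)
      syn <- synthetic_tumour_case(params = case$params, nx = nx,
                                   plasma = plasma,
                                   noise_level = case$noise_level,
                                   seed = noise_seed)
      cfg <- config; cfg$seed <- net_seed
      err <- tryCatch({
        fit <- ifp_pinn(syn$pair, case$params, plasma, config = cfg,
                        scheme = scheme)
        relative_mse(fit$pressure, syn$pressure, syn$geom$mask)
      }, error = function(e) {
        warning(sprintf("case %s replicate %d failed: %s", case$label, r,
                        conditionMessage(e)))
        NA_real_
      })
      errs[r] <- err
      rows[[length(rows) + 1L]] <- data.frame(
        case = case$label, replicate = r, error = err,
        noise_seed = noise_seed, net_seed = net_seed)
    }
    ok <- errs[is.finite(errs)]
    set.seed(derive_seed(seed, ci, 0, 3))
    boot <- replicate(bootstrap_n, mean(sample(ok, length(ok), replace = TRUE)))
    ci95 <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
    summ[[length(summ) + 1L]] <- data.frame(
      case = case$label, mean = mean(boot), ci_lo = ci95[1], ci_hi = ci95[2])
    if (verbose)
      message(sprintf("%-12s mean relative MSE %.3f%% [%.3f, %.3f]",
                      case$label, mean(boot) * 100, ci95[1] * 100, ci95[2] * 100))
  }
  structure(list(errors = do.call(rbind, rows), summary = do.call(rbind, summ),
                 replicates = replicates, bootstrap_n = bootstrap_n,
                 seed = seed, nx = nx, q = q),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> %d case(s), %d replicates, %d bootstrap samples\n",
              nrow(x$summary), x$replicates, x$bootstrap_n))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.3f%%  [%.3f, %.3f]\n", s$case[i], 100 * s$mean[i],
                100 * s$ci_lo[i], 100 * s$ci_hi[i]))
  invisible(x)
}

#' @export
plot.sensitivity_result <- function(x, ...) {
  s <- x$summary
  mids <- graphics::barplot(100 * s$mean, names.arg = s$case, las = 2,
                            ylab = "relative MSE [%]",
                            ylim = c(0, 1.1 * max(100 * s$ci_hi)), ...)
  graphics::arrows(mids, 100 * s$ci_lo, mids, 100 * s$ci_hi,
                   angle = 90, code = 3, length = 0.04)
  invisible(x)
}

#' Effect of the imaging time on the predictions
#'
#' Re-fits the inverse model using each candidate time as the
#' post-administration image, projects the accumulation curve over all sample
#' times of `C` with the learned pressure, and scores it against the held-out
#' mean-accumulation samples (sum of squared errors at the measured times).
#' On good data the mean IFP should be nearly independent of the imaging time
#' chosen.
#'
#' @param C a [concentration_field()] holding the measured (or simulated)
#'   time course.
#' @param geom the [tumour_geometry()].
#' @param candidate_times times (s) from `C$times` to use as the final image;
#'   default: all sampled times after the first. Time 0 is rejected.
#' @param params,plasma,config,q as in [ifp_pinn()].
#' @param noise_level optional noise applied to each snapshot pair.
#' @param seed seed for noise / network init derivation.
#' @return an object of class `timesweep_result`: data.frame `summary`
#'   (t2, mean_ifp, mse) plus the per-candidate predicted curves.
#' @export
imaging_time_sweep <- function(C, geom, candidate_times = NULL, params, plasma,
                               config = pinn_config(), q = 20,
                               noise_level = 0, seed = 1) {
  stopifnot(inherits(C, "concentration_field"))
  if (is.null(candidate_times)) candidate_times <- C$times[-1]
  if (any(candidate_times <= C$times[1]))
    stop("candidate times must be after the initial time")
  if (length(candidate_times) < 1L) stop("need at least one candidate time")
  scheme <- irk_gauss(q)
  mask <- geom$mask
  measured <- colMeans(C$values[mask, , drop = FALSE])
  rows <- list(); curves <- list()
  for (i in seq_along(candidate_times)) {
    t2 <- candidate_times[i]
    pair <- make_snapshots(C, geom, C$times[1], t2, noise_level = noise_level,
                           seed = derive_seed(seed, i, 1, 1))
    cfg <- config; cfg$seed <- derive_seed(seed, i, 1, 2)
    fit <- ifp_pinn(pair, params, plasma, config = cfg, scheme = scheme)
    proj <- solve_transport(fit$pressure, params, plasma, geom, C$times,
                            C0 = pair$u1)
    predicted <- colMeans(proj$values[mask, , drop = FALSE])
    rows[[i]] <- data.frame(t2 = t2, mean_ifp = mean_ifp(fit),
                            mse = sum((measured - predicted)^2))
    curves[[i]] <- data.frame(time = C$times, predicted = predicted,
                              measured = measured)
  }
  structure(list(summary = do.call(rbind, rows), curves = curves),
            class = "timesweep_result")
}

#' @export
print.timesweep_result <- function(x, ...) {
  cat("<timesweep_result>\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  t2 = %7.1f h  mean IFP %.2f mmHg  curve MSE %.4g\n",
                s$t2[i] / 3600, s$mean_ifp[i], s$mse[i]))
  invisible(x)
}

#' Cohort summary of per-subject mean IFP
#'
#' @param mean_ifps numeric vector of per-subject mask-mean IFP values (mmHg),
#'   or a list of [ifp_pinn()] fits.
#' @return a list with `n`, `min`, `max`, `mean` and `sem` (sample SD /
#'   sqrt(n); 0 with a flag `sem_defined = FALSE` for a single subject).
#' @export
summarize_cohort <- function(mean_ifps) {
  if (is.list(mean_ifps))
    mean_ifps <- vapply(mean_ifps, mean_ifp, numeric(1))
  if (length(mean_ifps) < 1L) stop("need at least one subject")
  n <- length(mean_ifps)
  list(n = n, min = min(mean_ifps), max = max(mean_ifps),
       mean = mean(mean_ifps),
       sem = if (n > 1L) stats::sd(mean_ifps) / sqrt(n) else 0,
       sem_defined = n > 1L)
}
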