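#' Retained white-matter tract voxels
#'
#' @param chi voxel susceptibilities (ppb).
#' @param theta fiber-to-field angles (radians, in \[0, pi/2\]).
#' @param fa fractional anisotropies.
#' @param tract tract identifier.
#' @param subjects ids of the subjects contributing voxels.
#' @return list of class `tract_voxel_set`.
#' @export
tract_voxel_set <- function(chi, theta, fa, tract = "tract",
                            subjects = character(0)) {
  n <- length(chi)
  stopifnot(length(theta) == n, length(fa) == n)
  if (n > 0) {
    stopifnot(all(is.finite(chi)), all(is.finite(theta)), all(is.finite(fa)))
    if (any(theta < -1e-9 | theta > pi / 2 + 1e-9))
      stop("theta must lie in [0, pi/2]")
  }
  structure(list(tract = tract, chi = as.numeric(chi),
                 theta = as.numeric(theta), fa = as.numeric(fa),
                 subjects = subjects, empty = n == 0L),
            class = "tract_voxel_set")
}

#' @export
print.tract_voxel_set <- function(x, ...) {
  cat(sprintf("<tract_voxel_set> %s: %d voxels\n", x$tract, length(x$chi)))
  invisible(x)
}

#' Select analyzable white-matter voxels
#'
#' Applies the retention rules for the anisotropy fit: the white-matter mask
#' is eroded by a physical radius (default 2 mm), the tract mask by one
#' 6-connected erosion; voxels must lie in both eroded masks, have
#' fractional anisotropy >= 0.6 (lower values indicate crossing fibers),
#' and susceptibility inside the censoring bounds (default the printed
#' -110 to 30 ppb 1st/99th percentiles, or recomputed percentiles of the
#' candidate voxels).
#'
#' @param chi,fa,theta aligned [volume3d()]s.
#' @param wm_mask logical white-matter mask (NULL = everywhere).
#' @param tract_mask logical tract mask (NULL = everywhere).
#' @param fa_min minimum fractional anisotropy retained.
#' @param bounds inclusive chi censoring bounds (ppb).
#' @param recompute_bounds if TRUE, bounds are the 1st/99th percentiles of
#'   the voxels passing the mask and FA rules.
#' @param erode_wm_mm erosion radius for the white-matter mask (0 skips).
#' @param erode_tract if TRUE, one 6-connected erosion of the tract mask.
#' @param tract,subjects provenance for the output.
#' @return A [tract_voxel_set()]; empty results are flagged with a warning,
#'   not an error.
#' @export
prepare_wm_voxels <- function(chi, fa, theta, wm_mask = NULL,
                              tract_mask = NULL, fa_min = 0.6,
                              bounds = c(-110, 30), recompute_bounds = FALSE,
                              erode_wm_mm = 2, erode_tract = TRUE,
                              tract = "tract", subjects = character(0)) {
  stopifnot(inherits(chi, "volume3d"), inherits(fa, "volume3d"),
            inherits(theta, "volume3d"))
  check_aligned(chi, fa); check_aligned(chi, theta)
  d <- dim(chi$data)
  vox <- vol_voxdim(chi$affine)
  if (is.null(wm_mask)) wm_mask <- array(TRUE, d)
  if (is.null(tract_mask)) tract_mask <- array(TRUE, d)
  if (erode_wm_mm > 0 && !all(wm_mask))
    wm_mask <- suppressWarnings(
      erode_mask(wm_mask, "radius_mm", radius_mm = erode_wm_mm, voxdim = vox))
  if (erode_tract && !all(tract_mask))
    tract_mask <- suppressWarnings(erode_mask(tract_mask, "six_connected"))
  sel <- wm_mask & tract_mask & chi$mask & fa$mask & theta$mask &
    is.finite(chi$data) & is.finite(fa$data) & is.finite(theta$data) &
    fa$data >= fa_min
  if (recompute_bounds) {
    cv <- chi$data[sel]
    bounds <- if (length(cv)) stats::quantile(cv, c(0.01, 0.99), names = FALSE)
              else bounds
  }
  sel <- sel & chi$data >= bounds[1] & chi$data <= bounds[2]
  if (!any(sel)) {
    warning("no voxels retained for tract ", tract)
    return(tract_voxel_set(numeric(0), numeric(0), numeric(0),
                           tract = tract, subjects = subjects))
  }
  tvs <- tract_voxel_set(chi$data[sel], theta$data[sel], fa$data[sel],
                         tract = tract, subjects = subjects)
  attr(tvs, "bounds") <- bounds
  tvs
}

#' Split tract voxels into equally populated angle bins
#'
#' Voxels are sorted by theta and divided into `n_bins` contiguous groups
#' whose sizes differ by at most one (the first `n %% n_bins` bins take the
#' extra voxel).
#'
#' @param tvs a [tract_voxel_set()].
#' @param n_bins number of bins (default 10).
#' @return data.frame with `bin`, `n`, `mean_theta`, `mean_chi`,
#'   `mean_cos2` per bin.
#' @export
bin_by_theta <- function(tvs, n_bins = 10L) {
  stopifnot(inherits(tvs, "tract_voxel_set"))
  n <- length(tvs$theta)
  if (n < n_bins) stop("fewer voxels than bins")
  ord <- order(tvs$theta)
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + as.integer(seq_len(n_bins) <= extra)
  grp <- rep(seq_len(n_bins), times = sizes)
  th <- tvs$theta[ord]; ch <- tvs$chi[ord]
  data.frame(bin = seq_len(n_bins), n = sizes,
             mean_theta = as.numeric(tapply(th, grp, mean)),
             mean_chi = as.numeric(tapply(ch, grp, mean)),
             mean_cos2 = as.numeric(tapply(cos(th)^2, grp, mean)))
}

#' Fit magnetic susceptibility anisotropy from binned tract voxels
#'
#' Ordinary least squares of per-bin mean chi on the per-bin mean of
#' cos^2 theta (the model chi = delta_chi * cos^2 theta + chi_iso): the
#' slope is the anisotropy delta_chi, the intercept the
#' orientation-independent chi_iso. The bin mean of cos^2 theta is the
#' default regressor because the bin-mean susceptibility is exactly linear
#' in it under the model, making the estimator unbiased; regressing on
#' cos^2 of the bin-mean angle (available via `regressor`) introduces a
#' small systematic attenuation. Significance is a two-sided t-test on the
#' slope with `n_bins - 2` degrees of freedom.
#'
#' @param bins a bin table from [bin_by_theta()].
#' @param regressor `"mean_cos2"` (bin mean of cos^2 theta, default) or
#'   `"cos2_mean_theta"` (cos^2 of the bin-mean angle).
#' @return object of class `anisofit` with `delta_chi`, `chi_iso`, `se`,
#'   `t`, `p`, `df`, and the bin table.
#' @export
fit_delta_chi <- function(bins, regressor = c("mean_cos2", "cos2_mean_theta")) {
  regressor <- match.arg(regressor)
  x <- if (regressor == "cos2_mean_theta") cos(bins$mean_theta)^2
       else bins$mean_cos2
  y <- bins$mean_chi
  if (nrow(bins) < 3) stop("need at least 3 bins")
  if (stats::sd(x) < 1e-12) stop("collinear regressor: all bin angles equal")
  fit <- stats::lm(y ~ x)
  # noiseless bins fit exactly; lm's perfect-fit warning is expected there
  sm <- suppressWarnings(summary(fit))$coefficients
  structure(list(delta_chi = unname(stats::coef(fit)[2]),
                 chi_iso = unname(stats::coef(fit)[1]),
                 se = unname(sm[2, 2]), t = unname(sm[2, 3]),
                 p = unname(sm[2, 4]), df = fit$df.residual,
                 bins = bins, n_voxels = sum(bins$n),
                 regressor = regressor),
            class = "anisofit")
}

#' @export
print.anisofit <- function(x, ...) {
  cat(sprintf(
    "anisotropy fit: delta_chi = %.2f ppb (SE %.2f, t(%d) = %.2f, p = %.3g), chi_iso = %.2f ppb\n",
    x$delta_chi, x$se, x$df, x$t, x$p, x$chi_iso))
  invisible(x)
}

#' @export
coef.anisofit <- function(object, ...) {
  c(chi_iso = object$chi_iso, delta_chi = object$delta_chi)
}

#' @export
summary.anisofit <- function(object, ...) {
  ci <- object$delta_chi + c(-1, 1) * stats::qt(0.975, object$df) * object$se
  list(delta_chi = object$delta_chi, chi_iso = object$chi_iso,
       se = object$se, t = object$t, p = object$p, df = object$df,
       ci95 = ci, n_voxels = object$n_voxels)
}

#' @export
predict.anisofit <- function(object, theta, ...) {
  object$delta_chi * cos(theta)^2 + object$chi_iso
}

#' @export
plot.anisofit <- function(x, ...) {
  ct <- cos(x$bins$mean_theta)^2
  graphics::plot(ct, x$bins$mean_chi, xlab = expression(cos^2 * theta),
                 ylab = expression(chi ~ "(ppb)"),
                 main = sprintf("%s: delta_chi = %.1f ppb",
                                "anisotropy fit", x$delta_chi), ...)
  graphics::abline(x$chi_iso, x$delta_chi)
  invisible(x)
}

#' Fit a tract in one step
#'
#' Convenience wrapper: [bin_by_theta()] then [fit_delta_chi()].
#'
#' @param tvs a [tract_voxel_set()].
#' @param n_bins number of angle bins.
#' @param ... passed to [fit_delta_chi()].
#' @return An `anisofit`.
#' @export
fit_tract <- function(tvs, n_bins = 10L, ...) {
  fit_delta_chi(bin_by_theta(tvs, n_bins), ...)
}

#' Select tracts with significantly positive anisotropy
#'
#' Tracts qualify for case-control analysis when the pooled-control fit has
#' delta_chi > 0 with p < 0.05.
#'
#' @param control_fits named list of `anisofit` objects (control-pooled, one
#'   per tract).
#' @return Character vector of selected tract names (may be empty, with a
#'   warning).
#' @export
select_tracts <- function(control_fits) {
  if (length(control_fits) == 0) return(character(0))
  keep <- vapply(control_fits,
                 function(f) f$delta_chi > 0 && f$p < 0.05, logical(1))
  out <- names(control_fits)[keep]
  if (length(out) == 0) warning("no tract has significantly positive delta_chi")
  out
}

#' Participant white-matter anisotropy
#'
#' Unweighted mean of a subject's per-tract delta_chi over the selected
#' tracts; tracts the subject lacks are dropped (recorded in the
#' `"dropped"` attribute).
#'
#' @param subject_fits named list of the subject's per-tract `anisofit`s.
#' @param selected selected tract names (from [select_tracts()]).
#' @return Mean delta_chi (ppb).
#' @export
participant_delta_chi <- function(subject_fits, selected) {
  avail <- intersect(selected, names(subject_fits))
  if (length(avail) == 0) stop("no selected tract measurable for subject")
  vals <- vapply(subject_fits[avail], function(f) f$delta_chi, numeric(1))
  out <- mean(vals)
  attr(out, "dropped") <- setdiff(selected, avail)
  out
}
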