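#' Censor extreme susceptibility values
#'
#' Marks entries outside the inclusive `[low, high]` bounds as missing for
#' that voxel's regression (the default bounds are the printed 1st/99th
#' percentiles, -74 and 171 ppb).
#'
#' @param values per-subject values at one voxel.
#' @param bounds length-2 numeric `(low, high)`, `low < high`.
#' @return Numeric vector with censored entries set to `NA`; attributes
#'   `censored` (logical) and `dropped` (TRUE when every entry was censored).
#' @export
censor_voxels <- function(values, bounds = c(-74, 171)) {
  if (length(bounds) != 2 || any(!is.finite(bounds)) || bounds[1] >= bounds[2])
    stop("bounds must be finite with low < high")
  cens <- !is.na(values) & (values < bounds[1] | values > bounds[2])
  out <- values
  out[cens] <- NA_real_
  attr(out, "censored") <- cens
  attr(out, "dropped") <- all(!is.finite(out))
  out
}

# covariate data.frame -> voxelwise design matrix (group effect first after
# the intercept)
vw_design <- function(covariates) {
  if (is.matrix(covariates)) return(covariates)
  cbind(`(Intercept)` = 1,
        group = as.numeric(covariates$group == "patient"),
        current_smoker = as.numeric(covariates$smoking == "current"),
        past_smoker = as.numeric(covariates$smoking == "past"),
        thc = as.numeric(covariates$thc_positive),
        male = as.numeric(covariates$male),
        age = covariates$age)
}

# drop constant nuisance columns (e.g. an unobserved smoking category);
# the intercept (column 1) and group effect (column 2) must remain
drop_degenerate <- function(X) {
  keep <- c(TRUE, TRUE, apply(X[, -(1:2), drop = FALSE], 2,
                              function(col) stats::sd(col) > 0))
  if (stats::sd(X[, 2]) == 0) stop("group indicator is constant")
  X[, keep, drop = FALSE]
}

# subjects x voxels matrix from a stack (list of volume3d or 4D array)
stack_matrix <- function(chi_stack, mask) {
  if (is.list(chi_stack)) {
    arrs <- lapply(chi_stack, function(v) {
      if (inherits(v, "volume3d")) v$data else v
    })
    Y <- do.call(rbind, lapply(arrs, function(a) as.numeric(a[mask])))
  } else {
    d <- dim(chi_stack)
    stopifnot(length(d) == 4L)
    n <- d[4]
    Y <- t(matrix(chi_stack, ncol = n)[as.vector(mask), , drop = FALSE])
  }
  Y
}

stack_geometry <- function(chi_stack, mask = NULL) {
  if (is.list(chi_stack)) {
    v1 <- chi_stack[[1]]
    dims <- dim(v1$data)
    affine <- v1$affine
    if (is.null(mask)) {
      mask <- Reduce(`&`, lapply(chi_stack, function(v)
        if (inherits(v, "volume3d")) v$mask else is.finite(v)))
    }
  } else {
    d <- dim(chi_stack)
    dims <- d[1:3]
    affine <- diag(4)
    if (is.null(mask)) mask <- apply(is.finite(chi_stack), 1:3, all)
  }
  list(dims = dims, affine = affine, mask = mask)
}

# fast per-voxel OLS t map for the column `coef_idx`; Y has NA for censored
ols_tmap <- function(Y, X, coef_idx = 2L) {
  n <- nrow(X); p <- ncol(X)
  V <- ncol(Y)
  tvals <- rep(NA_real_, V)
  complete <- colSums(!is.finite(Y)) == 0L
  if (any(complete)) {
    XtXinv <- chol2inv(chol(crossprod(X)))
    pinv <- XtXinv %*% t(X)
    B <- pinv %*% Y[, complete, drop = FALSE]
    R <- Y[, complete, drop = FALSE] - X %*% B
    sigma2 <- colSums(R^2) / (n - p)
    tvals[complete] <- B[coef_idx, ] /
      sqrt(pmax(sigma2 * XtXinv[coef_idx, coef_idx], 1e-300))
  }
  for (j in which(!complete)) {
    ok <- is.finite(Y[, j])
    if (sum(ok) <= p + 1) next
    Xo <- X[ok, , drop = FALSE]
    if (qr(Xo)$rank < p) next
    XtXinv <- chol2inv(chol(crossprod(Xo)))
    b <- XtXinv %*% crossprod(Xo, Y[ok, j])
    r <- Y[ok, j] - Xo %*% b
    sigma2 <- sum(r^2) / (sum(ok) - p)
    tvals[j] <- b[coef_idx] / sqrt(pmax(sigma2 * XtXinv[coef_idx, coef_idx],
                                        1e-300))
  }
  tvals
}

# complete-data OLS t map with precomputed projector (permutation fast path)
ols_tmap_fast <- function(Y, X, XtXinv, coef_idx = 2L) {
  n <- nrow(X); p <- ncol(X)
  XtY <- crossprod(X, Y)
  B <- XtXinv %*% XtY
  rss <- colSums(Y^2) - colSums(B * XtY)
  sigma2 <- pmax(rss, 0) / (n - p)
  B[coef_idx, ] / sqrt(pmax(sigma2 * XtXinv[coef_idx, coef_idx], 1e-300))
}

huber_tmap <- function(Y, X, coef_idx = 2L) {
  V <- ncol(Y)
  p <- ncol(X)
  tvals <- rep(NA_real_, V)
  for (j in seq_len(V)) {
    ok <- is.finite(Y[, j])
    if (sum(ok) <= p + 1) next
    fit <- tryCatch(huber_regress(Y[ok, j], X[ok, , drop = FALSE]),
                    error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) {
      # robust fit failed at this voxel: fall back to OLS
      tvals[j] <- ols_tmap(Y[, j, drop = FALSE], X, coef_idx)
    } else {
      tvals[j] <- fit$t[coef_idx]
    }
  }
  tvals
}

#' Voxelwise group-effect t-score map
#'
#' Per voxel, regresses susceptibility on case-control status adjusting for
#' smoking, THC screen, sex, and age (Huber robust regression by default,
#' with OLS fallback at voxels where the robust fit fails), after censoring
#' extreme values. Returns the map of the group-coefficient t-score.
#'
#' @param chi_stack list of per-subject [volume3d()]s, or a 4D array
#'   (x, y, z, subject).
#' @param design covariate data.frame (`group`, `age`, `male`, `smoking`,
#'   `thc_positive`) or a prebuilt design matrix whose second column is the
#'   group effect.
#' @param mask logical analysis mask; defaults to voxels finite in every
#'   subject.
#' @param bounds censoring bounds passed to [censor_voxels()]; NULL skips.
#' @param robust use Huber regression (TRUE) or OLS (FALSE).
#' @return A [volume3d()] of t-scores (`NaN` outside the mask) with
#'   attributes `covariates` and `bounds`.
#' @export
voxel_glm <- function(chi_stack, design, mask = NULL, bounds = c(-74, 171),
                      robust = TRUE) {
  geo <- stack_geometry(chi_stack, mask)
  X <- drop_degenerate(vw_design(design))
  n <- nrow(X)
  if (n < 20) stop("need at least 20 subjects")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
  Y <- stack_matrix(chi_stack, geo$mask)
  if (nrow(Y) != n) stop("stack size and design rows differ")
  if (!is.null(bounds))
    Y <- apply(Y, 2, function(v) as.numeric(censor_voxels(v, bounds)))
  tv <- if (robust) huber_tmap(Y, X) else ols_tmap(Y, X)
  out <- array(NaN, geo$dims)
  out[geo$mask] <- tv
  v <- volume3d(out, geo$affine, geo$mask & array(is.finite(out), geo$dims),
                units = "t")
  attr(v, "covariates") <- colnames(X)
  attr(v, "bounds") <- bounds
  v
}

#' Threshold-free cluster enhancement
#'
#' Integrates cluster extent and height over all thresholds:
#' enhanced(v) = sum over h of extent_h(v)^E * h^H * dh, with extent_h(v)
#' the size of the suprathreshold connected component containing v.
#' Positive and negative tails are enhanced separately (on the map and its
#' negation) and recombined with sign.
#'
#' @param stat a [volume3d()] t-score map or a numeric 3D array (`NaN` =
#'   background).
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh threshold step; default `max(abs(stat)) / 100`.
#' @param connectivity 6, 18, or 26 (default 26).
#' @return Enhanced map, same container type as the input; positive where
#'   the statistic was positive, negative where negative.
#' @export
tfce <- function(stat, E = 0.5, H = 2, dh = NULL, connectivity = 26) {
  arr <- if (inherits(stat, "volume3d")) stat$data else stat
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  if (!is.null(dh) && dh <= 0) stop("dh must be positive")
  mx <- suppressWarnings(max(abs(arr), na.rm = TRUE))
  if (!is.finite(mx) || mx == 0) {
    enh <- array(0, dim(arr))
  } else {
    if (is.null(dh)) dh <- mx / 100
    dims <- as.integer(dim(arr))
    pos <- arr; pos[!is.finite(pos) | pos < 0] <- 0
    neg <- -arr; neg[!is.finite(neg) | neg < 0] <- 0
    enh <- .tfce_cpp(pos, dims, E, H, dh, as.integer(connectivity)) -
      .tfce_cpp(neg, dims, E, H, dh, as.integer(connectivity))
  }
  if (inherits(stat, "volume3d")) {
    volume3d(enh, stat$affine, stat$mask, units = "tfce")
  } else enh
}

#' Connected components of a 3D mask
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18, or 26.
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(length(dim(mask)) == 3L)
  .label_components_cpp(as.logical(mask), as.integer(dim(mask)),
                        as.integer(connectivity))
}

#' Permutation inference on TFCE-enhanced voxelwise statistics
#'
#' Builds the null distribution of TFCE-enhanced group-effect statistics by
#' the Freedman-Lane scheme (residuals under the nuisance-only model are
#' permuted, the full model refitted) or by simple group-label permutation.
#' Voxelwise p-values use the plus-one rule on the enhanced magnitude and
#' are BH-FDR corrected across in-mask voxels; significant clusters are
#' connected components of adjusted p < `alpha`.
#'
#' The permuted and observed maps use the same estimator; the default is
#' OLS score maps (`robust = FALSE`), the standard choice for permutation
#' engines since the observed and null statistics must be exchangeable and
#' refitting a robust M-estimator per voxel per permutation is orders of
#' magnitude slower.
#'
#' @inheritParams voxel_glm
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param scheme `"freedman_lane"` or `"labels"`.
#' @param E,H,dh,connectivity TFCE parameters; `dh` defaults to 1/100 of the
#'   observed maximum |t| and is held fixed across permutations.
#' @param alpha adjusted-p threshold defining reported clusters.
#' @return list of class `tfce_result`: `tmap`, `enhanced`, `p`, `p_adj`
#'   ([volume3d()]s), `clusters` (data.frame: sign, n_voxels, peak indices,
#'   peak MNI mm, peak t), `n_perm`, `seed`.
#' @export
permutation_inference <- function(chi_stack, design, mask = NULL,
                                  n_perm = 10000L, seed = 1L,
                                  bounds = c(-74, 171), robust = FALSE,
                                  scheme = c("freedman_lane", "labels"),
                                  E = 0.5, H = 2, dh = NULL,
                                  connectivity = 26, alpha = 0.05) {
  scheme <- match.arg(scheme)
  if (n_perm < 100) stop("too few permutations for the requested alpha")
  geo <- stack_geometry(chi_stack, mask)
  X <- drop_degenerate(vw_design(design))
  n <- nrow(X)
  Y <- stack_matrix(chi_stack, geo$mask)
  if (!is.null(bounds))
    Y <- apply(Y, 2, function(v) as.numeric(censor_voxels(v, bounds)))
  tmap_fun <- if (robust) huber_tmap else ols_tmap
  dims <- as.integer(geo$dims)
  to_map <- function(tv) {
    a <- array(0, geo$dims)
    a[geo$mask] <- ifelse(is.finite(tv), tv, 0)
    a
  }
  t_obs <- tmap_fun(Y, X)
  obs_arr <- to_map(t_obs)
  mx <- max(abs(obs_arr))
  if (is.null(dh)) dh <- if (mx > 0) mx / 100 else 1
  enh_of <- function(arr) {
    pos <- arr; pos[pos < 0] <- 0
    neg <- -arr; neg[neg < 0] <- 0
    .tfce_cpp(pos, dims, E, H, dh, as.integer(connectivity)) -
      .tfce_cpp(neg, dims, E, H, dh, as.integer(connectivity))
  }
  enh_obs <- enh_of(obs_arr)
  obs_mag <- abs(enh_obs[geo$mask])

  set.seed(seed)
  nuis_idx <- setdiff(seq_len(ncol(X)), 2L)
  Z <- X[, nuis_idx, drop = FALSE]
  if (scheme == "freedman_lane") {
    # residualize Y under the nuisance-only model (complete rows only; the
    # few voxels with censored entries keep their censoring pattern)
    Yz <- Y
    Yz[!is.finite(Yz)] <- 0
    Hz <- Z %*% chol2inv(chol(crossprod(Z))) %*% t(Z)
    Fz <- Hz %*% Yz
    Rz <- Yz - Fz
    miss <- !is.finite(Y)
  }
  complete <- !any(!is.finite(Y))
  XtXinv <- chol2inv(chol(crossprod(X)))
  count <- rep(0L, sum(geo$mask))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    if (scheme == "freedman_lane") {
      Yp <- Fz + Rz[perm, , drop = FALSE]
      if (any(miss)) Yp[miss] <- NA_real_
      tv <- if (!robust && complete) ols_tmap_fast(Yp, X, XtXinv)
            else tmap_fun(Yp, X)
    } else {
      Xp <- X
      Xp[, 2] <- X[perm, 2]
      tv <- tmap_fun(Y, Xp)
    }
    mag <- abs(enh_of(to_map(tv))[geo$mask])
    count <- count + (mag >= obs_mag)
  }
  pvec <- (1 + count) / (n_perm + 1)
  padj <- bh_fdr(pvec)

  mk_vol <- function(vals, units) {
    a <- array(NaN, geo$dims)
    a[geo$mask] <- vals
    volume3d(a, geo$affine, geo$mask, units = units)
  }
  p_vol <- mk_vol(pvec, "p")
  padj_vol <- mk_vol(padj, "p")
  tmap_vol <- mk_vol(t_obs, "t")
  enh_vol <- mk_vol(enh_obs[geo$mask], "tfce")

  sig <- array(FALSE, geo$dims)
  sig[geo$mask] <- padj < alpha
  labs <- label_components(sig, connectivity)
  clusters <- data.frame()
  if (max(labs) > 0) {
    for (l in seq_len(max(labs))) {
      idx <- which(labs == l, arr.ind = TRUE)
      tv <- obs_arr[labs == l]
      pk <- idx[which.max(abs(tv)), ]
      mni <- as.numeric(geo$affine %*% c(pk - 1, 1))[1:3]
      clusters <- rbind(clusters, data.frame(
        cluster = l, sign = sign(tv[which.max(abs(tv))]),
        n_voxels = nrow(idx),
        peak_i = pk[1], peak_j = pk[2], peak_k = pk[3],
        peak_x = mni[1], peak_y = mni[2], peak_z = mni[3],
        peak_t = tv[which.max(abs(tv))]))
    }
  }
  structure(list(tmap = tmap_vol, enhanced = enh_vol, p = p_vol,
                 p_adj = padj_vol, clusters = clusters,
                 n_perm = n_perm, seed = seed, alpha = alpha,
                 E = E, H = H, dh = dh, connectivity = connectivity),
            class = "tfce_result")
}

#' @export
print.tfce_result <- function(x, ...) {
  cat(sprintf("TFCE permutation inference: %d permutations, %d significant cluster(s) at FDR p < %.2f\n",
              x$n_perm, nrow(x$clusters), x$alpha))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}
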