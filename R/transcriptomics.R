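#' Gene-expression panel with sample coordinates
#'
#' @param X samples x genes expression matrix.
#' @param coords samples x 3 matrix of MNI mm coordinates.
#' @param genes gene identifiers (default `colnames(X)`).
#' @param t_scores optional per-sample matched t-scores.
#' @return list of class `expression_panel`.
#' @export
expression_panel <- function(X, coords, genes = colnames(X), t_scores = NULL) {
  X <- as.matrix(X)
  coords <- as.matrix(coords)
  stopifnot(nrow(X) == nrow(coords), ncol(coords) == 3)
  if (is.null(genes)) genes <- sprintf("G%04d", seq_len(ncol(X)))
  if (!is.null(t_scores)) stopifnot(length(t_scores) == nrow(X))
  structure(list(X = X, coords = coords, genes = genes, t = t_scores),
            class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("<expression_panel> %d samples x %d genes%s\n",
              nrow(x$X), ncol(x$X),
              if (is.null(x$t)) "" else ", t-scores matched"))
  invisible(x)
}

#' Match tissue samples to t-score voxels
#'
#' Each sample receives the t-score of the voxel whose center is nearest
#' its MNI coordinate (by rounding the inverse-affine voxel coordinate).
#' Samples falling outside the grid or the map's mask are dropped (`NA`),
#' with the count reported in the `n_dropped` attribute.
#'
#' @param coords samples x 3 matrix of MNI mm coordinates.
#' @param tmap a [volume3d()] t-score map.
#' @return Numeric vector of per-sample t-scores (`NA` = dropped), with
#'   attribute `n_dropped`.
#' @export
match_samples <- function(coords, tmap) {
  stopifnot(inherits(tmap, "volume3d"))
  coords <- as.matrix(coords)
  vox <- cbind(coords, 1) %*% t(solve(tmap$affine))
  idx <- round(vox[, 1:3, drop = FALSE])
  d <- dim(tmap$data)
  ok <- idx[, 1] >= 0 & idx[, 1] < d[1] &
        idx[, 2] >= 0 & idx[, 2] < d[2] &
        idx[, 3] >= 0 & idx[, 3] < d[3]
  out <- rep(NA_real_, nrow(coords))
  lin <- idx[ok, , drop = FALSE] + 1L
  vals <- tmap$data[lin]
  inmask <- tmap$mask[lin] & is.finite(vals)
  out[which(ok)[inmask]] <- vals[inmask]
  if (all(is.na(out))) stop("all samples fall outside the map mask")
  attr(out, "n_dropped") <- sum(is.na(out))
  out
}

#' Robust sigmoid normalization
#'
#' y = 1 / (1 + exp(-(x - median(x)) / (IQR(x) / 1.35))), optionally
#' min-max rescaled to \[0, 1\]. Median/IQR make the transform insensitive
#' to outliers; it is strictly monotone, so ranks are preserved.
#'
#' @param x numeric vector (>= 3 values, positive IQR).
#' @param rescale rescale the sigmoid output to \[0, 1\] (default TRUE).
#' @return Normalized vector.
#' @export
robust_sigmoid_norm <- function(x, rescale = TRUE) {
  if (length(x) < 3) stop("need at least 3 values")
  iqr <- stats::IQR(x)
  if (iqr <= 0) stop("zero interquartile range")
  y <- 1 / (1 + exp(-(x - stats::median(x)) / (iqr / 1.35)))
  if (rescale) y <- (y - min(y)) / (max(y) - min(y))
  y
}

#' Normalize every gene of an expression panel
#'
#' Applies [robust_sigmoid_norm()] per gene; genes with zero interquartile
#' range are dropped (names recorded in the `dropped_genes` attribute).
#'
#' @param panel an [expression_panel()].
#' @return A normalized [expression_panel()] with values in \[0, 1\].
#' @export
normalize_panel <- function(panel) {
  stopifnot(inherits(panel, "expression_panel"))
  ok <- apply(panel$X, 2, function(g) stats::IQR(g) > 0)
  Xn <- apply(panel$X[, ok, drop = FALSE], 2, robust_sigmoid_norm)
  out <- expression_panel(Xn, panel$coords, panel$genes[ok], panel$t)
  attr(out, "dropped_genes") <- panel$genes[!ok]
  out
}

#' Partial least squares regression by NIPALS (univariate response)
#'
#' Extracts components maximizing covariance between the (column-centered)
#' predictors and response, with deflation after each component. For a
#' univariate response the NIPALS inner loop is non-iterative.
#'
#' @param X samples x genes predictor matrix.
#' @param y response vector (voxel t-scores).
#' @param K number of components.
#' @return object of class `plsr_model`: unit-norm weights `W`, loadings
#'   `P`, response loadings `Q`, scores `TT`, per-component explained
#'   response sum of squares `SS`, and centering means.
#' @export
plsr_nipals <- function(X, y, K) {
  X <- as.matrix(X)
  n <- nrow(X); G <- ncol(X)
  stopifnot(length(y) == n)
  if (stats::sd(y) == 0) stop("zero-variance response")
  if (K > min(n - 1, G)) stop("K exceeds the rank of X")
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  W <- matrix(0, G, K); P <- matrix(0, G, K)
  Q <- numeric(K); TT <- matrix(0, n, K); SS <- numeric(K)
  for (a in seq_len(K)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) stop("K exceeds the effective rank of X")
    w <- w / nw
    t_ <- as.numeric(Xc %*% w)
    tt <- sum(t_^2)
    p_ <- as.numeric(crossprod(Xc, t_)) / tt
    q_ <- sum(yc * t_) / tt
    Xc <- Xc - tcrossprod(t_, p_)
    yc <- yc - q_ * t_
    W[, a] <- w; P[, a] <- p_; Q[a] <- q_; TT[, a] <- t_
    SS[a] <- q_^2 * tt
  }
  structure(list(W = W, P = P, Q = Q, TT = TT, SS = SS, K = K,
                 x_means = xm, y_mean = ym,
                 genes = colnames(X)),
            class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("NIPALS PLSR: %d component(s), %d genes\n", x$K, nrow(x$W)))
  invisible(x)
}

#' @export
coef.plsr_model <- function(object, ncomp = object$K, ...) {
  W <- object$W[, seq_len(ncomp), drop = FALSE]
  P <- object$P[, seq_len(ncomp), drop = FALSE]
  Q <- object$Q[seq_len(ncomp)]
  B <- W %*% solve(crossprod(P, W), Q)
  as.numeric(B)
}

#' @export
predict.plsr_model <- function(object, newX, ncomp = object$K, ...) {
  newX <- as.matrix(newX)
  B <- coef(object, ncomp = ncomp)
  object$y_mean + as.numeric(sweep(newX, 2, object$x_means) %*% B)
}

#' Variable importance in projection
#'
#' VIP_j = sqrt(G * sum_a SS_a w_ja^2 / sum_a SS_a) with SS_a the response
#' sum of squares explained by component a; mean squared VIP equals 1 by
#' construction.
#'
#' @param model a [plsr_nipals()] fit.
#' @return Numeric vector of VIP scores, one per gene.
#' @export
plsr_vip <- function(model) {
  stopifnot(inherits(model, "plsr_model"))
  G <- nrow(model$W)
  wt <- sweep(model$W^2, 2, model$SS, `*`)
  sqrt(G * rowSums(wt) / sum(model$SS))
}

# fold assignments: n x n_repeats matrix of fold ids 1..n_folds
cv_folds <- function(n, n_folds, n_repeats) {
  f <- replicate(n_repeats, sample(rep_len(seq_len(n_folds), n)))
  if (min(table(f[, 1])) < 2) stop("fold with < 2 samples")
  f
}

# mean out-of-fold Pearson r per candidate K over fixed fold assignments;
# y may be a matrix of response columns (rows of the result)
cv_r_grid <- function(X, y, grid, folds) {
  Y <- as.matrix(y)
  out <- .pls1_cv_r_cpp(X, Y, folds, as.integer(grid))
  if (ncol(Y) == 1L) as.numeric(out) else out
}

# plain-R reference for the cross-validation kernel (used in tests)
cv_r_grid_ref <- function(X, y, grid, folds) {
  kmax <- max(grid)
  r_mat <- matrix(NA_real_, ncol(folds), length(grid))
  for (rep_i in seq_len(ncol(folds))) {
    fold <- folds[, rep_i]
    pred <- matrix(NA_real_, length(y), length(grid))
    for (f in sort(unique(fold))) {
      test <- fold == f
      fit <- plsr_nipals(X[!test, , drop = FALSE], y[!test], kmax)
      for (gi in seq_along(grid))
        pred[test, gi] <- predict(fit, X[test, , drop = FALSE],
                                  ncomp = grid[gi])
    }
    r_mat[rep_i, ] <- apply(pred, 2, function(p) stats::cor(y, p))
  }
  colMeans(r_mat)
}

#' Cross-validated component selection
#'
#' Averages the out-of-fold Pearson correlation between observed and
#' predicted responses over repeated k-fold cross-validation, per candidate
#' component count; the best K maximizes the mean r (ties to the smallest K).
#'
#' @param X,y predictors and response.
#' @param grid candidate component counts (default 2:10).
#' @param n_repeats,n_folds cross-validation design (default five sets of
#'   five folds).
#' @param seed integer seed for fold assignment.
#' @return list: `grid`, `cv_r` (mean r per K), `best_k`.
#' @export
select_components_cv <- function(X, y, grid = 2:10, n_repeats = 5,
                                 n_folds = 5, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < 2 * n_folds) stop("need at least 2 * n_folds samples")
  set.seed(seed)
  folds <- cv_folds(nrow(X), n_folds, n_repeats)
  cvr <- cv_r_grid(X, y, grid, folds)
  names(cvr) <- grid
  list(grid = grid, cv_r = cvr, best_k = grid[which.max(cvr)])
}

#' Permutation significance of the cross-validated PLSR accuracy
#'
#' The observed statistic is the mean cross-validated Pearson r over
#' components 2-10 (or the supplied grid). Null statistics re-run the same
#' cross-validation on permuted responses (`random` mode) or on
#' variogram-matched spatially autocorrelated surrogates (`spatial` mode);
#' p-values use the plus-one rule.
#'
#' @param X,y predictors and response.
#' @param n_perm permutations per mode.
#' @param modes subset of `c("random", "spatial")`.
#' @param coords sample coordinates (required for `spatial`).
#' @param grid,n_repeats,n_folds cross-validation design.
#' @param seed integer seed.
#' @return list: `statistic` (observed mean cv r), `p` (named per mode),
#'   `null` (list of null statistic vectors).
#' @export
permutation_significance <- function(X, y, n_perm = 10000,
                                     modes = c("random", "spatial"),
                                     coords = NULL, grid = 2:10,
                                     n_repeats = 5, n_folds = 5, seed = 1L) {
  modes <- match.arg(modes, c("random", "spatial"), several.ok = TRUE)
  if ("spatial" %in% modes && is.null(coords))
    stop("spatial mode requires sample coordinates")
  X <- as.matrix(X)
  set.seed(seed)
  folds <- cv_folds(nrow(X), n_folds, n_repeats)
  observed <- mean(cv_r_grid(X, y, grid, folds))
  p <- numeric(0)
  null <- list()
  for (mode in modes) {
    ynull <- if (mode == "random") {
      replicate(n_perm, sample(y))
    } else {
      t(variogram_surrogates(y, coords, n_surr = n_perm,
                             seed = seed + 1L))
    }
    stats_null <- rowMeans(cv_r_grid(X, ynull, grid, folds))
    p[mode] <- (1 + sum(stats_null >= observed)) / (n_perm + 1)
    null[[mode]] <- stats_null
  }
  list(statistic = observed, p = p, null = null)
}

# binned empirical variogram: mean of 0.5 (y_i - y_j)^2 per distance bin
binned_variogram <- function(y, D, edges) {
  iu <- which(upper.tri(D))
  d <- D[iu]
  g <- 0.5 * (outer(y, y, `-`)^2)[iu]
  bin <- findInterval(d, edges, rightmost.closed = TRUE)
  out <- rep(NA_real_, length(edges) - 1)
  agg <- tapply(g, factor(bin, levels = seq_len(length(edges) - 1)), mean)
  out[as.integer(names(agg))] <- agg
  out
}

#' Variogram-matched spatially autocorrelated surrogates
#'
#' Each surrogate starts as a random permutation of the values, is smoothed
#' by Gaussian distance kernels over the k nearest neighbours, mixed with a
#' white-noise term whose weights are least-squares fitted so the binned
#' empirical variogram matches the original's, and finally re-ranked to the
#' original marginal distribution. These surrogates preserve the spatial
#' autocorrelation of the input while destroying its association with any
#' other map, giving a spatial null.
#'
#' @param y per-sample values.
#' @param coords samples x 3 coordinates (mm).
#' @param n_surr number of surrogates.
#' @param n_bins distance bins for the variogram fit (default 25).
#' @param k_nn smoothing neighbourhood size (default `min(30, n - 1)`).
#' @param seed integer seed.
#' @return n_surr x n matrix; each row is one surrogate map.
#' @export
variogram_surrogates <- function(y, coords, n_surr = 1000, n_bins = 25,
                                 k_nn = NULL, seed = 1L) {
  n <- length(y)
  if (n < 20) stop("need at least 20 samples")
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == n)
  D <- as.matrix(stats::dist(coords))
  if (max(D) <= 0) stop("degenerate coordinates")
  if (is.null(k_nn)) k_nn <- min(30, n - 1)
  set.seed(seed)
  edges <- seq(0, max(D) * (1 + 1e-9), length.out = n_bins + 1)
  gamma_obs <- binned_variogram(y, D, edges)

  # Gaussian kernel smoothing weights over the k nearest neighbours
  Wsm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(k_nn + 1)]    # includes self
    bw <- max(D[i, nb])
    w <- exp(-(D[i, nb] / (0.5 * bw))^2)
    Wsm[i, nb] <- w / sum(w)
  }
  ys_sorted <- sort(y)
  out <- matrix(NA_real_, n_surr, n)
  ok_bins <- which(is.finite(gamma_obs))
  for (s in seq_len(n_surr)) {
    yp <- sample(y)
    ysm <- as.numeric(Wsm %*% yp)
    eps <- stats::rnorm(n, 0, stats::sd(y))
    g_sm <- binned_variogram(ysm, D, edges)
    g_eps <- binned_variogram(eps, D, edges)
    A <- cbind(g_sm[ok_bins], g_eps[ok_bins])
    ab <- tryCatch(stats::coef(stats::lm.fit(A, gamma_obs[ok_bins])),
                   error = function(e) c(1, 0))
    ab[!is.finite(ab) | ab < 0] <- 0
    if (all(ab == 0)) ab <- c(1, 0)
    raw <- sqrt(ab[1]) * ysm + sqrt(ab[2]) * eps
    out[s, ] <- ys_sorted[rank(raw, ties.method = "first")]
  }
  out
}

#' Bootstrap VIP z-scores and gene ranking
#'
#' Each gene's z-score divides its VIP score by the standard error of VIP
#' over bootstrap resamples (rows of X with their t-scores resampled with
#' replacement, or t-scores alone with `paired = FALSE`). VIP is unsigned,
#' so a sign is attached from the gene's Pearson correlation with the
#' t-scores (or from its first-component weight). Genes are ranked by z in
#' descending order (rank 1 = most associated with higher chi in patients)
#' and ascending order.
#'
#' @param X,y predictors and response.
#' @param K component count (from [select_components_cv()]).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @param sign_by `"cor"` (default) or `"weight"`.
#' @param paired resample X rows with their y (TRUE, default) or y only.
#' @param brain_genes optional character vector of brain-expressed genes;
#'   genes absent from it are flagged (`brain_expressed = FALSE`).
#' @return data.frame of class `ranked_gene_list`: `gene`, `vip`, `se`,
#'   `z`, `rank_desc`, `rank_asc`, `brain_expressed`.
#' @export
bootstrap_vip_z <- function(X, y, K, n_boot = 10000, seed = 1L,
                            sign_by = c("cor", "weight"), paired = TRUE,
                            brain_genes = NULL) {
  sign_by <- match.arg(sign_by)
  X <- as.matrix(X)
  n <- nrow(X); G <- ncol(X)
  fit <- plsr_nipals(X, y, K)
  vip <- plsr_vip(fit)
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, G)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    bf <- tryCatch({
      if (paired) plsr_nipals(X[idx, , drop = FALSE], y[idx], K)
      else plsr_nipals(X, y[idx], K)
    }, error = function(e) NULL)
    if (!is.null(bf)) boot[b, ] <- plsr_vip(bf)
  }
  se <- apply(boot, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(se) | se == 0))
    stop("zero bootstrap standard error; increase n_boot")
  sgn <- if (sign_by == "cor") {
    sign(as.numeric(stats::cor(X, y)))
  } else {
    sign(fit$W[, 1])
  }
  sgn[sgn == 0] <- 1
  z <- sgn * vip / se
  genes <- colnames(X)
  if (is.null(genes)) genes <- sprintf("G%04d", seq_len(G))
  out <- data.frame(gene = genes, vip = vip, se = se, z = z,
                    rank_desc = rank(-z, ties.method = "first"),
                    rank_asc = rank(z, ties.method = "first"),
                    brain_expressed = if (is.null(brain_genes)) TRUE
                                      else genes %in% brain_genes,
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_gene_list", "data.frame")
  out
}

#' Export a ranked gene list (one symbol per line)
#'
#' Writes plain gene symbols ordered by z (descending or ascending),
#' dropping genes not flagged as brain-expressed, in the single-ranked-list
#' format expected by GO enrichment tools.
#'
#' @param ranked a [bootstrap_vip_z()] result.
#' @param path output file.
#' @param order `"descending"` or `"ascending"`.
#' @param brain_only drop genes with `brain_expressed = FALSE` (default TRUE).
#' @return `path`, invisibly.
#' @export
export_ranked_list <- function(ranked, path,
                               order = c("descending", "ascending"),
                               brain_only = TRUE) {
  order <- match.arg(order)
  df <- ranked
  if (brain_only) df <- df[df$brain_expressed, , drop = FALSE]
  ord <- if (order == "descending") base::order(df$rank_desc)
         else base::order(df$rank_asc)
  writeLines(df$gene[ord], path)
  invisible(path)
}

#' Cell-type median-rank deviation test
#'
#' With genes ranked 1..G descending by z (rank 1 = most associated with
#' higher chi in patients), each cell type's deviation is the median rank
#' of its genes minus the list center (G + 1) / 2. Negative deviation ties
#' the cell type to higher chi in patients, positive to lower chi.
#' Significance is two-sided against deviations of randomly selected gene
#' sets of the same size.
#'
#' @param ranked a [bootstrap_vip_z()] result.
#' @param cell_lists named list of character vectors of genes per cell type.
#' @param n_perm random same-size gene sets per cell type.
#' @param seed integer seed.
#' @return data.frame of class `cell_type_result`: `cell_type`, `n_genes`
#'   (intersection size), `median_rank`, `deviation`, `p`.
#' @export
cell_type_rank_test <- function(ranked, cell_lists, n_perm = 10000,
                                seed = 1L) {
  G <- nrow(ranked)
  center <- (G + 1) / 2
  rk <- ranked$rank_desc
  names(rk) <- ranked$gene
  set.seed(seed)
  out <- data.frame(cell_type = names(cell_lists),
                    n_genes = NA_integer_, median_rank = NA_real_,
                    deviation = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(cell_lists)) {
    genes <- intersect(cell_lists[[i]], ranked$gene)
    m <- length(genes)
    if (m == 0) stop("empty intersection for cell type ",
                     names(cell_lists)[i])
    obs <- stats::median(rk[genes]) - center
    null <- replicate(n_perm,
                      stats::median(sample.int(G, m)) - center)
    out$n_genes[i] <- m
    out$median_rank[i] <- obs + center
    out$deviation[i] <- obs
    out$p[i] <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
  }
  class(out) <- c("cell_type_result", "data.frame")
  out
}
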