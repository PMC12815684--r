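test_that("samples are matched to the nearest voxel center", {
  set.seed(40)
  d <- c(6, 6, 6)
  arr <- array(stats::rnorm(prod(d)), d)
  aff <- diag(4); aff[1:3, 4] <- c(-2, -2, -2)
  tmap <- volume3d(arr, affine = aff, units = "t")

  # exactly at the center of voxel (3,2,4) zero-based -> mm (1, 0, 2)
  expect_equal(match_samples(rbind(c(1, 0, 2)), tmap)[1], arr[4, 3, 5])
  # 0.4 mm from A beats 0.9 mm from B
  expect_equal(match_samples(rbind(c(1.4, 0, 2)), tmap)[1], arr[4, 3, 5])

  # brute-force nearest-center oracle
  coords <- matrix(stats::runif(60, -2.4, 3.2), ncol = 3)
  got <- match_samples(coords, tmap)
  centers <- as.matrix(expand.grid(i = 0:5, j = 0:5, k = 0:5))
  mm <- sweep(centers, 2, c(-2, -2, -2), `+`)
  for (s in seq_len(nrow(coords))) {
    nn <- which.min(rowSums(sweep(mm, 2, coords[s, ])^2))
    expect_equal(got[s], arr[centers[nn, 1] + 1, centers[nn, 2] + 1,
                             centers[nn, 3] + 1])
  }
  out <- match_samples(rbind(c(0, 0, 0), c(500, 500, 500)), tmap)
  expect_equal(attr(out, "n_dropped"), 1)
})

test_that("robust sigmoid normalization matches its formula and preserves ranks", {
  set.seed(41)
  for (i in 1:100) {
    x <- stats::rnorm(sample(10:50, 1), sd = stats::runif(1, 0.5, 5))
    got <- robust_sigmoid_norm(x, rescale = FALSE)
    want <- 1 / (1 + exp(-(x - stats::median(x)) / (stats::IQR(x) / 1.35)))
    expect_equal(got, want, tolerance = 1e-12)
  }
  x <- sort(stats::rnorm(20))
  expect_true(all(diff(robust_sigmoid_norm(x)) > 0))
  xmed <- c(1, 2, 3, 4, 5)
  expect_equal(robust_sigmoid_norm(xmed, rescale = FALSE)[3], 0.5)
  # location/scale equivariance of median and IQR
  expect_equal(robust_sigmoid_norm(3 * x + 7), robust_sigmoid_norm(x))
  expect_error(robust_sigmoid_norm(rep(1, 10)), "interquartile")
  expect_error(robust_sigmoid_norm(c(1, 2)), "3 values")

  pan <- expression_panel(cbind(g1 = stats::rnorm(10), g2 = rep(2, 10)),
                          matrix(stats::rnorm(30), 10))
  npan <- normalize_panel(pan)
  expect_identical(attr(npan, "dropped_genes"), "g2")
  expect_true(all(npan$X >= 0 & npan$X <= 1))
})

test_that("NIPALS recovers exact low-rank signals and the analytic first direction", {
  set.seed(42)
  # rank-3 predictor matrix: 3 components reproduce y exactly
  Q <- qr.Q(qr(matrix(stats::rnorm(50 * 3), 50)))
  Z <- matrix(stats::rnorm(30 * 3), 30)
  X <- Z %*% t(Q)
  y <- as.numeric(Z %*% c(1, -2, 0.5))
  fit <- plsr_nipals(X, y, 3)
  expect_gt(stats::cor(predict(fit, X), y), 1 - 1e-8)

  Xr <- matrix(stats::rnorm(20 * 50), 20)
  yr <- stats::rnorm(20)
  f1 <- plsr_nipals(Xr, yr, 1)
  v <- crossprod(sweep(Xr, 2, colMeans(Xr)), yr - mean(yr))
  v <- v / sqrt(sum(v^2))
  expect_gt(abs(sum(f1$W[, 1] * v)), 1 - 1e-10)

  expect_error(plsr_nipals(Xr, yr, 25), "rank")
  expect_error(plsr_nipals(Xr, rep(1, 20), 2), "zero-variance")
})

test_that("NIPALS predictions match an independent PLS implementation", {
  set.seed(43)
  X <- matrix(stats::rnorm(20 * 50), 20,
              dimnames = list(NULL, sprintf("g%02d", 1:50)))
  y <- stats::rnorm(20)
  fit <- plsr_nipals(X, y, 5)
  ref <- mixOmics::pls(X, y, ncomp = 5, mode = "regression", scale = FALSE)
  refp <- predict(ref, X)$predict
  for (k in 1:5)
    expect_lt(max(abs(predict(fit, X, ncomp = k) - refp[, 1, k])), 1e-6)
})

test_that("explained response variance is non-decreasing in component count", {
  set.seed(44)
  X <- matrix(stats::rnorm(40 * 30), 40)
  y <- stats::rnorm(40)
  fit <- plsr_nipals(X, y, 8)
  expect_true(all(fit$SS >= -1e-12))
  r2 <- sapply(1:8, function(k) stats::cor(predict(fit, X, ncomp = k), y)^2)
  expect_true(all(diff(r2) >= -1e-10))
})

test_that("the C++ cross-validation kernel agrees with the plain-R path", {
  set.seed(45)
  X <- matrix(stats::rnorm(40 * 60), 40)
  y <- stats::rnorm(40)
  folds <- chisep:::cv_folds(40, 5, 5)
  expect_equal(chisep:::cv_r_grid(X, y, 2:10, folds),
               chisep:::cv_r_grid_ref(X, y, 2:10, folds),
               tolerance = 1e-10)
})

test_that("component selection is seeded and behaves under null and 3-component signals", {
  set.seed(46)
  X <- matrix(stats::rnorm(50 * 60), 50)
  y <- stats::rnorm(50)
  s1 <- select_components_cv(X, y, seed = 3)
  s2 <- select_components_cv(X, y, seed = 3)
  expect_identical(s1, s2)

  # pure noise: the best cross-validated accuracy stays near zero
  best <- sapply(1:50, function(s) {
    set.seed(s)
    Xn <- matrix(stats::rnorm(60 * 80), 60)
    max(select_components_cv(Xn, stats::rnorm(60), seed = s + 100)$cv_r)
  })
  expect_lt(abs(mean(best)), 0.1)

  # three latent components with distinct scales: K = 3 is recovered
  tr <- expression_truth(n_genes = 200, genes_per_component = 15,
                         corr_length_mm = 0, loading = c(4, 2, 1),
                         component_betas = c(1, 1, 1),
                         gene_noise_sd = 0.4, noise_sd = 0.4)
  k3 <- sapply(1:50, function(s) {
    sim <- simulate_expression(100, tr, seed = s)
    select_components_cv(sim$panel$X, sim$panel$t, seed = s + 1000)$best_k
  })
  expect_gte(mean(k3 == 3), 0.6)
})

test_that("surrogates keep the marginal distribution and the variogram", {
  set.seed(47)
  n <- 60
  coords <- matrix(stats::runif(n * 3, -20, 20), n)
  L <- chisep:::se_chol(coords, 12)
  y <- as.numeric(L %*% stats::rnorm(n)) + 0.2 * stats::rnorm(n)
  sur <- variogram_surrogates(y, coords, n_surr = 20, seed = 1)
  expect_identical(variogram_surrogates(y, coords, n_surr = 20, seed = 1), sur)
  for (i in 1:20) expect_equal(sort(sur[i, ]), sort(y))
  expect_error(variogram_surrogates(y[1:10], coords[1:10, ]), "20 samples")
})

test_that("permutation significance hits the attainable minimum under strong signal", {
  set.seed(48)
  tr <- expression_truth(n_genes = 100, genes_per_component = 10,
                         loading = c(4, 2, 1), gene_noise_sd = 0.2,
                         noise_sd = 0.2)
  sim <- simulate_expression(60, tr, seed = 2)
  ps <- permutation_significance(sim$panel$X, sim$panel$t, n_perm = 100,
                                 coords = sim$panel$coords, seed = 5)
  expect_equal(unname(ps$p["random"]), 1 / 101)
  expect_equal(unname(ps$p["spatial"]), 1 / 101)
  expect_error(permutation_significance(sim$panel$X, sim$panel$t,
                                        n_perm = 10, modes = "spatial"),
               "coordinates")
})

test_that("bootstrap VIP z-scores rank a planted gene first and are normalized", {
  set.seed(49)
  vip_means <- sapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(stats::rnorm(40 * 60), 40)
    mean(plsr_vip(plsr_nipals(X, stats::rnorm(40), 3))^2)
  })
  expect_true(all(vip_means > 0.8 & vip_means < 1.2))

  tr <- expression_truth(n_genes = 50, n_components = 1,
                         genes_per_component = 1, gene_noise_sd = 0,
                         noise_sd = 0)
  sim <- simulate_expression(40, tr, seed = 3)
  rk <- bootstrap_vip_z(sim$panel$X, sim$panel$t, K = 1, n_boot = 100,
                        seed = 4)
  expect_equal(rk$rank_desc[1], 1L)
  expect_true(all(sort(rk$rank_desc) == 1:50))
  expect_error(bootstrap_vip_z(sim$panel$X, sim$panel$t, K = 1, n_boot = 1),
               "standard error")
})

test_that("ranked-list export is ordered and honours the brain-expressed flag", {
  set.seed(50)
  X <- matrix(stats::rnorm(30 * 60), 30,
              dimnames = list(NULL, sprintf("G%03d", 1:60)))
  y <- stats::rnorm(30)
  rk <- bootstrap_vip_z(X, y, K = 2, n_boot = 50, seed = 1,
                        brain_genes = sprintf("G%03d", 1:40))
  path <- tempfile(fileext = ".txt")
  export_ranked_list(rk, path)
  lines <- readLines(path)
  expect_length(lines, 40)
  zs <- rk$z[match(lines, rk$gene)]
  expect_true(all(diff(zs) < 0))
})

test_that("cell-type deviations hit the closed-form extreme and honest p-values", {
  G <- 501
  ranked <- data.frame(gene = sprintf("g%03d", 1:G), z = seq(G, 1),
                       rank_desc = 1:G)
  class(ranked) <- c("ranked_gene_list", "data.frame")
  k <- 25
  top <- cell_type_rank_test(ranked, list(top = ranked$gene[1:k]),
                             n_perm = 200, seed = 1)
  expect_equal(top$deviation, (k + 1) / 2 - (G + 1) / 2)
  expect_gt(top$p, 0)
  expect_error(cell_type_rank_test(ranked, list(none = "absent")), "empty")
})

test_that("causal genes outrank noise genes through the whole pipeline", {
  tr <- expression_truth(n_genes = 500, n_components = 3,
                         genes_per_component = 10, loading = c(3, 2, 1),
                         gene_noise_sd = 0.5, noise_sd = 0.5)
  sim <- simulate_expression(201, tr, seed = 8)
  rk <- bootstrap_vip_z(sim$panel$X, sim$panel$t, K = 3, n_boot = 60,
                        seed = 9)
  causal <- !is.na(tr$comp_of)
  wt <- stats::wilcox.test(abs(rk$z[causal]), abs(rk$z[!causal]),
                           alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})
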