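make_vols <- function(chi, fa, theta) {
  list(chi = volume3d(chi, units = "ppb"),
       fa = volume3d(fa, units = "fa"),
       theta = volume3d(theta, units = "radians"))
}

test_that("voxel retention applies the FA and censoring rules", {
  d <- c(5, 5, 5)
  chi <- array(0, d); fa <- array(0.5, d); th <- array(0.3, d)
  v <- make_vols(chi, fa, th)
  expect_warning(
    tvs <- prepare_wm_voxels(v$chi, v$fa, v$theta, erode_wm_mm = 0,
                             erode_tract = FALSE),
    "no voxels")
  expect_true(tvs$empty)

  # toy censoring: chi (-120, -50, 0, 25, 40) with printed bounds keeps 3
  chi2 <- array(25, d)
  chi2[1:5, 1, 1] <- c(-120, -50, 0, 25, 40)
  fa2 <- array(0.8, d)
  keepers <- prepare_wm_voxels(volume3d(chi2, units = "ppb"),
                               volume3d(fa2), volume3d(th),
                               erode_wm_mm = 0, erode_tract = FALSE)
  expect_equal(sort(unique(keepers$chi)), c(-50, 0, 25))
  expect_equal(sum(keepers$chi %in% c(-120, 40)), 0)
})

test_that("retained voxel count equals a brute-force triple filter", {
  set.seed(20)
  d <- c(8, 8, 8)
  chi <- array(stats::rnorm(prod(d), -20, 60), d)
  fa <- array(stats::runif(prod(d), 0.3, 1), d)
  th <- array(stats::runif(prod(d), 0, pi / 2), d)
  wm <- array(stats::runif(prod(d)) > 0.2, d)
  v <- make_vols(chi, fa, th)
  tvs <- suppressWarnings(
    prepare_wm_voxels(v$chi, v$fa, v$theta, wm_mask = wm,
                      erode_wm_mm = 0, erode_tract = FALSE))
  n_brute <- 0
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    if (wm[i, j, k] && fa[i, j, k] >= 0.6 &&
        chi[i, j, k] >= -110 && chi[i, j, k] <= 30)
      n_brute <- n_brute + 1
  }
  expect_equal(length(tvs$chi), n_brute)
})

test_that("theta binning yields equally populated, deterministic bins", {
  tv <- simulate_tract(10, -30, 100, noise_sd = 2, seed = 21)
  b <- bin_by_theta(tv)
  expect_equal(b$n, rep(10L, 10))
  expect_true(all(diff(b$mean_theta) > 0))

  tv2 <- simulate_tract(10, -30, 103, noise_sd = 2, seed = 22)
  b2 <- bin_by_theta(tv2)
  expect_equal(sort(unique(b2$n)), c(10L, 11L))
  expect_equal(b2$n, c(11L, 11L, 11L, rep(10L, 7)))
  expect_equal(sum(b2$n), 103)

  # per-bin means against an explicit partition
  ord <- order(tv2$theta)
  grp <- rep(1:10, times = b2$n)
  expect_equal(b2$mean_chi,
               as.numeric(tapply(tv2$chi[ord], grp, mean)))
  expect_equal(b2$mean_theta,
               as.numeric(tapply(tv2$theta[ord], grp, mean)))

  expect_error(bin_by_theta(simulate_tract(1, 0, 20, seed = 1), 21), "fewer")
})

test_that("the anisotropy fit is exact on noiseless tracts and matches normal equations", {
  tv <- simulate_tract(20, -40, 2000, noise_sd = 0, seed = 23)
  fit <- fit_tract(tv)
  expect_equal(fit$delta_chi, 20, tolerance = 1e-10)
  expect_equal(fit$chi_iso, -40, tolerance = 1e-10)
  expect_equal(fit$df, 8)

  tvn <- simulate_tract(13, -35, 1000, noise_sd = 5, seed = 24)
  b <- bin_by_theta(tvn)
  f <- fit_delta_chi(b)
  # closed-form normal equations oracle
  x <- b$mean_cos2; y <- b$mean_chi
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(f$delta_chi, slope, tolerance = 1e-12)
  expect_equal(f$chi_iso, mean(y) - slope * mean(x), tolerance = 1e-12)

  bc <- b; bc$mean_theta <- rep(0.5, 10); bc$mean_cos2 <- rep(0.3, 10)
  expect_error(fit_delta_chi(bc), "collinear")
})

test_that("chi decreasing with angle gives positive anisotropy", {
  theta <- seq(0.05, pi / 2 - 0.05, length.out = 200)
  tv <- tract_voxel_set(chi = 15 * cos(theta)^2 - 30, theta = theta,
                        fa = rep(0.8, 200))
  expect_gt(fit_tract(tv)$delta_chi, 0)
})

test_that("the fitted anisotropy is unbiased with nominal CI coverage", {
  res <- sapply(1:200, function(s) {
    f <- fit_tract(simulate_tract(13.35, -40, 2000, noise_sd = 5, seed = s))
    ci <- summary(f)$ci95
    c(est = f$delta_chi, hit = ci[1] <= 13.35 && 13.35 <= ci[2])
  })
  expect_gte(mean(res["hit", ]), 0.9)
  expect_lt(abs(mean(res["est", ]) - 13.35),
            3 * stats::sd(res["est", ]) / sqrt(200))
})

test_that("tract selection keeps significantly positive anisotropy only", {
  fits <- list(
    splenium = structure(list(delta_chi = 13.35, p = 0.014), class = "anisofit"),
    cst = structure(list(delta_chi = -25.77, p = 0.014), class = "anisofit"),
    slf = structure(list(delta_chi = 9.93, p = 4e-04), class = "anisofit"),
    atr = structure(list(delta_chi = 5.2, p = 0.31), class = "anisofit"))
  expect_identical(select_tracts(fits), c("splenium", "slf"))
  expect_identical(select_tracts(list()), character(0))
  expect_warning(sel <- select_tracts(fits["cst"]), "no tract")
  expect_identical(sel, character(0))
})

test_that("participant anisotropy averages the selected tracts", {
  mk <- function(d) structure(list(delta_chi = d), class = "anisofit")
  sf <- list(a = mk(10), b = mk(20), c = mk(30), d = mk(99))
  expect_equal(as.numeric(participant_delta_chi(sf, c("a", "b", "c"))), 20)
  expect_equal(as.numeric(participant_delta_chi(sf, "b")), 20)
  one <- participant_delta_chi(sf["a"], c("a", "c"))
  expect_equal(as.numeric(one), 10)
  expect_identical(attr(one, "dropped"), "c")
  expect_error(participant_delta_chi(sf["a"], "c"), "no selected tract")

  # brute-force mean over the available/selected intersection
  sel <- c("a", "c", "d")
  avail <- intersect(sel, names(sf))
  expect_equal(as.numeric(participant_delta_chi(sf, sel)),
               mean(sapply(sf[avail], function(f) f$delta_chi)))
})
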