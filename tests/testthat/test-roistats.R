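test_that("Cohen's d follows the pooled-SD formula", {
  expect_equal(cohens_d(10, 2, 30, 10, 3, 30), 0)
  # independent oracle: direct pooled-SD arithmetic
  m1 <- 5; s1 <- 1.5; n1 <- 12; m2 <- 7; s2 <- 2.5; n2 <- 18
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  expect_equal(cohens_d(m1, s1, n1, m2, s2, n2), (m2 - m1) / sp)
  expect_error(cohens_d(1, 0, 10, 2, 1, 10), "positive")
  expect_error(cohens_d(1, 1, 1, 2, 1, 10), ">= 2")
})

test_that("two-sample t handles identity, matches the textbook formula, and orients with d", {
  x <- c(1, 2, 3, 4, 5)
  r <- two_sample_t(x, x)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  a <- c(2.1, 3.4, 1.9, 4.2, 2.8)
  b <- c(3.0, 4.1, 3.8, 5.2, 4.4)
  # hand-computed pooled t
  sp2 <- ((4) * stats::var(a) + (4) * stats::var(b)) / 8
  t_hand <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  r2 <- two_sample_t(a, b)
  expect_equal(r2$t, t_hand, tolerance = 1e-10)
  expect_equal(r2$df, 8)
  expect_equal(sign(r2$d), sign(r2$t))
  expect_error(two_sample_t(rep(1, 3), rep(1, 3)), "zero variance")

  # Student and Welch coincide when n and s are equal
  rs <- two_sample_t(a, a + 1, "student")
  rw <- two_sample_t(a, a + 1, "welch")
  expect_equal(rs$t, rw$t)
  expect_equal(rs$p, rw$p)
})

test_that("the t-test is calibrated under the null", {
  set.seed(10)
  rej <- mean(replicate(10000, {
    two_sample_t(stats::rnorm(30), stats::rnorm(30))$p < 0.05
  }))
  expect_gte(rej, 0.04)
  expect_lte(rej, 0.06)
})

test_that("BH adjustment matches the step-up definition and is order-invariant", {
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  expect_equal(bh_fdr(rep(0.3, 5)), rep(0.3, 5))

  brute_bh <- function(p) {
    m <- length(p)
    ord <- order(p)
    adj <- numeric(m)
    for (i in seq_len(m)) {
      vals <- sapply(i:m, function(j) m / j * p[ord[j]])
      adj[ord[i]] <- min(1, min(vals))
    }
    adj
  }
  set.seed(11)
  for (i in 1:10) {
    p <- stats::runif(sample(3:20, 1))
    expect_equal(bh_fdr(p), brute_bh(p))
    expect_true(all(bh_fdr(p) >= p))
    perm <- sample(length(p))
    expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  }
})

test_that("clinical correlations find exact linear relations and flag degeneracies", {
  co <- simulate_cohort(cohort_config(seed = 3))
  co$panss_total <- 2 * co$chi_whole_subcortex + 5
  co$panss_total[co$group == "control"] <- NA
  res <- clinical_correlations(co, scores = c("panss_total", "bnss"))
  row <- res[res$region == "whole_subcortex" & res$score == "panss_total", ]
  expect_equal(row$r, 1, tolerance = 1e-12)

  co$cgi_s[co$group == "patient"] <- 4
  res2 <- clinical_correlations(co, scores = "cgi_s")
  expect_true(all(res2$flag == "degenerate_variance"))
  expect_true(all(is.na(res2$r)))

  co$bnss[co$group == "patient"][-(1:2)] <- NA
  res3 <- clinical_correlations(co, scores = "bnss")
  expect_true(all(res3$flag == "too_few_pairs"))
})

test_that("null clinical correlations are centered at zero", {
  set.seed(12)
  rs <- sapply(1:50, function(s) {
    co <- simulate_cohort(cohort_config(seed = s))
    res <- clinical_correlations(co, scores = "bnss",
                                 regions = "whole_subcortex")
    res$r
  })
  expect_lt(abs(mean(rs)), 3 * stats::sd(rs) / sqrt(50))
})

test_that("Huber regression is exact on noiseless data and equals OLS when residuals are bounded", {
  x <- seq(-2, 2, length.out = 30)
  X <- cbind(1, x)
  fit <- huber_regress(1 + 2 * x, X)
  expect_equal(unname(coef(fit)), c(1, 2), tolerance = 1e-12)

  # clean data: all scaled residuals inside the Huber threshold -> weights
  # are all 1 and the M-estimate is exactly least squares
  set.seed(13)
  e <- sample(c(-1, 1), 80, TRUE) * stats::runif(80, 0.8, 1)
  xr <- stats::rnorm(80)
  Xr <- cbind(1, xr)
  yr <- 1 + 2 * xr + e
  expect_lt(max(abs(coef(huber_regress(yr, Xr)) - qr.coef(qr(Xr), yr))), 1e-6)

  expect_error(huber_regress(yr, cbind(Xr, xr)), "rank-deficient")
  expect_error(huber_regress(yr[1:2], Xr[1:2, ]), "more observations")
})

test_that("Huber regression agrees with an independent M-estimation implementation", {
  set.seed(14)
  x <- stats::rnorm(100)
  y <- 1 + 2 * x + stats::rnorm(100)
  y[1:10] <- y[1:10] + 25
  fit <- huber_regress(y, cbind(1, x))
  ref <- MASS::rlm(y ~ x, k = 1.345, acc = 1e-8, maxit = 100)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(stats::vcov(ref)))),
               tolerance = 1e-4)
})

test_that("Huber beats OLS under gross contamination at high-leverage points", {
  set.seed(15)
  better <- replicate(200, {
    n <- 100
    x <- stats::rnorm(n)
    y <- 1 + 2 * x + stats::rnorm(n)
    out <- order(x, decreasing = TRUE)[1:(n / 10)]
    y[out] <- y[out] - 30
    X <- cbind(1, x)
    abs(coef(huber_regress(y, X))[2] - 2) < abs(qr.coef(qr(X), y)[2] - 2)
  })
  expect_gte(mean(better), 0.95)
})

test_that("the final adjusted model has the 9-term design and a no-op imputation path", {
  co <- simulate_cohort(cohort_config(seed = 5))
  fm <- final_model(co)
  expect_length(coef(fm), 9)
  expect_identical(names(coef(fm))[1:2],
                   c("(Intercept)", "Schizophrenia Group Status"))

  # complete data: imputation changes nothing
  cfg <- cohort_config(n_md_control = 80L, n_md_patient = 79L, seed = 6)
  co2 <- simulate_cohort(cfg)
  fm2 <- final_model(co2)
  raw <- huber_regress(co2$chi_whole_subcortex,
                       chisep:::final_model_design(co2))
  expect_equal(coef(fm2), coef(raw))

  co3 <- co
  co3$wm_delta_chi[co3$group == "control"] <- NA
  expect_error(final_model(co3), "entirely missing")
})

test_that("the final model recovers a known group effect with nominal CI coverage", {
  rs <- roi_reference_stats()
  rs$mean_patient[rs$region == "whole_subcortex" & rs$metric == "chi"] <-
    28.83 - 1.6
  dc <- list(mean_control = 20, sd_control = 8,
             mean_patient = 20, sd_patient = 8)
  hits <- sapply(1:200, function(s) {
    co <- simulate_cohort(cohort_config(roi_stats = rs, delta_chi = dc,
                                        seed = s))
    sm <- summary(final_model(co))
    sm$ci_low[2] <= -1.6 && -1.6 <= sm$ci_high[2]
  })
  expect_gte(mean(hits), 0.9)
})
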