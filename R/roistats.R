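#' Cohen's d from group summary statistics
#'
#' Pooled-SD standardized mean difference, d = (m2 - m1) / s_pooled with
#' s_pooled^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2). With group 1
#' the controls, a negative d means the metric is lower in patients.
#'
#' @param m1,s1,n1 control mean, SD, size.
#' @param m2,s2,n2 patient mean, SD, size.
#' @return Cohen's d (numeric scalar).
#' @export
cohens_d <- function(m1, s1, n1, m2, s2, n2) {
  if (s1 <= 0 || s2 <= 0) stop("SDs must be positive")
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  (m2 - m1) / sp
}

#' Two-sample t-test with effect size
#'
#' Independent-sample t-test (pooled-variance Student by default, Welch by
#' flag) of patients vs controls. The t statistic is oriented as patients
#' minus controls, so its sign matches Cohen's d.
#'
#' @param values1 control values.
#' @param values2 patient values.
#' @param variant `"student"` or `"welch"`.
#' @param metric,region optional annotations carried in the result.
#' @return list of class `group_comparison`: `d`, `t`, `df`, `p`, group
#'   means/SDs/ns, `p_adj` (NA until FDR correction).
#' @export
two_sample_t <- function(values1, values2, variant = c("student", "welch"),
                         metric = NA_character_, region = NA_character_) {
  variant <- match.arg(variant)
  values1 <- values1[is.finite(values1)]
  values2 <- values2[is.finite(values2)]
  if (length(values1) < 2 || length(values2) < 2)
    stop("each group needs >= 2 finite values")
  if (stats::sd(values1) == 0 && stats::sd(values2) == 0)
    stop("zero variance in both groups")
  tt <- stats::t.test(values2, values1, var.equal = variant == "student")
  d <- cohens_d(mean(values1), stats::sd(values1), length(values1),
                mean(values2), stats::sd(values2), length(values2))
  structure(list(metric = metric, region = region, d = d,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, p_adj = NA_real_,
                 mean1 = mean(values1), sd1 = stats::sd(values1),
                 n1 = length(values1),
                 mean2 = mean(values2), sd2 = stats::sd(values2),
                 n2 = length(values2), variant = variant),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group comparison%s: d = %.2f, t(%.1f) = %.2f, p = %.3g\n",
              if (is.na(x$region)) "" else paste0(" [", x$region, "]"),
              x$d, x$df, x$t, x$p))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone-enforced, capped at 1), preserving
#' input order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Correlations between a regional metric and clinical scores
#'
#' Pearson correlations within the patient group between each region's
#' metric value and each clinical score, using pairwise-complete
#' observations, with BH-FDR correction across the whole family.
#' Pairs with fewer than 3 complete observations or zero variance are
#' returned as `NA` with a flag.
#'
#' @param cohort a [simulate_cohort()]-style data.frame with `group` and
#'   `<metric>_<region>` columns.
#' @param metric metric prefix (default `"chi"`).
#' @param scores clinical score column names.
#' @param regions region names; defaults to every `<metric>_*` column.
#' @return data.frame with `region`, `score`, `n`, `r`, `p`, `p_adj`, `flag`.
#' @export
clinical_correlations <- function(cohort, metric = "chi",
                                  scores = c("panss_total", "panss_positive",
                                             "panss_negative", "panss_general",
                                             "bnss", "cgi_s",
                                             "illness_duration"),
                                  regions = NULL) {
  pat <- cohort[cohort$group == "patient", , drop = FALSE]
  pre <- paste0(metric, "_")
  if (is.null(regions)) {
    cols <- grep(paste0("^", pre), names(cohort), value = TRUE)
    regions <- sub(pre, "", cols)
  }
  out <- expand.grid(region = regions, score = scores,
                     stringsAsFactors = FALSE)
  out$n <- NA_integer_; out$r <- NA_real_; out$p <- NA_real_
  out$flag <- ""
  for (i in seq_len(nrow(out))) {
    x <- pat[[paste0(pre, out$region[i])]]
    y <- pat[[out$score[i]]]
    ok <- is.finite(x) & is.finite(y)
    out$n[i] <- sum(ok)
    if (sum(ok) < 3) { out$flag[i] <- "too_few_pairs"; next }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      out$flag[i] <- "degenerate_variance"; next
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    out$r[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
  }
  out$p_adj <- NA_real_
  ok <- is.finite(out$p)
  out$p_adj[ok] <- bh_fdr(out$p[ok])
  out
}

huber_psi <- function(u, k) pmax(-k, pmin(k, u))

#' Huber robust linear regression
#'
#' M-estimation with the Huber loss, fitted by iteratively reweighted least
#' squares. Scale is re-estimated each iteration by the normalized median
#' absolute deviation of the residuals. Standard errors use the Huber
#' sandwich-type asymptotic formula, with two-sided p-values on n - p
#' degrees of freedom.
#'
#' @param y response vector.
#' @param X design matrix (include the intercept column yourself, or use
#'   `add_intercept = TRUE`).
#' @param k Huber tuning constant (1.345 gives 95% Gaussian efficiency).
#' @param maxit maximum IRLS iterations.
#' @param tol convergence when the largest coefficient change is below this.
#' @param add_intercept prepend a column of ones.
#' @return list of class `huber_fit` with `coefficients`, `se`, `t`, `p`,
#'   `df`, `scale`, `weights`, `fitted`, `residuals`, `converged`,
#'   `iterations`.
#' @export
huber_regress <- function(y, X, k = 1.345, maxit = 100L, tol = 1e-8,
                          add_intercept = FALSE) {
  X <- as.matrix(X)
  if (add_intercept) X <- cbind(`(Intercept)` = 1, X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (n <= p) stop("need more observations than parameters")
  if (qr(X)$rank < p) stop("rank-deficient design")
  beta <- qr.coef(qr(X), y)
  converged <- FALSE
  it <- 0L
  s <- 1
  for (it in seq_len(maxit)) {
    r <- y - as.numeric(X %*% beta)
    s <- stats::median(abs(r)) / 0.6745
    if (s < 1e-12) { converged <- TRUE; break }
    w <- pmin(1, k * s / abs(r))
    w[abs(r) < 1e-300] <- 1
    sw <- sqrt(w)
    beta_new <- qr.coef(qr(X * sw), y * sw)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new; converged <- TRUE; break
    }
    beta <- beta_new
  }
  if (!converged && s >= 1e-12)
    warning("IRLS did not converge in ", maxit, " iterations")
  r <- y - as.numeric(X %*% beta)
  if (s < 1e-12) {
    se <- rep(0, p)
  } else {
    u <- r / s
    psi <- huber_psi(u, k)
    dpsi <- as.numeric(abs(u) <= k)
    m1 <- mean(dpsi)
    kappa <- 1 + p / n * stats::var(dpsi) / m1^2   # Huber 1973 correction
    tau <- kappa^2 * (s^2 * sum(psi^2) / (n - p)) / m1^2
    XtXinv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(tau * diag(XtXinv))
  }
  tval <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(p))
  names(beta) <- names(se) <- names(tval) <- names(pval) <- nm
  structure(list(coefficients = beta, se = se, t = tval, p = pval,
                 df = n - p, scale = s,
                 weights = if (s < 1e-12) rep(1, n) else pmin(1, k * s / pmax(abs(r), 1e-300)),
                 fitted = as.numeric(X %*% beta), residuals = r,
                 converged = converged, iterations = it, k = k),
            class = "huber_fit")
}

#' @export
coef.huber_fit <- function(object, ...) object$coefficients

#' @export
print.huber_fit <- function(x, ...) {
  cat("Huber robust linear regression (k =", x$k, ")\n")
  print(summary(x))
  invisible(x)
}

#' @export
summary.huber_fit <- function(object, ...) {
  ci <- cbind(object$coefficients + stats::qt(0.025, object$df) * object$se,
              object$coefficients + stats::qt(0.975, object$df) * object$se)
  data.frame(coefficient = object$coefficients, se = object$se,
             t = object$t, p = object$p,
             ci_low = ci[, 1], ci_high = ci[, 2])
}

#' @export
residuals.huber_fit <- function(object, ...) object$residuals

#' @export
predict.huber_fit <- function(object, newX, ...) {
  as.numeric(as.matrix(newX) %*% object$coefficients)
}

# Table-3-order design matrix from a cohort table
final_model_design <- function(cohort, impute = c("group", "overall")) {
  impute <- match.arg(impute)
  md <- cohort$md_whole_subcortex
  wm <- cohort$wm_delta_chi
  for (v in c("md", "wm")) {
    val <- get(v)
    if (all(!is.finite(val))) stop("covariate entirely missing: ", v)
    if (impute == "group") {
      for (g in levels(cohort$group)) {
        sel <- cohort$group == g
        if (all(!is.finite(val[sel])))
          stop("a group is entirely missing covariate: ", v)
        val[sel & !is.finite(val)] <- mean(val[sel], na.rm = TRUE)
      }
    } else {
      val[!is.finite(val)] <- mean(val, na.rm = TRUE)
    }
    assign(v, val)
  }
  cbind(`(Intercept)` = 1,
        `Schizophrenia Group Status` = as.numeric(cohort$group == "patient"),
        `Current Smoker` = as.numeric(cohort$smoking == "current"),
        `Past Smoker` = as.numeric(cohort$smoking == "past"),
        `THC-positive UDS` = as.numeric(cohort$thc_positive),
        `Male Sex` = as.numeric(cohort$male),
        Age = cohort$age,
        `Subcortical Mean Diffusivity` = md,
        `White Matter dchi` = wm)
}

#' Final adjusted model of subcortical susceptibility
#'
#' Robust (Huber) regression of whole-subcortex chi on case-control status,
#' smoking, THC urine screen, sex, age, subcortical mean diffusivity, and
#' white-matter delta-chi. Missing MD and delta-chi values are imputed with
#' that subject's group mean before fitting.
#'
#' @param cohort a cohort table (see [simulate_cohort()]).
#' @param impute `"group"` (case/control-specific means, default) or
#'   `"overall"`.
#' @return A `huber_fit` with the 9-term coefficient table.
#' @export
final_model <- function(cohort, impute = c("group", "overall")) {
  if (nrow(cohort) < 20) stop("need at least 20 subjects")
  X <- final_model_design(cohort, impute)
  huber_regress(cohort$chi_whole_subcortex, X)
}
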