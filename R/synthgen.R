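#' Default per-ROI group summary statistics
#'
#' Group means and standard deviations of subcortical magnetic
#' susceptibility (chi, ppb) and mean diffusivity (MD, printed-table units
#' of 10^5 mm^2/s) for healthy controls and patients, used as the default
#' generating parameters of [simulate_cohort()].
#'
#' @return data.frame with columns `region`, `metric`, `mean_control`,
#'   `sd_control`, `mean_patient`, `sd_patient`.
#' @export
roi_reference_stats <- function() {
  regions <- c("whole_subcortex", "thalamus", "caudate", "putamen",
               "accumbens", "globus_pallidus", "sn_vta")
  chi <- rbind(
    c(28.83, 4.73, 27.00, 5.29),
    c(-2.25, 6.35, -1.26, 6.36),
    c(38.29, 7.49, 35.50, 7.51),
    c(32.15, 8.77, 29.19, 7.58),
    c(-2.95, 13.08, -1.20, 12.32),
    c(123.32, 16.53, 113.18, 18.92),
    c(114.23, 23.18, 99.53, 21.19))
  md <- rbind(
    c(79.50, 6.04, 83.05, 10.23),
    c(80.54, 5.81, 83.36, 7.73),
    c(76.92, 4.15, 77.87, 3.85),
    c(72.42, 1.42, 72.38, 1.36),
    c(76.29, 2.57, 76.11, 2.19),
    c(76.00, 2.41, 75.61, 2.19),
    c(78.08, 3.63, 78.14, 3.01))
  out <- rbind(
    data.frame(region = regions, metric = "chi", chi),
    data.frame(region = regions, metric = "md", md))
  names(out)[3:6] <- c("mean_control", "sd_control",
                       "mean_patient", "sd_patient")
  rownames(out) <- NULL
  out
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the reference study conditions: 80 controls / 79
#' patients with susceptibility data, of whom the first 43 / 73 also carry
#' diffusion (MD) and white-matter anisotropy values.
#'
#' @param roi_stats per-ROI generating means/SDs as from [roi_reference_stats()].
#' @param n_control,n_patient group sizes for the chi sample.
#' @param n_md_control,n_md_patient subjects (from the start of each group)
#'   with MD and delta-chi measurements; the rest are missing.
#' @param delta_chi list of generating mean/SD per group for participant
#'   white-matter delta-chi (ppb).
#' @param age list of mean/SD per group (years).
#' @param p_male,p_thc per-group probabilities (control, patient).
#' @param p_smoking per-group probabilities over (non, past, current) smoker;
#'   a 2 x 3 matrix with rows control, patient.
#' @param confound named coefficients (age, male, past_smoker,
#'   current_smoker, thc) added to every chi value, for confounding studies.
#' @param group_effect_shift additional ppb added to patients' chi on top of
#'   the configured means (0 keeps the reference case-control difference).
#' @param heavy_tails if TRUE, metric noise is drawn from a t distribution
#'   with 3 df (scaled to the configured SD) instead of a Gaussian.
#' @param seed integer seed recorded in the output provenance.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(roi_stats = roi_reference_stats(),
                          n_control = 80L, n_patient = 79L,
                          n_md_control = 43L, n_md_patient = 73L,
                          delta_chi = list(mean_control = 20.4, sd_control = 8,
                                           mean_patient = 17.4, sd_patient = 8),
                          age = list(mean_control = 32.1, sd_control = 6.4,
                                     mean_patient = 31.5, sd_patient = 6.9),
                          p_male = c(0.70, 0.72),
                          p_thc = c(0.05, 0.15),
                          p_smoking = rbind(control = c(0.60, 0.20, 0.20),
                                            patient = c(0.40, 0.20, 0.40)),
                          confound = c(age = 0, male = 0, past_smoker = 0,
                                       current_smoker = 0, thc = 0),
                          group_effect_shift = 0,
                          heavy_tails = FALSE,
                          seed = 1L) {
  stopifnot(all(roi_stats$sd_control >= 0), all(roi_stats$sd_patient >= 0),
            n_control >= 2, n_patient >= 2,
            n_md_control <= n_control, n_md_patient <= n_patient)
  structure(list(roi_stats = roi_stats,
                 n_control = as.integer(n_control),
                 n_patient = as.integer(n_patient),
                 n_md_control = as.integer(n_md_control),
                 n_md_patient = as.integer(n_md_patient),
                 delta_chi = delta_chi, age = age, p_male = p_male,
                 p_thc = p_thc, p_smoking = p_smoking, confound = confound,
                 group_effect_shift = group_effect_shift,
                 heavy_tails = heavy_tails, seed = as.integer(seed)),
            class = "cohort_config")
}

rnoise <- function(n, sd, heavy) {
  if (heavy) sd * stats::rt(n, df = 3) / sqrt(3) else stats::rnorm(n, 0, sd)
}

#' Simulate a case-control cohort table
#'
#' Draws per-subject ROI metric values from the configured per-group
#' distributions, attaches covariates (age, sex, smoking, THC urine screen)
#' and, for patients, clinical scores. Metric columns are named
#' `<metric>_<region>` (e.g. `chi_whole_subcortex`); subjects without a
#' diffusion scan have `NA` MD and delta-chi.
#'
#' @param cfg a [cohort_config()].
#' @return data.frame of class `cohort_table` with attribute `provenance`
#'   (the config seed). Controls precede patients.
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  n1 <- cfg$n_control; n2 <- cfg$n_patient; n <- n1 + n2
  grp <- factor(rep(c("control", "patient"), c(n1, n2)),
                levels = c("control", "patient"))
  pat <- grp == "patient"
  age <- ifelse(pat,
                stats::rnorm(n, cfg$age$mean_patient, cfg$age$sd_patient),
                stats::rnorm(n, cfg$age$mean_control, cfg$age$sd_control))
  male <- stats::rbinom(n, 1, ifelse(pat, cfg$p_male[2], cfg$p_male[1])) == 1
  smoking <- character(n)
  lv <- c("non", "past", "current")
  smoking[!pat] <- sample(lv, n1, TRUE, prob = cfg$p_smoking[1, ])
  smoking[pat] <- sample(lv, n2, TRUE, prob = cfg$p_smoking[2, ])
  smoking <- factor(smoking, levels = lv)
  thc <- stats::rbinom(n, 1, ifelse(pat, cfg$p_thc[2], cfg$p_thc[1])) == 1

  out <- data.frame(id = sprintf("S%03d", seq_len(n)), group = grp,
                    age = age, male = male, smoking = smoking,
                    thc_positive = thc, stringsAsFactors = FALSE)

  conf <- cfg$confound[c("age", "male", "past_smoker", "current_smoker", "thc")]
  conf[is.na(conf)] <- 0
  shift <- conf["age"] * age + conf["male"] * male +
    conf["past_smoker"] * (smoking == "past") +
    conf["current_smoker"] * (smoking == "current") +
    conf["thc"] * thc

  has_md <- c(seq_len(n1) <= cfg$n_md_control,
              seq_len(n2) <= cfg$n_md_patient)
  for (i in seq_len(nrow(cfg$roi_stats))) {
    row <- cfg$roi_stats[i, ]
    mu <- ifelse(pat, row$mean_patient, row$mean_control)
    sdv <- ifelse(pat, row$sd_patient, row$sd_control)
    val <- mu + rnoise(n, 1, cfg$heavy_tails) * sdv
    if (row$metric == "chi") {
      val <- val + shift + cfg$group_effect_shift * pat
    } else {
      val[!has_md] <- NA_real_
    }
    out[[paste(row$metric, row$region, sep = "_")]] <- val
  }

  dc <- cfg$delta_chi
  wm <- ifelse(pat, stats::rnorm(n, dc$mean_patient, dc$sd_patient),
               stats::rnorm(n, dc$mean_control, dc$sd_control))
  wm[!has_md] <- NA_real_
  out$wm_delta_chi <- wm

  # clinical scores, patients only
  clin <- rbind(panss_total = c(73.5, 14.1), panss_positive = c(17.4, 5.6),
                panss_negative = c(20.3, 5.6), panss_general = c(36.0, 7.1),
                bnss = c(30.9, 14.5), cgi_s = c(4.0, 0.9))
  for (s in rownames(clin)) {
    v <- rep(NA_real_, n)
    v[pat] <- stats::rnorm(n2, clin[s, 1], clin[s, 2])
    out[[s]] <- v
  }
  dur <- rep(NA_real_, n)
  dur[pat] <- stats::rlnorm(n2, meanlog = log(2.7), sdlog = 0.8)
  out$illness_duration <- dur

  attr(out, "provenance") <- list(seed = cfg$seed)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Simulate white-matter tract voxels with orientation-dependent chi
#'
#' Voxel susceptibility follows chi = delta_chi * cos^2(theta) + chi_iso +
#' Gaussian noise, with the fiber-to-field angle theta drawn on \[0, pi/2\].
#' The default `theta_dist = "sin"` is the angle distribution of a uniformly
#' random 3D fiber direction (density proportional to sin theta).
#'
#' @param delta_chi anisotropy slope (ppb).
#' @param chi_iso orientation-independent susceptibility intercept (ppb).
#' @param n_voxels number of voxels (>= 20).
#' @param theta_dist `"sin"`, `"uniform"`, a function of `n` returning
#'   angles, or a numeric vector of fixed angles of length `n_voxels`.
#' @param noise_sd Gaussian noise SD (ppb).
#' @param seed integer seed.
#' @param fa_min,fa_max fractional anisotropy drawn uniformly in this range
#'   (>= 0.6 by default, matching the retention rule downstream).
#' @return A [tract_voxel_set()].
#' @export
simulate_tract <- function(delta_chi, chi_iso, n_voxels = 2000L,
                           theta_dist = "sin", noise_sd = 5, seed = 1L,
                           fa_min = 0.6, fa_max = 0.95) {
  if (n_voxels < 20) stop("n_voxels must be >= 20")
  set.seed(seed)
  theta <- if (is.function(theta_dist)) {
    theta_dist(n_voxels)
  } else if (is.numeric(theta_dist)) {
    if (length(theta_dist) != n_voxels)
      stop("fixed theta vector must have length n_voxels")
    theta_dist
  } else if (theta_dist == "sin") {
    acos(stats::runif(n_voxels))
  } else if (theta_dist == "uniform") {
    stats::runif(n_voxels, 0, pi / 2)
  } else stop("unknown theta_dist")
  if (stats::sd(theta) == 0)
    stop("degenerate theta distribution: slope unidentifiable")
  chi <- delta_chi * cos(theta)^2 + chi_iso +
    stats::rnorm(n_voxels, 0, noise_sd)
  fa <- stats::runif(n_voxels, fa_min, fa_max)
  tract_voxel_set(chi = chi, theta = theta, fa = fa, tract = "synthetic",
                  subjects = "sim")
}

#' Ground truth for synthetic expression panels
#'
#' @param n_genes total genes in the panel.
#' @param n_components latent spatial components.
#' @param genes_per_component causal genes loading on each component.
#' @param loading loading of causal genes on their component; a vector is
#'   recycled over components (distinct per-component scales make the
#'   component count identifiable by cross-validation).
#' @param component_betas contribution of each component to the t-score map
#'   (recycled to `n_components`).
#' @param corr_length_mm squared-exponential spatial correlation length of
#'   gene maps (0 = white noise).
#' @param gene_noise_sd white noise SD added to every gene map.
#' @param noise_sd noise SD added to the t-score map.
#' @return list of class `expression_truth`; `weights` is the n_genes
#'   causal-weight vector (nonzero for causal genes).
#' @export
expression_truth <- function(n_genes = 500L, n_components = 3L,
                             genes_per_component = 10L, loading = 1,
                             component_betas = c(1, 0.8, 0.6),
                             corr_length_mm = 10, gene_noise_sd = 0.5,
                             noise_sd = 0.5) {
  stopifnot(corr_length_mm >= 0, n_components >= 1,
            genes_per_component >= 1,
            n_components * genes_per_component <= n_genes)
  betas <- rep_len(component_betas, n_components)
  loading <- rep_len(loading, n_components)
  comp_of <- rep(NA_integer_, n_genes)
  comp_of[seq_len(n_components * genes_per_component)] <-
    rep(seq_len(n_components), each = genes_per_component)
  weights <- ifelse(is.na(comp_of), 0, loading[comp_of] * betas[comp_of])
  if (all(weights == 0)) stop("at least one nonzero weight required")
  structure(list(n_genes = as.integer(n_genes),
                 n_components = as.integer(n_components),
                 comp_of = comp_of, loading = loading, betas = betas,
                 weights = weights, corr_length_mm = corr_length_mm,
                 gene_noise_sd = gene_noise_sd, noise_sd = noise_sd),
            class = "expression_truth")
}

# squared-exponential kernel Cholesky factor with jitter
se_chol <- function(coords, ell) {
  n <- nrow(coords)
  if (ell <= 0) return(diag(n))
  d2 <- as.matrix(stats::dist(coords))^2
  K <- exp(-d2 / (2 * ell^2)) + diag(1e-8, n)
  t(chol(K))
}

#' Simulate a spatially autocorrelated gene-expression panel
#'
#' Each gene's spatial profile over the sample coordinates is a smooth
#' Gaussian-process-like field (squared-exponential kernel) plus white
#' noise; causal genes share their component's latent field, and the
#' per-sample t-score is the weighted sum of the latent fields plus noise.
#' The ground truth is returned for parameter-recovery tests.
#'
#' @param n_samples number of tissue samples (>= 20; default mirrors the
#'   201 subcortical samples of the reference atlas).
#' @param truth an [expression_truth()].
#' @param coords optional n_samples x 3 matrix of MNI mm coordinates;
#'   drawn uniformly in a 40-mm cube when omitted.
#' @param seed integer seed.
#' @return list with `panel` (an [expression_panel()], raw expression) and
#'   `truth`.
#' @export
simulate_expression <- function(n_samples = 201L, truth = expression_truth(),
                                coords = NULL, seed = 1L) {
  stopifnot(inherits(truth, "expression_truth"))
  if (n_samples < 20) stop("need at least 20 samples")
  if (truth$n_genes < 50) stop("need at least 50 genes")
  set.seed(seed)
  if (is.null(coords))
    coords <- matrix(stats::runif(n_samples * 3, -20, 20), ncol = 3)
  if (nrow(coords) != n_samples) stop("coords/n_samples mismatch")
  if (any(duplicated(coords)) && truth$corr_length_mm > 0)
    stop("singular coordinate set: duplicated sample coordinates")
  L <- se_chol(coords, truth$corr_length_mm)
  Z <- L %*% matrix(stats::rnorm(n_samples * truth$n_components),
                    ncol = truth$n_components)
  X <- matrix(0, n_samples, truth$n_genes)
  for (j in seq_len(truth$n_genes)) {
    base <- if (is.na(truth$comp_of[j])) {
      as.numeric(L %*% stats::rnorm(n_samples))
    } else {
      truth$loading[truth$comp_of[j]] * Z[, truth$comp_of[j]]
    }
    X[, j] <- base + stats::rnorm(n_samples, 0, truth$gene_noise_sd)
  }
  colnames(X) <- sprintf("G%04d", seq_len(truth$n_genes))
  y <- as.numeric(Z %*% truth$betas) +
    stats::rnorm(n_samples, 0, truth$noise_sd)
  panel <- expression_panel(X, coords, t_scores = y)
  list(panel = panel, truth = truth)
}
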