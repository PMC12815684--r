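# shared fixtures built in code

make_covariates <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    group = factor(rep(c("control", "patient"), each = n / 2),
                   levels = c("control", "patient")),
    age = stats::rnorm(n, 30, 5),
    male = stats::rbinom(n, 1, 0.5) == 1,
    smoking = factor(sample(c("non", "past", "current"), n, TRUE,
                            prob = c(0.5, 0.2, 0.3)),
                     levels = c("non", "past", "current")),
    thc_positive = stats::rbinom(n, 1, 0.1) == 1)
}

# independent TFCE oracle: explicit threshold loop with connected components
tfce_brute <- function(m, E = 0.5, H = 2, dh, connectivity = 26) {
  bf <- array(0, dim(m))
  mx <- suppressWarnings(max(m[is.finite(m)], 0))
  if (mx <= 0) return(bf)
  for (t in seq_len(floor(mx / dh + 1e-12))) {
    h <- t * dh
    sup <- is.finite(m) & m >= h
    labs <- label_components(sup, connectivity)
    if (max(labs) > 0) {
      for (l in seq_len(max(labs))) {
        ext <- sum(labs == l)
        bf[labs == l] <- bf[labs == l] + ext^E * h^H * dh
      }
    }
  }
  bf
}

# signed two-tail TFCE via the brute-force oracle
tfce_brute_signed <- function(m, E = 0.5, H = 2, dh, connectivity = 26) {
  pos <- m; pos[!is.finite(pos) | pos < 0] <- 0
  neg <- -m; neg[!is.finite(neg) | neg < 0] <- 0
  tfce_brute(pos, E, H, dh, connectivity) -
    tfce_brute(neg, E, H, dh, connectivity)
}

# binned empirical variogram (mirrors the internal definition)
variogram_of <- function(y, coords, n_bins = 25) {
  D <- as.matrix(stats::dist(coords))
  edges <- seq(0, max(D) * (1 + 1e-9), length.out = n_bins + 1)
  iu <- which(upper.tri(D))
  g <- 0.5 * (outer(y, y, `-`)^2)[iu]
  bin <- findInterval(D[iu], edges, rightmost.closed = TRUE)
  as.numeric(tapply(g, factor(bin, levels = seq_len(n_bins)), mean))
}
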