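# Independent oracles and small fixture builders shared across test files.
# Each oracle is a from-scratch implementation kept deliberately separate
# from the package code paths it checks.

# Classic NIPALS PLS1 (single response), one latent variable: iterative
# weights/scores/y-weights formulation from the textbook algorithm.
nipals_pls1 <- function(X, y, tol = 1e-12, maxit = 500) {
  Xc <- scale(X, center = TRUE, scale = apply(X, 2, sd))
  yc <- y - mean(y)
  u <- yc
  w_old <- rep(0, ncol(Xc))
  for (i in seq_len(maxit)) {
    w <- drop(crossprod(Xc, u)) / sum(u^2)
    w <- w / sqrt(sum(w^2))
    t <- drop(Xc %*% w)
    q <- sum(yc * t) / sum(t^2)
    u <- yc * q / max(q^2, .Machine$double.eps)
    if (sqrt(sum((w - w_old)^2)) < tol) break
    w_old <- w
  }
  list(w = w, t = t, q = q, fitted = mean(y) + q * t)
}

# Exhaustive pairwise AUC: (#{pos > neg} + 0.5 #{ties}) / (n1 n0).
pairwise_auc <- function(y01, score) {
  pos <- score[y01 == 1]
  neg <- score[y01 == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Small two-group spectrum cohort for fast model tests.
small_cohort <- function(n_per = 10, seed = 1, tissue_mode = "extract",
                         magnitude = 0.5, resolution = 300) {
  cfg <- simulation_config(c(healthy = n_per, benign = n_per, malignant = 0),
                           seed = seed, tissue_mode = tissue_mode,
                           resolution = resolution)
  generate_spectra(cfg, effects = NULL)
}

lesion_labels <- function(groups) {
  ifelse(groups == "healthy", "healthy", "lesion")
}

# Tiny synthetic X with a y-correlated direction and an orthogonal
# structured direction, for OPLS-vs-PLS comparisons.
structured_xy <- function(n = 24, p = 30, seed = 1, noise = 0.5) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n / 2)
  a <- rnorm(p); c <- rnorm(p)
  z <- rnorm(n); z <- z - mean(z)
  yc <- y - mean(y)
  z <- z - sum(z * yc) / sum(yc^2) * yc   # orthogonalize z against y
  X <- outer(yc, a) + 3 * outer(z, c) + noise * matrix(rnorm(n * p), n)
  list(X = X, y = y)
}
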