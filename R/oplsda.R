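# Scaling -------------------------------------------------------------------

# Compute centering/scaling parameters on a training matrix. Variables with
# zero variance cannot be unit-variance scaled; they are dropped (indices kept
# so prediction can subset consistently) with a warning.
scaling_params <- function(M, mode = c("unit_variance", "mean_center")) {
  mode <- match.arg(mode)
  means <- colMeans(M)
  sds <- apply(M, 2, stats::sd)
  keep <- if (mode == "unit_variance") sds > 0 else rep(TRUE, ncol(M))
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-variance variable(s) before unit-variance scaling",
                    sum(!keep)), call. = FALSE)
  }
  list(mode = mode, means = means[keep], sds = sds[keep], keep = which(keep))
}

apply_scaling <- function(M, sp) {
  M <- M[, sp$keep, drop = FALSE]
  M <- sweep(M, 2, sp$means)
  if (sp$mode == "unit_variance") M <- sweep(M, 2, sp$sds, "/")
  M
}

# OPLS-DA --------------------------------------------------------------------

#' Fit a two-class OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis with a
#' single predictive component, in the standard two-block formulation: the
#' class membership (encoded 0/1 and centered) is the single-column Y, the
#' scaled bucket matrix is X. For each orthogonal component the X-variation
#' uncorrelated with Y is estimated and deflated; the predictive score is
#' then the projection of the deflated X onto the Y-correlated weight.
#'
#' The algorithm (single-y case, closed form, no NIPALS iteration needed):
#' with scaled X and centered y, `w = X'y / |X'y|`; then for each of the
#' `n_ortho` components, `t = Xw`, `p = X't/(t't)`,
#' `w_o = (p - (w'p)w)` normalized, `t_o = X w_o`, `p_o = X't_o/(t_o't_o)`,
#' `X <- X - t_o p_o'`; finally the predictive score `t = Xw`, loading
#' `p = X't/(t't)` and the inner regression `b = t'y/(t't)`. The component
#' sign is fixed so that `cor(t, y) >= 0`.
#'
#' @param X A `bucket_table` or numeric matrix (samples x variables).
#' @param y Two-class labels (factor/character/0-1 numeric).
#' @param n_ortho Number of orthogonal components (>= 0); default 1.
#' @param scaling `"unit_variance"` (default, the convention for bucketed NMR
#'   data) or `"mean_center"`.
#' @param positive Class coded 1; defaults to the second sorted level.
#' @return An `oplsda_model`: predictive weight `w` (unit norm), scores `t`,
#'   loading `p`; orthogonal `W_o`, `T_o`, `P_o`; inner coefficient `b`;
#'   `y_mean`, class `levels`; `scaling` parameters; variance bookkeeping
#'   `R2X` (named: predictive, orthogonal, total), `R2Y`; `fitted` values on
#'   the 0/1 scale.
#' @examples
#' X <- matrix(rnorm(40), 10, 4)
#' y <- rep(c("a", "b"), each = 5)
#' X[, 1] <- X[, 1] + (y == "b")
#' m <- fit_oplsda(X, y, n_ortho = 0)
#' @export
fit_oplsda <- function(X, y, n_ortho = 1,
                       scaling = c("unit_variance", "mean_center"),
                       positive = NULL) {
  M <- as_X(X)
  scaling <- match.arg(scaling)
  yb <- encode_binary(y, positive)
  assert_that(n_ortho >= 0, "n_ortho must be >= 0")
  assert_that(nrow(M) == length(yb), "X rows and y length differ")

  sp <- scaling_params(M, scaling)
  X0 <- apply_scaling(M, sp)
  if (n_ortho >= min(nrow(X0) - 1L, ncol(X0))) {
    stop2("n_ortho must be smaller than the rank bound min(n-1, p)")
  }
  y_mean <- mean(yb)
  yc <- as.numeric(yb) - y_mean
  ssy <- sum(yc^2)
  ssx <- sum(X0^2)

  w <- drop(crossprod(X0, yc))
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop2("X carries no covariance with y; cannot fit")
  w <- w / nw

  Xd <- X0
  W_o <- T_o <- P_o <- NULL
  ssx_ortho <- 0
  if (n_ortho > 0) {
    for (a in seq_len(n_ortho)) {
      t <- drop(Xd %*% w)
      p <- drop(crossprod(Xd, t)) / sum(t^2)
      w_o <- p - sum(w * p) * w
      nwo <- sqrt(sum(w_o^2))
      if (nwo < 1e-12) {
        stop2("orthogonal variation exhausted; reduce n_ortho")
      }
      w_o <- w_o / nwo
      t_o <- drop(Xd %*% w_o)
      p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
      Xd <- Xd - tcrossprod(t_o, p_o)
      ssx_ortho <- ssx_ortho + sum(t_o^2) * sum(p_o^2)
      W_o <- cbind(W_o, w_o); T_o <- cbind(T_o, t_o); P_o <- cbind(P_o, p_o)
    }
  }
  t <- drop(Xd %*% w)
  p <- drop(crossprod(Xd, t)) / sum(t^2)
  b <- sum(t * yc) / sum(t^2)
  if (b < 0) {  # sign convention: predictive score positively tracks y
    w <- -w; t <- -t; p <- -p; b <- -b
  }
  fitted <- y_mean + b * t
  structure(list(w = w, t = t, p = p,
                 W_o = W_o, T_o = T_o, P_o = P_o,
                 b = b, y_mean = y_mean, y = as.numeric(yb),
                 levels = attr(yb, "levels"),
                 scaling = sp, n_ortho = n_ortho,
                 R2X = c(predictive = sum(t^2) * sum(p^2) / ssx,
                         orthogonal = ssx_ortho / ssx,
                         total = (sum(t^2) * sum(p^2) + ssx_ortho) / ssx),
                 R2Y = 1 - sum((yc - b * t)^2) / ssy,
                 fitted = fitted),
            class = "oplsda_model")
}

#' @export
print.oplsda_model <- function(x, ...) {
  cat(sprintf("<oplsda_model> 1 predictive + %d orthogonal component(s)\n",
              x$n_ortho))
  cat(sprintf("  classes: %s (0) vs %s (1)\n", x$levels[1], x$levels[2]))
  cat(sprintf("  R2X = %.3f (pred %.3f, ortho %.3f), R2Y = %.3f\n",
              x$R2X["total"], x$R2X["predictive"], x$R2X["orthogonal"],
              x$R2Y))
  invisible(x)
}

#' Predict class scores for new samples
#'
#' Applies the training scaling, removes the stored orthogonal variation
#' (`t_o = X w_o`; `X <- X - t_o p_o'` per component), and returns
#' `y_mean + b * (X w)` on the training 0/1 scale, plus the predictive score
#' and the thresholded class (midpoint of the centered encoding).
#'
#' @param object An `oplsda_model`.
#' @param newdata `bucket_table` or matrix with the training variables.
#' @param ... Unused.
#' @return List with `y_pred`, `t`, `class`.
#' @export
predict.oplsda_model <- function(object, newdata, ...) {
  M <- as_X(newdata)
  assert_that(ncol(M) >= max(object$scaling$keep),
              "newdata has fewer variables than the training matrix")
  Xs <- apply_scaling(M, object$scaling)
  if (!is.null(object$W_o)) {
    for (a in seq_len(ncol(object$W_o))) {
      t_o <- drop(Xs %*% object$W_o[, a])
      Xs <- Xs - tcrossprod(t_o, object$P_o[, a])
    }
  }
  t_new <- drop(Xs %*% object$w)
  y_pred <- object$y_mean + object$b * t_new
  list(y_pred = y_pred, t = t_new,
       class = object$levels[(y_pred >= 0.5) + 1L])
}

#' Serialize an OPLS-DA model to JSON
#'
#' @param model An `oplsda_model`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_oplsda_json <- function(model, path) {
  out <- model[c("w", "t", "p", "b", "y_mean", "levels", "n_ortho",
                 "R2Y")]
  out$R2X <- as.list(model$R2X)
  out$W_o <- model$W_o; out$T_o <- model$T_o; out$P_o <- model$P_o
  out$scaling <- model$scaling
  write_json_file(out, path)
}
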