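#' Seeded stratified fold assignment
#'
#' Shuffles each class with the seeded RNG and deals its members to folds
#' 1..K in turn, so folds are class-balanced up to rounding. A class with
#' fewer members than K simply appears in fewer folds (every training split
#' still contains both classes whenever each class has >= 2 members).
#'
#' @param y Two-class labels.
#' @param K Number of folds.
#' @param seed RNG seed.
#' @return Integer fold id per sample.
#' @export
assign_folds <- function(y, K = 7, seed = 1) {
  y <- as.character(y)
  K <- as.integer(K)
  assert_that(K >= 2, "K must be >= 2")
  assert_that(K <= length(y), "K cannot exceed the sample count")
  set.seed(seed)
  folds <- integer(length(y))
  start <- 0L
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- if (length(idx) > 1) sample(idx) else idx
    folds[idx] <- (start + seq_along(idx) - 1L) %% K + 1L
    start <- start + length(idx)
  }
  folds
}

#' K-fold cross-validation of an OPLS-DA model
#'
#' Stratified K-fold (default 7-fold) cross-validation. For every fold the
#' scaling parameters and the OPLS-DA model are refit on the training portion
#' only — held-out samples never influence centering, unit-variance scaling
#' or the model — and the held-out predicted y values are pooled into PRESS
#' and the predictive ability Q2 = 1 - PRESS/SS_tot.
#'
#' @inheritParams fit_oplsda
#' @param K Number of folds (default 7).
#' @param seed Seed for the fold shuffle.
#' @param folds Optional explicit fold assignment (integer per sample),
#'   overriding the seeded stratified assignment.
#' @return A `cv_result`: `fold_assignment`, `y_pred_cv`, `y`, `PRESS`,
#'   `SS_tot`, `Q2`, `K`, `n_ortho`, `levels`, and `fold_scaling` (per-fold
#'   training scaling parameters, retained for leakage audits).
#' @export
cross_validate <- function(X, y, n_ortho = 1, K = 7, seed = 1,
                           scaling = c("unit_variance", "mean_center"),
                           positive = NULL, folds = NULL) {
  M <- as_X(X)
  scaling <- match.arg(scaling)
  yb <- encode_binary(y, positive)
  if (is.null(folds)) {
    folds <- assign_folds(as.character(y), K = K, seed = seed)
  } else {
    assert_that(length(folds) == length(yb),
                "folds must assign every sample")
    K <- max(folds)
  }
  y_num <- as.numeric(yb)
  y_pred <- rep(NA_real_, length(y_num))
  fold_scaling <- vector("list", K)
  for (k in sort(unique(folds))) {
    tr <- folds != k
    if (length(unique(y_num[tr])) < 2L) {
      stop2(sprintf("training split for fold %d contains a single class", k))
    }
    fit <- fit_oplsda(M[tr, , drop = FALSE], y_num[tr], n_ortho = n_ortho,
                      scaling = scaling, positive = "1")
    fold_scaling[[k]] <- fit$scaling
    y_pred[!tr] <- predict(fit, M[!tr, , drop = FALSE])$y_pred
  }
  PRESS <- sum((y_num - y_pred)^2)
  SS_tot <- sum((y_num - mean(y_num))^2)
  structure(list(fold_assignment = folds, y_pred_cv = y_pred, y = y_num,
                 PRESS = PRESS, SS_tot = SS_tot, Q2 = 1 - PRESS / SS_tot,
                 K = K, n_ortho = n_ortho, seed = seed,
                 levels = attr(yb, "levels"),
                 fold_scaling = fold_scaling),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold, %d samples: Q2 = %.3f (PRESS %.3f / SS_tot %.3f)\n",
              x$K, length(x$y), x$Q2, x$PRESS, x$SS_tot))
  invisible(x)
}

#' CV-ANOVA significance test for a cross-validated model
#'
#' The cross-validated ANOVA significance test for PLS-family models: the
#' variation explained by cross-validated predictions,
#' `SS_reg = SS_tot - PRESS`, is compared against the cross-validated
#' residual variation through
#' `F = (SS_reg / df1) / (PRESS / df2)` with `df1` the model degrees of
#' freedom and `df2 = n - df1 - 1`, and p is the upper tail of
#' `F(df1, df2)`. When the model predicts no better than the mean
#' (`SS_reg <= 0`) F is floored at 0 and p reported as 1.
#'
#' `model_df` defaults to `2 + 2 * n_ortho`: one predictive component, a
#' score/loading pair per orthogonal component, and an intercept — a
#' component-counting convention (pinned by a regression test), not a fact
#' inherited from any particular software.
#'
#' @param cv A `cv_result`.
#' @param model_df Model degrees of freedom.
#' @return A `cv_anova_result`: `F`, `df1`, `df2`, `p`.
#' @export
cv_anova <- function(cv, model_df = 2 + 2 * cv$n_ortho) {
  assert_that(inherits(cv, "cv_result"), "cv must come from cross_validate()")
  n <- length(cv$y)
  df1 <- model_df
  df2 <- n - df1 - 1
  if (df2 <= 0) stop2("not enough samples for the model degrees of freedom")
  SS_reg <- cv$SS_tot - cv$PRESS
  if (SS_reg <= 0) {
    out <- list(F = 0, df1 = df1, df2 = df2, p = 1)
  } else if (cv$PRESS == 0) {
    out <- list(F = Inf, df1 = df1, df2 = df2, p = 0)
  } else {
    Fv <- (SS_reg / df1) / (cv$PRESS / df2)
    out <- list(F = Fv, df1 = df1, df2 = df2,
                p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
  }
  structure(out, class = "cv_anova_result")
}

#' @export
print.cv_anova_result <- function(x, ...) {
  cat(sprintf("<cv_anova> F(%g, %g) = %.3f, p = %.3g\n",
              x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' ROC curve from predicted Y values
#'
#' Sweeps the decision threshold over the observed predicted values and
#' reports sensitivity/specificity at each threshold plus the area under the
#' curve. Ties are handled by midranks, so the AUC equals the normalized
#' Mann-Whitney U statistic `(#{pos > neg} + 0.5 #{ties}) / (n1 n0)`, which
#' is also the trapezoidal area under the empirical curve.
#'
#' @param y_true Two-class labels.
#' @param score Predicted values (higher = more likely positive class), e.g.
#'   cross-validated predicted y.
#' @param positive Class treated as positive; default second sorted level.
#' @return A `roc_curve`: data.frame `curve` (`threshold`, `sensitivity`,
#'   `specificity`), `auc`, and the Youden-optimal operating point
#'   (`youden`: threshold, sensitivity, specificity).
#' @export
roc_curve <- function(y_true, score, positive = NULL) {
  yb <- encode_binary(y_true, positive)
  assert_that(length(score) == length(yb), "score and y_true lengths differ")
  pos <- as.numeric(yb) == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  assert_that(n1 > 0 && n0 > 0, "both classes must be present")

  thr <- sort(unique(score), decreasing = TRUE)
  sens <- vapply(thr, function(v) sum(score >= v & pos) / n1, 0)
  spec <- vapply(thr, function(v) sum(score < v & !pos) / n0, 0)
  curve <- data.frame(threshold = c(Inf, thr),
                      sensitivity = c(0, sens),
                      specificity = c(1, spec))

  r <- rank(score)                      # midranks handle ties
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  j <- which.max(curve$sensitivity + curve$specificity - 1)
  structure(list(curve = curve, auc = auc,
                 youden = curve[j, , drop = FALSE]),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.3f; Youden point: sens %.2f / spec %.2f at %.3g\n",
              x$auc, x$youden$sensitivity, x$youden$specificity,
              x$youden$threshold))
  invisible(x)
}

#' Model-quality summary for one comparison
#'
#' Bundles the quantities reported per OPLS-DA comparison — R2X, R2Y, Q2,
#' CV-ANOVA F and p, AUC, and the Youden-point sensitivity/specificity —
#' into one list suitable for JSON export.
#'
#' @param model An `oplsda_model`.
#' @param cv Matching `cv_result`.
#' @param roc Matching `roc_curve` (from the cross-validated predictions).
#' @return Named list of scalars.
#' @export
model_summary <- function(model, cv, roc) {
  an <- cv_anova(cv)
  list(n = length(cv$y), n_ortho = model$n_ortho,
       R2X = unname(model$R2X["total"]), R2Y = model$R2Y, Q2 = cv$Q2,
       cv_anova_F = an$F, cv_anova_df1 = an$df1, cv_anova_df2 = an$df2,
       cv_anova_p = an$p,
       auc = roc$auc,
       sensitivity = roc$youden$sensitivity,
       specificity = roc$youden$specificity)
}

#' Choose the number of orthogonal components by cross-validated Q2
#'
#' Starts at 0 orthogonal components and adds one while the Q2 gain is at
#' least `min_gain` (default 0.01), up to `max_ortho`.
#'
#' @inheritParams cross_validate
#' @param max_ortho Upper bound on orthogonal components.
#' @param min_gain Minimum Q2 improvement to accept another component.
#' @return List with `n_ortho` and the `q2` path.
#' @export
select_n_ortho <- function(X, y, K = 7, seed = 1, max_ortho = 3,
                           min_gain = 0.01) {
  q2 <- numeric(0)
  best <- 0
  for (a in 0:max_ortho) {
    q2[a + 1] <- cross_validate(X, y, n_ortho = a, K = K, seed = seed)$Q2
    if (a > 0 && q2[a + 1] < q2[a] + min_gain) break
    best <- a
  }
  list(n_ortho = best, q2 = q2)
}
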