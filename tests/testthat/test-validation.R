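test_that("K = n stratified assignment is leave-one-out", {
  y <- c("a", "a", "a", "a", "b", "b", "b")
  f <- assign_folds(y, K = 7, seed = 3)
  expect_identical(sort(f), 1:7)
  # stratification: class counts per fold differ by at most one
  f2 <- assign_folds(rep(c("a", "b"), c(20, 15)), K = 7, seed = 3)
  tab <- table(f2, rep(c("a", "b"), c(20, 15)))
  expect_lte(max(tab[, "a"]) - min(tab[, "a"]), 1)
  expect_lte(max(tab[, "b"]) - min(tab[, "b"]), 1)
  expect_identical(assign_folds(y, K = 7, seed = 3), f)
})

test_that("every sample is predicted exactly once and Q2 <= 1", {
  s <- structured_xy(n = 22, p = 12, seed = 31)
  cv <- cross_validate(s$X, s$y, n_ortho = 1, K = 7, seed = 1)
  expect_false(anyNA(cv$y_pred_cv))
  expect_identical(length(cv$y_pred_cv), 22L)
  expect_lte(cv$Q2, 1)
  expect_equal(cv$Q2, 1 - cv$PRESS / cv$SS_tot, tolerance = 1e-12)
  expect_error(cross_validate(s$X, s$y, K = 50), "exceed")
})

test_that("Q2 is invariant to sample permutation with matching folds", {
  s <- structured_xy(n = 20, p = 10, seed = 32)
  f <- assign_folds(as.character(s$y), K = 5, seed = 2)
  cv1 <- cross_validate(s$X, s$y, n_ortho = 1, folds = f)
  perm <- sample(20)
  cv2 <- cross_validate(s$X[perm, ], s$y[perm], n_ortho = 1,
                        folds = f[perm])
  expect_equal(cv2$Q2, cv1$Q2, tolerance = 1e-10)
  expect_equal(cv2$y_pred_cv, cv1$y_pred_cv[perm], tolerance = 1e-10)
})

test_that("held-out samples cannot leak into training scaling", {
  s <- structured_xy(n = 22, p = 12, seed = 33)
  f <- assign_folds(as.character(s$y), K = 7, seed = 5)
  cv1 <- cross_validate(s$X, s$y, n_ortho = 0, folds = f)
  victim <- which(f == 3)[1]
  X2 <- s$X
  X2[victim, ] <- X2[victim, ] * 1e6   # extreme artifact in a held-out row
  cv2 <- cross_validate(X2, s$y, n_ortho = 0, folds = f)
  expect_equal(cv2$fold_scaling[[3]]$means, cv1$fold_scaling[[3]]$means,
               tolerance = 1e-12)
  expect_equal(cv2$fold_scaling[[3]]$sds, cv1$fold_scaling[[3]]$sds,
               tolerance = 1e-12)
})

test_that("pure-noise responses give non-positive predictive ability", {
  q2 <- vapply(1:50, function(r) {
    set.seed(400 + r)
    X <- matrix(rnorm(24 * 30), 24, 30)
    y <- rep(c(0, 1), each = 12)
    cross_validate(X, y, n_ortho = 1, K = 7, seed = r)$Q2
  }, 0)
  expect_lt(mean(q2), 0.05)
})

test_that("a noiseless informative column gives Q2 near 1", {
  y <- rep(c(0, 1), each = 10)
  X <- cbind(y, 2 * y - 1)
  cv <- cross_validate(X, y, n_ortho = 0, K = 7, seed = 1)
  expect_gt(cv$Q2, 0.9)
})

test_that("cv_anova handles degenerate and regular cases", {
  s <- structured_xy(n = 22, p = 12, seed = 35)
  cv <- cross_validate(s$X, s$y, n_ortho = 1, K = 7, seed = 1)
  an <- cv_anova(cv)
  expect_identical(an$df1, 4)          # 1 predictive + 2x1 orthogonal + 1
  expect_identical(an$df2, 22 - 4 - 1)
  expect_gte(an$F, 0)
  expect_true(an$p >= 0 && an$p <= 1)

  perfect <- cv; perfect$PRESS <- 0
  expect_equal(cv_anova(perfect)$p, 0)
  expect_identical(cv_anova(perfect)$F, Inf)

  hopeless <- cv; hopeless$PRESS <- cv$SS_tot * 2
  expect_identical(cv_anova(hopeless)$F, 0)
  expect_identical(cv_anova(hopeless)$p, 1)

  tiny <- cv; tiny$y <- tiny$y[1:4]
  expect_error(cv_anova(tiny), "degrees of freedom")
})

test_that("cv_anova p falls monotonically with planted effect size", {
  mean_p <- vapply(c(0.3, 0.8, 1.6), function(beta) {
    ps <- vapply(1:50, function(r) {
      set.seed(500 + r)
      n <- 24; y <- rep(c(0, 1), each = n / 2)
      X <- matrix(rnorm(n * 20), n, 20)
      X[, 1:4] <- X[, 1:4] + beta * y
      cv_anova(cross_validate(X, y, n_ortho = 1, K = 7, seed = r))$p
    }, 0)
    mean(ps)
  }, 0)
  expect_true(all(diff(mean_p) < 0))
})

test_that("AUC equals the exhaustive pairwise count and pROC agrees", {
  expect_equal(roc_curve(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2))$auc, 1.0)
  expect_equal(roc_curve(c(1, 1, 0, 0), rep(0.5, 4))$auc, 0.5)

  set.seed(36)
  y <- rbinom(30, 1, 0.5); y[1:2] <- c(0, 1)
  score <- round(rnorm(30), 1)          # rounding forces ties
  r <- roc_curve(y, score, positive = "1")
  expect_equal(r$auc, pairwise_auc(y, score), tolerance = 1e-12)
  expect_equal(as.numeric(pROC::auc(pROC::roc(y, score, quiet = TRUE,
                                              direction = "<"))),
               r$auc, tolerance = 1e-12)
  # symmetry under score negation
  expect_equal(roc_curve(y, -score, positive = "1")$auc + r$auc, 1,
               tolerance = 1e-12)
})

test_that("ROC curve is monotone with valid operating points", {
  set.seed(37)
  y <- rep(c(0, 1), each = 15)
  score <- rnorm(30) + y
  r <- roc_curve(y, score, positive = "1")
  expect_true(all(diff(r$curve$sensitivity) >= 0))
  expect_true(all(diff(r$curve$specificity) <= 0))
  expect_true(all(r$curve$sensitivity >= 0 & r$curve$sensitivity <= 1))
  expect_true(all(r$curve$specificity >= 0 & r$curve$specificity <= 1))
  j <- r$youden$sensitivity + r$youden$specificity - 1
  expect_gte(j, max(r$curve$sensitivity + r$curve$specificity - 1) - 1e-12)
  expect_error(roc_curve(rep(1, 5), rnorm(5)), "two classes")
})

test_that("orthogonal-component selection stops when Q2 stalls", {
  s <- structured_xy(n = 24, p = 30, seed = 38, noise = 0.3)
  sel <- select_n_ortho(s$X, s$y, K = 7, seed = 1, max_ortho = 3)
  expect_gte(sel$n_ortho, 0)
  expect_lte(sel$n_ortho, 3)
  expect_identical(which.max(sel$q2) - 1L <= sel$n_ortho + 1L, TRUE)
})
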