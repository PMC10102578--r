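# Forest sizes and Boruta iteration caps here are scaled down from the
# defaults (500 trees, 100 runs) to fit a 1-CPU budget; decision thresholds
# are unchanged.

test_that("Boruta confirms duplicated informative features, rejects noise", {
  set.seed(17)
  n <- 80
  y <- rep(c("case", "control"), each = n / 2)
  signal <- as.numeric(y == "case") + rnorm(n, sd = 0.3)
  X <- cbind(signal, signal + rnorm(n, sd = 0.05),
             matrix(rnorm(n * 20), n, 20))
  b <- boruta_select(X, y, max_runs = 40, ntree = 200, seed = 3)
  expect_equal(as.character(b$status[1]), "confirmed")
  expect_equal(as.character(b$status[2]), "confirmed")   # duplicate too
  expect_gte(mean(b$status[-(1:2)] == "rejected"), 0.8)
  expect_equal(sum(b$status[-(1:2)] == "confirmed"), 0)
  expect_true(all(b$hit_count <= b$n_iterations))
  expect_error(boruta_select(X, rep("case", n), seed = 1), "both classes")
})

test_that("all-noise Boruta confirms nothing in >= 90% of seeds", {
  # full default iteration budget so the binomial test decides features
  # before the tentative rough fix; forest size scaled down
  confirmed <- vapply(1:10, function(s) {
    set.seed(400 + s)
    X <- matrix(rnorm(60 * 25), 60, 25)
    y <- rep(c("case", "control"), each = 30)
    length(boruta_select(X, y, max_runs = 100, ntree = 100, seed = s)$confirmed)
  }, 0L)
  expect_gte(mean(confirmed == 0), 0.9)
})

test_that("linear SVM separates and weights classes", {
  set.seed(2)
  n <- 60
  y <- rep(c("case", "control"), each = n / 2)
  X <- cbind(as.numeric(y == "case") * 4 + rnorm(n, sd = 0.2),
             matrix(rnorm(n * 3), n, 3))
  m <- svm_train(X, y)
  sc <- svm_decision(m, X)
  expect_equal(roc_curve(sc, y)$auc, 1.0)
  expect_gt(mean(sc[y == "case"]), mean(sc[y == "control"]))
})

test_that("ROC curves are monotone with correct endpoints and AUC", {
  rc <- roc_curve(c(3, 2, 1, 0.5), c("case", "case", "control", "control"))
  expect_equal(rc$auc, 1.0)
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[length(rc$tpr)], 1)
  expect_true(!is.unsorted(rc$tpr) && !is.unsorted(rc$fpr))
  # chance scores give AUC near 0.5 on balanced labels
  set.seed(5)
  rc2 <- roc_curve(rnorm(400), rep(c("case", "control"), 200))
  expect_lt(abs(rc2$auc - 0.5), 0.1)
})

test_that("vertical averaging matches hand calculation", {
  perfect <- list(fpr = c(0, 0, 1), tpr = c(0, 1, 1), auc = 1)
  chance <- list(fpr = c(0, 1), tpr = c(0, 1), auc = 0.5)
  avg <- average_roc(list(perfect, chance), grid_step = 0.01)
  # averaged TPR = (1 + FPR)/2 pointwise; mean AUC = 0.75
  expect_equal(avg$tpr, (1 + avg$fpr) / 2)
  expect_equal(avg$auc, 0.75)

  # identical folds average to themselves; a single fold is returned as-is
  same <- average_roc(list(perfect, perfect))
  expect_equal(same$tpr, approx(perfect$fpr, perfect$tpr, same$fpr,
                                ties = max)$y)
  single <- average_roc(list(chance))
  expect_equal(single$tpr, single$fpr)
  expect_equal(single$auc, 0.5)
})

test_that("bootstrap band degenerates correctly and covers the mean", {
  perfect <- list(fpr = c(0, 0, 1), tpr = c(0, 1, 1), auc = 1)
  chance <- list(fpr = c(0, 1), tpr = c(0, 1), auc = 0.5)
  # identical folds: zero-width band
  bd <- bootstrap_band(list(perfect, perfect, perfect), n_boot = 200, seed = 1)
  expect_equal(bd$lower, bd$upper)
  expect_equal(bd$auc_ci, c(1, 1))

  bd2 <- bootstrap_band(list(perfect, chance), n_boot = 4000, seed = 2)
  avg2 <- average_roc(list(perfect, chance))
  expect_true(all(bd2$lower <= avg2$tpr + 1e-12))
  expect_true(all(bd2$upper >= avg2$tpr - 1e-12))

  # two-fold enumeration oracle: resamples are (A,A), (A,B)/(B,A), (B,B)
  # with weights 1/4, 1/2, 1/4; the 2.5% quantile of the mean fold AUC is
  # the smallest resample mean, the 97.5% the largest
  expect_equal(bd2$auc_ci, c(0.5, 1), tolerance = 0.02)
})

test_that("cross-validation is deterministic and honest", {
  set.seed(11)
  n <- 40; p <- 25
  y <- rep(c("case", "control"), each = n / 2)
  X <- cbind(as.numeric(y == "case") * 3 + rnorm(n, sd = 0.1),
             matrix(rnorm(n * (p - 1)), n, p - 1))
  # separable toy: mean AUC 1.0
  cv <- run_cv(X, y, n_repeats = 1, n_folds = 4, sva = FALSE,
               boruta_max_runs = 25, ntree = 80, n_boot = 200, seed = 9)
  expect_equal(cv$mean_auc, 1.0)
  expect_gte(cv$n_selected_mean, 1)

  # identical seeds give identical reports
  cv2 <- run_cv(X, y, n_repeats = 1, n_folds = 4, sva = FALSE,
                boruta_max_runs = 25, ntree = 80, n_boot = 200, seed = 9)
  expect_identical(cv$fold_aucs, cv2$fold_aucs)
  expect_identical(cv$selected_sets, cv2$selected_sets)
  expect_identical(cv$band$lower, cv2$band$lower)

  expect_error(run_cv(X[1:6, ], y[1:6], n_folds = 10), "fewer samples")
})

test_that("nothing fit on training changes when held-out rows are corrupted", {
  set.seed(23)
  n <- 40; p <- 30
  y <- rep(c("case", "control"), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1] <- as.numeric(y == "case") + rnorm(n, sd = 0.4)
  test_idx <- c(1:5, 21:25)
  train_idx <- setdiff(seq_len(n), test_idx)
  f1 <- cv_fold(X, y, train_idx, test_idx, sva = TRUE, boruta_max_runs = 10,
                ntree = 60, seed = 5)
  Xc <- X
  Xc[test_idx, ] <- matrix(rnorm(length(test_idx) * p, mean = 50), ncol = p)
  f2 <- cv_fold(Xc, y, train_idx, test_idx, sva = TRUE, boruta_max_runs = 10,
                ntree = 60, seed = 5)
  # frozen training artifacts identical; held-out scores differ
  expect_identical(f1$frozen$mu, f2$frozen$mu)
  expect_identical(f1$frozen$sd, f2$frozen$sd)
  expect_identical(f1$frozen$w, f2$frozen$w)
  expect_identical(f1$frozen$b, f2$frozen$b)
  expect_identical(f1$selected, f2$selected)
  if (!is.null(f1$frozen$sv))
    expect_identical(f1$frozen$sv$sv_loadings, f2$frozen$sv$sv_loadings)
  expect_false(isTRUE(all.equal(f1$scores, f2$scores)))
})

test_that("selected-feature counts stay within the sanity band on synthetic data", {
  cfg <- small_cohort_config(seed = 19, n_features = 60, n_differential = 10,
                             n_up = 5, effect_range = c(0.8, 1.2),
                             batch_sd_log2 = 0)
  coh <- simulate_cohort(cfg)
  cv <- run_cv(coh$abundances, coh$cohort$group, n_repeats = 1, n_folds = 3,
               sva = FALSE, boruta_max_runs = 30, ntree = 100, n_boot = 200,
               seed = 4)
  # mean selected in [true count x 0.1, matrix width]
  expect_gte(cv$n_selected_mean, length(true_differential(coh$truth)) * 0.1)
  expect_lte(cv$n_selected_mean, ncol(coh$abundances))
  # consistency of the two AUC conventions on a non-degenerate scenario
  expect_lt(abs(cv$average_roc$auc - cv$average_roc$auc_of_mean_curve), 0.02)
})
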