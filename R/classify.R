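#' Boruta all-relevant feature selection
#'
#' Per iteration every still-undecided feature is paired with a "shadow"
#' copy whose values are permuted across samples; a random forest is fit on
#' the extended matrix and a feature scores a hit when its permutation
#' importance exceeds the maximum shadow importance. Features are decided
#' by a two-sided binomial test (p = 0.5), Bonferroni-corrected over all
#' tests performed (features x evaluations -- the decision is re-checked
#' after every iteration, and uncorrected sequential peeking would inflate
#' false confirmations); rejected features leave the active set. With
#' `rough_fix = TRUE`, residual tentatives after `max_runs` iterations are
#' resolved by comparing their median importance to the median of the
#' shadow maxima; the default leaves them tentative (the reference
#' implementation's default), which is what keeps the confirmed set empty
#' on pure-noise data.
#'
#' @param X samples x features numeric matrix.
#' @param y Binary labels (factor, character or 0/1); both classes required.
#' @param max_runs Maximum Boruta iterations (default 100).
#' @param ntree Trees per forest (default 500).
#' @param alpha Decision level before Bonferroni (default 0.01).
#' @param seed Integer seed (forest and shadow permutations derive from it).
#' @param rough_fix Resolve residual tentatives by the median-importance
#'   rule (default FALSE: they stay tentative).
#' @return Object of class `boruta_decision`: `status` (factor per feature:
#'   confirmed / rejected / tentative), `hit_count`, `n_iterations`,
#'   `confirmed` (feature indices).
#' @export
boruta_select <- function(X, y, max_runs = 100, ntree = 500, alpha = 0.01,
                          seed = 1L, rough_fix = FALSE) {
  X <- as.matrix(X)
  yb <- .binary_labels(y)
  if (length(unique(yb)) < 2) stop("y must contain both classes")
  p <- ncol(X)
  set.seed(seed)
  status <- rep("tentative", p)
  hits <- integer(p)
  imp_hist <- vector("list", p)
  shadow_max_hist <- numeric(0)
  runs <- 0L
  min_runs <- 5L
  for (run in seq_len(max_runs)) {
    active <- which(status == "tentative")
    if (!length(active)) break
    runs <- run
    # keep the shadow pool at the original feature count so the
    # max-shadow bar never weakens as the active set shrinks; a hit
    # always means beating the maximum of p null importances
    shadow_src <- rep_len(active, p)
    shadows <- apply(X[, shadow_src, drop = FALSE], 2, sample)
    Xext <- cbind(X[, active, drop = FALSE], shadows)
    fit <- cpp_rf_importance(Xext, yb, ntree = ntree, mtry = 0, min_node = 1,
                             seed = sample.int(.Machine$integer.max, 1))
    imp <- fit$importance
    n_act <- length(active)
    real_imp <- imp[seq_len(n_act)]
    shadow_max <- max(imp[n_act + seq_len(length(shadow_src))])
    shadow_max_hist <- c(shadow_max_hist, shadow_max)
    hit <- real_imp > shadow_max
    hits[active] <- hits[active] + hit
    for (k in seq_len(n_act))
      imp_hist[[active[k]]] <- c(imp_hist[[active[k]]], real_imp[k])
    if (run >= min_runs) {
      p_conf <- stats::pbinom(hits[active] - 1L, run, 0.5, lower.tail = FALSE)
      p_rej <- stats::pbinom(hits[active], run, 0.5)
      thr <- alpha / (p * run)   # Bonferroni over features x evaluations
      status[active[p_conf < thr]] <- "confirmed"
      status[active[p_rej < thr]] <- "rejected"
    }
  }
  # optional rough fix for residual tentatives
  tent <- if (rough_fix) which(status == "tentative") else integer()
  if (length(tent) && length(shadow_max_hist)) {
    med_shadow <- stats::median(shadow_max_hist)
    for (k in tent) {
      status[k] <- if (stats::median(imp_hist[[k]]) > med_shadow)
        "confirmed" else "rejected"
    }
  }
  structure(list(
    status = factor(status, levels = c("confirmed", "rejected", "tentative")),
    hit_count = hits, n_iterations = runs,
    confirmed = which(status == "confirmed")
  ), class = "boruta_decision")
}

.binary_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    lev <- sort(unique(y))
    if (length(lev) > 2) stop("more than two classes")
    # "case" (or the first level alphabetically) is the positive class
    pos <- if ("case" %in% lev) "case" else lev[1]
    as.integer(y == pos)
  } else {
    as.integer(y != 0)
  }
}

#' Train a linear support vector machine
#'
#' L2-regularized hinge-loss SVM (dual coordinate descent) with class-weight
#' balancing: each sample's box constraint is `C * n / (2 * n_class)`.
#'
#' @param X samples x features matrix (standardize before calling).
#' @param y Binary labels; `"case"` (or 1) is the positive class.
#' @param C Cost parameter (default 1).
#' @param balanced Apply class-weight balancing (default TRUE).
#' @param seed Seed for the coordinate-descent order.
#' @return list `w`, `b`; decision value is `X %*% w + b`, positive
#'   favouring the positive class.
#' @export
svm_train <- function(X, y, C = 1, balanced = TRUE, seed = 1L) {
  X <- as.matrix(X)
  yb <- .binary_labels(y)
  ys <- ifelse(yb == 1, 1, -1)
  n <- nrow(X)
  cost <- rep(C, n)
  if (balanced) {
    n1 <- sum(yb == 1); n0 <- n - n1
    cost <- C * n / (2 * ifelse(yb == 1, n1, n0))
  }
  fit <- cpp_svm_train(X, ys, cost, 1000L, 1e-4, as.integer(seed))
  list(w = as.numeric(fit$w), b = as.numeric(fit$b))
}

#' @rdname svm_train
#' @param model A fitted SVM from [svm_train()].
#' @export
svm_decision <- function(model, X) {
  as.numeric(as.matrix(X) %*% model$w + model$b)
}

#' Empirical ROC curve from decision scores
#'
#' @param scores Decision values (higher = more positive).
#' @param labels Binary labels; positive class as in [svm_train()].
#' @return list: `fpr`, `tpr` (including the (0,0) and (1,1) endpoints),
#'   `auc` (trapezoidal).
#' @export
roc_curve <- function(scores, labels) {
  yb <- .binary_labels(labels)
  stopifnot(length(scores) == length(yb), any(yb == 1), any(yb == 0))
  o <- order(scores, decreasing = TRUE)
  ys <- yb[o]; ss <- scores[o]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  # collapse tied scores to one operating point
  last <- c(ss[-1] != ss[-length(ss)], TRUE)
  tpr <- c(0, tp[last] / sum(yb))
  fpr <- c(0, fp[last] / sum(1 - yb))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Vertically average fold ROC curves on a fixed FPR grid
#'
#' Each fold's TPR is linearly interpolated at the grid; the averaged curve
#' is the pointwise mean. The headline AUC is the mean of the per-fold
#' trapezoidal AUCs; the area under the averaged curve is also returned.
#'
#' @param fold_rocs List of [roc_curve()] results (>= 1).
#' @param grid_step FPR grid step (default 0.01).
#' @return list: `fpr` (grid), `tpr` (mean curve), `auc` (mean of fold
#'   AUCs), `auc_of_mean_curve`, `tpr_matrix` (folds x grid).
#' @export
average_roc <- function(fold_rocs, grid_step = 0.01) {
  stopifnot(length(fold_rocs) >= 1)
  grid <- seq(0, 1, by = grid_step)
  tprm <- t(vapply(fold_rocs, function(rc) {
    stats::approx(rc$fpr, rc$tpr, xout = grid, ties = max, rule = 2)$y
  }, numeric(length(grid))))
  mean_tpr <- colMeans(tprm)
  auc_mean_curve <- sum(diff(grid) *
                          (mean_tpr[-1] + mean_tpr[-length(mean_tpr)]) / 2)
  list(fpr = grid, tpr = mean_tpr,
       auc = mean(vapply(fold_rocs, `[[`, 0, "auc")),
       auc_of_mean_curve = auc_mean_curve, tpr_matrix = tprm)
}

#' Bootstrap pointwise confidence band for the averaged ROC
#'
#' Fold curves are resampled with replacement `n_boot` times; the 2.5/97.5
#' percentiles of the resampled mean curve give the band, and the same
#' percentiles of the resampled mean fold AUC give the AUC CI.
#'
#' @param fold_rocs List of fold [roc_curve()] results (>= 2).
#' @param grid_step FPR grid step.
#' @param n_boot Bootstrap repetitions (default 10000).
#' @param seed Seed.
#' @return list: `fpr`, `lower`, `upper` (band), `auc_ci` (length 2),
#'   `mean_tpr`.
#' @export
bootstrap_band <- function(fold_rocs, grid_step = 0.01, n_boot = 10000,
                           seed = 1L) {
  stopifnot(length(fold_rocs) >= 2)
  avg <- average_roc(fold_rocs, grid_step)
  tprm <- avg$tpr_matrix
  aucs <- vapply(fold_rocs, `[[`, 0, "auc")
  nf <- nrow(tprm)
  set.seed(seed)
  boot_mean <- matrix(0, n_boot, ncol(tprm))
  boot_auc <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    ix <- sample.int(nf, nf, replace = TRUE)
    boot_mean[b, ] <- colMeans(tprm[ix, , drop = FALSE])
    boot_auc[b] <- mean(aucs[ix])
  }
  list(fpr = avg$fpr,
       lower = apply(boot_mean, 2, stats::quantile, probs = 0.025),
       upper = apply(boot_mean, 2, stats::quantile, probs = 0.975),
       auc_ci = stats::quantile(boot_auc, c(0.025, 0.975), names = FALSE),
       mean_tpr = avg$tpr)
}

# stratified fold assignment: returns integer fold id per sample
.stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Fit and score a single cross-validation fold (leakage-proof)
#'
#' All data-dependent transforms are fit on the training rows only:
#' surrogate variables are estimated on training and frozen (held-out rows
#' are projected by least squares onto the training loadings),
#' standardization uses training means/SDs, and Boruta runs on the adjusted
#' training matrix. The returned `frozen` element exposes everything fit on
#' training so leakage can be audited by corrupting held-out rows.
#'
#' @param values samples x features matrix.
#' @param labels Binary labels aligned to rows.
#' @param train_idx,test_idx Row indices.
#' @param sva Estimate and regress out surrogate variables (default TRUE).
#' @param boruta_max_runs,ntree,C Tuning parameters (see [boruta_select()],
#'   [svm_train()]).
#' @param seed Integer seed.
#' @return list: `scores` (decision values for `test_idx`), `roc`, `auc`,
#'   `selected` (feature indices used by the classifier), `frozen` (feature
#'   means/SDs, SV loadings, SVM weights).
#' @export
cv_fold <- function(values, labels, train_idx, test_idx, sva = TRUE,
                    boruta_max_runs = 100, ntree = 500, C = 1, seed = 1L) {
  Ytr <- values[train_idx, , drop = FALSE]
  Yte <- values[test_idx, , drop = FALSE]
  ytr <- labels[train_idx]
  set.seed(seed)
  if (sva) {
    sv_mod <- estimate_surrogates(Ytr, make_design(ytr),
                                   seed = sample.int(.Machine$integer.max, 1))
    if (sv_mod$n_sv > 0) {
      U <- sv_mod$sv_scores
      G <- solve(crossprod(U), crossprod(U, scale(Ytr, scale = FALSE)))
      ctr <- colMeans(Ytr)
      Ytr <- Ytr - U %*% G
      Ute <- project_surrogates(sv_mod, Yte)
      Yte <- Yte - Ute %*% G
    }
  } else sv_mod <- NULL
  mu <- colMeans(Ytr)
  sdv <- apply(Ytr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Ztr <- sweep(sweep(Ytr, 2, mu), 2, sdv, `/`)
  Zte <- sweep(sweep(Yte, 2, mu), 2, sdv, `/`)
  bor <- boruta_select(Ztr, ytr, max_runs = boruta_max_runs, ntree = ntree,
                       seed = sample.int(.Machine$integer.max, 1))
  sel <- bor$confirmed
  if (!length(sel)) sel <- seq_len(ncol(Ztr))   # fall back to all features
  svc <- svm_train(Ztr[, sel, drop = FALSE], ytr, C = C,
                   seed = sample.int(.Machine$integer.max, 1))
  scores <- svm_decision(svc, Zte[, sel, drop = FALSE])
  rc <- if (length(unique(labels[test_idx])) == 2)
    roc_curve(scores, labels[test_idx]) else NULL
  list(scores = scores, roc = rc, auc = if (!is.null(rc)) rc$auc else NA_real_,
       selected = bor$confirmed,
       frozen = list(mu = mu, sd = sdv, sv = sv_mod, w = svc$w, b = svc$b))
}

#' Repeated stratified cross-validation with in-fold feature selection
#'
#' For every fold: surrogate variables fit on training and frozen, features
#' standardized by training statistics, Boruta selection on training, a
#' class-weighted linear SVM trained on the confirmed features, and
#' decision values computed for the held-out samples. Fold ROC curves are
#' vertically averaged and a bootstrap band is attached.
#'
#' @param values samples x features matrix (or `breath_profile`).
#' @param labels Binary labels (`"case"`/`"control"` or 0/1) per row.
#' @param n_repeats,n_folds Repetitions and folds (defaults 10 and 10).
#' @param sva,boruta_max_runs,ntree,C See [cv_fold()].
#' @param n_boot Bootstrap repetitions for the band (default 10000).
#' @param seed Master seed; folds, shadows and bootstrap all derive from it.
#' @return Object of class `cv_report`: `fold_aucs`, `fold_rocs`,
#'   `selected_sets`, `selection_frequency`, `mean_auc`, `auc_ci`,
#'   `average_roc`, `band`, `n_selected_mean`, `n_selected_sd`.
#' @export
run_cv <- function(values, labels, n_repeats = 10, n_folds = 10, sva = TRUE,
                   boruta_max_runs = 100, ntree = 500, C = 1,
                   n_boot = 10000, seed = 1L) {
  if (inherits(values, "breath_profile")) values <- values$values
  values <- as.matrix(values)
  yb <- .binary_labels(labels)
  stopifnot(length(yb) == nrow(values))
  if (min(table(yb)) < n_folds)
    stop("smallest class has fewer samples than folds; stratification fails")
  set.seed(seed)
  fold_rocs <- list(); fold_aucs <- numeric(); selected_sets <- list()
  for (r in seq_len(n_repeats)) {
    fold <- .stratified_folds(yb, n_folds)
    for (f in seq_len(n_folds)) {
      res <- cv_fold(values, labels, which(fold != f), which(fold == f),
                     sva = sva, boruta_max_runs = boruta_max_runs,
                     ntree = ntree, C = C,
                     seed = sample.int(.Machine$integer.max, 1))
      fold_rocs[[length(fold_rocs) + 1L]] <- res$roc
      fold_aucs <- c(fold_aucs, res$auc)
      selected_sets[[length(selected_sets) + 1L]] <- res$selected
    }
  }
  avg <- average_roc(fold_rocs)
  band <- bootstrap_band(fold_rocs, n_boot = n_boot,
                         seed = sample.int(.Machine$integer.max, 1))
  sel_freq <- tabulate(unlist(selected_sets), nbins = ncol(values)) /
    length(selected_sets)
  n_sel <- lengths(selected_sets)
  structure(list(
    fold_aucs = fold_aucs, fold_rocs = fold_rocs,
    selected_sets = selected_sets, selection_frequency = sel_freq,
    mean_auc = mean(fold_aucs), auc_ci = band$auc_ci,
    average_roc = avg, band = band,
    n_selected_mean = mean(n_sel), n_selected_sd = stats::sd(n_sel)
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Repeated stratified CV: %d folds\n", length(x$fold_aucs)))
  cat(sprintf("  mean AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$mean_auc, x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("  selected features per fold: %.1f (+/- %.1f)\n",
              x$n_selected_mean, x$n_selected_sd))
  invisible(x)
}
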