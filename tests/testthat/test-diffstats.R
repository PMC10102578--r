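test_that("design coding makes negative coefficients mean higher in cases", {
  g <- c("case", "case", "control", "control")
  X <- make_design(g)
  expect_equal(unname(X[, "group"]), c(0, 0, 1, 1))
  Y <- cbind(c(10, 10, 8, 8))                  # elevated in cases
  tt <- fit_moderated(cbind(Y, Y + rnorm(4, sd = .01)), X)
  expect_lt(tt$lfc[1], 0)
})

test_that("moderated statistics agree with the reference empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(21)
  n <- 24; p <- 500
  g <- rep(c("case", "control"), each = n / 2)
  # heteroscedastic features so the prior df is finite
  sds <- sqrt(1 / rgamma(p, shape = 4, rate = 4))
  Y <- sapply(sds, function(s) rnorm(n, sd = s))
  Y[g == "case", 1:40] <- Y[g == "case", 1:40] + 0.8
  X <- make_design(g)
  tt <- fit_moderated(Y, X)
  fit <- limma::lmFit(t(Y), X)
  eb <- limma::eBayes(fit)
  expect_equal(attr(tt, "d0"), unname(eb$df.prior), tolerance = 1e-6)
  expect_equal(attr(tt, "s0_sq"), unname(eb$s2.prior), tolerance = 1e-6)
  expect_equal(tt$t_mod, unname(eb$t[, "group"]), tolerance = 1e-8)
  expect_equal(tt$p_raw, unname(eb$p.value[, "group"]), tolerance = 1e-8)
  expect_equal(tt$lfc, unname(eb$coefficients[, "group"]), tolerance = 1e-10)
})

test_that("equal residual variances hit the d0 = Inf fixed point", {
  # construct features with identical residual sum of squares
  n <- 8
  g <- rep(c("case", "control"), each = 4)
  base <- c(1, -1, 2, -2, 1.5, -1.5, 0.5, -0.5)
  Y <- sapply(1:50, function(j) base + j)       # same spread, shifted means
  tt <- fit_moderated(Y, make_design(g))
  expect_equal(attr(tt, "d0"), Inf)
  # all posterior variances collapse to s0^2: moderated t proportional to
  # the ordinary t with a common scale
  expect_equal(length(unique(round(tt$s2, 10))), 1)
})

test_that("zero-variance features are flagged with p = 1, not dropped", {
  set.seed(4)
  n <- 10
  g <- rep(c("case", "control"), each = 5)
  Y <- cbind(matrix(rnorm(n * 20), n), rep(3, n))
  tt <- fit_moderated(Y, make_design(g))
  expect_equal(nrow(tt), 21)
  expect_true(tt$flagged[21])
  expect_equal(tt$p_raw[21], 1)
})

test_that("BH step-up matches hand computation and reference implementation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(2)
  for (i in 1:10) {
    p <- runif(200)^2
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
    # permutation-equivariance (monotone in rank, exact)
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  }
  pp <- bh_adjust(runif(100))
  expect_true(all(pp >= 0 & pp <= 1))
})

test_that("SVA recovers a planted batch factor and ignores pure noise", {
  set.seed(13)
  n <- 60; p <- 400
  g <- rep(c("case", "control"), each = 30)
  batch <- sample(rep(0:1, each = 30))          # orthogonal-ish to group
  Y <- matrix(rnorm(n * p, sd = 0.3), n, p) +
    outer(batch - 0.5, rnorm(p, sd = 1))        # effect SD >= 3x noise SD
  sv <- estimate_surrogates(Y, make_design(g), seed = 2)
  expect_gte(sv$n_sv, 1)
  expect_gt(abs(cor(sv$sv_scores[, 1], batch)), 0.9)
  # orthonormal scores
  expect_equal(crossprod(sv$sv_scores), diag(sv$n_sv), tolerance = 1e-8)

  # i.i.d. noise: no surrogate found in >= 90% of seeds
  found <- vapply(1:10, function(s) {
    set.seed(100 + s)
    Y0 <- matrix(rnorm(40 * 200), 40, 200)
    estimate_surrogates(Y0, make_design(rep(c("case", "control"), each = 20)),
                        seed = s)$n_sv
  }, 0L)
  expect_gte(mean(found == 0), 0.9)

  # adding a constant to every sample is absorbed by the intercept
  sv2 <- estimate_surrogates(Y + 5, make_design(g), seed = 2)
  expect_equal(sv2$sv_scores, sv$sv_scores, tolerance = 1e-8)
})

test_that("frozen projection reproduces training scores for training data", {
  set.seed(31)
  n <- 40; p <- 150
  g <- rep(c("case", "control"), each = 20)
  batch <- rep_len(0:1, n)
  Y <- matrix(rnorm(n * p, sd = .3), n, p) + outer(batch - .5, rnorm(p))
  sv <- estimate_surrogates(Y, make_design(g), seed = 7)
  proj <- project_surrogates(sv, Y)
  # least-squares projection of the training rows correlates strongly with
  # the fitted scores (they differ by the primary-model residualization)
  expect_gt(abs(cor(proj[, 1], sv$sv_scores[, 1])), 0.95)
})

test_that("PCA scores behave on rank-1, isotropic and reordered data", {
  set.seed(6)
  u <- rnorm(20); v <- rnorm(5)
  r1 <- pca_scores(outer(u, v))
  expect_equal(r1$explained[1], 1)
  expect_equal(sum(r1$explained), 1)

  iso <- matrix(rnorm(4000 * 2), 4000, 2)
  expect_lt(max(abs(pca_scores(iso)$explained - 0.5)), 0.1)

  Y <- matrix(rnorm(30 * 8), 30, 8)
  a <- pca_scores(Y); b <- pca_scores(Y[, sample(8)])
  expect_equal(abs(a$scores[, 1]), abs(b$scores[, 1]), tolerance = 1e-8)
})

test_that("cohort statistics reproduce the participant-table p-values", {
  # age row: means/SDs/n per group
  expect_equal(round(t_test_from_summary(12.1, 3.1, 48, 10.8, 4.0, 56)$p, 2),
               0.07)
  # male sex 2x2
  expect_equal(round(fisher_2x2(33, 15, 24, 32), 2), 0.01)
  # equal proportions, equal n: Fisher p = 1
  expect_equal(fisher_2x2(10, 10, 10, 10), 1)
  # Mann-Whitney wrapper: symmetric null sanity + exact/normal switch
  set.seed(8)
  expect_gt(mann_whitney(rnorm(15), rnorm(15)), 0.01)
  expect_gt(mann_whitney(rnorm(30), rnorm(30)), 0.01)
  expect_lt(mann_whitney(rnorm(30), rnorm(30) + 5), 1e-6)
})
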