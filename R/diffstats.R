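#' Build the primary design matrix
#'
#' Intercept plus a binary group indicator coded control = 1, case = 0, so
#' that a negative group coefficient means higher average expression in the
#' case (asthmatic) group; surrogate variables are appended as extra
#' columns when supplied.
#'
#' @param group Character/factor vector with levels `"case"`/`"control"`.
#' @param sv Optional samples x k matrix of surrogate variable scores.
#' @return Numeric design matrix (samples x (2 + k)).
#' @export
make_design <- function(group, sv = NULL) {
  g <- as.character(group)
  stopifnot(all(g %in% c("case", "control")))
  X <- cbind(intercept = 1, group = as.numeric(g == "control"))
  if (!is.null(sv) && NCOL(sv) > 0) {
    sv <- as.matrix(sv)
    colnames(sv) <- sprintf("sv%d", seq_len(ncol(sv)))
    X <- cbind(X, sv)
  }
  X
}

# Newton inversion of trigamma, tolerance 1e-8
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

#' Empirical-Bayes moderated t-statistics for a two-group design
#'
#' Per-feature least squares on a common design gives coefficients and
#' residual variances s2_g on d = n - p degrees of freedom. A scaled
#' inverse-chi-square prior (d0, s0^2) is estimated by method of moments on
#' e_g = log s2_g - digamma(d/2) + log(d/2) (digamma/trigamma relations,
#' trigamma inverted by Newton iteration); the posterior variance
#' s2_post = (d0 s0^2 + d s2_g) / (d0 + d) moderates the t statistic
#' t = beta / (u sqrt(s2_post)) on d0 + d degrees of freedom. When the
#' moment estimate of the spread is <= 0 the d0 = Inf branch applies and
#' every posterior variance equals s0^2.
#'
#' @param values samples x features log2 matrix (or a `breath_profile`).
#' @param design Design matrix from [make_design()]; the tested coefficient
#'   is the column named `group`.
#' @return data.frame (one row per feature): `beta_hat`, `lfc` (same as
#'   beta_hat under the control-coded design: negative = higher in cases),
#'   `s2`, `df_resid`, `t_mod`, `p_raw`, `p_adj`, `flagged` (zero-variance
#'   features, assigned p = 1); attributes `d0`, `s0_sq`.
#' @export
fit_moderated <- function(values, design) {
  if (inherits(values, "breath_profile")) values <- values$values
  Y <- as.matrix(values)
  X <- as.matrix(design)
  n <- nrow(Y); p <- ncol(X)
  stopifnot(n == nrow(X), n > p)
  ci <- match("group", colnames(X))
  if (is.na(ci)) stop("design has no 'group' column")
  XtXi <- solve(crossprod(X))
  beta <- XtXi %*% crossprod(X, Y)              # p x G
  resid <- Y - X %*% beta
  d <- n - p
  s2 <- colSums(resid^2) / d
  u <- sqrt(XtXi[ci, ci])

  # zero-variance features: exact constants leave rounding-level residuals
  ok <- s2 > 1e-20 * pmax(colMeans(Y * Y), 1)
  if (!any(ok)) stop("all features have zero residual variance")
  e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s0_sq + d * s2) / (d0 + d)
    df_total <- d0 + d
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
    s2_post <- rep(s0_sq, length(s2))
    df_total <- Inf
  }
  t_mod <- beta[ci, ] / (u * sqrt(s2_post))
  p_raw <- 2 * stats::pt(-abs(t_mod), df = df_total)
  flagged <- !ok
  t_mod[flagged] <- 0
  p_raw[flagged] <- 1
  out <- data.frame(
    beta_hat = beta[ci, ], lfc = beta[ci, ], s2 = s2, df_resid = d,
    t_mod = t_mod, p_raw = p_raw, p_adj = bh_adjust(p_raw),
    flagged = flagged
  )
  rownames(out) <- colnames(Y)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adj_(i) = min_{j >= i} (p_(j) m / j)`, capped at 1, returned in the
#' input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p)
  adj <- pmin(1, cummin(rev(p[o] * m / seq_len(m))))
  out <- numeric(m)
  out[o] <- rev(adj)
  out
}

#' Surrogate variable analysis (permutation-calibrated, iteratively
#' reweighted)
#'
#' The number of surrogate variables is chosen by permutation parallel
#' analysis on the residuals of the primary model: each feature's residuals
#' are permuted independently across samples `n_perm` times, and the k-th
#' observed singular-value variance fraction must exceed the permuted
#' (1 - alpha) quantile for the k-th component (counting consecutively from
#' the first). The scores are then refined by an iteratively reweighted SVD:
#' each iteration weights every feature by its empirical probability of
#' association with the current surrogate scores times the probability of
#' NO association with the group (both from F-test p-values), scales the
#' centered data columns by these weights, and takes the leading left
#' singular vectors of the weighted matrix. Working on the weighted data
#' rather than the residuals lets a confounder partially aligned with the
#' group be recovered in full from the group-null features. Feature-space
#' loadings are stored so held-out samples can be projected onto frozen
#' surrogates by least squares.
#'
#' @param values samples x features matrix (or `breath_profile`).
#' @param design Primary design matrix (intercept + group).
#' @param n_perm Permutations for parallel analysis (default 20).
#' @param alpha Per-component significance level (default 0.05).
#' @param n_iter Reweighting iterations (default 20; under strong
#'   confounding the reweighting needs well over 5 iterations to converge
#'   on the confounder direction).
#' @param seed Seed for the permutation stream.
#' @return Object of class `sv_model`: `n_sv`, `sv_scores` (orthonormal
#'   columns), `sv_loadings` (features x n_sv), `iterations_run`,
#'   `feature_means`.
#' @export
estimate_surrogates <- function(values, design, n_perm = 20, alpha = 0.05,
                                n_iter = 20, seed = 1L) {
  if (inherits(values, "breath_profile")) values <- values$values
  Y <- as.matrix(values)
  X <- as.matrix(design)
  n <- nrow(Y)
  stopifnot(n > qr(X)$rank + 1)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  R <- Y - H %*% Y
  dsv <- svd(R, nu = 0, nv = 0)$d
  frac <- dsv^2 / sum(dsv^2)
  set.seed(seed)
  kmax <- length(dsv)
  perm_frac <- matrix(0, n_perm, kmax)
  for (b in seq_len(n_perm)) {
    Rp <- apply(R, 2, sample)
    Rp <- Rp - H %*% Rp
    dp <- svd(Rp, nu = 0, nv = 0)$d
    perm_frac[b, ] <- dp^2 / sum(dp^2)
  }
  qthr <- apply(perm_frac, 2, stats::quantile, probs = 1 - alpha)
  n_sv <- 0L
  for (k in seq_len(kmax)) {
    if (frac[k] > qthr[k]) n_sv <- k else break
  }
  if (n_sv == 0L) {
    return(structure(list(n_sv = 0L, sv_scores = matrix(0, n, 0),
                          sv_loadings = matrix(0, ncol(Y), 0),
                          iterations_run = 0L,
                          feature_means = colMeans(Y)),
                     class = "sv_model"))
  }
  # iteratively reweighted refinement. Weights favour features associated
  # with the current surrogates but NOT with the primary variable, and the
  # SVD runs on the weighted *centered data* (not the residuals): this is
  # what lets a batch direction partially aligned with the group be
  # recovered in full from the group-null features.
  Yc <- sweep(Y, 2, colMeans(Y))
  X0 <- X[, setdiff(colnames(X), "group"), drop = FALSE]
  if (!ncol(X0)) X0 <- matrix(1, n, 1)
  sv <- svd(R, nu = n_sv, nv = 0)$u
  iters <- 0L
  for (it in seq_len(n_iter)) {
    p_sv <- .f_test_p(Y, X, sv)                 # association with surrogates
    p_grp <- .f_test_p(Y, cbind(X0, sv), X[, "group", drop = FALSE])
    w <- (1 - p_sv) * p_grp
    Yw <- sweep(Yc, 2, w, `*`)
    sv <- svd(Yw, nu = n_sv, nv = 0)$u
    iters <- it
  }
  loadings <- crossprod(Yc, sv)   # features x n_sv, for frozen projection
  structure(list(n_sv = n_sv, sv_scores = sv, sv_loadings = loadings,
                 iterations_run = iters, feature_means = colMeans(Y)),
            class = "sv_model")
}

# per-feature F-test p for adding columns U to design X
.f_test_p <- function(Y, X, U) {
  n <- nrow(Y)
  X1 <- cbind(X, U)
  H0 <- X %*% solve(crossprod(X)) %*% t(X)
  H1 <- X1 %*% solve(crossprod(X1)) %*% t(X1)
  rss0 <- colSums((Y - H0 %*% Y)^2)
  rss1 <- colSums((Y - H1 %*% Y)^2)
  df1 <- ncol(X1) - ncol(X)
  df2 <- n - ncol(X1)
  f <- pmax(0, (rss0 - rss1) / df1) / pmax(rss1 / df2, .Machine$double.eps)
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

#' Project held-out samples onto frozen surrogate loadings
#'
#' Held-out rows are centered by the training feature means and regressed
#' on the training loadings by least squares; no quantity is re-estimated
#' from the held-out data.
#'
#' @param model An `sv_model` fit on training data.
#' @param values Held-out samples x features matrix.
#' @return samples x n_sv matrix of surrogate scores.
#' @export
project_surrogates <- function(model, values) {
  stopifnot(inherits(model, "sv_model"))
  Y <- as.matrix(values)
  if (model$n_sv == 0L) return(matrix(0, nrow(Y), 0))
  Yc <- sweep(Y, 2, model$feature_means)
  B <- model$sv_loadings
  t(solve(crossprod(B), t(Yc %*% B)))
}

#' Principal-component scores of a feature matrix
#'
#' Column-centered SVD; explained-variance fractions sum to 1.
#'
#' @param values samples x features matrix (or `breath_profile`).
#' @param feature_subset Optional column indices to restrict to.
#' @return list: `scores` (samples x k), `explained` (variance fractions).
#' @export
pca_scores <- function(values, feature_subset = NULL) {
  if (inherits(values, "breath_profile")) values <- values$values
  Y <- as.matrix(values)
  if (!is.null(feature_subset)) Y <- Y[, feature_subset, drop = FALSE]
  stopifnot(nrow(Y) >= 2, ncol(Y) >= 2)
  Yc <- sweep(Y, 2, colMeans(Y))
  s <- svd(Yc)
  pos <- s$d > s$d[1] * 1e-12
  scores <- s$u[, pos, drop = FALSE] %*% diag(s$d[pos], sum(pos))
  list(scores = scores, explained = s$d[pos]^2 / sum(s$d[pos]^2))
}

#' Two-sample pooled-variance t-test from summary statistics
#'
#' @param mean1,sd1,n1 Summary of group 1.
#' @param mean2,sd2,n2 Summary of group 2.
#' @return list: `t`, `df`, `p` (two-sided).
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Two-sided Fisher's exact test on a 2x2 count table
#'
#' @param a,b First row of the table (e.g. males per group).
#' @param c,d Second row.
#' @return Two-sided p-value.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, c, b, d), 2, 2))$p.value
}

#' Mann-Whitney U test (exact for small samples, otherwise normal
#' approximation with continuity correction)
#'
#' @param x,y Raw observations per group.
#' @return Two-sided p-value.
#' @export
mann_whitney <- function(x, y) {
  exact <- length(x) <= 20 && length(y) <= 20
  stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
}
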