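# Supervised PLS-DA, written from scratch around the classical NIPALS
# (nonlinear iterative partial least squares) algorithm, with SIMCA-style
# diagnostics: cross-validated Q2, VIP scores, permutation validation and
# the Hotelling T2 ellipse.

#' Autoscale a numeric matrix
#'
#' Centers every column to mean 0 and scales it to unit sample standard
#' deviation. Zero-variance columns are mapped to all-zeros and flagged
#' rather than producing NaNs; their scale is recorded as 1 so the
#' transform stays invertible.
#'
#' @param x Numeric matrix or data frame with at least 2 rows.
#' @return List with `x` (scaled matrix), `center`, `scale`,
#'   `zero_variance` (logical per column).
#' @export
autoscale <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("autoscaling needs at least 2 rows", call. = FALSE)
  center <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  zero <- !is.finite(s) | s < .Machine$double.eps^0.5
  s[zero] <- 1
  xs <- sweep(sweep(x, 2, center, "-"), 2, s, "/")
  xs[, zero] <- 0
  list(x = xs, center = center, scale = s, zero_variance = zero)
}

#' Invert an autoscaling transform
#'
#' @param xs Scaled matrix.
#' @param scaling The list returned by [autoscale()] (or any list with
#'   `center` and `scale`).
#' @return The matrix on its original scale.
#' @export
unscale <- function(xs, scaling) {
  sweep(sweep(as.matrix(xs), 2, scaling$scale, "*"), 2, scaling$center, "+")
}

#' One-hot (dummy) coding of group labels
#'
#' @param groups Character or factor vector of group labels.
#' @param group_labels Ordered set of allowed labels; defaults to the
#'   observed labels in order of first appearance.
#' @return An n x G indicator matrix with one 1 per row.
#' @export
one_hot <- function(groups, group_labels = unique(as.character(groups))) {
  groups <- as.character(groups)
  unknown <- setdiff(unique(groups), group_labels)
  if (length(unknown) > 0) {
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  y <- matrix(0, nrow = length(groups), ncol = length(group_labels),
              dimnames = list(NULL, group_labels))
  y[cbind(seq_along(groups), match(groups, group_labels))] <- 1
  y
}

# NIPALS PLS2 on already-scaled X and Y. Deterministic: the starting u is
# the Y column with the largest variance; each weight vector's
# largest-magnitude element is made positive. Components whose score norm
# collapses (rank exhausted) stop extraction early.
.nipals_pls <- function(xs, ys, ncomp, tol = 1e-10, maxit = 500L) {
  n <- nrow(xs); p <- ncol(xs); g <- ncol(ys)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  C <- matrix(0, g, ncomp); TT <- matrix(0, n, ncomp)
  ssx <- ssy <- numeric(ncomp)
  X <- xs; Y <- ys
  a_done <- 0L
  for (a in seq_len(ncomp)) {
    yvar <- apply(Y, 2, stats::var)
    if (all(yvar < .Machine$double.eps)) break
    u <- Y[, which.max(yvar)]
    w <- rep(0, p)
    for (it in seq_len(maxit)) {
      w_old <- w
      w <- crossprod(X, u)[, 1] / sum(u^2)
      nw <- sqrt(sum(w^2))
      if (nw < .Machine$double.eps) break
      w <- w / nw
      t_a <- X %*% w
      c_a <- crossprod(Y, t_a)[, 1] / sum(t_a^2)
      u <- (Y %*% c_a)[, 1] / sum(c_a^2)
      if (sqrt(sum((w - w_old)^2)) < tol) break
    }
    t_a <- (X %*% w)[, 1]
    tt <- sum(t_a^2)
    if (tt < 1e-12) break
    c_a <- crossprod(Y, t_a)[, 1] / tt
    # sign convention: largest-magnitude weight element positive
    j <- which.max(abs(w))
    if (w[j] < 0) { w <- -w; t_a <- -t_a; c_a <- -c_a }
    p_a <- crossprod(X, t_a)[, 1] / tt
    X <- X - tcrossprod(t_a, p_a)
    Y <- Y - tcrossprod(t_a, c_a)
    W[, a] <- w; P[, a] <- p_a; C[, a] <- c_a; TT[, a] <- t_a
    ssx[a] <- tt * sum(p_a^2)
    ssy[a] <- tt * sum(c_a^2)
    a_done <- a
  }
  keep <- seq_len(a_done)
  list(W = W[, keep, drop = FALSE], P = P[, keep, drop = FALSE],
       C = C[, keep, drop = FALSE], scores = TT[, keep, drop = FALSE],
       ssx = ssx[keep], ssy = ssy[keep], ncomp = a_done)
}

# regression coefficients for cumulative predictions at each model size
.pls_coef <- function(fit, a) {
  W <- fit$W[, seq_len(a), drop = FALSE]
  P <- fit$P[, seq_len(a), drop = FALSE]
  C <- fit$C[, seq_len(a), drop = FALSE]
  W %*% solve(crossprod(P, W), t(C))
}

# interleaved (venetian-blind) fold assignment
.venetian_folds <- function(n, folds) ((seq_len(n) - 1L) %% folds) + 1L

# cross-validated Q2 for model sizes 1..ncomp; scaling parameters are
# re-estimated inside each training fold
.plsda_cv <- function(x, groups, ncomp, folds, group_labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  fold_id <- .venetian_folds(n, folds)
  press <- numeric(ncomp)
  ss <- 0
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    absent <- setdiff(group_labels, unique(as.character(groups[tr])))
    if (length(absent) > 0) {
      warning("fold ", f, " leaves group(s) absent from training: ",
              paste(absent, collapse = ", "), call. = FALSE)
    }
    sx <- autoscale(x[tr, , drop = FALSE])
    y_tr <- one_hot(groups[tr], group_labels)
    sy <- autoscale(y_tr)
    fit <- .nipals_pls(sx$x, sy$x, ncomp)
    if (fit$ncomp == 0) next
    x_te <- sweep(sweep(x[!tr, , drop = FALSE], 2, sx$center, "-"),
                  2, sx$scale, "/")
    x_te[, sx$zero_variance] <- 0
    y_te <- one_hot(groups[!tr], group_labels)
    # Y columns are kept even when constant in training (a class the fold
    # cannot predict); their deviance counts against the model
    y_te <- sweep(sweep(y_te, 2, sy$center, "-"), 2, sy$scale, "/")
    ss <- ss + sum(y_te^2)
    for (a in seq_len(ncomp)) {
      a_eff <- min(a, fit$ncomp)
      resid <- y_te - x_te %*% .pls_coef(fit, a_eff)
      press[a] <- press[a] + sum(resid^2)
    }
  }
  if (ss <= 0) return(rep(NA_real_, ncomp))
  1 - press / ss
}

#' Cross-validated predictive ability Q2
#'
#' Computes `Q2 = 1 - PRESS/SS` by interleaved (venetian-blind) k-fold
#' cross-validation: fold `i` holds every k-th injection, scaling is
#' re-estimated inside each training fold, and squared prediction errors of
#' the held-out dummy response accumulate into PRESS. `Q2 <= 0` means the
#' model predicts no better than the training-fold mean.
#'
#' @param x Injections-by-compounds numeric matrix or data frame.
#' @param groups Group label per row.
#' @param ncomp Number of PLS components.
#' @param folds Number of folds (default 7).
#' @param group_labels Ordered group set (defaults to observed labels).
#' @return Q2 at `ncomp` components (scalar).
#' @export
cross_validated_q2 <- function(x, groups, ncomp, folds = 7,
                               group_labels = unique(as.character(groups))) {
  stopifnot(folds >= 2)
  q2 <- .plsda_cv(x, groups, ncomp, folds, group_labels)
  q2[length(q2)]
}

#' Fit a PLS-DA model
#'
#' Supervised partial least squares discriminant analysis: the group labels
#' are dummy-coded, both blocks are autoscaled, and components are
#' extracted by NIPALS PLS2 with deflation. Reported diagnostics follow
#' chemometrics convention: `r2x`/`r2y` are the fractions of X/Y variance
#' explained by the extracted components and `q2` is the cross-validated
#' predictive ability.
#'
#' With `ncomp = "auto"` the model grows while cross-validated Q2 improves
#' by more than `q2_improvement`, capped at `min(10, n - 1, p, G)`.
#'
#' @param x Injections-by-compounds matrix or data frame (numeric).
#' @param groups Group label per row (character or factor).
#' @param ncomp Number of components, or `"auto"` (default).
#' @param folds Cross-validation folds for Q2 (default 7, interleaved).
#' @param group_labels Ordered group set; defaults to observed labels.
#' @param q2_improvement Minimal Q2 gain to add a component (default 0.01).
#' @param max_ncomp Hard cap on components under `"auto"` (default 10).
#' @return An object of class `plsda` with scores, weights, loadings,
#'   per-component explained variances, `r2x`, `r2y`, `q2` and the scaling
#'   parameters. Use [tidy()], [glance()], [vip()] and [autoplot()] on it.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 20, 3)
#' x[1:10, 1] <- x[1:10, 1] + 4
#' fit <- fit_plsda(x, rep(c("a", "b"), each = 10), ncomp = 2)
#' glance(fit)
fit_plsda <- function(x, groups, ncomp = "auto", folds = 7,
                      group_labels = unique(as.character(groups)),
                      q2_improvement = 0.01, max_ncomp = 10) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 3) stop("need at least 3 rows to fit a PLS-DA model",
                  call. = FALSE)
  if (length(groups) != n) stop("groups must match rows of x",
                                call. = FALSE)
  g <- length(group_labels)
  a_cap <- min(max_ncomp, n - 1, p, g)
  q2_path <- NULL
  if (identical(ncomp, "auto")) {
    q2_path <- .plsda_cv(x, groups, a_cap, folds, group_labels)
    a <- 1L
    while (a < a_cap && q2_path[a + 1] - q2_path[a] > q2_improvement) {
      a <- a + 1L
    }
  } else {
    a <- as.integer(ncomp)
    if (a > min(n - 1, p)) {
      warning("ncomp exceeds the data rank bound; truncated to ",
              min(n - 1, p), call. = FALSE)
      a <- min(n - 1, p)
    }
  }
  sx <- autoscale(x)
  y <- one_hot(groups, group_labels)
  sy <- autoscale(y)
  fit <- .nipals_pls(sx$x, sy$x, a)
  if (fit$ncomp < a) {
    warning("rank exhausted: extracted ", fit$ncomp, " of ", a,
            " requested components", call. = FALSE)
  }
  if (is.null(q2_path)) {
    q2_path <- .plsda_cv(x, groups, fit$ncomp, folds, group_labels)
  }
  rownames(fit$scores) <- rownames(x)
  rownames(fit$W) <- rownames(fit$P) <- colnames(x)
  rownames(fit$C) <- group_labels
  structure(list(
    scores = fit$scores, weights = fit$W, x_loadings = fit$P,
    y_loadings = fit$C, ssx = fit$ssx, ssy = fit$ssy,
    ncomp = fit$ncomp,
    r2x = sum(fit$ssx) / sum(sx$x^2),
    r2y = sum(fit$ssy) / sum(sy$x^2),
    q2 = q2_path[min(fit$ncomp, length(q2_path))],
    q2_per_component = q2_path,
    x_center = sx$center, x_scale = sx$scale,
    zero_variance = sx$zero_variance,
    y_center = sy$center, y_scale = sy$scale,
    groups = as.character(groups), group_labels = group_labels,
    compounds = colnames(x), folds = folds, n = n, p = p),
    class = "plsda")
}

#' Variable importance in projection (VIP) scores
#'
#' `VIP_j = sqrt( p * sum_a ssy_a w_aj^2 / sum_a ssy_a )` with unit-norm
#' weight vectors, so the mean squared VIP is exactly 1; VIP > 1 marks a
#' variable contributing more than average to the discrimination.
#'
#' @param model A fitted [fit_plsda()] object.
#' @return Tibble with columns `compound_id`, `vip`, sorted by decreasing
#'   VIP.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "plsda"))
  if (sum(model$ssy) <= 0) {
    stop("model explains no Y variance; VIP undefined", call. = FALSE)
  }
  v <- sqrt(model$p * (model$weights^2 %*% model$ssy)[, 1] / sum(model$ssy))
  out <- tibble::tibble(
    compound_id = model$compounds %||% as.character(seq_len(model$p)),
    vip = unname(v))
  dplyr::arrange(out, dplyr::desc(.data$vip))
}

#' SIMCA-style permutation validation of a PLS-DA model
#'
#' Refits the model `n_perm` times with jointly permuted group labels and
#' records, for each permutation, the label-correlation statistic (mean
#' absolute column-wise Pearson correlation between the permuted and
#' original dummy response), the permuted R2Y, and the permuted
#' cross-validated Q2. Regression lines of R2Y and Q2 against the
#' correlation, through all permutations plus the original model at
#' correlation 1, give the reported intercepts. A reliable model shows all
#' permuted Q2 below the original and a negative Q2 intercept.
#'
#' @param x Injections-by-compounds matrix.
#' @param groups Group label per row.
#' @param ncomp Number of components (fixed across refits).
#' @param n_perm Number of permutations (default 200).
#' @param folds CV folds for Q2 (default 7).
#' @param seed Integer seed for the permutations.
#' @param group_labels Ordered group set.
#' @return An object of class `plsda_permutation`; see [tidy()] and
#'   [glance()] methods.
#' @export
permutation_test <- function(x, groups, ncomp, n_perm = 200, folds = 7,
                             seed = 1L,
                             group_labels = unique(as.character(groups))) {
  stopifnot(n_perm >= 1)
  x <- as.matrix(x)
  n <- nrow(x)
  set.seed(as.integer(seed))
  y0 <- one_hot(groups, group_labels)
  fit0 <- fit_plsda(x, groups, ncomp = ncomp, folds = folds,
                    group_labels = group_labels)
  rows <- vector("list", n_perm + 1)
  rows[[1]] <- tibble::tibble(perm = 0L, correlation = 1,
                              r2y = fit0$r2y, q2 = fit0$q2)
  for (k in seq_len(n_perm)) {
    ord <- sample.int(n)
    gp <- groups[ord]
    yp <- y0[ord, , drop = FALSE]
    corr <- mean(abs(diag(stats::cor(yp, y0))))
    fitp <- fit_plsda(x, gp, ncomp = ncomp, folds = folds,
                      group_labels = group_labels)
    rows[[k + 1]] <- tibble::tibble(perm = k, correlation = corr,
                                    r2y = fitp$r2y, q2 = fitp$q2)
  }
  perms <- dplyr::bind_rows(rows)
  r2_fit <- stats::lm(r2y ~ correlation, data = perms)
  q2_fit <- stats::lm(q2 ~ correlation, data = perms)
  structure(list(
    permutations = perms,
    r2_intercept = unname(stats::coef(r2_fit)[1]),
    q2_intercept = unname(stats::coef(q2_fit)[1]),
    r2y_original = fit0$r2y, q2_original = fit0$q2,
    ncomp = fit0$ncomp, n_perm = n_perm, folds = folds),
    class = "plsda_permutation")
}

#' Hotelling's T2 confidence ellipse for a 2-D score plot
#'
#' The (1 - alpha) T2 region of a two-component score plot is an
#' axis-aligned ellipse centered at the origin with semi-axis
#' `s_k * sqrt( 2 (n-1)(n+1) / (n (n-2)) * F(1 - alpha; 2, n-2) )`
#' along component k, `s_k` being the score standard deviation. Points
#' outside the ellipse are flagged as potential outliers.
#'
#' @param scores n x 2 matrix of scores (n >= 4).
#' @param alpha Significance level (default 0.05 for a 95% region).
#' @return Object of class `hotelling_ellipse`: `semi_axes` (length 2),
#'   `outside` (logical per row), `crit`, `alpha`, `n`.
#' @export
hotelling_ellipse <- function(scores, alpha = 0.05) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 4) stop("Hotelling ellipse needs at least 4 points",
                  call. = FALSE)
  if (ncol(scores) != 2) stop("scores must have exactly 2 columns",
                              call. = FALSE)
  s <- apply(scores, 2, stats::sd)
  crit <- 2 * (n - 1) * (n + 1) / (n * (n - 2)) *
    stats::qf(1 - alpha, 2, n - 2)
  semi <- s * sqrt(crit)
  d2 <- (scores[, 1] / semi[1])^2 + (scores[, 2] / semi[2])^2
  structure(list(semi_axes = semi, outside = d2 > 1, crit = crit,
                 alpha = alpha, n = n),
            class = "hotelling_ellipse")
}

#' Points on a Hotelling ellipse boundary (for plotting)
#'
#' @param ellipse A [hotelling_ellipse()] object.
#' @param n Number of boundary points.
#' @return Tibble with columns `x`, `y`.
#' @export
ellipse_points <- function(ellipse, n = 200) {
  theta <- seq(0, 2 * pi, length.out = n)
  tibble::tibble(x = ellipse$semi_axes[1] * cos(theta),
                 y = ellipse$semi_axes[2] * sin(theta))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
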