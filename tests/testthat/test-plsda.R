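test_that("autoscaling centers, unit-scales, flags constants and inverts", {
  sc <- autoscale(cbind(a = c(1, 2, 3), b = c(5, 5, 5)))
  expect_equal(unname(sc$x[, "a"]), c(-1, 0, 1))   # sample SD 1
  expect_equal(unname(sc$x[, "b"]), c(0, 0, 0))
  expect_equal(unname(sc$zero_variance), c(FALSE, TRUE))

  set.seed(2)
  x <- matrix(rnorm(40, sd = 3) + 7, 8, 5)
  sc <- autoscale(x)
  expect_lt(max(abs(unscale(sc$x, sc) - x)), 1e-10)
  expect_error(autoscale(x[1, , drop = FALSE]), "at least 2 rows")
})

test_that("one-hot coding builds a valid indicator matrix", {
  y <- one_hot(c("a", "a", "b"), c("a", "b"))
  expect_equal(unname(y), rbind(c(1, 0), c(1, 0), c(0, 1)))
  expect_equal(unname(rowSums(y)), rep(1, 3))
  expect_equal(unname(colSums(y)), c(2, 1))     # group sizes
  expect_equal(unname(one_hot(rep("a", 4))), matrix(1, 4, 1))
  expect_error(one_hot(c("a", "z"), "a"), "unknown group")
})

test_that("first NIPALS weight equals the dominant eigenvector of X'YY'X", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(24), 6, 4)
    g <- rep(c("a", "b"), 3)
    fit <- fit_plsda(x, g, ncomp = 1, folds = 3)
    xs <- autoscale(x)$x
    ys <- autoscale(one_hot(g))$x
    m <- crossprod(xs, ys) %*% crossprod(ys, xs)
    v <- eigen(m, symmetric = TRUE)$vectors[, 1]
    w <- fit$weights[, 1]
    expect_lt(min(sqrt(sum((w - v)^2)), sqrt(sum((w + v)^2))), 1e-6)
  }
})

test_that("scores are orthogonal and weights unit-norm on fitted models", {
  for (seed in 1:5) {
    fit <- random_plsda(seed, ncomp = 3)
    tt <- crossprod(fit$scores)
    off <- abs(tt[upper.tri(tt)])
    norms <- sqrt(diag(tt))
    expect_true(all(off < 1e-8 * tcrossprod(norms)[upper.tri(tt)]))
    expect_equal(unname(colSums(fit$weights^2)), rep(1, fit$ncomp),
                 tolerance = 1e-10)
  }
})

test_that("a single informative response column is fit perfectly at one component", {
  x <- matrix(c(rep(0, 6), rep(1, 6)), ncol = 1)
  fit <- fit_plsda(x, rep(c("a", "b"), each = 6), ncomp = 1, folds = 2)
  expect_equal(fit$r2y, 1, tolerance = 1e-10)
})

test_that("R2Y is non-decreasing in the number of components", {
  set.seed(3)
  x <- matrix(rnorm(40 * 8), 40, 8)
  g <- sample(c("a", "b", "c"), 40, replace = TRUE)
  r2y <- vapply(1:5, function(a) {
    fit_plsda(x, g, ncomp = a, folds = 4)$r2y
  }, numeric(1))
  expect_true(all(diff(r2y) >= -1e-10))
})

test_that("pure-noise predictors inflate R2Y but not Q2", {
  set.seed(7)
  x <- matrix(rnorm(60 * 10), 60, 10)
  g <- rep(c("a", "b"), 30)
  fit <- fit_plsda(x, g, ncomp = 5, folds = 6)
  expect_gt(fit$r2y, 0.05)   # apparent fit grows with components
  expect_lt(fit$q2, 0.1)     # but predicts nothing
})

test_that("cross-validated Q2 separates structure from shuffled labels", {
  d <- separable_data()
  q2 <- cross_validated_q2(d$x, d$groups, ncomp = 2, folds = 7)
  expect_gt(q2, 0.9)

  set.seed(21)
  q2_shuffled <- replicate(50, {
    cross_validated_q2(d$x[, 1:5], sample(d$groups), ncomp = 2, folds = 4)
  })
  expect_lte(mean(q2_shuffled), 0)
})

test_that("n-fold CV equals a directly coded leave-one-out PRESS oracle", {
  set.seed(13)
  n <- 12
  x <- matrix(rnorm(n * 4), n, 4)
  g <- rep(c("a", "b"), n / 2)
  q2_pkg <- cross_validated_q2(x, g, ncomp = 2, folds = n)

  press <- 0; ss <- 0
  for (i in seq_len(n)) {
    sx <- autoscale(x[-i, , drop = FALSE])
    sy <- autoscale(one_hot(g[-i], c("a", "b")))
    fit <- aromakey:::.nipals_pls(sx$x, sy$x, 2)
    xi <- (x[i, ] - sx$center) / sx$scale
    yi <- (one_hot(g[i], c("a", "b")) - sy$center) / sy$scale
    pred <- xi %*% aromakey:::.pls_coef(fit, 2)
    press <- press + sum((yi - pred)^2)
    ss <- ss + sum(yi^2)
  }
  expect_equal(q2_pkg, 1 - press / ss, tolerance = 1e-10)
})

test_that("VIP has the closed form and the sum-of-squares identity", {
  # A = 1, w = (1, 0, 0): VIP = (sqrt(3), 0, 0)
  model <- structure(list(weights = matrix(c(1, 0, 0), 3, 1), ssy = 1,
                          p = 3L, compounds = c("a", "b", "c")),
                     class = "plsda")
  v <- vip(model)
  expect_equal(v$vip[v$compound_id == "a"], sqrt(3))
  expect_equal(sort(v$vip), c(0, 0, sqrt(3)))

  # mean squared VIP is 1 on random fitted models
  for (seed in 6:10) {
    fit <- random_plsda(seed, ncomp = 2)
    v <- vip(fit)
    expect_equal(sum(v$vip^2), fit$p, tolerance = 1e-8)
  }
})

test_that("the informative variable earns the top VIP among noise", {
  set.seed(17)
  n <- 40
  x <- matrix(rnorm(n * 21), n, 21,
              dimnames = list(NULL, paste0("v", 1:21)))
  g <- rep(c("a", "b"), each = n / 2)
  x[g == "a", 1] <- x[g == "a", 1] + 4
  v <- vip(fit_plsda(x, g, ncomp = 1, folds = 4))
  expect_equal(v$compound_id[1], "v1")
  expect_gt(v$vip[1], 1)
})

test_that("permutation validation keeps the original model on top for structured data", {
  d <- separable_data()
  perm <- permutation_test(d$x, d$groups, ncomp = 2, n_perm = 30,
                           folds = 5, seed = 3)
  tbl <- tidy(perm)
  orig <- tbl[tbl$perm == 0, ]
  expect_equal(orig$correlation, 1)
  expect_equal(orig$q2, perm$q2_original)    # identity permutation row
  expect_equal(orig$r2y, perm$r2y_original)
  expect_true(all(tbl$q2[tbl$perm > 0] < perm$q2_original))
  expect_lt(perm$q2_intercept, 0)
  expect_equal(nrow(tbl), 31)
})

test_that("on label-free noise the original model is not systematically best", {
  set.seed(31)
  x <- matrix(rnorm(36 * 6), 36, 6)
  g <- sample(rep(c("a", "b", "c"), 12))
  perm <- permutation_test(x, g, ncomp = 2, n_perm = 20, folds = 4,
                           seed = 5)
  tbl <- tidy(perm)
  expect_gt(sum(tbl$q2[tbl$perm > 0] > perm$q2_original), 0)
})

test_that("Hotelling ellipse covers, scales and nests as expected", {
  set.seed(41)
  scores <- matrix(rnorm(40), 20, 2)
  e <- hotelling_ellipse(scores)
  e2 <- hotelling_ellipse(scores * 2)
  expect_equal(e2$semi_axes, 2 * e$semi_axes)      # scale equivariance
  e50 <- hotelling_ellipse(scores, alpha = 0.5)
  expect_true(all(e50$semi_axes < e$semi_axes))    # nested regions
  expect_error(hotelling_ellipse(scores[1:3, ]), "at least 4")
  expect_error(hotelling_ellipse(matrix(rnorm(30), 10, 3)), "2 columns")
})

test_that("tidiers and plots expose the model surface", {
  fit <- random_plsda(1, ncomp = 2)
  expect_equal(nrow(tidy(fit, "scores")), fit$n)
  expect_equal(nrow(tidy(fit, "loadings")), fit$p)
  gl <- glance(fit)
  expect_named(gl, c("ncomp", "r2x", "r2y", "q2", "n", "p", "folds"))
  expect_true(gl$r2x <= 1 && gl$r2y <= 1)
  expect_s3_class(autoplot(fit), "ggplot")
  d <- separable_data(n_per_group = 8, p = 5)
  perm <- permutation_test(d$x, d$groups, ncomp = 2, n_perm = 5,
                           folds = 4, seed = 1)
  expect_s3_class(autoplot(perm), "ggplot")
})
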