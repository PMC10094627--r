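test_that("z-scoring standardizes, clips and is idempotent in range", {
  m <- cbind(a = c(0, 10), b = c(1, 3))
  z <- zscore_clip(m)
  expect_equal(unname(z[, "a"]), c(-0.707, 0.707), tolerance = 1e-3)

  set.seed(3)
  m2 <- matrix(rnorm(50), 10, 5)
  z2 <- zscore_clip(m2, clip = 4)
  expect_equal(unname(colMeans(z2)), rep(0, 5), tolerance = 1e-10)

  # an extreme outlier (> 4 SD) is clamped to the bound
  expect_equal(max(zscore_clip(cbind(c(rep(0, 20), 100)), 4)), 4)

  # idempotent on already-standardized, in-range data
  expect_equal(zscore_clip(z2, 4), z2, tolerance = 1e-10)

  # constant columns become zeros
  expect_equal(unname(zscore_clip(cbind(c(1, 1, 1)))), cbind(rep(0, 3)))
})

test_that("hierarchical clustering merges nearest pairs deterministically", {
  m <- matrix(c(0, 1, 10), ncol = 1,
              dimnames = list(c("p0", "p1", "p10"), "x"))
  hc <- hierarchical_cluster(m, "rows")$hclust
  expect_equal(hc$height[1], 1)                 # first merge {0, 1}
  expect_equal(sort(-hc$merge[1, ]), c(1, 2))   # leaves p0 and p1

  dup <- rbind(a = c(1, 2), b = c(1, 2), c = c(5, 9))
  expect_equal(hierarchical_cluster(dup, "rows")$hclust$height[1], 0)
})

test_that("average linkage agrees with a brute-force agglomerative oracle", {
  # O(n^3) oracle: merge the closest pair under average linkage over the
  # full pairwise distance matrix, tracking merge heights
  brute_average <- function(m) {
    d <- as.matrix(stats::dist(m))
    clusters <- as.list(seq_len(nrow(m)))
    heights <- numeric(0)
    while (length(clusters) > 1) {
      best <- c(Inf, NA, NA)
      for (i in seq_along(clusters)) {
        for (j in seq_len(i - 1)) {
          h <- mean(d[clusters[[i]], clusters[[j]]])
          if (h < best[1]) best <- c(h, j, i)
        }
      }
      heights <- c(heights, best[1])
      clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
      clusters[[best[3]]] <- NULL
    }
    heights
  }
  set.seed(47)
  m <- matrix(rnorm(16), 8, 2)
  rownames(m) <- paste0("r", 1:8)
  hc <- hierarchical_cluster(m, "rows", "euclidean", "average")$hclust
  expect_equal(hc$height, brute_average(m), tolerance = 1e-10)
})

test_that("clustering is invariant to input permutation", {
  set.seed(53)
  m <- matrix(rnorm(20), 10, 2)
  rownames(m) <- paste0("r", 1:10)
  ord <- sample(10)
  h1 <- hierarchical_cluster(m, "rows")$hclust
  h2 <- hierarchical_cluster(m[ord, ], "rows")$hclust
  expect_equal(h1$height, h2$height, tolerance = 1e-10)
  # same partition at every merge height
  for (k in c(2, 4, 6)) {
    p1 <- stats::cutree(h1, k)
    p2 <- stats::cutree(h2, k)[rownames(m)]
    expect_equal(length(unique(paste(p1, p2))), k)
  }
})

test_that("correlation metric falls back to euclidean on constant vectors", {
  m <- rbind(a = c(1, 1, 1), b = c(1, 2, 3), c = c(3, 2, 1))
  expect_warning(hierarchical_cluster(m, "rows", metric = "correlation"),
                 "falling back to euclidean")
})

test_that("heat-map export obeys its invariants", {
  sim <- simulate_peak_table(generator_config(seed = 6))
  conc <- semi_quantify(sim$peaks)
  compounds <- unique(calibration_markers()$compound_id)
  hd <- heatmap_data(conc, compounds, clip = 4)
  expect_lte(max(abs(hd$matrix)), 4)
  expect_setequal(hd$row_order, seq_len(nrow(hd$matrix)))
  expect_setequal(hd$col_order, seq_len(ncol(hd$matrix)))
  expect_equal(length(hd$row_dendrogram$order), nrow(hd$matrix))
  expect_equal(length(hd$col_dendrogram$order), ncol(hd$matrix))
  expect_s3_class(autoplot(hd), "ggplot")
})

test_that("run summaries report gaps, serialize and parse back", {
  empty_vip <- summarize_run(
    screening = screen_key_active(
      tibble::tibble(compound_id = "x", vip = 0.2),
      tibble::tibble(compound_id = "x", group = "g", oav = 5)))
  expect_equal(empty_vip$screening$n_vip_selected, 0)
  expect_true(all(c("class_profile", "plsda", "permutation") %in%
                    empty_vip$gaps))
  expect_output(print(empty_vip), "zero differential")

  d <- separable_data(n_per_group = 8, p = 5)
  fit <- fit_plsda(d$x, d$groups, ncomp = 2, folds = 4)
  summ <- summarize_run(model = fit)
  path <- withr::local_tempfile(fileext = ".json")
  write_run_summary(summ, path)
  back <- read_run_summary(path)
  expect_equal(back$plsda$q2, fit$q2, tolerance = 1e-12)
  expect_equal(back$gaps, setdiff(c("class_profile", "permutation",
                                    "screening"), character(0)))
})
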