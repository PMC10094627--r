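test_that("OAV is concentration over threshold, with exclusions never imputed", {
  cat_ <- toy_catalog()   # hexanal has no threshold
  gm <- tibble::tibble(
    group = "Heyuan",
    compound_id = c("linalool", "geraniol", "hexanal"),
    mean_ng_g = c(48.64, 0, 100))
  oav <- compute_oav(gm, cat_)
  expect_equal(oav$oav[oav$compound_id == "linalool"], 1)   # conc == OT
  expect_equal(oav$oav[oav$compound_id == "geraniol"], 0)   # zero conc
  expect_false("hexanal" %in% oav$compound_id)
  expect_equal(attr(oav, "excluded"), "hexanal")

  # published anchor pair: 1621.01 ng/g over 160.02 ng/g -> OAV 10.13
  gm2 <- tibble::tibble(group = "Heyuan", compound_id = "linalool",
                        mean_ng_g = 1621.01)
  cat2 <- toy_catalog(); cat2$odor_threshold_air[1] <- 160.02
  expect_equal(round(compute_oav(gm2, cat2)$oav, 2), 10.13)

  cat_bad <- toy_catalog(); cat_bad$odor_threshold_air[1] <- 0
  expect_error(compute_oav(gm, cat_bad), "non-positive odor_threshold")
})

test_that("OAV is invariant to jointly rescaling concentration and threshold", {
  set.seed(19)
  cat_ <- toy_catalog()
  gm <- tidyr::expand_grid(group = c("g1", "g2"),
                           compound_id = cat_$compound_id)
  gm$mean_ng_g <- rexp(nrow(gm), rate = 0.01)
  k <- 37.5
  cat_scaled <- cat_
  cat_scaled$odor_threshold_air <- cat_$odor_threshold_air * k
  gm_scaled <- gm
  gm_scaled$mean_ng_g <- gm$mean_ng_g * k
  expect_equal(compute_oav(gm, cat_)$oav,
               compute_oav(gm_scaled, cat_scaled)$oav, tolerance = 1e-12)
})

test_that("screening the packaged reference panel reproduces the published pattern", {
  panel <- key_odorant_oav()
  vips <- tibble::tibble(compound_id = unique(panel$compound_id), vip = 2)
  rep_ <- screen_key_active(vips, panel)

  expect_equal(length(rep_$key_active), 8)

  # six compounds qualify in every group
  per_group <- rep_$qualifying %>%
    dplyr::count(compound_id) %>%
    dplyr::filter(n == 8)
  expect_equal(sort(per_group$compound_id),
               sort(c("phenylethylalcohol", "methylsalicylate", "pcresol",
                      "benzeneacetaldehyde", "linalool", "geraniol")))

  benz <- dplyr::filter(rep_$qualifying, compound_id == "benzaldehyde")
  expect_equal(benz$group, "Luokeng")
  expect_equal(benz$oav, 1.18)

  mba <- dplyr::filter(rep_$qualifying,
                       compound_id == "3methylbutanoicacid")
  expect_setequal(mba$group, c("Meizhou", "Heyuan", "Lianshan", "Chaozhou"))

  # published row maxima
  maxima <- panel %>%
    dplyr::filter(!censored) %>%
    dplyr::group_by(compound_id) %>%
    dplyr::summarise(m = max(oav))
  get <- function(cid) maxima$m[maxima$compound_id == cid]
  expect_equal(get("linalool"), 42.48)
  expect_equal(get("geraniol"), 150.63)
  expect_equal(get("pcresol"), 5.49)
  expect_equal(get("phenylethylalcohol"), 10.13)
})

test_that("key-active screening is monotone in both cutoffs", {
  panel <- key_odorant_oav()
  set.seed(23)
  vips <- tibble::tibble(compound_id = unique(panel$compound_id),
                         vip = runif(8, 0.5, 2.5))
  sets <- lapply(c(1, 1.5, 3), function(cut) {
    screen_key_active(vips, panel, vip_cutoff = cut)$key_active
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
  sets_oav <- lapply(c(1, 2, 5), function(cut) {
    screen_key_active(vips, panel, oav_cutoff = cut)$key_active
  })
  expect_true(all(sets_oav[[2]] %in% sets_oav[[1]]))
  expect_true(all(sets_oav[[3]] %in% sets_oav[[2]]))
})

test_that("one-way ANOVA matches a brute-force sum-of-squares oracle", {
  brute_anova <- function(values, groups) {
    grand <- mean(values)
    means <- tapply(values, groups, mean)
    ns <- tapply(values, groups, length)
    ssb <- sum(ns * (means - grand)^2)
    ssw <- sum((values - means[groups])^2)
    df1 <- length(means) - 1
    df2 <- length(values) - length(means)
    f <- (ssb / df1) / (ssw / df2)
    list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
  }

  # frozen hand case: groups {1,2,3}, {2,3,4}, {6,7,8}
  hand <- brute_anova(c(1, 2, 3, 2, 3, 4, 6, 7, 8), rep(c("a", "b", "c"),
                                                        each = 3))
  expect_equal(hand$f, 21)
  expect_equal(hand$p, 0.001953125, tolerance = 1e-9)

  make_conc <- function(values, groups) {
    tibble::tibble(sample_id = paste0("s", seq_along(values)),
                   group = groups, replicate = 1L, compound_id = "x",
                   conc_ng_g = values)
  }
  res <- anova_by_group(make_conc(c(1, 2, 3, 2, 3, 4, 6, 7, 8),
                                  rep(c("a", "b", "c"), each = 3)), "x")
  expect_equal(res$f_statistic, 21, tolerance = 1e-10)
  expect_equal(res$p_value, hand$p, tolerance = 1e-10)

  set.seed(29)
  for (i in 1:5) {
    vals <- rnorm(15)
    grp <- rep(c("a", "b", "c"), each = 5)
    oracle <- brute_anova(vals, grp)
    got <- anova_by_group(make_conc(vals, grp), "x")
    expect_equal(got$f_statistic, oracle$f, tolerance = 1e-10)
    expect_equal(got$p_value, oracle$p, tolerance = 1e-10)
  }
})

test_that("degenerate ANOVA inputs are handled, not errored", {
  make_conc <- function(values, groups) {
    tibble::tibble(sample_id = paste0("s", seq_along(values)),
                   group = groups, replicate = 1L, compound_id = "x",
                   conc_ng_g = values)
  }
  # identical groups -> F = 0, p = 1
  same <- anova_by_group(make_conc(rep(c(1, 2, 3), 2),
                                   rep(c("a", "b"), each = 3)), "x")
  expect_equal(same$f_statistic, 0)
  expect_equal(same$p_value, 1)

  # near-perfect separation -> p -> 0
  set.seed(37)
  sep <- anova_by_group(make_conc(c(rnorm(4, 0, 1e-6), rnorm(4, 1, 1e-6)),
                                  rep(c("a", "b"), each = 4)), "x")
  expect_lt(sep$p_value, 1e-10)

  expect_error(anova_by_group(make_conc(1:3, c("a", "a", "b")), "x"),
               ">= 2 groups")
})

test_that("top-group flags require dominance over every other group", {
  make_conc <- function(values, groups) {
    tibble::tibble(sample_id = paste0("s", seq_along(values)),
                   group = groups, replicate = 1L, compound_id = "x",
                   conc_ng_g = values)
  }
  set.seed(43)
  vals <- c(rnorm(6, 0), rnorm(6, 0.2), rnorm(6, 10))  # +10 SD shift
  grp <- rep(c("a", "b", "top"), each = 6)
  res <- top_group_flags(make_conc(vals, grp), "x")
  expect_equal(res$top_group, "top")
  expect_equal(res$flag, "**")

  flat <- top_group_flags(make_conc(rep(5, 12),
                                    rep(c("a", "b"), each = 6)), "x")
  expect_equal(flat$flag, "none")
  expect_true(flat$tie)
})
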