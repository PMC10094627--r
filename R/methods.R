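# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA: %d observations, %d variables, %d groups\n",
              x$n, x$p, length(x$group_labels)))
  cat(sprintf("  %d components: R2X = %.3f, R2Y = %.3f, Q2 = %.3f (%d-fold CV)\n",
              x$ncomp, x$r2x, x$r2y, x$q2, x$folds))
  invisible(x)
}

#' Tidy a PLS-DA model
#'
#' @param x A `plsda` object.
#' @param what One of `"scores"` (per observation), `"loadings"` (weights
#'   and X-loadings per compound) or `"vip"`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.plsda <- function(x, what = c("scores", "loadings", "vip"), ...) {
  what <- match.arg(what)
  comp_names <- paste0("comp", seq_len(x$ncomp))
  if (what == "scores") {
    out <- tibble::as_tibble(x$scores, .name_repair = ~comp_names)
    out$group <- x$groups
    return(dplyr::relocate(out, "group"))
  }
  if (what == "loadings") {
    w <- tibble::as_tibble(x$weights, .name_repair = ~paste0("w_", comp_names))
    p <- tibble::as_tibble(x$x_loadings,
                           .name_repair = ~paste0("p_", comp_names))
    return(dplyr::bind_cols(
      tibble::tibble(compound_id = x$compounds %||%
                       as.character(seq_len(x$p))), w, p))
  }
  vip(x)
}

#' One-row model diagnostics of a PLS-DA fit
#'
#' @param x A `plsda` object.
#' @param ... Unused.
#' @return Tibble with `ncomp`, `r2x`, `r2y`, `q2`, `n`, `p`, `folds`.
#' @exportS3Method generics::glance
glance.plsda <- function(x, ...) {
  tibble::tibble(ncomp = x$ncomp, r2x = x$r2x, r2y = x$r2y, q2 = x$q2,
                 n = x$n, p = x$p, folds = x$folds)
}

#' Score plot of a PLS-DA model
#'
#' First two components colored by group, with the 95% Hotelling T2
#' ellipse.
#'
#' @param object A `plsda` object with at least 2 components.
#' @param alpha Significance level of the T2 ellipse (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.plsda <- function(object, alpha = 0.05, ...) {
  if (object$ncomp < 2) stop("score plot needs >= 2 components",
                             call. = FALSE)
  d <- tibble::tibble(t1 = object$scores[, 1], t2 = object$scores[, 2],
                      group = object$groups)
  ell <- ellipse_points(hotelling_ellipse(object$scores[, 1:2], alpha))
  pct <- function(a) round(100 * object$ssx[a] / (object$r2x^-1 *
                                                    sum(object$ssx)), 1)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t1, y = .data$t2,
                                  color = .data$group)) +
    ggplot2::geom_path(data = ell,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       inherit.aes = FALSE, linetype = 2,
                       color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("t[1] (%.1f%% of X)", pct(1)),
      y = sprintf("t[2] (%.1f%% of X)", pct(2)),
      title = sprintf("PLS-DA scores (R2X %.3f, R2Y %.3f, Q2 %.3f)",
                      object$r2x, object$r2y, object$q2)) +
    ggplot2::theme_minimal()
}

#' @export
print.plsda_permutation <- function(x, ...) {
  cat(sprintf("Permutation validation: %d permutations, %d components\n",
              x$n_perm, x$ncomp))
  cat(sprintf("  original R2Y = %.3f, Q2 = %.3f\n", x$r2y_original,
              x$q2_original))
  cat(sprintf("  intercepts: R2 = %.3f, Q2 = %.3f\n", x$r2_intercept,
              x$q2_intercept))
  invisible(x)
}

#' Per-permutation results of a permutation validation
#'
#' @param x A `plsda_permutation` object.
#' @param ... Unused.
#' @return Tibble with `perm` (0 = original), `correlation`, `r2y`, `q2`.
#' @exportS3Method generics::tidy
tidy.plsda_permutation <- function(x, ...) x$permutations

#' One-row summary of a permutation validation
#'
#' @param x A `plsda_permutation` object.
#' @param ... Unused.
#' @return Tibble with original statistics and regression intercepts.
#' @exportS3Method generics::glance
glance.plsda_permutation <- function(x, ...) {
  tibble::tibble(n_perm = x$n_perm, ncomp = x$ncomp,
                 r2y_original = x$r2y_original, q2_original = x$q2_original,
                 r2_intercept = x$r2_intercept,
                 q2_intercept = x$q2_intercept)
}

#' SIMCA-style permutation validation plot
#'
#' Permuted R2Y and Q2 against the label-correlation statistic, with the
#' fitted regression lines whose intercepts summarize model validity.
#'
#' @param object A `plsda_permutation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.plsda_permutation <- function(object, ...) {
  d <- tidyr::pivot_longer(object$permutations, c("r2y", "q2"),
                           names_to = "statistic", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$correlation, y = .data$value,
                                  color = .data$statistic)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         fullrange = TRUE, linewidth = 0.4) +
    ggplot2::labs(x = "correlation with original labels", y = NULL,
                  title = sprintf(
                    "Permutation validation (R2 int. %.3f, Q2 int. %.3f)",
                    object$r2_intercept, object$q2_intercept)) +
    ggplot2::theme_minimal()
}

#' Stacked-bar chart of chemical-class composition per group
#'
#' @param class_profile Tibble from [class_proportions()].
#' @return A ggplot object.
#' @export
plot_class_profile <- function(class_profile) {
  ggplot2::ggplot(class_profile,
                  ggplot2::aes(x = .data$group, y = .data$percent,
                               fill = .data$chem_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of total VFC concentration",
                  fill = "class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Heat-map of clustered, z-scored concentrations
#'
#' @param object A [heatmap_data()] object.
#' @param ... Unused.
#' @return A ggplot object (tile heat map in clustered order).
#' @exportS3Method ggplot2::autoplot
autoplot.heatmap_data <- function(object, ...) {
  m <- object$matrix[object$row_order, object$col_order, drop = FALSE]
  d <- tibble::as_tibble(m, rownames = "sample_id")
  d <- tidyr::pivot_longer(d, -"sample_id", names_to = "compound_id",
                           values_to = "z")
  d$sample_id <- factor(d$sample_id, levels = rownames(m))
  d$compound_id <- factor(d$compound_id, levels = colnames(m))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$compound_id,
                                  y = .data$sample_id, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red",
                                  limits = c(-object$clip, object$clip)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
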