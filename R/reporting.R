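# Heat-map export (z-scoring, hierarchical clustering) and run summary.

#' Column-wise z-scoring with clipping
#'
#' Standardizes each column to mean 0 and unit sample SD, then clamps
#' values to `[-clip, clip]` so a few extreme injections cannot dominate
#' the heat-map color scale. Constant columns become all zeros.
#'
#' @param x Numeric matrix (>= 2 rows).
#' @param clip Absolute bound (default 4).
#' @return Matrix of the same shape.
#' @export
zscore_clip <- function(x, clip = 4) {
  stopifnot(clip > 0)
  sc <- autoscale(x)
  pmin(pmax(sc$x, -clip), clip)
}

#' Agglomerative hierarchical clustering of matrix rows or columns
#'
#' Standard agglomerative clustering with euclidean or correlation
#' (1 - Pearson) distance and average, complete or Ward linkage. When the
#' correlation metric meets a constant vector (undefined correlation) the
#' metric falls back to euclidean with a warning. Leaf order is the
#' dendrogram's left-before-right traversal.
#'
#' @param x Numeric matrix.
#' @param axis `"rows"` or `"cols"`.
#' @param metric `"euclidean"` or `"correlation"`.
#' @param linkage `"average"`, `"complete"` or `"ward"`.
#' @return List with `hclust` (a [stats::hclust] object), `order` (leaf
#'   order), `labels`.
#' @export
hierarchical_cluster <- function(x, axis = c("rows", "cols"),
                                 metric = c("euclidean", "correlation"),
                                 linkage = c("average", "complete",
                                             "ward")) {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  m <- if (axis == "cols") t(as.matrix(x)) else as.matrix(x)
  if (nrow(m) < 2) stop("need at least 2 items to cluster", call. = FALSE)
  if (metric == "correlation") {
    sds <- apply(m, 1, stats::sd)
    if (any(sds < .Machine$double.eps)) {
      warning("correlation metric undefined on constant vectors; ",
              "falling back to euclidean", call. = FALSE)
      metric <- "euclidean"
    }
  }
  d <- if (metric == "euclidean") stats::dist(m) else
    stats::as.dist(1 - stats::cor(t(m)))
  method <- c(average = "average", complete = "complete",
              ward = "ward.D2")[[linkage]]
  hc <- stats::hclust(d, method = method)
  list(hclust = hc, order = hc$order, labels = rownames(m))
}

#' Build heat-map export data for selected compounds
#'
#' Produces the clustered, z-scored sample-by-compound matrix that backs a
#' differential-compound heat map: per-sample mean concentrations of the
#' selected compounds are z-scored per compound, clipped, and both axes are
#' clustered hierarchically.
#'
#' @param conc Concentration tibble from [semi_quantify()].
#' @param compounds Compound ids to include (e.g. the VIP > 1 set).
#' @param clip Clipping bound for z-scores (default 4).
#' @param metric,linkage Passed to [hierarchical_cluster()].
#' @return Object of class `heatmap_data`: `matrix` (samples x compounds,
#'   clipped z-scores), `row_order`, `col_order`, `row_dendrogram`,
#'   `col_dendrogram`, `sample_groups`.
#' @export
heatmap_data <- function(conc, compounds, clip = 4, metric = "euclidean",
                         linkage = "average") {
  d <- dplyr::filter(conc, .data$compound_id %in% compounds)
  if (nrow(d) == 0) stop("no data for the selected compounds",
                         call. = FALSE)
  per_sample <- dplyr::summarise(
    dplyr::group_by(d, .data$sample_id, .data$group, .data$compound_id),
    conc = mean(.data$conc_ng_g), .groups = "drop")
  wide <- tidyr::pivot_wider(per_sample, id_cols = c("sample_id", "group"),
                             names_from = "compound_id",
                             values_from = "conc")
  m <- as.matrix(wide[setdiff(names(wide), c("sample_id", "group"))])
  rownames(m) <- wide$sample_id
  z <- zscore_clip(m, clip)
  rows <- hierarchical_cluster(z, "rows", metric, linkage)
  cols <- hierarchical_cluster(z, "cols", metric, linkage)
  structure(list(matrix = z, row_order = rows$order,
                 col_order = cols$order,
                 row_dendrogram = rows$hclust, col_dendrogram = cols$hclust,
                 sample_groups = stats::setNames(wide$group,
                                                 wide$sample_id),
                 clip = clip),
            class = "heatmap_data")
}

#' Summarize a full pipeline run
#'
#' Collects the stage outputs into one machine-readable report: class
#' profiles, PLS-DA diagnostics (R2X, R2Y, Q2, permutation intercepts), the
#' VIP > cutoff count and the key-active compound set with per-group OAVs
#' and significance flags. Stages that were not run are reported as
#' explicit gaps rather than silently dropped.
#'
#' @param class_profile Tibble from [class_proportions()] (or `NULL`).
#' @param model A `plsda` fit (or `NULL`).
#' @param permutation A `plsda_permutation` (or `NULL`).
#' @param screening A `screening_report` (or `NULL`).
#' @return Object of class `run_summary` (a named list).
#' @export
summarize_run <- function(class_profile = NULL, model = NULL,
                          permutation = NULL, screening = NULL) {
  gaps <- character()
  out <- list()
  if (is.null(class_profile)) gaps <- c(gaps, "class_profile") else
    out$class_profile <- class_profile
  if (is.null(model)) gaps <- c(gaps, "plsda") else
    out$plsda <- list(ncomp = model$ncomp, r2x = model$r2x,
                      r2y = model$r2y, q2 = model$q2)
  if (is.null(permutation)) gaps <- c(gaps, "permutation") else
    out$permutation <- list(n_perm = permutation$n_perm,
                            r2_intercept = permutation$r2_intercept,
                            q2_intercept = permutation$q2_intercept)
  if (is.null(screening)) gaps <- c(gaps, "screening") else {
    out$screening <- list(
      n_vip_selected = length(screening$vip_selected),
      vip_selected = screening$vip_selected,
      key_active = screening$key_active,
      qualifying = screening$qualifying,
      tests = screening$tests)
  }
  out$gaps <- gaps
  structure(out, class = "run_summary")
}

#' Write a run summary to JSON
#'
#' @param summary A [summarize_run()] object.
#' @param path Output path.
#' @export
write_run_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Read back a run summary written by [write_run_summary()]
#'
#' @param path JSON path.
#' @return A `run_summary` list (tibbles restored for tabular sections).
#' @export
read_run_summary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in intersect(c("class_profile", "qualifying"), names(x))) {
    x[[nm]] <- tibble::as_tibble(x[[nm]])
  }
  if (!is.null(x$screening)) {
    for (nm in intersect(c("qualifying", "tests"), names(x$screening))) {
      x$screening[[nm]] <- tibble::as_tibble(x$screening[[nm]])
    }
  }
  structure(x, class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("Pipeline run summary\n")
  if (!is.null(x$plsda)) {
    cat(sprintf("  PLS-DA: %d components, R2X %.3f, R2Y %.3f, Q2 %.3f\n",
                x$plsda$ncomp, x$plsda$r2x, x$plsda$r2y, x$plsda$q2))
  }
  if (!is.null(x$permutation)) {
    cat(sprintf("  permutation (%d): R2 intercept %.3f, Q2 intercept %.3f\n",
                x$permutation$n_perm, x$permutation$r2_intercept,
                x$permutation$q2_intercept))
  }
  if (!is.null(x$screening)) {
    if (x$screening$n_vip_selected == 0) {
      cat("  screening: zero differential compounds\n")
    } else {
      cat("  screening:", x$screening$n_vip_selected,
          "differential (VIP-selected);",
          length(x$screening$key_active), "key active\n")
    }
  }
  if (length(x$gaps) > 0) {
    cat("  missing stages:", paste(x$gaps, collapse = ", "), "\n")
  }
  invisible(x)
}
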