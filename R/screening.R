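# Odor-activity-value screening and group-difference testing.

#' Compute odor activity values (OAVs)
#'
#' `OAV = group mean concentration / odor threshold in air`. A compound
#' with OAV > 1 in some group is perceptible there and counts as
#' aroma-active. Compounds whose threshold is unknown (`NA` in the catalog)
#' are excluded, never imputed; their ids are attached as the `excluded`
#' attribute.
#'
#' @param group_means Tibble from [group_mean_concentrations()] (`group`,
#'   `compound_id`, `mean_ng_g`).
#' @param catalog Compound catalog carrying `odor_threshold_air` (ng/g).
#' @return Tibble with columns `compound_id`, `group`, `oav`, with
#'   attribute `excluded` listing threshold-less compounds.
#' @export
compute_oav <- function(group_means, catalog) {
  catalog <- validate_catalog(catalog)
  thr <- dplyr::select(catalog, "compound_id", "odor_threshold_air")
  joined <- dplyr::inner_join(group_means, thr, by = "compound_id")
  bad <- joined$compound_id[!is.na(joined$odor_threshold_air) &
                              joined$odor_threshold_air <= 0]
  if (length(bad) > 0) {
    stop("non-positive odor threshold for: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  excluded <- unique(joined$compound_id[is.na(joined$odor_threshold_air)])
  out <- dplyr::filter(joined, !is.na(.data$odor_threshold_air))
  out <- dplyr::mutate(out,
                       oav = .data$mean_ng_g / .data$odor_threshold_air)
  out <- dplyr::select(out, "compound_id", "group", "oav")
  attr(out, "excluded") <- excluded
  out
}

#' Screen for key active differential odorants
#'
#' A compound is a *key active differential odorant* when it is
#' differential (VIP strictly above `vip_cutoff`) and aroma-active
#' somewhere (maximum OAV over groups strictly above `oav_cutoff`). The
#' report also records, per compound, the set of groups in which it
#' qualifies (OAV above the cutoff).
#'
#' @param vip_table Tibble of `compound_id`, `vip` (from [vip()]), or any
#'   table with those columns.
#' @param oav_table Tibble of `compound_id`, `group`, `oav` (from
#'   [compute_oav()]). `NA` OAVs are treated as below the cutoff.
#' @param vip_cutoff,oav_cutoff Strict cutoffs (defaults 1 and 1).
#' @return Object of class `screening_report`: `vip_selected` and
#'   `key_active` compound-id vectors and `qualifying` (long tibble of
#'   compound, group pairs with OAV above the cutoff).
#' @export
#' @examples
#' panel <- key_odorant_oav()
#' vips <- tibble::tibble(compound_id = unique(panel$compound_id), vip = 2)
#' rep <- screen_key_active(vips, panel)
#' rep$key_active
screen_key_active <- function(vip_table, oav_table,
                              vip_cutoff = 1, oav_cutoff = 1) {
  vip_selected <- vip_table$compound_id[vip_table$vip > vip_cutoff]
  oav_ok <- dplyr::filter(oav_table,
                          !is.na(.data$oav) & .data$oav > oav_cutoff)
  active_anywhere <- unique(oav_ok$compound_id)
  key_active <- intersect(vip_selected, active_anywhere)
  qualifying <- dplyr::select(
    dplyr::filter(oav_ok, .data$compound_id %in% key_active),
    "compound_id", "group", "oav")
  structure(list(vip_selected = vip_selected, key_active = key_active,
                 qualifying = qualifying,
                 vip_cutoff = vip_cutoff, oav_cutoff = oav_cutoff),
            class = "screening_report")
}

#' One-way ANOVA of a compound's concentration across groups
#'
#' Classical one-way fixed-effects ANOVA on injection-level concentrations.
#' When every value is identical (no between- or within-group variance) the
#' test is vacuous and `F = 0, p = 1` is returned rather than an error.
#'
#' @param conc Concentration tibble from [semi_quantify()].
#' @param compound Compound id to test.
#' @return One-row tibble: `compound_id`, `f_statistic`, `p_value`,
#'   `df_between`, `df_within`.
#' @export
anova_by_group <- function(conc, compound) {
  d <- dplyr::filter(conc, .data$compound_id == compound)
  if (nrow(d) == 0) stop("compound not found: ", compound, call. = FALSE)
  counts <- table(d$group)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("one-way ANOVA needs >= 2 groups with >= 2 injections each",
         call. = FALSE)
  }
  if (stats::var(d$conc_ng_g) < .Machine$double.eps) {
    return(tibble::tibble(compound_id = compound, f_statistic = 0,
                          p_value = 1,
                          df_between = length(counts) - 1L,
                          df_within = nrow(d) - length(counts)))
  }
  fit <- stats::oneway.test(conc_ng_g ~ group, data = d, var.equal = TRUE)
  tibble::tibble(compound_id = compound,
                 f_statistic = unname(fit$statistic),
                 p_value = fit$p.value,
                 df_between = unname(fit$parameter[1]),
                 df_within = unname(fit$parameter[2]))
}

# Welch two-sample one-sided test that group a exceeds group b, robust to
# (near-)constant groups: with no usable variance the p-value degenerates
# to 0 or 1 according to the mean difference
.welch_greater_p <- function(a, b) {
  if (stats::sd(a) < .Machine$double.eps &&
      stats::sd(b) < .Machine$double.eps) {
    return(if (mean(a) > mean(b)) 0 else 1)
  }
  out <- tryCatch(
    stats::t.test(a, b, alternative = "greater")$p.value,
    error = function(e) if (mean(a) > mean(b)) 0 else 1)
  out
}

#' Top-group significance flag for a compound
#'
#' Identifies the group with the highest mean concentration and asks
#' whether it is significantly higher than *every* other group: one-sided
#' Welch t-tests of the top group against each other group,
#' Holm-corrected. `**` requires all adjusted p-values below
#' `strong_alpha`, `*` below `alpha`, otherwise `none`. A tie for the top
#' mean yields no flag and is reported.
#'
#' @param conc Concentration tibble from [semi_quantify()].
#' @param compound Compound id.
#' @param alpha,strong_alpha Significance levels (defaults 0.05, 0.01).
#' @return One-row tibble: `compound_id`, `top_group`, `flag` (`none`,
#'   `*` or `**`), `max_adj_p`, `tie`.
#' @export
top_group_flags <- function(conc, compound, alpha = 0.05,
                            strong_alpha = 0.01) {
  d <- dplyr::filter(conc, .data$compound_id == compound)
  if (nrow(d) == 0) stop("compound not found: ", compound, call. = FALSE)
  means <- tapply(d$conc_ng_g, d$group, mean)
  top <- names(means)[which.max(means)]
  tie <- sum(abs(means - max(means)) < .Machine$double.eps^0.5) > 1
  if (tie) {
    return(tibble::tibble(compound_id = compound, top_group = top,
                          flag = "none", max_adj_p = NA_real_, tie = TRUE))
  }
  others <- setdiff(names(means), top)
  a_vals <- d$conc_ng_g[d$group == top]
  p_raw <- vapply(others, function(g) {
    .welch_greater_p(a_vals, d$conc_ng_g[d$group == g])
  }, numeric(1))
  p_adj <- stats::p.adjust(p_raw, method = "holm")
  worst <- max(p_adj)
  flag <- if (worst < strong_alpha) "**" else if (worst < alpha) "*" else
    "none"
  tibble::tibble(compound_id = compound, top_group = top, flag = flag,
                 max_adj_p = worst, tie = FALSE)
}

#' Full screening stage of the pipeline
#'
#' Combines VIP selection, OAV screening and per-compound group-difference
#' testing into one report: for every key active differential odorant the
#' ANOVA p-value, the top group and its significance flag.
#'
#' @param conc Concentration tibble from [semi_quantify()].
#' @param catalog Compound catalog with odor thresholds.
#' @param vip_table Tibble of `compound_id`, `vip`.
#' @param config An [aroma_config()] (cutoffs and significance levels).
#' @return A `screening_report` with an additional `tests` tibble
#'   (`compound_id`, `p_value`, `top_group`, `flag`) and the `oav` matrix
#'   in long form.
#' @export
screen_compounds <- function(conc, catalog, vip_table,
                             config = aroma_config()) {
  gm <- group_mean_concentrations(conc)
  oav <- compute_oav(gm, catalog)
  rep <- screen_key_active(vip_table, oav,
                           vip_cutoff = config$vip_cutoff,
                           oav_cutoff = config$oav_cutoff)
  tests <- lapply(rep$key_active, function(cid) {
    av <- anova_by_group(conc, cid)
    fl <- top_group_flags(conc, cid, alpha = config$alpha,
                          strong_alpha = config$strong_alpha)
    tibble::tibble(compound_id = cid, f_statistic = av$f_statistic,
                   p_value = av$p_value, top_group = fl$top_group,
                   flag = fl$flag)
  })
  rep$tests <- dplyr::bind_rows(tests)
  rep$oav <- oav
  # single-sample groups: replicate injections measure technical, not
  # biological, variation -- note them so flags are read with care
  n_samples <- dplyr::summarise(
    dplyr::group_by(conc, .data$group),
    n = dplyr::n_distinct(.data$sample_id), .groups = "drop")
  rep$single_sample_groups <- n_samples$group[n_samples$n == 1]
  rep
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Key active differential odorant screening\n")
  cat("  VIP >", x$vip_cutoff, ":", length(x$vip_selected),
      "differential compounds\n")
  cat("  key active (max OAV >", x$oav_cutoff, "):",
      length(x$key_active), "compounds\n")
  if (length(x$key_active) > 0) {
    cat("  ", paste(x$key_active, collapse = ", "), "\n")
  }
  if (!is.null(x$tests) && nrow(x$tests) > 0) {
    print(x$tests)
  }
  invisible(x)
}
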