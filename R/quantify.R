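# Internal-standard semi-quantification and chemical-class profiling.

#' Semi-quantify peak areas against the internal standard
#'
#' Converts raw GC-MS peak areas to relative concentrations (ng/g dry mass)
#' by reference to the ethyl decanoate internal standard spiked into every
#' extraction:
#' `conc = peak_area * is_mass_ng / (is_peak_area * dry_mass_g)`.
#' This is a semi-quantification: it assumes a common response factor and
#' reports concentrations relative to the internal standard, not absolute
#' amounts.
#'
#' @param peaks Long-format peak tibble (see [validate_peak_table()] for the
#'   schema); `is_peak_area` and `dry_mass_g` must be positive for every
#'   injection.
#' @param is_mass_ng Mass of internal standard per extraction, ng
#'   (default 400 = 20 uL x 0.02 mg/mL).
#' @return Tibble with columns `sample_id`, `group`, `replicate`,
#'   `compound_id`, `conc_ng_g`.
#' @export
#' @examples
#' peaks <- tibble::tibble(sample_id = "S01", group = "YJ-Yingde",
#'   replicate = 1L, dry_mass_g = 1.5, is_peak_area = 5000,
#'   compound_id = "linalool", peak_area = 5000)
#' semi_quantify(peaks)  # 400 / 1.5 = 266.67 ng/g
semi_quantify <- function(peaks, is_mass_ng = 400) {
  stopifnot(is_mass_ng > 0)
  required <- c("sample_id", "group", "replicate", "dry_mass_g",
                "is_peak_area", "compound_id", "peak_area")
  missing <- setdiff(required, names(peaks))
  if (length(missing) > 0) {
    stop("peak table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(!(peaks$is_peak_area > 0))
  if (length(bad) > 0) {
    stop("internal-standard area must be positive (sample ",
         peaks$sample_id[bad[1]], ", replicate ",
         peaks$replicate[bad[1]], ")", call. = FALSE)
  }
  bad <- which(!(peaks$dry_mass_g > 0))
  if (length(bad) > 0) {
    stop("dry mass must be positive (sample ", peaks$sample_id[bad[1]],
         ")", call. = FALSE)
  }
  tibble::tibble(
    sample_id = peaks$sample_id,
    group = peaks$group,
    replicate = peaks$replicate,
    compound_id = peaks$compound_id,
    conc_ng_g = peaks$peak_area * is_mass_ng /
      (peaks$is_peak_area * peaks$dry_mass_g))
}

#' Group-mean concentrations
#'
#' Averages the relative concentration of each compound over all injections
#' (samples times replicates) carrying a group label. With balanced
#' replicate counts this equals the mean of per-sample means; for
#' unbalanced inputs every injection still counts once.
#'
#' @param conc Concentration tibble from [semi_quantify()].
#' @return Tibble with columns `group`, `compound_id`, `mean_ng_g`.
#' @export
group_mean_concentrations <- function(conc) {
  if (nrow(conc) == 0) stop("no injections to average", call. = FALSE)
  dplyr::summarise(dplyr::group_by(conc, .data$group, .data$compound_id),
                   mean_ng_g = mean(.data$conc_ng_g), .groups = "drop")
}

#' Chemical-class composition per group
#'
#' For each group, the percentage of total volatile concentration carried by
#' each of the twelve chemical classes, computed on group-mean
#' concentrations. Percentages sum to 100 within each group; classes absent
#' from the data appear with 0.
#'
#' @param conc Concentration tibble from [semi_quantify()].
#' @param catalog Compound catalog assigning every compound a `chem_class`.
#' @return Tibble with columns `group`, `chem_class`, `percent`.
#' @export
class_proportions <- function(conc, catalog) {
  catalog <- validate_catalog(catalog)
  gm <- group_mean_concentrations(conc)
  unknown <- setdiff(unique(gm$compound_id), catalog$compound_id)
  if (length(unknown) > 0) {
    stop("compound(s) without a catalog class: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  gm <- dplyr::left_join(
    gm, dplyr::select(catalog, "compound_id", "chem_class"),
    by = "compound_id")
  by_class <- dplyr::summarise(
    dplyr::group_by(gm, .data$group, .data$chem_class),
    total = sum(.data$mean_ng_g), .groups = "drop_last")
  out <- dplyr::mutate(by_class,
                       percent = 100 * .data$total / sum(.data$total))
  out <- dplyr::ungroup(dplyr::select(out, -"total"))
  tidyr::complete(out, .data$group,
                  chem_class = chem_classes(),
                  fill = list(percent = 0))
}
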