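#' The twelve chemical classes of volatile flavor compounds
#'
#' Volatile flavor compounds (VFCs) detected in tea headspace are grouped by
#' chemical structure into twelve classes. Every compound in a catalog must
#' carry exactly one of these labels.
#'
#' @return Character vector of the twelve class labels.
#' @export
#' @examples
#' chem_classes()
chem_classes <- function() {
  c("alcohol", "heterocyclic", "aldehyde", "ketone", "alkene", "acid",
    "aromatic_hydrocarbon", "ester", "alkane", "amino_acid", "phenol",
    "n_compound")
}

#' Default district group labels
#'
#' The eight tea-producing district groups used throughout the package.
#' Yingde is split into two groups (YJ and HY) because its samples come from
#' two distinct tea varieties with different aroma profiles.
#'
#' @return Character vector of eight group labels, in fixed display order.
#' @export
district_groups <- function() {
  c("YJ-Yingde", "HY-Yingde", "Luokeng", "Renhua", "Meizhou", "Heyuan",
    "Lianshan", "Chaozhou")
}

#' Normalize a compound name for matching
#'
#' Lower-cases, strips punctuation and whitespace, and resolves known
#' spelling variants (e.g. "menthyl salicylate" is treated as
#' "methyl salicylate", a variant that appears in the tea literature).
#'
#' @param x Character vector of compound names.
#' @return Character vector of normalized keys.
#' @export
#' @examples
#' normalize_compound_name(c("Methyl Salicylate", "menthyl salicylate"))
normalize_compound_name <- function(x) {
  key <- stringr::str_to_lower(x)
  key <- stringr::str_replace_all(key, "[^a-z0-9]+", "")
  aliases <- c(menthylsalicylate = "methylsalicylate",
               pcresol = "pcresol",
               benzeneacetaldehyde = "benzeneacetaldehyde")
  hit <- match(key, names(aliases))
  key[!is.na(hit)] <- aliases[hit[!is.na(hit)]]
  key
}

#' Run configuration for the screening pipeline
#'
#' Bundles the tunable thresholds of the pipeline: the VIP and OAV cutoffs
#' that define a key active differential odorant, the cross-validation and
#' permutation settings of the PLS-DA stage, the significance levels for
#' group-difference flags, and the clipping bound of the z-scored heat map.
#'
#' @param group_labels Ordered character vector of allowed group labels.
#' @param vip_cutoff Variable-importance cutoff; compounds with VIP strictly
#'   greater than this are "differential" (default 1).
#' @param oav_cutoff Odor-activity-value cutoff; a compound is aroma-active
#'   in a group when its OAV strictly exceeds this (default 1).
#' @param cv_folds Number of interleaved cross-validation folds (default 7).
#' @param n_permutations Number of label permutations in model validation
#'   (default 200).
#' @param alpha,strong_alpha Significance levels for the `*` and `**`
#'   top-group flags (defaults 0.05 and 0.01).
#' @param heat_clip Absolute bound applied to z-scored heat-map intensities
#'   (default 4).
#' @param seed Integer seed used by stochastic stages.
#' @return A list of class `aroma_config`.
#' @export
aroma_config <- function(group_labels = district_groups(),
                         vip_cutoff = 1, oav_cutoff = 1,
                         cv_folds = 7, n_permutations = 200,
                         alpha = 0.05, strong_alpha = 0.01,
                         heat_clip = 4, seed = 1L) {
  stopifnot(vip_cutoff > 0, oav_cutoff > 0, cv_folds >= 2,
            n_permutations >= 1, alpha > 0, alpha < 1,
            strong_alpha > 0, strong_alpha < 1, heat_clip > 0)
  structure(list(group_labels = group_labels, vip_cutoff = vip_cutoff,
                 oav_cutoff = oav_cutoff, cv_folds = cv_folds,
                 n_permutations = n_permutations, alpha = alpha,
                 strong_alpha = strong_alpha, heat_clip = heat_clip,
                 seed = as.integer(seed)),
            class = "aroma_config")
}

#' Validate a compound catalog
#'
#' A catalog is a tibble with one row per compound: `compound_id`, `name`,
#' `chem_class` (one of [chem_classes()]), `odor_note` (free text) and
#' `odor_threshold_air` (ng/g; may be `NA` for compounds whose threshold in
#' air is not tabulated).
#'
#' @param catalog A data frame.
#' @return The catalog as a tibble, invisibly validated.
#' @export
validate_catalog <- function(catalog) {
  catalog <- tibble::as_tibble(catalog)
  required <- c("compound_id", "name", "chem_class", "odor_note",
                "odor_threshold_air")
  missing <- setdiff(required, names(catalog))
  if (length(missing) > 0) {
    stop("catalog is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(catalog$compound_id)) {
    stop("duplicate compound_id in catalog", call. = FALSE)
  }
  bad_class <- setdiff(unique(catalog$chem_class), chem_classes())
  if (length(bad_class) > 0) {
    stop("unknown chem_class value(s): ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  }
  thr <- catalog$odor_threshold_air
  if (any(!is.na(thr) & thr <= 0)) {
    bad <- catalog$compound_id[!is.na(thr) & thr <= 0]
    stop("non-positive odor_threshold_air for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  catalog
}

#' Read a compound catalog from CSV
#'
#' @param path Path to a CSV file with columns `compound_id`, `name`,
#'   `chem_class`, `odor_note`, `odor_threshold_air`.
#' @return A validated catalog tibble.
#' @export
read_compound_catalog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  catalog <- readr::read_csv(path, show_col_types = FALSE,
                             col_types = readr::cols(
                               odor_threshold_air = readr::col_double(),
                               .default = readr::col_character()))
  if ("odor_note" %in% names(catalog)) {
    catalog$odor_note[is.na(catalog$odor_note)] <- ""
  }
  validate_catalog(catalog)
}

#' Validate a long-format peak table
#'
#' A peak table holds one row per (injection, compound): `sample_id`,
#' `group`, `replicate`, `dry_mass_g`, `is_peak_area` (internal-standard
#' peak area of that injection) and `peak_area`. All compound ids must
#' resolve in the catalog and all group labels must belong to the declared
#' group set.
#'
#' @param peaks A data frame in the long peak schema.
#' @param catalog A compound catalog tibble (see [validate_catalog()]).
#' @param group_labels Allowed group labels; defaults to the labels present.
#' @return The peak table as a tibble.
#' @export
validate_peak_table <- function(peaks, catalog, group_labels = NULL) {
  peaks <- tibble::as_tibble(peaks)
  required <- c("sample_id", "group", "replicate", "dry_mass_g",
                "is_peak_area", "compound_id", "peak_area")
  missing <- setdiff(required, names(peaks))
  if (length(missing) > 0) {
    stop("peak table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  catalog <- validate_catalog(catalog)
  unknown <- setdiff(unique(peaks$compound_id), catalog$compound_id)
  if (length(unknown) > 0) {
    stop("compound_id not in catalog: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  if (!is.null(group_labels)) {
    offenders <- setdiff(unique(peaks$group), group_labels)
    if (length(offenders) > 0) {
      stop("group label(s) outside the configured set: ",
           paste(offenders, collapse = ", "), call. = FALSE)
    }
  }
  bad_row <- which(peaks$peak_area < 0)
  if (length(bad_row) > 0) {
    stop("negative peak_area at row ", bad_row[1], " (sample ",
         peaks$sample_id[bad_row[1]], ", compound ",
         peaks$compound_id[bad_row[1]], ")", call. = FALSE)
  }
  bad_row <- which(peaks$dry_mass_g <= 0)
  if (length(bad_row) > 0) {
    stop("non-positive dry_mass_g at row ", bad_row[1], " (sample ",
         peaks$sample_id[bad_row[1]], ")", call. = FALSE)
  }
  bad_row <- which(peaks$is_peak_area <= 0)
  if (length(bad_row) > 0) {
    stop("non-positive internal-standard area at row ", bad_row[1],
         " (sample ", peaks$sample_id[bad_row[1]], ", replicate ",
         peaks$replicate[bad_row[1]], ")", call. = FALSE)
  }
  peaks
}

#' Read a long-format peak table from CSV
#'
#' @param path Path to the peaks CSV (`sample_id, group, replicate,
#'   dry_mass_g, is_peak_area, compound_id, peak_area`).
#' @param catalog_path Path to the compound catalog CSV.
#' @param group_labels Optional allowed group set; when given, any other
#'   label is rejected.
#' @return A list with elements `peaks` (tibble) and `catalog` (tibble).
#' @export
read_peak_table <- function(path, catalog_path, group_labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  catalog <- read_compound_catalog(catalog_path)
  peaks <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             sample_id = readr::col_character(),
                             group = readr::col_character(),
                             replicate = readr::col_integer(),
                             dry_mass_g = readr::col_double(),
                             is_peak_area = readr::col_double(),
                             compound_id = readr::col_character(),
                             peak_area = readr::col_double()))
  peaks <- validate_peak_table(peaks, catalog, group_labels)
  list(peaks = peaks, catalog = catalog)
}

#' Write a peak table (and optionally its catalog) to CSV
#'
#' @param peaks Long-format peak tibble.
#' @param path Output CSV path.
#' @export
write_peak_table <- function(peaks, path) {
  readr::write_csv(peaks, path)
  invisible(path)
}

#' Write a labeled numeric matrix to CSV
#'
#' Row labels go in the first column (`row`), column labels in the header.
#' Values survive a write/read round trip to at least 12 significant digits.
#'
#' @param mat Numeric matrix with unique row and column names.
#' @param path Output CSV path.
#' @export
write_matrix_csv <- function(mat, path) {
  if (is.null(rownames(mat)) && nrow(mat) > 0) {
    stop("matrix must have row names", call. = FALSE)
  }
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat))) {
    stop("row and column labels must be unique", call. = FALSE)
  }
  df <- tibble::as_tibble(mat, rownames = "row")
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a labeled numeric matrix written by [write_matrix_csv()]
#'
#' @param path CSV path.
#' @return Numeric matrix with dimnames restored.
#' @export
read_matrix_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          row = readr::col_character(),
                          .default = readr::col_double()))
  mat <- as.matrix(df[setdiff(names(df), "row")])
  rownames(mat) <- df$row
  mat
}

#' Published OAV reference panel for the eight key odorants
#'
#' Loads the packaged odor-activity-value (OAV) reference panel: eight key
#' active differential odorants of Guangdong black teas by eight district
#' groups, with odor notes. Cells censored in the source as "<1" are
#' returned as `NA` and flagged in `censored`; they denote an OAV below 1,
#' not a missing measurement.
#'
#' @param path Optional path to an alternative panel CSV in the same layout.
#' @return A long tibble with columns `compound_id`, `name`, `odor_note`,
#'   `group`, `oav`, `censored`.
#' @export
#' @examples
#' panel <- key_odorant_oav()
#' dplyr::filter(panel, compound_id == "benzaldehyde", !censored)
key_odorant_oav <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "key_odorant_oav.csv",
                        package = "aromakey", mustWork = TRUE)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  long <- tidyr::pivot_longer(raw, cols = -c("name", "odor_note"),
                              names_to = "group", values_to = "oav_raw")
  long$censored <- long$oav_raw == "<1"
  long$oav <- suppressWarnings(as.numeric(long$oav_raw))
  long$compound_id <- normalize_compound_name(long$name)
  long$group <- factor(long$group, levels = district_groups())
  long$group <- as.character(long$group)
  dplyr::select(long, "compound_id", "name", "odor_note", "group",
                "oav", "censored")
}
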