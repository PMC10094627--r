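# Calibrated synthetic peak-table generator.
#
# The generator emulates a multi-district black-tea GC-MS survey: 31 samples
# in 8 district groups, 6 replicate injections each, 135 compounds in 12
# chemical classes. Group-specific marker concentrations are fixed at the
# published values for the key odorants; background compounds get frozen
# per-compound means chosen so each group's class composition lands inside
# the published class-share bands. Peak areas are emitted by inverting the
# internal-standard semi-quantification formula, so quantifying generated
# data recovers the configured concentration field.

# frozen internal seed for the background-abundance draw; independent of the
# user-facing simulation seed so the calibration itself is a constant
.CALIBRATION_SEED <- 20230406L

#' Default group sizes of the emulated survey
#'
#' @return Tibble with columns `group` and `n_samples` (31 samples total).
#' @export
default_group_sizes <- function() {
  tibble::tibble(
    group = district_groups(),
    n_samples = c(12L, 3L, 4L, 6L, 3L, 1L, 1L, 1L))
}

#' Default chemical-class composition of the compound catalog
#'
#' @return Named integer vector: compounds per class, summing to 135.
#' @export
default_class_counts <- function() {
  stats::setNames(
    c(24L, 25L, 9L, 17L, 10L, 6L, 9L, 17L, 9L, 3L, 5L, 1L),
    chem_classes())
}

# named (non-generic) compounds of the default catalog, with display names
.named_compounds <- function() {
  tibble::tribble(
    ~name,                          ~chem_class,
    "Linalool",                     "alcohol",
    "Geraniol",                     "alcohol",
    "Phenylethyl alcohol",          "alcohol",
    "Benzyl alcohol",               "alcohol",
    "(Z)-2-Penten-1-ol",            "alcohol",
    "(Z)-3-Hexen-1-ol",             "alcohol",
    "trans-Linalool oxide (furanoid)", "alcohol",
    "Benzaldehyde",                 "aldehyde",
    "Benzeneacetaldehyde",          "aldehyde",
    "Hexanal",                      "aldehyde",
    "Citral",                       "aldehyde",
    "(E,E)-2,4-Heptadienal",        "aldehyde",
    "2,5-Dimethyl-benzaldehyde",    "aldehyde",
    "Methyl salicylate",            "ester",
    "Heptanoic acid ethyl ester",   "ester",
    "beta-Ionone",                  "ketone",
    "p-Cresol",                     "phenol",
    "3-Methyl-butanoic acid",       "acid",
    "D-Limonene",                   "alkene",
    "2-Ethyl-1,4-dimethyl-benzene", "aromatic_hydrocarbon")
}

# odor notes for the key odorants (free-text annotations)
.odor_notes <- function() {
  c(linalool = "floral, lavender",
    geraniol = "rose, geranium",
    benzeneacetaldehyde = "honey, floral, rose, sweet",
    methylsalicylate = "peppermint",
    pcresol = "medicine, phenol, smoke",
    phenylethylalcohol = "honey, spice, rose, lilac",
    `3methylbutanoicacid` = "sour, cheesy, disagreeable",
    benzaldehyde = "almond, burnt sugar",
    betaionone = "sweet, floral, violet")
}

#' The published calibration triples of the generator
#'
#' The eleven (compound, group, mean concentration) anchors taken from the
#' survey's reported group-level concentrations of marker compounds (ng/g,
#' relative to the ethyl decanoate internal standard). The benzaldehyde
#' Luokeng value is the mean of the two reported sample concentrations
#' (2619.61 and 1824.31 ng/g).
#'
#' @return Tibble with columns `compound_id`, `group`, `mean_ng_g`.
#' @export
#' @examples
#' calibration_markers()
calibration_markers <- function() {
  tibble::tribble(
    ~compound_id,            ~group,       ~mean_ng_g,
    "linalool",              "YJ-Yingde",  2066.04,
    "geraniol",              "Meizhou",    1891.58,
    "geraniol",              "Lianshan",   1426,
    "phenylethylalcohol",    "Heyuan",     1621.01,
    "benzaldehyde",          "Luokeng",    (2619.61 + 1824.31) / 2,
    "benzeneacetaldehyde",   "YJ-Yingde",  377.02,
    "betaionone",            "Meizhou",    278.91,
    "methylsalicylate",      "HY-Yingde",  996.06,
    "methylsalicylate",      "Renhua",     1121.95,
    "pcresol",               "Chaozhou",   3.66,
    "3methylbutanoicacid",   "Chaozhou",   97.79)
}

# threshold anchors: one (concentration, OAV) pair per key odorant, taken at
# the group holding the row-maximum OAV of the reference panel; the odor
# threshold in air is back-derived as conc / oav
.threshold_anchors <- function() {
  tibble::tribble(
    ~compound_id,          ~group,      ~conc,                     ~oav,
    "linalool",            "YJ-Yingde", 2066.04,                   42.48,
    "geraniol",            "Lianshan",  1426,                      150.63,
    "benzeneacetaldehyde", "YJ-Yingde", 377.02,                    13.06,
    "methylsalicylate",    "Renhua",    1121.95,                   4.22,
    "pcresol",             "Chaozhou",  3.66,                      5.49,
    "phenylethylalcohol",  "Heyuan",    1621.01,                   10.13,
    "3methylbutanoicacid", "Chaozhou",  97.79,                     4.07,
    "benzaldehyde",        "Luokeng",   (2619.61 + 1824.31) / 2,   1.18)
}

# background concentration budget per class (ng/g summed over the class's
# non-key compounds, identical in every group); calibrated once so that,
# together with the fixed marker means, every group's alcohol share falls
# mid-band in 31.40-44.43% and the ester/aldehyde/ketone shares fall in
# their published bands
.class_budgets <- function() {
  c(alcohol = 4050, heterocyclic = 2400, aldehyde = 800, ketone = 1650,
    alkene = 500, acid = 250, aromatic_hydrocarbon = 400, ester = 1200,
    alkane = 400, amino_acid = 100, phenol = 150, n_compound = 100)
}

# district-specific elevations of secondary (non-key) compounds, reflecting
# the compounds reported to cluster with particular districts; expressed as
# multipliers on the compound's background mean
.secondary_elevations <- function() {
  tibble::tribble(
    ~compound_id,                ~group,      ~multiplier,
    "z2penten1ol",               "YJ-Yingde", 2.5,
    "z3hexen1ol",                "YJ-Yingde", 2.0,
    "dlimonene",                 "YJ-Yingde", 3.0,
    "benzylalcohol",             "HY-Yingde", 2.5,
    "heptanoicacidethylester",   "Luokeng",   3.0,
    "2ethyl14dimethylbenzene",   "Renhua",    3.0)
}

# OAV assigned to cells censored as "<1" in the reference panel; keeps the
# implied concentration safely below the odor threshold
.CENSORED_OAV <- 0.5

# builds the catalog skeleton (ids, names, classes) without thresholds
.catalog_skeleton <- function(class_counts = default_class_counts()) {
  named <- .named_compounds()
  named$compound_id <- normalize_compound_name(named$name)
  rows <- lapply(names(class_counts), function(cl) {
    n_total <- class_counts[[cl]]
    have <- named[named$chem_class == cl, , drop = FALSE]
    if (nrow(have) > n_total) {
      stop("class ", cl, " has more named compounds than its count",
           call. = FALSE)
    }
    n_gen <- n_total - nrow(have)
    if (n_gen > 0) {
      gen <- tibble::tibble(
        name = sprintf("%s %02d (synthetic)", cl, seq_len(n_gen)),
        chem_class = cl,
        compound_id = sprintf("%s%02d", gsub("_", "", cl), seq_len(n_gen)))
      have <- dplyr::bind_rows(have, gen)
    }
    have
  })
  out <- dplyr::bind_rows(rows)
  notes <- .odor_notes()
  out$odor_note <- unname(notes[out$compound_id])
  out$odor_note[is.na(out$odor_note)] <- ""
  dplyr::select(out, "compound_id", "name", "chem_class", "odor_note")
}

# frozen per-compound background means: each class's budget is split across
# its non-key compounds with lognormal weights drawn under the fixed
# internal calibration seed
.background_means <- function(skeleton) {
  key_ids <- .threshold_anchors()$compound_id
  bg <- skeleton[!skeleton$compound_id %in% key_ids, , drop = FALSE]
  budgets <- .class_budgets()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(.CALIBRATION_SEED)
  means <- lapply(split(bg, bg$chem_class), function(d) {
    w <- exp(stats::rnorm(nrow(d), 0, 0.6))
    d$mean_ng_g <- budgets[[d$chem_class[1]]] * w / sum(w)
    d
  })
  out <- dplyr::bind_rows(means)
  dplyr::select(out, "compound_id", "mean_ng_g")
}

#' Default marker profile: target mean concentrations per compound and group
#'
#' Builds the full 135-compound by 8-group grid of target mean
#' concentrations (ng/g) that calibrates the generator:
#' * key-odorant cells are derived from the published OAV reference panel
#'   times the back-derived odor threshold, with the eleven published
#'   concentration triples ([calibration_markers()]) taking precedence;
#' * censored ("<1") panel cells are fixed at OAV 0.5;
#' * background compounds carry a frozen group-independent mean, with a few
#'   district-specific secondary elevations.
#'
#' @return Tibble with columns `compound_id`, `group`, `mean_ng_g`.
#' @export
#' @examples
#' prof <- default_marker_profile()
#' dplyr::filter(prof, compound_id == "linalool", group == "YJ-Yingde")
default_marker_profile <- function() {
  skeleton <- .catalog_skeleton()
  groups <- district_groups()
  grid <- tidyr::expand_grid(compound_id = skeleton$compound_id,
                             group = groups)
  bg <- .background_means(skeleton)
  grid <- dplyr::left_join(grid, bg, by = "compound_id")

  # secondary district elevations on background compounds
  sec <- .secondary_elevations()
  grid <- dplyr::left_join(grid, sec, by = c("compound_id", "group"))
  grid$mean_ng_g <- grid$mean_ng_g *
    ifelse(is.na(grid$multiplier), 1, grid$multiplier)
  grid$multiplier <- NULL

  # key odorants: concentration = panel OAV x odor threshold in air
  anchors <- .threshold_anchors()
  thr <- stats::setNames(anchors$conc / anchors$oav, anchors$compound_id)
  panel <- key_odorant_oav()
  panel$oav[panel$censored] <- .CENSORED_OAV
  panel$mean_key <- panel$oav * thr[panel$compound_id]
  grid <- dplyr::left_join(
    grid, dplyr::select(panel, "compound_id", "group", "mean_key"),
    by = c("compound_id", "group"))
  grid$mean_ng_g <- ifelse(is.na(grid$mean_key), grid$mean_ng_g,
                           grid$mean_key)
  grid$mean_key <- NULL

  # published concentration triples take final precedence
  markers <- dplyr::rename(calibration_markers(), marker = "mean_ng_g")
  grid <- dplyr::left_join(grid, markers, by = c("compound_id", "group"))
  grid$mean_ng_g <- ifelse(is.na(grid$marker), grid$mean_ng_g, grid$marker)
  grid$marker <- NULL
  grid
}

#' Default odor-threshold table
#'
#' Odor thresholds in air (ng/g, the same unit basis as the concentrations).
#' For the eight key odorants the threshold is back-derived from a published
#' (concentration, OAV) pair, so dividing the anchored group-mean
#' concentration by the threshold reproduces the published OAV. All other
#' compounds default to ten times their across-group mean concentration,
#' which keeps their OAVs below 1 in every group.
#'
#' @return Tibble with columns `compound_id`, `odor_threshold_air`.
#' @export
default_threshold_table <- function() {
  anchors <- .threshold_anchors()
  key <- tibble::tibble(compound_id = anchors$compound_id,
                        odor_threshold_air = anchors$conc / anchors$oav)
  prof <- default_marker_profile()
  glob <- dplyr::summarise(dplyr::group_by(prof, .data$compound_id),
                           gmean = mean(.data$mean_ng_g), .groups = "drop")
  rest <- glob[!glob$compound_id %in% key$compound_id, , drop = FALSE]
  rest <- tibble::tibble(compound_id = rest$compound_id,
                         odor_threshold_air = 10 * rest$gmean)
  dplyr::bind_rows(key, rest)
}

#' Default compound catalog of the emulated survey
#'
#' 135 compounds in the 12 chemical classes, with display names, odor notes
#' for the key odorants, and odor thresholds in air from
#' [default_threshold_table()]. Compounds without a literature identity are
#' synthetic placeholders, named accordingly.
#'
#' @return A validated catalog tibble.
#' @export
default_compound_catalog <- function() {
  skeleton <- .catalog_skeleton()
  thr <- default_threshold_table()
  out <- dplyr::left_join(skeleton, thr, by = "compound_id")
  validate_catalog(out)
}

#' Generator configuration
#'
#' @param groups Tibble of `group`, `n_samples` (default: the 31-sample,
#'   8-group survey design).
#' @param replicates Replicate injections per sample (default 6).
#' @param marker_profile Target mean-concentration grid
#'   (default [default_marker_profile()]).
#' @param catalog Compound catalog (default [default_compound_catalog()]).
#' @param sample_cv Total between-sample lognormal coefficient of variation
#'   of each compound's concentration (default 0.25).
#' @param sample_cv_compound Portion of `sample_cv` that is
#'   compound-specific; the remainder acts as a shared per-sample
#'   extraction-efficiency factor (default 0.10; capped at `sample_cv`).
#' @param replicate_cv Injection-level lognormal CV (default 0.08).
#' @param dry_mass_g Dry tea mass per extraction, grams (default 1.5).
#' @param is_mass_ng Mass of the ethyl decanoate internal standard, ng
#'   (default 400, i.e. 20 uL of 0.02 mg/mL).
#' @param is_area_mean,is_area_cv Mean and CV of the internal-standard peak
#'   area per injection (arbitrary area units).
#' @param class_share_targets Named list of `(low, high)` percentage bands
#'   per chemical class that the calibration is expected to satisfy.
#' @param seed Default simulation seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(groups = default_group_sizes(),
                             replicates = 6L,
                             marker_profile = default_marker_profile(),
                             catalog = default_compound_catalog(),
                             sample_cv = 0.25,
                             sample_cv_compound = 0.10,
                             replicate_cv = 0.08,
                             dry_mass_g = 1.5,
                             is_mass_ng = 400,
                             is_area_mean = 5e5,
                             is_area_cv = 0.05,
                             class_share_targets = list(
                               alcohol = c(31.40, 44.43),
                               ester = c(6.89, 16.29),
                               aldehyde = c(5.24, 20.79),
                               ketone = c(8.92, 12.90)),
                             seed = 1L) {
  stopifnot(replicates >= 1, sample_cv >= 0, replicate_cv >= 0,
            dry_mass_g > 0, is_mass_ng > 0, is_area_mean > 0)
  missing_marker <- setdiff(unique(marker_profile$compound_id),
                            catalog$compound_id)
  if (length(missing_marker) > 0) {
    stop("marker profile references compounds absent from the catalog: ",
         paste(utils::head(missing_marker, 5), collapse = ", "),
         call. = FALSE)
  }
  structure(list(groups = groups, replicates = as.integer(replicates),
                 marker_profile = marker_profile, catalog = catalog,
                 sample_cv = sample_cv,
                 sample_cv_compound = sample_cv_compound,
                 replicate_cv = replicate_cv, dry_mass_g = dry_mass_g,
                 is_mass_ng = is_mass_ng, is_area_mean = is_area_mean,
                 is_area_cv = is_area_cv,
                 class_share_targets = class_share_targets,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# lognormal multiplicative noise with mean 1 and the requested CV
.rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a peak table
#'
#' Draws a full survey's worth of injections under the configured
#' concentration field and noise model, then inverts the internal-standard
#' semi-quantification formula to emit raw peak areas:
#' `area = conc * noise * dry_mass_g * is_peak_area / is_mass_ng`.
#' Noise is multiplicative lognormal at two levels: a between-sample factor
#' (split into a shared extraction-efficiency part and a compound-specific
#' part, combining to `sample_cv`) and an injection-level factor
#' (`replicate_cv`). The same seed always yields an identical table.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list with `peaks` (long peak tibble) and `catalog`.
#' @export
#' @examples
#' sim <- simulate_peak_table(seed = 7)
#' dplyr::count(sim$peaks, group)
simulate_peak_table <- function(config = generator_config(),
                                seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(as.integer(seed))

  compounds <- config$catalog$compound_id
  p <- length(compounds)
  samples <- tibble::tibble(
    group = rep(config$groups$group, config$groups$n_samples))
  n_s <- nrow(samples)
  samples$sample_id <- sprintf("S%02d", seq_len(n_s))
  n_inj <- n_s * config$replicates

  # target mean matrix: compounds x groups
  prof <- config$marker_profile
  mu <- matrix(NA_real_, nrow = p, ncol = nrow(config$groups),
               dimnames = list(compounds, config$groups$group))
  mu[cbind(match(prof$compound_id, compounds),
           match(prof$group, config$groups$group))] <- prof$mean_ng_g
  if (anyNA(mu)) {
    stop("marker profile does not cover every compound x group cell",
         call. = FALSE)
  }

  # decompose the between-sample CV into shared and compound-specific parts
  cvc <- min(config$sample_cv_compound, config$sample_cv)
  cvs <- sqrt(max(0, (1 + config$sample_cv^2) / (1 + cvc^2) - 1))

  shared <- .rlnorm_cv(n_s, cvs)                        # per sample
  comp <- matrix(.rlnorm_cv(n_s * p, cvc), n_s, p)      # sample x compound
  repl <- matrix(.rlnorm_cv(n_inj * p, config$replicate_cv), n_inj, p)
  is_area <- config$is_area_mean * .rlnorm_cv(n_inj, config$is_area_cv)

  inj <- tibble::tibble(
    sample_id = rep(samples$sample_id, each = config$replicates),
    group = rep(samples$group, each = config$replicates),
    replicate = rep(seq_len(config$replicates), times = n_s))
  s_of_inj <- match(inj$sample_id, samples$sample_id)

  conc <- t(mu[, inj$group, drop = FALSE]) *            # n_inj x p
    shared[s_of_inj] * comp[s_of_inj, , drop = FALSE] * repl
  area <- conc * config$dry_mass_g * is_area / config$is_mass_ng

  peaks <- tibble::tibble(
    sample_id = rep(inj$sample_id, times = p),
    group = rep(inj$group, times = p),
    replicate = rep(inj$replicate, times = p),
    dry_mass_g = config$dry_mass_g,
    is_peak_area = rep(is_area, times = p),
    compound_id = rep(compounds, each = n_inj),
    peak_area = as.vector(area))
  peaks <- dplyr::arrange(peaks, match(.data$sample_id, samples$sample_id),
                          .data$replicate,
                          match(.data$compound_id, compounds))
  list(peaks = peaks, catalog = config$catalog)
}
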