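# Shared fixtures, built in code.

# minimal 3-compound catalog
toy_catalog <- function() {
  tibble::tibble(
    compound_id = c("linalool", "geraniol", "hexanal"),
    name = c("Linalool", "Geraniol", "Hexanal"),
    chem_class = c("alcohol", "alcohol", "aldehyde"),
    odor_note = "",
    odor_threshold_air = c(48.64, 9.47, NA))
}

# long peak table: `n_inj` injections over the toy catalog, constant areas
toy_peaks <- function(n_inj = 2, area = 5000, is_area = 5000,
                      dry_mass = 1.5, group = "YJ-Yingde") {
  cat_ <- toy_catalog()
  tidyr::expand_grid(
    tibble::tibble(sample_id = sprintf("S%02d", seq_len(n_inj)),
                   group = group, replicate = 1L,
                   dry_mass_g = dry_mass, is_peak_area = is_area),
    tibble::tibble(compound_id = cat_$compound_id, peak_area = area))
}

# small well-separated 2-group dataset for chemometrics tests
separable_data <- function(n_per_group = 12, p = 10, effect = 6,
                           noise = 0.5, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  x <- matrix(rnorm(n * p, sd = noise), n, p)
  x[seq_len(n_per_group), 1] <- x[seq_len(n_per_group), 1] + effect
  x[seq_len(n_per_group), 2] <- x[seq_len(n_per_group), 2] - effect / 2
  colnames(x) <- paste0("v", seq_len(p))
  list(x = x, groups = rep(c("a", "b"), each = n_per_group))
}

# random fitted plsda models for property checks
random_plsda <- function(seed, n = 20, p = 8, g = 3, ncomp = 2) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  groups <- sample(letters[seq_len(g)], n, replace = TRUE)
  while (length(unique(groups)) < g) {
    groups <- sample(letters[seq_len(g)], n, replace = TRUE)
  }
  fit_plsda(x, groups, ncomp = ncomp, folds = 4)
}
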