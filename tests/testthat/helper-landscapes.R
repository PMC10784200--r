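# Shared fixtures built in code.

# A clean landscape: merged classes, no missingness, no outliers — the
# configuration under which the generator's ground truth is directly
# recoverable by the model.
clean_config <- function(seed, n_rows = 60, n_cols = 60,
                         crops = c("corn", "rice"), presence = 0.9) {
  synthetic_config(
    seed = seed, n_rows = n_rows, n_cols = n_cols, crops = crops,
    missingness = c(pesticides = 0, mechanized = 0, n_fert = 0, classes = 0),
    outlier_rate = 0, crop_presence = presence, raw_classes = FALSE,
    class_block = 2 # small blocks so every class level is well populated
  )
}

# Flatten a ground-truth coefficient list into the named vector the fitted
# coefficient table uses (treatment coding, references T1/M2/S1).
truth_vector <- function(b) {
  c(
    "(Intercept)" = b$intercept,
    n_total = b$n_total, pesticides = b$pesticides,
    irrigation_tot = b$irrigation_tot, mechanized = b$mechanized,
    stats::setNames(b$thz, paste0("thz_class", names(b$thz))),
    stats::setNames(b$mst, paste0("mst_class", names(b$mst))),
    stats::setNames(b$soil, paste0("soil_class", names(b$soil)))
  )
}

# A tiny hand-made cell table with every column populated.
tiny_table <- function(n = 8, crop = "corn", seed = 42) {
  set.seed(seed)
  tab <- data.frame(
    cell_id = seq_len(n), lon = seq_len(n) / 10, lat = 50 - seq_len(n) / 10,
    region = rep(c("Africa", "Asia"), length.out = n),
    crop = rep(crop, n),
    yield_kg_ha = stats::rgamma(n, 4, scale = 500),
    harvested_area_ha = stats::rlnorm(n, log(500), 0.5),
    n_fert = stats::rlnorm(n, log(60), 0.5),
    n_manure = stats::rlnorm(n, log(15), 0.5),
    n_total = rep(NA_real_, n),
    pesticides = stats::rlnorm(n, log(1.5), 0.5),
    irrigation_tot = stats::runif(n),
    irrigation_reliant = stats::runif(n),
    mechanized = rep(c(0, 1), length.out = n),
    thz_class = rep(c("T1", "T3", "T6", "T4"), length.out = n),
    mst_class = rep(c("M2", "M4"), length.out = n),
    soil_class = rep(c("S1", "S3"), length.out = n),
    stringsAsFactors = FALSE
  )
  validate_cell_table(tab)
}
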