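# memoized fixtures shared across test files
.fixture_cache <- new.env(parent = emptyenv())

# a small full experiment: fast enough for unit tests
small_experiment <- function(seed = 101) {
  key <- paste0("small_", seed)
  if (is.null(.fixture_cache[[key]])) {
    cfg <- sim_config(n_genes = 600, n_arrays = 4, seed = seed)
    .fixture_cache[[key]] <- simulate_experiment(cfg)
  }
  .fixture_cache[[key]]
}

# default-scale dataset run through qc + normalization + fit, shared by the
# recovery and concordance checks (one ~30 s computation)
fullscale_fit <- function() {
  if (is.null(.fixture_cache$fullscale)) {
    cfg <- sim_config(seed = 14)
    sim <- simulate_experiment(cfg)
    qc <- lapply(sim$hybridizations, function(h) filter_hybridization(h)$hyb)
    ma <- lapply(qc, normalize_hybridization)
    em <- expression_matrix(ma,
                            vapply(qc, `[[`, integer(1), "orientation"),
                            vapply(qc, `[[`, character(1), "batch"))
    fit <- dyeswap_fit(em)
    .fixture_cache$fullscale <- list(sim = sim, em = em, fit = fit)
  }
  .fixture_cache$fullscale
}

# one clean spot row with all QC criteria passing; fields overridable
make_spot <- function(...) {
  base <- data.frame(
    probe_id = "g1", block = 1L, row = 1L, col = 1L, x = 100, y = 100,
    fg_median_ch1 = 1200, fg_pixels_ch1 = 50L, frac_fg_gt_bg2sd_ch1 = 0.95,
    bg_median_ch1 = 100, bg_sd_ch1 = 25,
    fg_median_ch2 = 900, fg_pixels_ch2 = 48L, frac_fg_gt_bg2sd_ch2 = 0.90,
    bg_median_ch2 = 110, bg_sd_ch2 = 28,
    stringsAsFactors = FALSE
  )
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}
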