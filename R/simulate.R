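#' Simulation configuration for synthetic two-color spotted arrays
#'
#' Builds and validates the configuration object consumed by the synthetic
#' data generators ([generate_gene_catalog()], [generate_tissue_atlas()],
#' [generate_planted_truth()], [generate_hybridizations()]). Defaults emulate
#' the study design the package targets: 21,487 printed spots, eight
#' dye-swapped arrays per contrast in two batches, 12% testis-specific and
#' 0.8% adult-midgut-specific genes, planted median log2 shifts of +0.24
#' (testis class), -0.23 (midgut class) and -0.03 (all other genes; the
#' three class medians are then jointly centered, consistent with
#' loess-normalized data), intensity-dependent dye bias and smooth spatial
#' artifacts, and a small fraction of spots built to fail quality control.
#'
#' @param n_genes number of genes (one printed spot per gene per array).
#' @param chromosome_proportions named fractions over arms
#'   `X, 2L, 2R, 3L, 3R, 4, Other` summing to 1; `Other` stands for probes
#'   not mapped to the assembled reference genome. Defaults are the observed
#'   all-spot arm counts divided by their total.
#' @param prop_testis_specific,prop_midgut_specific fractions of genes
#'   designated testis-/adult-midgut-specific.
#' @param n_arrays number of hybridizations in the contrast.
#' @param dye_swap_pattern vector of +1/-1 dye orientations, one per array
#'   (+1: genotype A in channel 1).
#' @param testis_median_shift,midgut_median_shift,background_shift planted
#'   median log2 fold-changes for the two specific classes and for all other
#'   genes; the generator pins the class sample medians to these exactly.
#' @param class_effect_sd,background_effect_sd log2 spread of planted
#'   effects around the class medians / the background median.
#' @param biological_sd,technical_sd per-spot log2-ratio noise components
#'   (added in quadrature).
#' @param dye_bias_amplitude max |log2| amplitude of the smooth
#'   intensity-dependent dye bias curve (cubic in A, per array).
#' @param spatial_amplitude max |log2| amplitude of the smooth spatial field
#'   (low-order polynomial plus one Gaussian bump, per array).
#' @param qc_fail_fraction fraction of spots per array constructed to
#'   violate at least one QC criterion.
#' @param atlas_absent_fraction fraction of atlas entries for broadly
#'   expressed genes that carry an "absent" call.
#' @param grid_shape integer `c(rows, cols)`; `NULL` picks a near-square
#'   grid with capacity >= `n_genes`.
#' @param seed integer seed; all generators derive their streams from it.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 21487,
                       chromosome_proportions = NULL,
                       prop_testis_specific = 0.12,
                       prop_midgut_specific = 0.008,
                       n_arrays = 8,
                       dye_swap_pattern = NULL,
                       testis_median_shift = 0.24,
                       midgut_median_shift = -0.23,
                       background_shift = -0.03,
                       class_effect_sd = 0.20,
                       background_effect_sd = 0.30,
                       biological_sd = 0.06,
                       technical_sd = 0.08,
                       dye_bias_amplitude = 0.3,
                       spatial_amplitude = 0.2,
                       qc_fail_fraction = 0.05,
                       atlas_absent_fraction = 0.2,
                       grid_shape = NULL,
                       seed = 1L) {
  if (is.null(chromosome_proportions)) {
    counts <- c(X = 2719, `2L` = 2992, `2R` = 3225, `3L` = 3235,
                `3R` = 3915, `4` = 98, Other = 514)
    chromosome_proportions <- counts / sum(counts)
  }
  if (is.null(dye_swap_pattern)) {
    dye_swap_pattern <- rep(c(1L, -1L), length.out = n_arrays)
  }
  if (is.null(grid_shape)) {
    nr <- ceiling(sqrt(n_genes))
    grid_shape <- c(nr, ceiling(n_genes / nr))
  }
  cfg <- list(
    n_genes = as.integer(n_genes),
    chromosome_proportions = chromosome_proportions,
    prop_testis_specific = prop_testis_specific,
    prop_midgut_specific = prop_midgut_specific,
    n_arrays = as.integer(n_arrays),
    dye_swap_pattern = as.integer(dye_swap_pattern),
    testis_median_shift = testis_median_shift,
    midgut_median_shift = midgut_median_shift,
    background_shift = background_shift,
    class_effect_sd = class_effect_sd,
    background_effect_sd = background_effect_sd,
    biological_sd = biological_sd,
    technical_sd = technical_sd,
    dye_bias_amplitude = dye_bias_amplitude,
    spatial_amplitude = spatial_amplitude,
    qc_fail_fraction = qc_fail_fraction,
    atlas_absent_fraction = atlas_absent_fraction,
    grid_shape = as.integer(grid_shape),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  arms <- c("X", "2L", "2R", "3L", "3R", "4", "Other")
  p <- cfg$chromosome_proportions
  if (!all(arms %in% names(p)) || length(p) != 7L) {
    stop_config("chromosome_proportions must be named over arms ",
                paste(arms, collapse = ", "))
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop_config("chromosome_proportions must sum to 1 (got ", sum(p), ")")
  }
  fracs <- c(p, cfg$prop_testis_specific, cfg$prop_midgut_specific,
             cfg$qc_fail_fraction, cfg$atlas_absent_fraction)
  if (any(fracs < 0 | fracs > 1)) {
    stop_config("all fractions must lie in [0, 1]")
  }
  if (cfg$prop_testis_specific + cfg$prop_midgut_specific > 1) {
    stop_config("tissue-class fractions exceed 1")
  }
  if (cfg$n_genes < 1L) stop_config("n_genes must be >= 1")
  if (prod(cfg$grid_shape) < cfg$n_genes) {
    stop_config("grid capacity ", prod(cfg$grid_shape),
                " is smaller than n_genes = ", cfg$n_genes)
  }
  if (!all(cfg$dye_swap_pattern %in% c(-1L, 1L)) ||
      length(cfg$dye_swap_pattern) != cfg$n_arrays) {
    stop_config("dye_swap_pattern must be +1/-1, one entry per array")
  }
  sds <- c(cfg$class_effect_sd, cfg$background_effect_sd, cfg$biological_sd,
           cfg$technical_sd, cfg$dye_bias_amplitude, cfg$spatial_amplitude)
  if (any(sds < 0)) stop_config("amplitudes and SDs must be >= 0")
  invisible(cfg)
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("poe_config_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("poe_data_error", "error")))
}

#' Largest-remainder apportionment of n items to proportions
#'
#' Ties in the fractional remainders are broken by position (stable order),
#' i.e. by the order in which the categories are listed.
#' @param n total count.
#' @param proportions numeric vector summing to 1.
#' @return integer vector of counts summing to `n`.
#' @export
largest_remainder <- function(n, proportions) {
  quota <- n * proportions
  counts <- floor(quota)
  short <- round(n - sum(counts))
  if (short > 0) {
    ord <- order(quota - counts, decreasing = TRUE)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  stats::setNames(as.integer(counts), names(proportions))
}

#' Generate a synthetic gene catalog
#'
#' Assigns each gene a chromosome arm, at most one tissue-specific class,
#' and a five-state chromatin color label (a fraction of genes carry no
#' color, emulating genes not covered by a single chromatin state). Arm and
#' class counts follow the configured proportions after largest-remainder
#' rounding.
#'
#' @param config a [sim_config()] object.
#' @return a `data.frame` of class `"gene_catalog"` with columns `gene_id`,
#'   `arm`, `tissue_class` (`"testis"`, `"midgut"` or `"none"`), and
#'   `chromatin_color`.
#' @export
generate_gene_catalog <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  arm_counts <- largest_remainder(n, config$chromosome_proportions)
  arm <- sample(rep(names(arm_counts), arm_counts))

  class_props <- c(testis = config$prop_testis_specific,
                   midgut = config$prop_midgut_specific)
  class_props <- c(class_props, none = 1 - sum(class_props))
  class_counts <- largest_remainder(n, class_props)
  tissue_class <- sample(rep(names(class_counts), class_counts))

  colors <- c("BLACK", "BLUE", "GREEN", "RED", "YELLOW")
  chromatin_color <- sample(colors, n, replace = TRUE,
                            prob = c(0.25, 0.15, 0.10, 0.20, 0.30))
  chromatin_color[stats::runif(n) < 0.2] <- NA_character_

  out <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n)),
    arm = arm,
    tissue_class = tissue_class,
    chromatin_color = chromatin_color,
    stringsAsFactors = FALSE
  )
  class(out) <- c("gene_catalog", "data.frame")
  out
}

#' The twenty atlas tissues
#'
#' The nonredundant tissue panel used for tissue-specificity calls: ten
#' adult tissues, six larval tissues, and the four reproductive tissues.
#' @return character vector of 20 tissue identifiers.
#' @export
atlas_tissues <- function() {
  c("adult_brain", "adult_accessory_gland", "adult_crop", "adult_eye",
    "adult_fat_body", "adult_hindgut", "adult_heart", "adult_midgut",
    "adult_salivary_gland", "adult_thoracicoabdominal_ganglion",
    "ejaculatory_duct", "female_spermatheca", "larval_cns",
    "larval_hindgut", "larval_midgut", "larval_salivary_gland",
    "larval_trachea", "larval_malpighian_tubules", "ovary", "testes")
}

#' Generate a synthetic tissue expression atlas
#'
#' Produces a probe-set x tissue atlas with presence/absence calls.
#' Designated tissue-specific genes are built so that after standard
#' preprocessing ([preprocess_atlas()]) their log2 profile has tau > 0.9
#' with the maximum in the designated tissue: the target tissue gets a high
#' signal and at most three other tissues are weakly "leaky" (log2 value at
#' most 30% of the target's). Broadly expressed genes get moderate signal in
#' every tissue with a configurable fraction of absent calls. About 10% of
#' genes carry a second, weaker probe set to exercise probe-set collapsing.
#'
#' @param catalog a [generate_gene_catalog()] result.
#' @param config the matching [sim_config()].
#' @return an object of class `"tissue_atlas"`: a list with character
#'   vectors `probe_set_id`, `gene_id`, numeric matrix `values`
#'   (probe sets x 20 tissues) and logical matrix `present`.
#' @export
generate_tissue_atlas <- function(catalog, config) {
  stopifnot(inherits(catalog, "gene_catalog"), nrow(catalog) >= 1)
  set.seed(config$seed + 1L)
  tissues <- atlas_tissues()
  nt <- length(tissues)
  n <- nrow(catalog)
  target <- ifelse(catalog$tissue_class == "testis", "testes",
                   ifelse(catalog$tissue_class == "midgut", "adult_midgut", NA))

  values <- matrix(0, n, nt, dimnames = list(NULL, tissues))
  present <- matrix(TRUE, n, nt, dimnames = list(NULL, tissues))
  for (i in seq_len(n)) {
    if (is.na(target[i])) {
      mu <- stats::rnorm(1, 7, 1)
      v <- 2^stats::rnorm(nt, mu, 0.8)
      absent <- stats::runif(nt) < config$atlas_absent_fraction
      v[absent] <- stats::runif(sum(absent), 0.5, 20)
      values[i, ] <- v
      present[i, ] <- !absent
    } else {
      tlog <- stats::rnorm(1, 11, 0.5)
      v <- stats::runif(nt, 0.5, 5)
      pr <- rep(FALSE, nt)
      leaky <- sample(setdiff(seq_len(nt), match(target[i], tissues)),
                      sample(0:3, 1))
      v[leaky] <- 2^stats::runif(length(leaky), 1, 0.3 * tlog)
      pr[leaky] <- TRUE
      v[match(target[i], tissues)] <- 2^tlog
      pr[match(target[i], tissues)] <- TRUE
      values[i, ] <- v
      present[i, ] <- pr
    }
  }
  probe_set_id <- paste0(catalog$gene_id, "_ps1")
  gene_id <- catalog$gene_id

  # redundant, weaker probe sets for ~10% of genes
  dup <- which(stats::runif(n) < 0.1)
  if (length(dup)) {
    shrink <- stats::runif(length(dup), 0.3, 0.7)
    values <- rbind(values, values[dup, , drop = FALSE] * shrink)
    present <- rbind(present, present[dup, , drop = FALSE])
    probe_set_id <- c(probe_set_id, paste0(catalog$gene_id[dup], "_ps2"))
    gene_id <- c(gene_id, catalog$gene_id[dup])
  }
  structure(list(probe_set_id = probe_set_id, gene_id = gene_id,
                 values = values, present = present),
            class = "tissue_atlas")
}

#' Generate planted ground truth for a simulated contrast
#'
#' Draws each gene's true log2 effect, fixes the per-array dye
#' orientations, and pre-assigns which spots on each array will be built to
#' fail QC (and by which criterion). The sample median of the true effects
#' within each tissue class is pinned exactly to the configured shift;
#' genes in no class get effects from a distribution whose sample median is
#' exactly `background_shift`.
#'
#' @param catalog a [generate_gene_catalog()] result.
#' @param config the matching [sim_config()].
#' @return an object of class `"planted_truth"`: list with `genes`
#'   (data.frame `gene_id`, `tissue_class`, `true_lfc`), `orientation`
#'   (per-array +1/-1), `batch` (per-array label), `qc_fail` and `qc_mode`
#'   (genes x arrays matrices; mode 1 = pixel fraction, 2 = dim foreground,
#'   3 = too few pixels, 0 = clean).
#' @export
generate_planted_truth <- function(catalog, config) {
  stopifnot(inherits(catalog, "gene_catalog"))
  set.seed(config$seed + 2L)
  n <- nrow(catalog)
  eff <- numeric(n)
  pin <- function(x, m) if (length(x)) x - stats::median(x) + m else x
  for (cl in c("testis", "midgut", "none")) {
    idx <- which(catalog$tissue_class == cl)
    shift <- switch(cl, testis = config$testis_median_shift,
                    midgut = config$midgut_median_shift,
                    none = config$background_shift)
    sdv <- if (cl == "none") config$background_effect_sd else config$class_effect_sd
    eff[idx] <- pin(stats::rnorm(length(idx), shift, sdv), shift)
  }
  qc_fail <- matrix(FALSE, n, config$n_arrays)
  qc_mode <- matrix(0L, n, config$n_arrays)
  for (j in seq_len(config$n_arrays)) {
    nf <- round(config$qc_fail_fraction * n)
    if (nf > 0) {
      bad <- sample.int(n, nf)
      qc_fail[bad, j] <- TRUE
      qc_mode[bad, j] <- sample(1:3, nf, replace = TRUE)
    }
  }
  nb <- ceiling(config$n_arrays / 2)
  structure(list(
    genes = data.frame(gene_id = catalog$gene_id,
                       tissue_class = catalog$tissue_class,
                       true_lfc = eff, stringsAsFactors = FALSE),
    orientation = config$dye_swap_pattern,
    batch = rep(c("b1", "b2"), c(nb, config$n_arrays - nb)),
    qc_fail = qc_fail,
    qc_mode = qc_mode
  ), class = "planted_truth")
}

# smooth per-array artifact fields -------------------------------------------

# cubic dye-bias curve in A, centered, scaled to max|.| = amplitude
dye_bias_curve <- function(A, amplitude) {
  if (amplitude == 0) return(numeric(length(A)))
  u <- (A - stats::median(A)) / max(1e-9, diff(range(A)) / 2)
  co <- stats::rnorm(3)
  b <- co[1] * u + co[2] * u^2 + co[3] * u^3
  b <- b - mean(b)
  b * amplitude / max(abs(b))
}

# low-order polynomial + Gaussian bump over unit-square coordinates
spatial_field <- function(u, v, amplitude) {
  if (amplitude == 0) return(numeric(length(u)))
  co <- stats::rnorm(5)
  ctr <- stats::runif(2)
  r <- stats::runif(1, 0.1, 0.3)
  f <- co[1] * u + co[2] * v + co[3] * u * v + co[4] * u^2 + co[5] * v^2 +
    stats::rnorm(1, 0, 1.5) * exp(-((u - ctr[1])^2 + (v - ctr[2])^2) / (2 * r^2))
  f <- f - mean(f)
  f * amplitude / max(abs(f))
}

#' Generate synthetic dye-swapped hybridizations
#'
#' Builds one spot per gene per array on the print grid. Each spot's log2
#' ratio is the orientation-signed planted effect plus an
#' intensity-dependent dye bias (smooth cubic in A), a smooth spatial field
#' over slide coordinates, and Gaussian noise; channel foreground medians
#' are reconstructed from (A, M). Spot summary statistics (background
#' medians and SDs, foreground pixel counts, and the fraction of foreground
#' pixels above background + 2 SD) come from closed-form log-normal pixel
#' populations, so QC pass/fail is controlled exactly: spots pre-assigned a
#' failure mode are constructed to violate that criterion, all other spots
#' are guaranteed to pass all three criteria.
#'
#' @param catalog a [generate_gene_catalog()] result.
#' @param truth a [generate_planted_truth()] result for the same catalog.
#' @param config the matching [sim_config()].
#' @return list of `"hybridization"` objects (see [read_spot_table()]).
#' @export
generate_hybridizations <- function(catalog, truth, config) {
  stopifnot(inherits(truth, "planted_truth"),
            identical(truth$genes$gene_id, catalog$gene_id))
  set.seed(config$seed + 3L)
  n <- nrow(catalog)
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  spot_of_gene <- sample.int(nr * nc, n)   # fixed print layout, all arrays
  row <- (spot_of_gene - 1L) %/% nc + 1L
  col <- (spot_of_gene - 1L) %% nc + 1L
  x <- col * 150; y <- row * 150          # slide coordinates, micrometers
  A0 <- pmin(14, pmax(8.5, stats::rnorm(n, 10.5, 1.2)))
  noise_sd <- sqrt(config$biological_sd^2 + config$technical_sd^2)
  sigma_pix <- 0.8                        # log2 SD of foreground pixel population

  hybs <- vector("list", config$n_arrays)
  for (j in seq_len(config$n_arrays)) {
    A <- A0 + stats::rnorm(n, 0, 0.1)
    M <- truth$orientation[j] * truth$genes$true_lfc +
      dye_bias_curve(A, config$dye_bias_amplitude) +
      spatial_field(x / max(x), y / max(y), config$spatial_amplitude) +
      stats::rnorm(n, 0, noise_sd)
    fg1 <- 2^(A + M / 2)
    fg2 <- 2^(A - M / 2)
    bg1 <- 2^stats::rnorm(n, 7, 0.3)
    bg2 <- 2^stats::rnorm(n, 7, 0.3)
    bsd1 <- bg1 * stats::runif(n, 0.2, 0.3)
    bsd2 <- bg2 * stats::runif(n, 0.2, 0.3)
    px1 <- 60L + stats::rpois(n, 30)
    px2 <- 60L + stats::rpois(n, 30)

    # clean spots: guarantee criterion 2 in the brighter channel
    brighter1 <- fg1 >= fg2
    bg1 <- ifelse(brighter1, pmin(bg1, fg1 / 3.3), bg1)
    bg2 <- ifelse(!brighter1, pmin(bg2, fg2 / 3.3), bg2)
    bsd1 <- pmin(bsd1, bg1 * 0.3)
    bsd2 <- pmin(bsd2, bg2 * 0.3)

    frac_from_model <- function(fg, bg, bsd) {
      pmin(1, pmax(0, 1 - stats::pnorm((log2(bg + 2 * bsd) - log2(fg)) / sigma_pix)))
    }
    fr1 <- frac_from_model(fg1, bg1, bsd1)
    fr2 <- frac_from_model(fg2, bg2, bsd2)

    mode <- truth$qc_mode[, j]
    m1 <- mode == 1L   # pixel-fraction failure in both channels
    fr1[m1] <- stats::runif(sum(m1), 0.10, 0.68)
    fr2[m1] <- stats::runif(sum(m1), 0.10, 0.68)
    m2 <- mode == 2L   # dim foreground: fg < 3*bg in both channels
    bg1[m2] <- fg1[m2] / stats::runif(sum(m2), 1.1, 2.7)
    bg2[m2] <- fg2[m2] / stats::runif(sum(m2), 1.1, 2.7)
    bsd1[m2] <- bg1[m2] * stats::runif(sum(m2), 0.2, 0.3)
    bsd2[m2] <- bg2[m2] * stats::runif(sum(m2), 0.2, 0.3)
    fr1[m2] <- frac_from_model(fg1[m2], bg1[m2], bsd1[m2])
    fr2[m2] <- frac_from_model(fg2[m2], bg2[m2], bsd2[m2])
    m3 <- mode == 3L   # too few foreground pixels
    px1[m3] <- sample(3:30, sum(m3), replace = TRUE)
    px2[m3] <- sample(3:30, sum(m3), replace = TRUE)

    spots <- data.frame(
      probe_id = catalog$gene_id,
      block = 1L, row = row, col = col, x = x, y = y,
      fg_median_ch1 = fg1, fg_pixels_ch1 = px1, frac_fg_gt_bg2sd_ch1 = fr1,
      bg_median_ch1 = bg1, bg_sd_ch1 = bsd1,
      fg_median_ch2 = fg2, fg_pixels_ch2 = px2, frac_fg_gt_bg2sd_ch2 = fr2,
      bg_median_ch2 = bg2, bg_sd_ch2 = bsd2,
      stringsAsFactors = FALSE
    )
    hybs[[j]] <- hybridization(spots, array_id = sprintf("array%02d", j),
                               orientation = truth$orientation[j],
                               batch = truth$batch[j])
  }
  hybs
}

#' Simulate a full synthetic experiment
#'
#' Convenience wrapper chaining catalog, planted truth, atlas, and
#' hybridization generation under one configuration.
#'
#' @param config a [sim_config()] object.
#' @return list with `catalog`, `truth`, `atlas`, `hybridizations`,
#'   `config`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  catalog <- generate_gene_catalog(config)
  truth <- generate_planted_truth(catalog, config)
  atlas <- generate_tissue_atlas(catalog, config)
  hybs <- generate_hybridizations(catalog, truth, config)
  list(catalog = catalog, truth = truth, atlas = atlas,
       hybridizations = hybs, config = config)
}
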