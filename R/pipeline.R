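#' Pipeline configuration
#'
#' Either a simulation block (a [sim_config()]) or input paths must be
#' given. Paths mode expects `spot_tables` (named vector of spot-table
#' files), `orientations`, `batches`, `annotation` (gene table path) and
#' `atlas` (atlas table path).
#'
#' @param simulate a [sim_config()] or `NULL`.
#' @param paths list of input paths (ignored when `simulate` is given).
#' @param qc run spot QC (default `TRUE`).
#' @param intensity_span,spatial_span loess spans for the two
#'   normalization passes.
#' @param alpha significance level for downstream calls.
#' @param tau_cutoff tissue-specificity cutoff.
#' @param n_perm permutations for the sign-flip FDR.
#' @param seed integer seed (pipeline-level randomness: permutations).
#' @param out_dir output directory.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL, qc = TRUE,
                            intensity_span = 0.3, spatial_span = 0.002,
                            alpha = 0.05, tau_cutoff = 0.9, n_perm = 100,
                            seed = 1L, out_dir = tempfile("poearray_run_")) {
  if (!(alpha > 0 && alpha < 1)) stop_config("alpha must be in (0, 1)")
  for (s in c(intensity_span, spatial_span)) {
    if (!(s > 0 && s <= 1)) stop_config("spans must lie in (0, 1]")
  }
  if (is.null(simulate) && is.null(paths)) {
    stop_config("either a simulate block or input paths must be given")
  }
  structure(list(simulate = simulate, paths = paths, qc = qc,
                 intensity_span = intensity_span,
                 spatial_span = spatial_span, alpha = alpha,
                 tau_cutoff = tau_cutoff, n_perm = n_perm,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

stage <- function(name, log_con, expr) {
  tryCatch(expr, error = function(e) {
    msg <- paste0("stage '", name, "' failed: ", conditionMessage(e))
    if (!is.null(log_con)) writeLines(paste(Sys.time(), msg), log_con)
    stop(errorCondition(msg, class = c("poe_stage_error", "error")))
  })
}

#' Run the full analysis pipeline
#'
#' simulate/ingest -> spot QC -> two-pass loess normalization -> dye-swap
#' model with moderated variances, BH q values and sign-flip permutation
#' FDR -> tissue-specificity classification -> statistical battery.
#' Writes, under `config$out_dir`: `config.yaml`, `manifest.yaml` (config
#' hash, seed, package version), `qc_report.tsv`, per-array normalized MA
#' tables under `ma/`, `contrast_results.tsv`, `specificity.tsv`,
#' `stats_report.tsv`, `chromosome_table.tsv`, and `pipeline.log`.
#' Identical config and seed give identical numeric outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `fit`, `perm` (moderated-t permutation
#'   FDR), `perm_median` (median-estimator permutation FDR), `specificity`,
#'   `chromosome_table`, `stats` (list of `"poe_test"`), `qc`,
#'   `catalog`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logln <- function(...) writeLines(paste(Sys.time(), ...), log_con)

  # ingest / simulate ---------------------------------------------------
  inputs <- stage("input", log_con, {
    if (!is.null(config$simulate)) {
      sim <- simulate_experiment(config$simulate)
      logln("simulated", length(sim$hybridizations), "arrays,",
            nrow(sim$catalog), "genes")
      sim
    } else {
      p <- config$paths
      for (f in c(unlist(p$spot_tables), p$annotation, p$atlas)) {
        if (!file.exists(f)) stop_data("input path not found: ", f)
      }
      hybs <- lapply(seq_along(p$spot_tables), function(j) {
        read_spot_table(p$spot_tables[[j]],
                        array_id = names(p$spot_tables)[j],
                        orientation = p$orientations[j],
                        batch = p$batches[j])
      })
      catalog <- read_annotation(p$annotation)
      atlas <- read_atlas(p$atlas)
      logln("read", length(hybs), "arrays from disk")
      list(catalog = catalog, truth = NULL, atlas = atlas,
           hybridizations = hybs, config = NULL)
    }
  })

  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(serializable_config(config), cfg_path)

  # spot QC -------------------------------------------------------------
  qc_out <- stage("qc", log_con, {
    if (config$qc) {
      res <- lapply(inputs$hybridizations, filter_hybridization)
      hybs <- lapply(res, `[[`, "hyb")
      reports <- lapply(res, `[[`, "report")
      tab <- qc_report_table(reports)
      logln("QC:", sum(tab$n_in - tab$n_passed), "of", sum(tab$n_in),
            "spots removed")
      list(hybs = hybs, table = tab)
    } else {
      list(hybs = inputs$hybridizations, table = NULL)
    }
  })
  if (!is.null(qc_out$table)) {
    write_tsv(qc_out$table, file.path(config$out_dir, "qc_report.tsv"))
  }

  # normalization -------------------------------------------------------
  ma_list <- stage("normalize", log_con, {
    dir.create(file.path(config$out_dir, "ma"), showWarnings = FALSE)
    lapply(qc_out$hybs, function(h) {
      ma <- normalize_hybridization(h, config$intensity_span,
                                    config$spatial_span)
      write_tsv(ma, file.path(config$out_dir, "ma",
                              paste0(h$array_id, ".tsv")))
      ma
    })
  })
  logln("normalized", length(ma_list), "arrays")

  # differential expression ---------------------------------------------
  de <- stage("de", log_con, {
    em <- expression_matrix(
      ma_list,
      orientation = vapply(qc_out$hybs, `[[`, integer(1), "orientation"),
      batch = vapply(qc_out$hybs, `[[`, character(1), "batch"))
    fit <- dyeswap_fit(em)
    perm <- permutation_fdr(em, n_perm = config$n_perm,
                            seed = config$seed)
    perm_median <- permutation_fdr(em, n_perm = config$n_perm,
                                   seed = config$seed,
                                   statistic = "median")
    fit$table$perm_fdr <- perm$perm_fdr[match(fit$table$gene_id,
                                              perm$gene_id)]
    logln("DE:", sum(fit$table$testable), "testable genes,",
          sum(fit$table$q < config$alpha, na.rm = TRUE),
          "significant at q <", config$alpha)
    list(em = em, fit = fit, perm = perm, perm_median = perm_median)
  })
  write_contrast_results(de$fit,
                         file.path(config$out_dir, "contrast_results.tsv"),
                         annotation = inputs$catalog)

  # tissue specificity ---------------------------------------------------
  spec <- stage("specificity", log_con, {
    atlas <- preprocess_atlas(inputs$atlas)
    st <- specificity_table(atlas, cutoff = config$tau_cutoff)
    logln("specificity:", sum(st$specific), "of", nrow(st),
          "genes specific at tau >", config$tau_cutoff)
    st
  })
  write_tsv(spec, file.path(config$out_dir, "specificity.tsv"))

  # statistical battery --------------------------------------------------
  stats_out <- stage("stats", log_con, {
    tab <- de$fit$table
    sig <- !is.na(tab$q) & tab$q < config$alpha
    spec_ok <- spec[spec$specific, ]
    testis_ids <- spec_ok$gene_id[spec_ok$tissue == "testes"]
    midgut_ids <- spec_ok$gene_id[spec_ok$tissue == "adult_midgut"]
    in_testis <- tab$gene_id %in% testis_ids
    in_midgut <- tab$gene_id %in% midgut_ids

    reports <- list()
    # class enrichment among significant genes
    for (cl in c("testis", "midgut")) {
      inc <- if (cl == "testis") in_testis else in_midgut
      reports[[paste0(cl, "_enrichment")]] <- contingency_test(
        sum(sig & inc), sum(sig & !inc),
        sum(!sig & inc), sum(!sig & !inc),
        test = paste0(cl, "-specific enrichment among significant genes"))
      reports[[paste0(cl, "_direction")]] <- direction_bias(
        tab$log2FC, sig, inc,
        test = paste0("direction bias, ", cl, "-specific genes"))
      grp <- tab$log2FC[inc & tab$testable]
      rest <- tab$log2FC[!inc & tab$testable]
      if (length(grp) > 0 && length(rest) > 0) {
        reports[[paste0(cl, "_shift")]] <- mannwhitney_shift(
          grp, rest, test = paste0("median shift, ", cl, "-specific genes"))
      }
    }
    # X-linked vs autosomal by direction among significant genes,
    # overall and restricted to active-chromatin (YELLOW) genes
    arm <- inputs$catalog$arm[match(tab$gene_id, inputs$catalog$gene_id)]
    color <- inputs$catalog$chromatin_color[match(tab$gene_id,
                                                  inputs$catalog$gene_id)]
    x_dir_table <- function(keep, label) {
      k <- sig & keep & !is.na(arm) & arm != "Other"
      contingency_test(sum(k & tab$log2FC > 0 & arm == "X"),
                       sum(k & tab$log2FC > 0 & arm != "X"),
                       sum(k & tab$log2FC < 0 & arm == "X"),
                       sum(k & tab$log2FC < 0 & arm != "X"),
                       test = label)
    }
    reports$x_direction <- x_dir_table(TRUE,
      "X-linked vs autosomal by direction, significant genes")
    if (any(!is.na(color) & color == "YELLOW")) {
      reports$x_direction_yellow <- x_dir_table(
        !is.na(color) & color == "YELLOW",
        "X-linked vs autosomal by direction, YELLOW-chromatin genes")
    }
    # estimator concordance (mean-based vs median-based fold-changes)
    tt <- tab[tab$testable, ]
    reports$estimator_concordance <- spearman_corr(
      tt$log2FC, tt$median_log2FC,
      test = "fold-change estimator concordance")
    # batch concordance + SMA between batch-wise estimates
    ub <- unique(de$em$batch)
    if (length(ub) >= 2) {
      corrected <- sweep(de$em$M, 2, de$em$orientation, `*`)
      b1 <- rowMeans(corrected[, de$em$batch == ub[1], drop = FALSE],
                     na.rm = TRUE)
      b2 <- rowMeans(corrected[, de$em$batch == ub[2], drop = FALSE],
                     na.rm = TRUE)
      ok <- is.finite(b1) & is.finite(b2)
      reports$batch_concordance <- spearman_corr(
        b1[ok], b2[ok], test = "batch concordance")
      reports$batch_sma <- sma_fit(b1[ok], b2[ok],
                                   test = "SMA, batch 2 on batch 1")
    }
    logln("stats:", length(reports), "tests")
    reports
  })
  write_stats_report(stats_out, file.path(config$out_dir,
                                          "stats_report.tsv"))

  chrom <- stage("chromosome_table", log_con, {
    tab <- de$fit$table
    sig_ids <- tab$gene_id[!is.na(tab$q) & tab$q < config$alpha]
    ct <- chromosome_table(sig_ids, tab$gene_id, inputs$catalog)
    write_tsv(ct, file.path(config$out_dir, "chromosome_table.tsv"))
    ct
  })

  manifest <- list(
    package = "poearray",
    version = as.character(utils::packageVersion("poearray")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_arrays = length(ma_list),
    created = format(Sys.time())
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  logln("done")

  invisible(list(fit = de$fit, em = de$em, perm = de$perm,
                 perm_median = de$perm_median, specificity = spec,
                 chromosome_table = chrom, stats = stats_out,
                 qc = qc_out$table, catalog = inputs$catalog,
                 truth = inputs$truth, out_dir = config$out_dir))
}

serializable_config <- function(config) {
  out <- unclass(config)
  if (!is.null(out$simulate)) {
    sim <- unclass(out$simulate)
    sim$chromosome_proportions <- as.list(sim$chromosome_proportions)
    out$simulate <- sim
  }
  out
}
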