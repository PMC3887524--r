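#' Construct a hybridization object
#'
#' One two-color array: a table of spot records plus the dye orientation
#' (which genotype is in which channel) and a batch label.
#'
#' @param spots data.frame of spot records (see [spot_columns()]).
#' @param array_id array identifier.
#' @param orientation +1 if genotype A is in channel 1, -1 if dye-swapped.
#' @param batch batch label.
#' @return an object of class `"hybridization"`.
#' @export
hybridization <- function(spots, array_id, orientation = 1L, batch = "b1") {
  orientation <- as.integer(orientation)
  if (!orientation %in% c(-1L, 1L)) {
    stop_data("orientation must be +1 or -1")
  }
  if (!is.data.frame(spots) || nrow(spots) < 1L) {
    stop_data("a hybridization needs at least one spot")
  }
  missing_cols <- setdiff(spot_columns(), names(spots))
  if (length(missing_cols)) {
    stop_data("spot table lacks required column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  key <- paste(spots$block, spots$row, spots$col)
  if (anyDuplicated(key)) {
    stop_data("duplicate (block,row,col) grid positions within one array")
  }
  num <- spots[, setdiff(spot_columns(), "probe_id")]
  if (any(vapply(num, function(v) any(v < 0, na.rm = TRUE), logical(1)))) {
    stop_data("negative values in spot summary fields")
  }
  structure(list(array_id = array_id, batch = batch,
                 orientation = orientation, spots = spots),
            class = "hybridization")
}

#' @export
print.hybridization <- function(x, ...) {
  cat("Two-color hybridization", x$array_id,
      sprintf("(batch %s, orientation %+d)\n", x$batch, x$orientation))
  cat(" ", nrow(x$spots), "spots\n")
  invisible(x)
}

#' Canonical spot-table columns
#'
#' The tab-delimited spot dialect this package reads and writes: probe id,
#' 1-based grid indices, slide coordinates in micrometers, and for each
#' channel the foreground median, foreground pixel count, fraction of
#' foreground pixels above background median + 2 background SD, background
#' median, and background SD.
#' @return character vector of required column names.
#' @export
spot_columns <- function() {
  c("probe_id", "block", "row", "col", "x", "y",
    "fg_median_ch1", "fg_pixels_ch1", "frac_fg_gt_bg2sd_ch1",
    "bg_median_ch1", "bg_sd_ch1",
    "fg_median_ch2", "fg_pixels_ch2", "frac_fg_gt_bg2sd_ch2",
    "bg_median_ch2", "bg_sd_ch2")
}

#' Column-mapping dialects for spot tables
#'
#' A dialect maps the canonical column names to the names found in a file,
#' so that real GenePix-style exports can be ingested. `genepix_dialect()`
#' maps the usual GenePix result columns, with channel 1 = 532 nm (Cy3)
#' and channel 2 = 635 nm (Cy5); note GenePix reports "% > B+2SD" in
#' percent, which is rescaled to a fraction on read.
#' @return named character vector `canonical -> file column`.
#' @export
default_dialect <- function() {
  stats::setNames(spot_columns(), spot_columns())
}

#' @rdname default_dialect
#' @export
genepix_dialect <- function() {
  c(probe_id = "ID", block = "Block", row = "Row", col = "Column",
    x = "X", y = "Y",
    fg_median_ch1 = "F532 Median", fg_pixels_ch1 = "F Pixels",
    frac_fg_gt_bg2sd_ch1 = "% > B532+2SD",
    bg_median_ch1 = "B532 Median", bg_sd_ch1 = "B532 SD",
    fg_median_ch2 = "F635 Median", fg_pixels_ch2 = "F Pixels",
    frac_fg_gt_bg2sd_ch2 = "% > B635+2SD",
    bg_median_ch2 = "B635 Median", bg_sd_ch2 = "B635 SD")
}

#' Read a spot-level two-color array table
#'
#' Reads a tab-delimited spot table into a [hybridization()]. Extra columns
#' are ignored; missing required columns and non-numeric cells are
#' reported as errors.
#'
#' @param path file path.
#' @param dialect column mapping, see [default_dialect()].
#' @param array_id,orientation,batch array metadata (not stored in the spot
#'   table itself).
#' @param percent_fraction if `TRUE`, the pixel-fraction columns are in
#'   percent (GenePix style) and divided by 100 on read.
#' @return a `"hybridization"` object.
#' @export
read_spot_table <- function(path, dialect = default_dialect(),
                            array_id = basename(path), orientation = 1L,
                            batch = "b1", percent_fraction = FALSE) {
  if (!file.exists(path)) stop_data("spot table not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  missing_cols <- setdiff(unname(dialect), names(raw))
  if (length(missing_cols)) {
    stop_data("spot table ", path, " lacks required column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  spots <- raw[, dialect[spot_columns()], drop = FALSE]
  names(spots) <- spot_columns()
  for (cn in setdiff(spot_columns(), "probe_id")) {
    v <- suppressWarnings(as.numeric(spots[[cn]]))
    bad <- which(is.na(v) & !is.na(spots[[cn]]) & nzchar(spots[[cn]]))
    if (length(bad)) {
      stop_data("non-numeric value in column '", cn, "' at data row ",
                bad[1], " of ", path)
    }
    spots[[cn]] <- v
  }
  if (percent_fraction) {
    spots$frac_fg_gt_bg2sd_ch1 <- spots$frac_fg_gt_bg2sd_ch1 / 100
    spots$frac_fg_gt_bg2sd_ch2 <- spots$frac_fg_gt_bg2sd_ch2 / 100
  }
  for (cn in c("block", "row", "col", "fg_pixels_ch1", "fg_pixels_ch2")) {
    spots[[cn]] <- as.integer(round(spots[[cn]]))
  }
  hybridization(spots, array_id = array_id, orientation = orientation,
                batch = batch)
}

#' Write a hybridization's spot table
#' @param hyb a `"hybridization"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(hyb, path) {
  stopifnot(inherits(hyb, "hybridization"))
  write_tsv(hyb$spots[, spot_columns()], path)
}

write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_data("cannot write file: ", path)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-delimited with header; columns `gene_id`, `arm`, optionally
#' `chromatin_color` and `tissue_class`. Arms must come from the closed
#' vocabulary X, 2L, 2R, 3L, 3R, 4, Other ("Other" = not mapped to the
#' assembled reference genome). Duplicate gene ids are an error.
#'
#' @param path file path.
#' @return a `"gene_catalog"` data.frame.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop_data("annotation table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "arm") %in% names(df))) {
    stop_data("annotation table needs columns gene_id and arm")
  }
  if (anyDuplicated(df$gene_id)) {
    stop_data("duplicate gene_id in annotation: ",
              df$gene_id[anyDuplicated(df$gene_id)])
  }
  arms <- c("X", "2L", "2R", "3L", "3R", "4", "Other")
  bad <- setdiff(unique(df$arm), arms)
  if (length(bad)) {
    stop_data("unknown arm label(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(df$tissue_class)) df$tissue_class <- "none"
  if (is.null(df$chromatin_color)) df$chromatin_color <- NA_character_
  class(df) <- c("gene_catalog", "data.frame")
  df
}

#' Write a gene annotation table
#' @param catalog a `"gene_catalog"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(catalog, path) {
  write_tsv(as.data.frame(catalog), path)
}

#' Read / write a tissue atlas
#'
#' Flat tab-delimited layout: `probe_set_id`, `gene_id`, one numeric column
#' per tissue and one call column per tissue (`<tissue>_call`, "P" present /
#' "A" absent).
#'
#' @param path file path.
#' @return `read_atlas`: a `"tissue_atlas"` object.
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop_data("atlas table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  tissues <- atlas_tissues()
  need <- c("probe_set_id", "gene_id", tissues, paste0(tissues, "_call"))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_data("atlas table lacks column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  values <- as.matrix(df[, tissues])
  present <- as.matrix(df[, paste0(tissues, "_call")]) == "P"
  colnames(present) <- tissues
  structure(list(probe_set_id = df$probe_set_id, gene_id = df$gene_id,
                 values = values, present = present),
            class = "tissue_atlas")
}

#' @rdname read_atlas
#' @param atlas a `"tissue_atlas"`.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "tissue_atlas"))
  calls <- ifelse(atlas$present, "P", "A")
  colnames(calls) <- paste0(atlas_tissues(), "_call")
  df <- data.frame(probe_set_id = atlas$probe_set_id,
                   gene_id = atlas$gene_id,
                   atlas$values, calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @export
print.tissue_atlas <- function(x, ...) {
  cat("Tissue atlas:", length(x$probe_set_id), "probe sets,",
      length(unique(x$gene_id)), "genes,", ncol(x$values), "tissues\n")
  invisible(x)
}

#' Write the per-gene contrast result table
#'
#' Tab-delimited gene table with full-precision numeric columns plus a
#' rounded display column for the fold-change.
#'
#' @param fit a [dyeswap_fit()] object.
#' @param path output file path.
#' @param annotation optional `"gene_catalog"` supplying arm / class /
#'   color columns.
#' @return `path`, invisibly.
#' @export
write_contrast_results <- function(fit, path, annotation = NULL) {
  stopifnot(inherits(fit, "dyeswap_fit"))
  tab <- fit$table
  if (!is.null(annotation)) {
    idx <- match(tab$gene_id, annotation$gene_id)
    tab$arm <- annotation$arm[idx]
    tab$tissue_class <- annotation$tissue_class[idx]
    front <- c("gene_id", "arm", "tissue_class")
    tab <- tab[, c(front, setdiff(names(tab), front))]
  }
  tab$log2FC_display <- round(tab$log2FC, 3)
  write_tsv(tab, path)
}

#' Write a statistical test report
#'
#' One row per test: name, input counts/sizes, statistic, P value, notes.
#' @param reports a list of `"poe_test"` objects (see e.g.
#'   [contingency_test()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stats_report <- function(reports, path) {
  rows <- lapply(reports, function(r) {
    data.frame(test = r$test,
               inputs = r$inputs,
               statistic_name = r$statistic_name,
               statistic = r$statistic,
               p_value = r$p_value,
               notes = if (is.null(r$notes)) "" else r$notes,
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}
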