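#' Preprocess a tissue atlas
#'
#' Applies the standard atlas preprocessing: expression values with an
#' "absent" call are set to 1 (as are any values below 1, so the log2
#' floor is 0); for genes represented by several probe sets, only the
#' probe set with the strongest signal — the largest total value across
#' tissues — is retained. The result has one row per gene.
#'
#' @param atlas a `"tissue_atlas"`.
#' @return a `"tissue_atlas"` with one probe set per gene, values >= 1,
#'   all entries marked present.
#' @export
preprocess_atlas <- function(atlas) {
  stopifnot(inherits(atlas, "tissue_atlas"))
  v <- atlas$values
  v[!atlas$present] <- 1
  v[v < 1] <- 1
  totals <- rowSums(v)
  ord <- order(atlas$gene_id, -totals)   # strongest probe set first per gene
  first <- ord[!duplicated(atlas$gene_id[ord])]
  keep <- logical(nrow(v))
  keep[first] <- TRUE
  structure(list(probe_set_id = atlas$probe_set_id[keep],
                 gene_id = atlas$gene_id[keep],
                 values = v[keep, , drop = FALSE],
                 present = matrix(TRUE, sum(keep), ncol(v),
                                  dimnames = dimnames(v))),
            class = "tissue_atlas")
}

#' Tissue-specificity index tau
#'
#' tau = sum_i (1 - x_i / max(x)) / (N - 1), computed by default on log2
#' values with the absent floor at 1 (log2 1 = 0): 0 for a uniform
#' profile, 1 for expression confined to a single tissue. A profile whose
#' values are all equal (including all at the floor) has tau = 0 by
#' definition.
#'
#' @param values per-tissue expression values (>= 1 after preprocessing).
#' @param log compute on log2-transformed values (default) or on the raw
#'   scale.
#' @return tau in `[0, 1]`.
#' @export
tau <- function(values, log = TRUE) {
  if (length(values) < 2) stop_data("tau needs >= 2 tissues")
  x <- if (log) log2(pmax(values, 1)) else values
  mx <- max(x)
  if (mx <= 0 || all(x == x[1])) return(0)
  sum(1 - x / mx) / (length(x) - 1)
}

#' Classify genes as tissue-specific
#'
#' A gene is called specific when tau exceeds the cutoff (strictly) and
#' its maximum is attained in a single tissue; ties in the argmax are not
#' specific.
#'
#' @param atlas a preprocessed `"tissue_atlas"` (one row per gene).
#' @param cutoff tau cutoff (default 0.9, strict).
#' @param log passed to [tau()].
#' @return data.frame `gene_id`, `tau`, `tissue` (argmax), `specific`.
#' @export
classify_specific <- function(atlas, cutoff = 0.9, log = TRUE) {
  stopifnot(inherits(atlas, "tissue_atlas"))
  tissues <- colnames(atlas$values)
  n <- nrow(atlas$values)
  tv <- numeric(n); arg <- character(n); spec <- logical(n)
  for (i in seq_len(n)) {
    v <- atlas$values[i, ]
    tv[i] <- tau(v, log = log)
    mx <- max(v)
    at_max <- which(v == mx)
    arg[i] <- tissues[at_max[1]]
    spec[i] <- (tv[i] > cutoff) && (length(at_max) == 1L)
  }
  data.frame(gene_id = atlas$gene_id, tau = tv, tissue = arg,
             specific = spec, stringsAsFactors = FALSE)
}

#' Quantitative tissue-enrichment score
#'
#' log2 expression in the target tissue minus the mean log2 expression
#' over the other tissues; 0 for a uniform profile.
#'
#' @param values named per-tissue expression values (preprocessed).
#' @param tissue target tissue name.
#' @return enrichment score in log2 units.
#' @export
enrichment_score <- function(values, tissue) {
  if (!tissue %in% names(values)) {
    stop_data("tissue '", tissue, "' not in the atlas profile")
  }
  x <- log2(pmax(values, 1))
  x[[tissue]] - mean(x[names(values) != tissue])
}

#' Full specificity table with per-tissue enrichment
#'
#' @param atlas a preprocessed `"tissue_atlas"`.
#' @param cutoff tau cutoff.
#' @return [classify_specific()] output with one extra `enrich_<tissue>`
#'   column per tissue.
#' @export
specificity_table <- function(atlas, cutoff = 0.9) {
  calls <- classify_specific(atlas, cutoff = cutoff)
  x <- log2(pmax(atlas$values, 1))
  nt <- ncol(x)
  # enrichment for tissue t = x_t - mean over others = (n*x_t - sum)/ (n-1)
  enr <- (nt * x - rowSums(x)) / (nt - 1)
  colnames(enr) <- paste0("enrich_", colnames(x))
  cbind(calls, as.data.frame(enr))
}
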