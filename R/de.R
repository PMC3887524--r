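#' Assemble a genes-by-arrays expression matrix from normalized MA tables
#'
#' Rows are the union of probe ids across arrays; entries missing on an
#' array (QC-dropped spots) are `NA`.
#'
#' @param ma_list list of normalized MA data.frames ([compute_ma()] output).
#' @param orientation per-array dye orientation (+1/-1).
#' @param batch per-array batch labels.
#' @return object of class `"expression_matrix"`: list with numeric matrix
#'   `M` (genes x arrays), `orientation`, `batch`.
#' @export
expression_matrix <- function(ma_list, orientation, batch = NULL) {
  stopifnot(length(ma_list) == length(orientation))
  if (length(ma_list) < 2) stop_data("need at least 2 arrays")
  if (is.null(batch)) batch <- rep("b1", length(ma_list))
  genes <- sort(unique(unlist(lapply(ma_list, `[[`, "probe_id"))))
  M <- matrix(NA_real_, length(genes), length(ma_list),
              dimnames = list(genes, vapply(seq_along(ma_list),
                                            function(j) paste0("a", j),
                                            character(1))))
  for (j in seq_along(ma_list)) {
    M[match(ma_list[[j]]$probe_id, genes), j] <- ma_list[[j]]$M
  }
  orientation <- as.integer(orientation)
  if (length(unique(orientation)) == 1L && length(orientation) > 1L) {
    warning("all arrays share one dye orientation; dye bias will not cancel")
  }
  structure(list(M = M, orientation = orientation, batch = batch),
            class = "expression_matrix")
}

row_var <- function(x) {
  n <- rowSums(!is.na(x))
  mu <- rowMeans(x, na.rm = TRUE)
  v <- rowSums((x - mu)^2, na.rm = TRUE) / pmax(1, n - 1)
  v[n < 2] <- NA_real_
  v
}

row_median <- function(x) apply(x, 1, stats::median, na.rm = TRUE)

#' Invert the trigamma function
#'
#' Newton iteration on psi'(x) = y, used when moment-matching the
#' scaled-F model for gene-wise variances.
#' @param y positive value(s).
#' @return x with `trigamma(x) = y`.
#' @export
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    if (yy < 1e-6) return(1 / yy)
    x <- 0.5 + 1 / yy
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' Fits the scaled-F model s_g^2 ~ s0^2 F(d_g, d0) by moment-matching the
#' marginal distribution of log s^2: the mean and variance of
#' e_g = log s_g^2 - digamma(d_g/2) + log(d_g/2) give digamma/trigamma
#' equations whose solution is (d0, s0^2); the posterior variance is the
#' df-weighted average s_post^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g).
#' When the excess variance of e is nonpositive the prior df is infinite
#' and the posterior collapses to the pooled mean variance.
#'
#' @param s2 gene-wise sample variances.
#' @param df gene-wise residual degrees of freedom.
#' @return list with `d0`, `s0_2`, `s2_post` (same length as `s2`).
#' @export
moderate_variances <- function(s2, df) {
  ok <- is.finite(s2) & is.finite(df) & df > 0 & s2 > 0
  if (sum(ok) < 10) {
    stop_data("need >= 10 testable genes to estimate the variance prior")
  }
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  excess <- evar - mean(trigamma(df[ok] / 2))
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s0_2 + df * s2) / (d0 + df)
  } else {
    d0 <- Inf
    s0_2 <- mean(s2[ok])
    s2_post <- rep(s0_2, length(s2))
    warning("no excess variability in gene-wise variances; ",
            "using pooled variance (infinite prior df)")
  }
  list(d0 = d0, s0_2 = s0_2, s2_post = s2_post)
}

#' Fit the dye-swap direct-comparison model
#'
#' For each gene the orientation-corrected log2 ratios o_j * M_gj across
#' arrays estimate the contrast: log2FC_g is their mean, s_g^2 their
#' sample variance with d_g = n_g - 1 df. With `moderate = TRUE` the
#' variances are shrunk via [moderate_variances()] and the moderated
#' t_g = log2FC_g / (s_post_g / sqrt(n_g)) is referred to a t distribution
#' on d0 + d_g df; q values are Benjamini-Hochberg. A median-based
#' fold-change estimate (`median_log2FC`) is always reported alongside as
#' an independent, robust estimator. With two or more batches the
#' Spearman concordance of batch-wise fold-changes is recorded in
#' `$batch_concordance`.
#'
#' @param em an [expression_matrix()].
#' @param moderate logical; `FALSE` gives the ordinary per-gene t-test
#'   (equivalent to prior df d0 = 0).
#' @return object of class `"dyeswap_fit"`: list with `table` (data.frame:
#'   `gene_id`, `n_arrays`, `log2FC`, `median_log2FC`, `s2`, `df`, `t`,
#'   `p`, `q`, `testable`), `d0`, `s0_2`, `batch_concordance`,
#'   `orientation`, `corrected` (the orientation-corrected matrix).
#' @export
dyeswap_fit <- function(em, moderate = TRUE) {
  stopifnot(inherits(em, "expression_matrix"))
  corrected <- sweep(em$M, 2, em$orientation, `*`)
  n_g <- rowSums(!is.na(corrected))
  if (all(n_g < 2)) stop_data("no gene has >= 2 non-missing arrays")
  lfc <- rowMeans(corrected, na.rm = TRUE)
  lfc[n_g == 0] <- NA_real_
  med <- row_median(corrected)
  s2 <- row_var(corrected)
  df <- pmax(0, n_g - 1)
  testable <- n_g >= 2

  if (moderate) {
    mod <- moderate_variances(s2[testable], df[testable])
    d0 <- mod$d0
    s0_2 <- mod$s0_2
    s2_post <- rep(NA_real_, length(s2))
    s2_post[testable] <- mod$s2_post
    df_total <- d0 + df
  } else {
    d0 <- 0
    s0_2 <- NA_real_
    s2_post <- s2
    df_total <- df
  }
  tstat <- lfc / sqrt(s2_post / n_g)
  tstat[!testable | s2_post == 0] <- NA_real_
  p <- 2 * stats::pt(abs(tstat), df_total, lower.tail = FALSE)
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- bh_fdr(p[!is.na(p)])

  batch_concordance <- NA_real_
  ub <- unique(em$batch)
  if (length(ub) >= 2) {
    blfc <- sapply(ub, function(b) {
      rowMeans(corrected[, em$batch == b, drop = FALSE], na.rm = TRUE)
    })
    cc <- stats::cor(blfc[, 1], blfc[, 2], method = "spearman",
                     use = "complete.obs")
    batch_concordance <- cc
  }

  structure(list(
    table = data.frame(
      gene_id = rownames(em$M), n_arrays = n_g, log2FC = lfc,
      median_log2FC = med, s2 = s2, df = df, s2_post = s2_post,
      t = tstat, p = p, q = q, testable = testable,
      stringsAsFactors = FALSE, row.names = NULL),
    d0 = d0, s0_2 = s0_2, batch_concordance = batch_concordance,
    orientation = em$orientation, batch = em$batch,
    corrected = corrected
  ), class = "dyeswap_fit")
}

#' @export
print.dyeswap_fit <- function(x, ...) {
  cat("Dye-swap direct-comparison fit\n")
  cat(" ", nrow(x$table), "genes on", length(x$orientation), "arrays (",
      sum(x$orientation == 1), "vs", sum(x$orientation == -1),
      "dye orientations )\n")
  cat("  prior df d0 =", format(x$d0, digits = 4),
      " prior variance s0^2 =", format(x$s0_2, digits = 4), "\n")
  cat("  genes with q < 0.05:", sum(x$table$q < 0.05, na.rm = TRUE), "\n")
  if (!is.na(x$batch_concordance)) {
    cat("  batch concordance (Spearman):",
        format(x$batch_concordance, digits = 3), "\n")
  }
  invisible(x)
}

#' @export
summary.dyeswap_fit <- function(object, alpha = 0.05, ...) {
  tab <- object$table
  sig <- !is.na(tab$q) & tab$q < alpha
  out <- list(
    n_genes = nrow(tab),
    n_testable = sum(tab$testable),
    n_significant = sum(sig),
    n_up = sum(sig & tab$log2FC > 0),
    n_down = sum(sig & tab$log2FC < 0),
    d0 = object$d0, s0_2 = object$s0_2,
    batch_concordance = object$batch_concordance,
    alpha = alpha
  )
  class(out) <- "summary.dyeswap_fit"
  out
}

#' @export
print.summary.dyeswap_fit <- function(x, ...) {
  cat("Dye-swap contrast:", x$n_testable, "testable of", x$n_genes,
      "genes\n")
  cat("  significant at q <", x$alpha, ":", x$n_significant,
      sprintf("(%d up, %d down)\n", x$n_up, x$n_down))
  cat("  variance prior: d0 =", format(x$d0, digits = 4), ", s0^2 =",
      format(x$s0_2, digits = 4), "\n")
  invisible(x)
}

#' @export
coef.dyeswap_fit <- function(object, ...) {
  stats::setNames(object$table$log2FC, object$table$gene_id)
}

#' @export
residuals.dyeswap_fit <- function(object, ...) {
  object$corrected - object$table$log2FC
}

#' Volcano plot of a dye-swap fit
#' @param x a `"dyeswap_fit"`.
#' @param alpha highlight genes with q below this level.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.dyeswap_fit <- function(x, alpha = 0.05, ...) {
  tab <- x$table[x$table$testable, ]
  sig <- !is.na(tab$q) & tab$q < alpha
  graphics::plot(tab$log2FC, -log10(tab$p),
                 col = ifelse(sig, "firebrick", "grey50"), pch = 20,
                 cex = 0.4, xlab = expression(log[2] ~ "fold-change"),
                 ylab = expression(-log[10] ~ "p"), ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Benjamini-Hochberg q values
#'
#' Step-up q values with enforced monotonicity (a thin, named wrapper
#' around `p.adjust(method = "BH")`).
#' @param p vector of p values in `[0, 1]`.
#' @return q values, same length.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_data("p values must be in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Sign-flip permutation FDR
#'
#' Builds an empirical null for the per-gene statistic by flipping each
#' array's dye-orientation sign over random flip patterns (identity
#' excluded) and refitting. For a threshold tau, FDR(tau) is the mean null
#' count of |statistic| >= tau divided by the observed count, capped at 1
#' and monotonized; each gene's FDR is evaluated at its own |statistic|.
#'
#' @param em an [expression_matrix()].
#' @param n_perm number of flip patterns (>= 10).
#' @param seed integer seed.
#' @param statistic `"moderated_t"` (default) or `"median"` — the latter
#'   uses the per-gene median fold-change scaled by the moderated standard
#'   error, the robust estimator's test statistic.
#' @return data.frame `gene_id`, `stat`, `perm_fdr`.
#' @export
permutation_fdr <- function(em, n_perm = 100, seed = 1L,
                            statistic = c("moderated_t", "median")) {
  stopifnot(inherits(em, "expression_matrix"))
  statistic <- match.arg(statistic)
  if (n_perm < 10) stop_data("n_perm must be >= 10")
  J <- ncol(em$M)
  if (J < 4) warning("fewer than 4 arrays: sign-flip null space is small")

  stat_fun <- function(M_signed) {
    n_g <- rowSums(!is.na(M_signed))
    est <- if (statistic == "median") row_median(M_signed)
           else rowMeans(M_signed, na.rm = TRUE)
    s2 <- row_var(M_signed)
    df <- pmax(0, n_g - 1)
    ok <- n_g >= 2 & is.finite(s2) & s2 > 0
    # under permuted orientations a pooled-variance fallback is expected
    mod <- suppressWarnings(moderate_variances(s2[ok], df[ok]))
    tt <- rep(NA_real_, nrow(M_signed))
    tt[ok] <- est[ok] / sqrt(mod$s2_post / n_g[ok])
    tt
  }

  corrected <- sweep(em$M, 2, em$orientation, `*`)
  obs <- stat_fun(corrected)

  set.seed(seed)
  null_pool <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    repeat {
      flips <- sample(c(-1, 1), J, replace = TRUE)
      if (any(flips != 1)) break
    }
    null_pool[[b]] <- stat_fun(sweep(corrected, 2, flips, `*`))
  }
  null_abs <- sort(abs(unlist(null_pool)))
  null_abs <- null_abs[is.finite(null_abs)]

  keep <- which(is.finite(obs))
  a_obs <- abs(obs[keep])
  ord <- order(a_obs, decreasing = TRUE)
  # observed count at gene's own |stat| = its rank; null count via binary search
  n_null_ge <- length(null_abs) -
    findInterval(a_obs[ord] - 1e-12, null_abs)
  raw <- pmin(1, (n_null_ge / n_perm) / seq_along(ord))
  qv <- rev(cummin(rev(raw)))
  fdr <- rep(NA_real_, length(obs))
  fdr[keep[ord]] <- qv

  data.frame(gene_id = rownames(em$M), stat = obs, perm_fdr = fdr,
             stringsAsFactors = FALSE)
}
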