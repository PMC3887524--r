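poe_test <- function(test, inputs, statistic_name, statistic, p_value,
                     notes = NULL, extra = list()) {
  structure(c(list(test = test, inputs = inputs,
                   statistic_name = statistic_name, statistic = statistic,
                   p_value = p_value, notes = notes), extra),
            class = "poe_test")
}

#' @export
print.poe_test <- function(x, ...) {
  cat(x$test, "\n  inputs: ", x$inputs, "\n  ", x$statistic_name, " = ",
      format(x$statistic, digits = 4), ", P = ",
      format(x$p_value, digits = 4), "\n", sep = "")
  if (!is.null(x$notes)) cat("  ", x$notes, "\n", sep = "")
  invisible(x)
}

#' 2x2 contingency test: odds ratio and Fisher exact P
#'
#' The odds ratio is the sample odds ratio ad/(bc) for the table
#' rbind(c(a, b), c(c, d)); it is reported as `NA` ("--") when b or c is
#' zero or a row is degenerate. The two-sided Fisher exact P sums the
#' probabilities of all tables as or less probable than the observed one.
#'
#' @param a,b,c,d cell counts: row 1 = (a, b), row 2 = (c, d).
#' @param test label for the report.
#' @return a `"poe_test"` with fields `or` and the counts.
#' @export
contingency_test <- function(a, b, c, d, test = "contingency 2x2") {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) stop_data("negative counts in contingency table")
  if (sum(counts) == 0) stop_data("empty contingency table")
  or <- if (b == 0 || c == 0 || (a == 0 && b == 0) || (c == 0 && d == 0)) {
    NA_real_
  } else {
    (a / b) / (c / d)
  }
  p <- stats::fisher.test(matrix(counts, 2, 2, byrow = TRUE))$p.value
  poe_test(test, sprintf("a=%d b=%d c=%d d=%d", a, b, c, d),
           "odds ratio", or, p, extra = list(or = or, counts = counts))
}

#' Chi-square goodness of fit against expected proportions
#'
#' chi^2 = sum (O - E)^2 / E with E = total * proportion, on k - 1 df.
#' `correct = TRUE` applies the Yates continuity correction
#' (|O - E| - 1/2), appropriate for the two-category form.
#'
#' @param observed integer counts.
#' @param expected_proportions proportions summing to 1.
#' @param correct apply continuity correction (default `FALSE`).
#' @param test label for the report.
#' @return a `"poe_test"` with field `chisq`.
#' @export
chisq_gof <- function(observed, expected_proportions, correct = FALSE,
                      test = "chi-square goodness of fit") {
  if (abs(sum(expected_proportions) - 1) > 1e-9) {
    stop_data("expected proportions must sum to 1")
  }
  if (sum(observed) <= 0) stop_data("observed total must be positive")
  e <- sum(observed) * expected_proportions
  if (any(e == 0)) stop_data("expected count of zero")
  dev <- abs(observed - e)
  if (correct) dev <- pmax(0, dev - 0.5)
  chisq <- sum(dev^2 / e)
  p <- stats::pchisq(chisq, df = length(observed) - 1, lower.tail = FALSE)
  poe_test(test, paste0("O=[", paste(observed, collapse = ","), "]"),
           "chi-square", chisq, p,
           notes = if (correct) "continuity-corrected" else NULL,
           extra = list(chisq = chisq))
}

#' Mann-Whitney test for a group median shift
#'
#' Two-sided Mann-Whitney U comparing a gene group against the rest
#' (exact for small untied samples, otherwise normal approximation with
#' tie correction, as in `wilcox.test`). Reports both medians and their
#' difference.
#'
#' @param group,rest numeric vectors (both nonempty).
#' @param test label for the report.
#' @return a `"poe_test"` with fields `U`, `median_group`, `median_rest`,
#'   `median_diff`.
#' @export
mannwhitney_shift <- function(group, rest, test = "Mann-Whitney shift") {
  if (length(group) == 0 || length(rest) == 0) {
    stop_data("both groups must be nonempty")
  }
  wt <- suppressWarnings(stats::wilcox.test(group, rest))
  mg <- stats::median(group); mr <- stats::median(rest)
  poe_test(test, sprintf("n=%d vs n=%d", length(group), length(rest)),
           "U", unname(wt$statistic), wt$p.value,
           notes = sprintf("medians %.4g vs %.4g", mg, mr),
           extra = list(U = unname(wt$statistic), median_group = mg,
                        median_rest = mr, median_diff = mg - mr))
}

#' Spearman rank correlation
#'
#' rho with average ranks for ties; P from the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 df.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param test label for the report.
#' @return a `"poe_test"` with field `rho`.
#' @export
spearman_corr <- function(x, y, test = "Spearman correlation") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || length(x) != length(y)) {
    stop_data("need equal-length vectors with >= 3 finite pairs")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_data("rho undefined for a constant vector")
  }
  rho <- stats::cor(x, y, method = "spearman")
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
  }
  poe_test(test, sprintf("n=%d", n), "rho", rho, p,
           extra = list(rho = rho))
}

#' Standard major axis regression
#'
#' Symmetric line fit: slope = sign(r) * sd(y) / sd(x), intercept through
#' the means — the geometric mean of the y-on-x slope and the inverse of
#' the x-on-y slope.
#'
#' @param x,y numeric vectors, n >= 3, both with positive variance.
#' @param test label for the report.
#' @return a `"poe_test"` with fields `slope`, `intercept`, `r`; the
#'   reported P is the correlation test P (slope significance).
#' @export
sma_fit <- function(x, y, test = "SMA regression") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_data("SMA needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_data("SMA undefined with zero variance")
  }
  r <- stats::cor(x, y)
  slope <- sign(r) * stats::sd(y) / stats::sd(x)
  if (slope == 0) slope <- stats::sd(y) / stats::sd(x)  # r exactly 0: sign convention +
  intercept <- mean(y) - slope * mean(x)
  p <- stats::cor.test(x, y)$p.value
  poe_test(test, sprintf("n=%d", length(x)), "slope", slope, p,
           notes = sprintf("intercept %.4g, r %.4g", intercept, r),
           extra = list(slope = slope, intercept = intercept, r = r))
}

#' Chromosomal distribution of differentially expressed genes
#'
#' Counts DE genes per chromosome arm (X, 2L, 2R, 3L, 3R, 4, plus "Other"
#' for probes not mapped to the assembled reference genome). Percentages
#' use mapped genes only as the denominator. Each mapped arm gets a
#' two-category goodness-of-fit test of the DE set against the all-genes
#' mapped proportions; flags are Benjamini-Hochberg adjusted at 0.05.
#'
#' @param de_genes character vector of DE gene ids.
#' @param all_genes character vector of background gene ids.
#' @param annotation `"gene_catalog"` covering all genes.
#' @param correct continuity-correct the per-arm tests (default `FALSE`).
#' @return data.frame, one row per arm: `arm`, `n_all`, `pct_all`, `n_de`,
#'   `pct_de`, `chisq`, `p`, `q`, `flag`.
#' @export
chromosome_table <- function(de_genes, all_genes, annotation,
                             correct = FALSE) {
  arms <- c("X", "2L", "2R", "3L", "3R", "4", "Other")
  idx <- match(all_genes, annotation$gene_id)
  if (anyNA(idx)) stop_data("annotation missing for some genes")
  arm_all <- annotation$arm[idx]
  arm_de <- annotation$arm[match(de_genes, annotation$gene_id)]
  n_all <- vapply(arms, function(a) sum(arm_all == a), numeric(1))
  n_de <- vapply(arms, function(a) sum(arm_de == a, na.rm = TRUE), numeric(1))
  mapped <- arms != "Other"
  tot_all <- sum(n_all[mapped]); tot_de <- sum(n_de[mapped])
  pct_all <- ifelse(mapped, 100 * n_all / tot_all, NA_real_)
  pct_de <- if (tot_de > 0) ifelse(mapped, 100 * n_de / tot_de, NA_real_)
            else rep(NA_real_, length(arms))

  chisq <- p <- rep(NA_real_, length(arms))
  if (tot_de > 0) {
    for (i in which(mapped)) {
      pr <- n_all[i] / tot_all
      gof <- chisq_gof(c(n_de[i], tot_de - n_de[i]), c(pr, 1 - pr),
                       correct = correct)
      chisq[i] <- gof$chisq; p[i] <- gof$p_value
    }
  }
  q <- rep(NA_real_, length(arms))
  q[mapped] <- bh_fdr(p[mapped])
  data.frame(arm = arms, n_all = n_all, pct_all = pct_all, n_de = n_de,
             pct_de = pct_de, chisq = chisq, p = p, q = q,
             flag = !is.na(q) & q < 0.05,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Direction bias of a gene class among significant genes
#'
#' Among significant genes, reports how many class members fall on each
#' side of zero, the Fisher exact P for class-vs-rest by up-vs-down
#' ([contingency_test()]), and the within-class exact binomial P against
#' an even split.
#'
#' @param lfc per-gene log2 fold-changes.
#' @param significant logical, per-gene significance calls.
#' @param in_class logical, per-gene class membership.
#' @param test label for the report.
#' @return a `"poe_test"` (binomial P as `p_value`) with fields `n_class`,
#'   `n_down`, `n_up`, `fisher_p`; all-`NA` statistic when no significant
#'   class member exists.
#' @export
direction_bias <- function(lfc, significant, in_class,
                           test = "direction bias") {
  sig <- which(significant & !is.na(lfc))
  cls <- sig[in_class[sig]]
  oth <- sig[!in_class[sig]]
  if (length(cls) == 0) {
    return(poe_test(test, "n=0", "prop down", NA_real_, NA_real_,
                    notes = "no significant class members",
                    extra = list(n_class = 0L, n_down = NA_integer_,
                                 n_up = NA_integer_, fisher_p = NA_real_)))
  }
  n_down <- sum(lfc[cls] < 0); n_up <- sum(lfc[cls] > 0)
  fisher_p <- if (length(oth) > 0) {
    contingency_test(n_up, sum(lfc[oth] > 0),
                     n_down, sum(lfc[oth] < 0))$p_value
  } else NA_real_
  binom_p <- stats::binom.test(n_down, n_down + n_up, 0.5)$p.value
  poe_test(test, sprintf("%d down / %d significant class genes",
                         n_down, length(cls)),
           "prop down", n_down / length(cls), binom_p,
           notes = sprintf("Fisher class-vs-rest P = %.4g", fisher_p),
           extra = list(n_class = length(cls), n_down = n_down,
                        n_up = n_up, fisher_p = fisher_p))
}
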