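#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: for each gene expressed in all
#' samples, the ratio of the sample's count to the gene's geometric mean
#' across samples; the factor is the median of those ratios. If no gene is
#' expressed in every sample, genes non-zero in at least 90% of samples are
#' used as the pseudo-reference (with a warning); if none qualify, an error
#' is raised.
#'
#' @param counts A [count_matrix()] or a plain counts matrix.
#' @return Positive numeric vector, one factor per sample.
#' @export
#'
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' size_factors(m)  # proportional to 1 : 2
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  keep <- rowSums(m == 0) == 0
  if (!any(keep)) {
    keep <- rowMeans(m > 0) >= 0.9
    if (!any(keep)) {
      stopf(paste("no gene is expressed in all (or >=90%% of) samples;",
                  "size factors need a pseudo-reference gene set"))
    }
    warning("no gene expressed in all samples; using genes non-zero in >=90% of samples",
            call. = FALSE)
    log_gm <- rowMeans(log(pmax(m[keep, , drop = FALSE], 0.5)))
    ratios <- log(pmax(m[keep, , drop = FALSE], 0.5)) - log_gm
  } else {
    log_gm <- rowMeans(log(m[keep, , drop = FALSE]))
    ratios <- log(m[keep, , drop = FALSE]) - log_gm
  }
  sf <- exp(apply(ratios, 2, median))
  setNames(sf, colnames(m))
}

#' Method-of-moments dispersion estimates
#'
#' Pooled within-group estimator of the negative-binomial dispersion
#' alpha in `Var = mu + alpha mu^2`: per group, `(s^2 - mu) / mu^2` on
#' normalized counts, pooled across groups with degrees-of-freedom weights
#' and clamped below at `floor`. Degenerate (Poisson-like or flat) genes
#' get the floor.
#'
#' @param norm_counts Matrix of normalized counts (genes x samples).
#' @param groups Factor/character vector assigning samples to groups;
#'   every group needs >= 2 replicates.
#' @param floor Lower clamp for the estimate.
#' @return Numeric vector of per-gene dispersions.
#' @export
estimate_dispersion <- function(norm_counts, groups, floor = 1e-8) {
  groups <- as.character(groups)
  stopifnot(ncol(norm_counts) == length(groups))
  tab <- table(groups)
  if (any(tab < 2)) stopf("every group needs >= 2 replicates")
  num <- 0
  den <- 0
  for (g in names(tab)) {
    sub <- norm_counts[, groups == g, drop = FALSE]
    mu <- rowMeans(sub)
    s2 <- apply(sub, 1, var)
    a <- ifelse(mu > 0, (s2 - mu) / mu^2, 0)
    w <- tab[[g]] - 1
    num <- num + w * a
    den <- den + w
  }
  pmax(floor, num / den)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, `padj_(i) = min_{j >= i} (m / j) p_(j)` clipped
#' at 1, returned in input order. `NA` p-values are excluded from `m` and
#' stay `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @export
#'
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Negative-binomial Wald test for one cell line
#'
#' Tests stimulated vs unstimulated within one line. Counts are normalized
#' by median-of-ratios size factors (computed on that line's samples),
#' per-group per-gene dispersions come from [estimate_dispersion()], and
#' the Wald statistic is `log2FC / SE` with a delta-method standard error
#' `SE^2 = [(1/m_u + a_u)/n_u + (1/m_s + a_s)/n_s] / ln(2)^2` on the group
#' means (each group's NB variance `m + a m^2` reduces to its method-of-
#' moments sample variance, floored at the Poisson variance, so the test
#' never assumes a dispersion shared across conditions). When either group
#' mean is zero a
#' pseudo-mean of 0.5 normalized counts is added to both means. Genes with
#' zero total counts in both groups are reported with `NA` p and excluded
#' from the Benjamini-Hochberg `m`. Calls require
#' `|log2FC| >= lfc_min` and adjusted (or raw, see `use_adjusted`)
#' p below `alpha`.
#'
#' @param counts A [count_matrix()] containing the line in both conditions.
#' @param line Cell line to test.
#' @param lfc_min Minimum |log2 fold change| for a call (default 1, i.e.
#'   2-fold).
#' @param alpha Significance cutoff (default 0.01).
#' @param use_adjusted Apply `alpha` to BH-adjusted p-values (default) or
#'   to raw p-values.
#' @return List with `result` (a `de_result` data frame: gene, baseMean,
#'   log2FC, SE, stat, p, padj) and `calls` (a `de_calls` object with `up`
#'   and `down` gene sets and the thresholds used).
#' @export
de_test <- function(counts, line, lfc_min = 1, alpha = 0.01, use_adjusted = TRUE) {
  validate_count_matrix(counts)
  meta <- counts$meta
  sel <- meta$line == line
  if (!any(sel)) stopf("line '%s' not present", line)
  cond <- meta$condition[sel]
  if (!all(c("unstim", "stim") %in% cond)) {
    stopf("line '%s' lacks one of the conditions", line)
  }
  m <- counts$counts[, sel, drop = FALSE]
  sf <- size_factors(m)
  norm <- sweep(m, 2, sf, "/")

  u <- norm[, cond == "unstim", drop = FALSE]
  s <- norm[, cond == "stim", drop = FALSE]
  n_u <- ncol(u)
  n_s <- ncol(s)
  mu_u <- rowMeans(u)
  mu_s <- rowMeans(s)
  disp_u <- estimate_dispersion(u, rep("unstim", n_u))
  disp_s <- estimate_dispersion(s, rep("stim", n_s))
  untestable <- rowSums(m) == 0

  zero <- mu_u == 0 | mu_s == 0
  mu_u_adj <- ifelse(zero, mu_u + 0.5, mu_u)
  mu_s_adj <- ifelse(zero, mu_s + 0.5, mu_s)
  log2fc <- log2(mu_s_adj / mu_u_adj)
  se <- sqrt((1 / mu_u_adj + disp_u) / n_u +
             (1 / mu_s_adj + disp_s) / n_s) / log(2)
  stat <- log2fc / se
  p <- 2 * pnorm(-abs(stat))
  p[untestable] <- NA_real_
  padj <- bh_adjust(p)

  result <- data.frame(
    gene = rownames(m), baseMean = rowMeans(norm), log2FC = log2fc,
    SE = se, stat = stat, p = p, padj = padj,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(result) <- c("de_result", "data.frame")

  crit <- if (use_adjusted) padj else p
  sig <- !is.na(crit) & crit < alpha
  up <- result$gene[sig & log2fc >= lfc_min]
  down <- result$gene[sig & log2fc <= -lfc_min]
  calls <- structure(list(line = line, up = up, down = down,
                          lfc_min = lfc_min, alpha = alpha,
                          use_adjusted = use_adjusted),
                     class = "de_calls")
  list(result = result, calls = calls)
}

#' @export
print.de_calls <- function(x, ...) {
  cat(sprintf("de_calls [%s]: %d up, %d down (|log2FC| >= %.2g, %s p < %.2g)\n",
              x$line, length(x$up), length(x$down), x$lfc_min,
              if (x$use_adjusted) "adjusted" else "raw", x$alpha))
  invisible(x)
}

#' Run the per-line DE test for every cell line
#'
#' @inheritParams de_test
#' @param lines Lines to test; defaults to every line in the metadata.
#' @return Named list (per line) of [de_test()] outputs.
#' @export
de_all_lines <- function(counts, lines = unique(counts$meta$line),
                         lfc_min = 1, alpha = 0.01, use_adjusted = TRUE) {
  setNames(lapply(lines, function(ln) {
    de_test(counts, ln, lfc_min = lfc_min, alpha = alpha,
            use_adjusted = use_adjusted)
  }), lines)
}

#' Write a per-line DE table as TSV
#' @param de Output of [de_test()].
#' @param path Destination file.
#' @export
write_de_table <- function(de, path) {
  tab <- de$result
  tab$call <- "ns"
  tab$call[tab$gene %in% de$calls$up] <- "up"
  tab$call[tab$gene %in% de$calls$down] <- "down"
  write.table(format(tab, digits = 10, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
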