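#' Yates-corrected chi-squared test on a 2x2 table
#'
#' `chi2 = N (max(0, |ad - bc| - N/2))^2 / ((a+b)(c+d)(a+c)(b+d))`, with p
#' from the chi-squared distribution on 1 df. A table with any zero
#' marginal returns `NA` with a warning.
#'
#' @param t 2x2 non-negative integer matrix (or vector `c(a, b, c, d)` in
#'   row-major order).
#' @return List `statistic`, `p`, `df = 1`.
#' @export
#'
#' @examples
#' chi2_yates(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))  # 18.05
chi2_yates <- function(t) {
  if (!is.matrix(t)) t <- matrix(t, 2, 2, byrow = TRUE)
  if (any(t < 0)) stopf("contingency counts must be >= 0")
  a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
  n <- a + b + c + d
  if (n <= 0) stopf("empty contingency table")
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) {
    warning("zero marginal; chi-squared test undefined", call. = FALSE)
    return(list(statistic = NA_real_, p = NA_real_, df = 1L))
  }
  stat <- n * max(0, abs(a * d - b * c) - n / 2)^2 / prod(marg)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE), df = 1L)
}

rank_blocks <- function(m) {
  t(apply(m, 1, rank))  # mid-ranks for ties, within each block (row)
}

#' Friedman rank test over blocks x treatments
#'
#' Rows are blocks (e.g. promoter position bins), columns treatments
#' (e.g. cell lines). Values are ranked within blocks with mid-ranks for
#' ties; `Q = [12 / (n k (k+1))] sum R_j^2 - 3 n (k+1)`, divided by the
#' tie correction `C = 1 - sum(t^3 - t) / (n k (k^2 - 1))`. The p-value
#' comes from the chi-squared distribution on `k - 1` df, or from
#' exhaustive permutation of values within blocks when
#' `exact = TRUE` (feasible for `n * k <= 12`).
#'
#' @param m Numeric matrix, blocks x treatments.
#' @param exact Use the exact within-block permutation null.
#' @return List `Q`, `p`, `df`, `rank_means` (mean rank per treatment),
#'   `method`.
#' @export
friedman <- function(m, exact = FALSE) {
  m <- as.matrix(m)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) stopf("need >= 2 blocks and >= 2 treatments")
  Q <- friedman_Q(m)
  rank_means <- colMeans(rank_blocks(m))
  if (exact) {
    if (n * k > 12) stopf("exact permutation limited to n * k <= 12")
    perms <- permutations_of(k)
    qs <- permutation_Q_values(m, perms)
    p <- mean(qs >= Q - 1e-12)
    method <- "exact permutation"
  } else {
    p <- if (is.na(Q)) 1 else pchisq(Q, df = k - 1, lower.tail = FALSE)
    method <- "chi-squared approximation"
  }
  if (is.na(Q)) {  # all blocks fully tied
    Q <- 0
    p <- 1
  }
  list(Q = Q, p = p, df = k - 1L, rank_means = rank_means, method = method)
}

friedman_Q <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  r <- rank_blocks(m)
  Rj <- colSums(r)
  raw <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  ties <- apply(m, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  })
  C <- 1 - sum(ties) / (n * k * (k^2 - 1))
  if (C <= 0) return(NA_real_)  # every block completely tied
  raw / C
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

permutation_Q_values <- function(m, perms) {
  n <- nrow(m)
  n_perm <- nrow(perms)
  idx <- rep(1L, n)
  qs <- numeric(n_perm^n)
  cnt <- 0L
  repeat {
    mm <- m
    for (b in seq_len(n)) mm[b, ] <- m[b, perms[idx[b], ]]
    cnt <- cnt + 1L
    q <- friedman_Q(mm)
    qs[cnt] <- if (is.na(q)) 0 else q
    pos <- 1L
    repeat {
      idx[pos] <- idx[pos] + 1L
      if (idx[pos] <= n_perm) break
      idx[pos] <- 1L
      pos <- pos + 1L
      if (pos > n) return(qs)
    }
  }
}

#' Dunn's many-to-one post hoc on Friedman ranks
#'
#' Compares each treatment's mean rank to the reference treatment:
#' `z_j = (Rbar_j - Rbar_ref) / sqrt(k (k+1) / (6 n))`, two-sided normal
#' p-values, Bonferroni-adjusted over the `k - 1` many-to-one comparisons.
#'
#' @param m Blocks x treatments matrix (with column names).
#' @param reference Reference treatment (column name).
#' @return Data frame `treatment`, `z`, `p`, `p_adj`.
#' @export
dunn_posthoc <- function(m, reference) {
  m <- as.matrix(m)
  if (is.null(colnames(m))) colnames(m) <- sprintf("T%d", seq_len(ncol(m)))
  if (!reference %in% colnames(m)) stopf("reference '%s' not among treatments", reference)
  n <- nrow(m)
  k <- ncol(m)
  rbar <- colMeans(rank_blocks(m))
  se <- sqrt(k * (k + 1) / (6 * n))
  others <- setdiff(colnames(m), reference)
  z <- (rbar[others] - rbar[reference]) / se
  p <- 2 * pnorm(-abs(z))
  data.frame(treatment = others, z = unname(z), p = unname(p),
             p_adj = pmin(1, unname(p) * length(others)),
             stringsAsFactors = FALSE)
}

#' Many-to-one mean comparisons with max-|t| adjustment
#'
#' Dunnett-type comparisons of each group mean against a control, with
#' pooled-variance t statistics and a family-wise adjustment obtained by
#' Monte-Carlo sampling of the max-|t| null over the comparisons' joint
#' distribution (shared control mean, pooled variance estimate). A
#' Bonferroni fallback is available.
#'
#' @param groups Named list of numeric vectors (>= 2 observations each).
#' @param control Name of the control group.
#' @param adjust `"montecarlo"` (default) or `"bonferroni"`.
#' @param n_draws Monte-Carlo draws (default 1e5).
#' @param seed Seed for the Monte-Carlo null.
#' @return Data frame `group`, `diff`, `t`, `p_raw`, `p_adj`.
#' @export
many_to_one_means <- function(groups, control, adjust = c("montecarlo", "bonferroni"),
                              n_draws = 1e5, seed = 1) {
  adjust <- match.arg(adjust)
  if (!control %in% names(groups)) stopf("control group '%s' missing", control)
  if (length(groups) < 2) stopf("need at least one non-control group")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stopf("every group needs >= 2 observations")
  means <- vapply(groups, mean, 0)
  df <- sum(sizes) - length(groups)
  s2 <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) / df
  others <- setdiff(names(groups), control)
  n0 <- sizes[[control]]
  tt <- vapply(others, function(g) {
    (means[[g]] - means[[control]]) / sqrt(s2 * (1 / sizes[[g]] + 1 / n0))
  }, 0)
  p_raw <- 2 * pt(-abs(tt), df = df)

  if (adjust == "bonferroni") {
    p_adj <- pmin(1, p_raw * length(others))
  } else {
    set.seed(derive_seed(seed, 9L))
    z0 <- rnorm(n_draws, sd = 1 / sqrt(n0))
    chi <- rchisq(n_draws, df = df) / df
    tmax <- rep(0, n_draws)
    for (g in others) {
      zg <- rnorm(n_draws, sd = 1 / sqrt(sizes[[g]]))
      tg <- abs(zg - z0) / sqrt(chi * (1 / sizes[[g]] + 1 / n0))
      tmax <- pmax(tmax, tg)
    }
    p_adj <- vapply(abs(tt), function(x) mean(tmax >= x), 0)
  }
  data.frame(group = others, diff = unname(means[others] - means[[control]]),
             t = unname(tt), p_raw = unname(p_raw), p_adj = unname(p_adj),
             stringsAsFactors = FALSE)
}

#' Error-weighted pathway activation Z-score
#'
#' Genes are first filtered by `|log2FC| >= lfc_min` and `p < alpha`
#' (adjusted p by default). With weights `1/SE^2`, the score of a pathway
#' is the difference between the weighted mean log2 fold change of its
#' selected members and the weighted mean over all selected genes. A
#' standardized variant divides by the standard error of that difference,
#' `sqrt(1/W_pathway + 1/W_all)` with `W` the summed weights. Pathways
#' with no selected member score `NA`.
#'
#' @param de A `de_result` (or [de_test()] output).
#' @param sets Named list of pathway gene-ID vectors.
#' @param lfc_min,alpha Gene-selection cut-offs (defaults: 1 log2 unit,
#'   p < 0.001).
#' @param use_adjusted Select on BH-adjusted p (default) or raw p.
#' @return Data frame `pathway`, `n_selected`, `Z`, `Z_standardized`.
#' @export
pathway_zscore <- function(de, sets, lfc_min = 1, alpha = 0.001,
                           use_adjusted = TRUE) {
  res <- if (is.data.frame(de)) de else de$result
  crit <- if (use_adjusted) res$padj else res$p
  sel <- !is.na(crit) & crit < alpha & abs(res$log2FC) >= lfc_min
  res <- res[sel, , drop = FALSE]
  if (!nrow(res)) {
    return(data.frame(pathway = names(sets), n_selected = 0L,
                      Z = NA_real_, Z_standardized = NA_real_))
  }
  w <- 1 / res$SE^2
  global_mean <- sum(w * res$log2FC) / sum(w)
  rows <- lapply(names(sets), function(nm) {
    idx <- res$gene %in% sets[[nm]]
    if (!any(idx)) {
      return(data.frame(pathway = nm, n_selected = 0L, Z = NA_real_,
                        Z_standardized = NA_real_))
    }
    wp <- w[idx]
    zm <- sum(wp * res$log2FC[idx]) / sum(wp)
    z <- zm - global_mean
    se_diff <- sqrt(1 / sum(wp) + 1 / sum(w))
    data.frame(pathway = nm, n_selected = sum(idx), Z = z,
               Z_standardized = z / se_diff)
  })
  do.call(rbind, rows)
}

#' PCA of samples with per-group outlier flagging
#'
#' Normalizes counts by median-of-ratios size factors, transforms with
#' `log2(x + 1)`, centers genes and projects samples onto the top two
#' principal components. Within each (line, condition) group, a sample is
#' flagged as an outlier when its PC1/PC2 distance to the group centroid
#' exceeds `median + mad_k * MAD` of the group's distances.
#'
#' @param counts A [count_matrix()].
#' @param mad_k MAD multiplier of the outlier rule.
#' @return A `pca_result`: data frame `sample`, `line`, `condition`,
#'   `PC1`, `PC2`, `outlier`; attribute `percent_var` holds the percent
#'   variance per component.
#' @export
pca_with_outliers <- function(counts, mad_k = 3) {
  validate_count_matrix(counts)
  if (ncol(counts$counts) < 3) stopf("PCA needs at least 3 samples")
  sf <- size_factors(counts)
  x <- log2(sweep(counts$counts, 2, sf, "/") + 1)
  x <- x - rowMeans(x)
  pc <- prcomp(t(x), center = FALSE)
  pv <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  coords <- data.frame(
    sample = counts$meta$sample, line = counts$meta$line,
    condition = counts$meta$condition,
    PC1 = pc$x[, 1], PC2 = pc$x[, 2], stringsAsFactors = FALSE
  )
  coords$outlier <- FALSE
  for (grp in split(seq_len(nrow(coords)),
                    paste(coords$line, coords$condition))) {
    cx <- coords$PC1[grp]
    cy <- coords$PC2[grp]
    d <- sqrt((cx - median(cx))^2 + (cy - median(cy))^2)
    cut <- median(d) + mad_k * mad(d, constant = 1.4826)
    coords$outlier[grp] <- d > cut & d > 0
  }
  structure(coords, percent_var = pv, class = c("pca_result", "data.frame"))
}
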