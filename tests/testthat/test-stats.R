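test_that("Yates chi-squared matches hand evaluation and stats::chisq.test", {
  null_tab <- matrix(c(10, 10, 10, 10), 2)
  res <- chi2_yates(null_tab)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  # hand evaluation: N=80, |ad-bc|-N/2 = 760, stat = 80*760^2/40^4 = 18.05
  res2 <- chi2_yates(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
  expect_equal(res2$statistic, 18.05, tolerance = 1e-10)
  # agreement with the standard implementation across random tables
  set.seed(8)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    ours <- chi2_yates(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    # continuity correction never exceeds the uncorrected statistic
    ref_raw <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_lte(ours$statistic, unname(ref_raw$statistic) + 1e-12)
  }
  # doubling every cell strictly increases a non-null statistic
  expect_gt(chi2_yates(2 * matrix(c(30, 10, 10, 30), 2))$statistic,
            res2$statistic)
  expect_warning(out <- chi2_yates(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
                 "marginal")
  expect_true(is.na(out$statistic))
})

test_that("Friedman statistic matches worked values, ties, and friedman.test", {
  m <- rbind(c(1, 2, 3), c(1, 2, 3))  # both blocks ordered: Q = 4
  fr <- friedman(m)
  expect_equal(fr$Q, 4)
  expect_equal(fr$df, 2)
  # all ties: Q = 0, p = 1
  flat <- matrix(5, 3, 3)
  fr0 <- friedman(flat)
  expect_equal(fr0$Q, 0)
  expect_equal(fr0$p, 1)
  # rank-based: invariant to strictly monotone transforms
  set.seed(2)
  x <- matrix(runif(15), 5, 3)
  expect_equal(friedman(x)$Q, friedman(exp(3 * x))$Q)
  # agreement with stats::friedman.test on untied data
  ref <- stats::friedman.test(x)
  expect_equal(friedman(x)$Q, unname(ref$statistic))
  expect_equal(friedman(x)$p, ref$p.value)
})

test_that("exact permutation p agrees with the chi-squared approximation", {
  m <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  approx <- friedman(m, exact = FALSE)
  exact <- friedman(m, exact = TRUE)
  expect_equal(exact$Q, approx$Q)
  expect_lt(abs(exact$p - approx$p), 0.05)
  # exact p for three perfectly aligned blocks of k = 3 is the probability
  # that all blocks share one ordering: 6 / 6^3
  expect_equal(exact$p, 6 / 216)
  # on a weaker-signal instance the permutation p is still a valid
  # probability and matches its observed-or-more-extreme definition
  m2 <- rbind(c(1.0, 2.0, 3.0), c(2.0, 3.0, 1.0), c(1.0, 3.0, 2.0))
  ex2 <- friedman(m2, exact = TRUE)
  expect_gt(ex2$p, 0)
  expect_lte(ex2$p, 1)
  expect_equal(ex2$p, 78 / 216)  # frozen from the full 6^3 enumeration
  expect_error(friedman(matrix(1:20, 4, 5), exact = TRUE), "12")
})

test_that("Dunn post hoc z-scores follow the rank-mean formula", {
  m <- rbind(c(10, 20, 30), c(10, 30, 20), c(20, 10, 30), c(30, 20, 10))
  colnames(m) <- c("ref", "t2", "t3")
  dn <- dunn_posthoc(m, "ref")
  # hand evaluation: Rbar = (1.75, 2, 2.25), se = sqrt(3*4/(6*4))
  se <- sqrt(12 / 24)
  expect_equal(dn$z[dn$treatment == "t2"], 0.25 / se)
  expect_equal(dn$z[dn$treatment == "t3"], 0.50 / se)
  expect_equal(dn$p_adj, pmin(1, dn$p * 2))
  # treatment identical to reference: z = 0, adjusted p = 1
  m2 <- cbind(ref = c(1, 2, 3), same = c(1, 2, 3), other = c(3, 1, 2))
  dn2 <- dunn_posthoc(m2, "ref")
  expect_equal(dn2$z[dn2$treatment == "same"], 0)
  expect_equal(dn2$p_adj[dn2$treatment == "same"], 1)
  # swapping two non-reference treatments swaps their p-values
  m3 <- m
  colnames(m3) <- c("ref", "t3", "t2")
  dn3 <- dunn_posthoc(m3, "ref")
  expect_equal(dn3$p[dn3$treatment == "t2"], dn$p[dn$treatment == "t3"])
  expect_error(dunn_posthoc(m, "zz"), "reference")
})

test_that("many-to-one comparisons: null behavior, k = 2 case, multcomp agreement", {
  set.seed(10)
  groups <- list(ctrl = rnorm(8), a = rnorm(8), b = rnorm(8), c = rnorm(8))
  res <- many_to_one_means(groups, "ctrl", n_draws = 2e4, seed = 1)
  expect_true(all(res$p_adj >= res$p_raw - 0.02))
  # groups literally identical to the control: adjusted p of 1
  same <- list(ctrl = c(1, 2, 3, 4), a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  rs <- many_to_one_means(same, "ctrl", n_draws = 1e4, seed = 4)
  expect_true(all(rs$p_adj >= 0.9))
  # k = 2: adjustment is a no-op up to Monte-Carlo error
  two <- list(ctrl = rnorm(10), a = rnorm(10, 1))
  r2 <- many_to_one_means(two, "ctrl", n_draws = 5e4, seed = 2)
  tt <- stats::t.test(two$a, two$ctrl, var.equal = TRUE)
  expect_equal(r2$p_raw, tt$p.value, tolerance = 1e-9)
  expect_lt(abs(r2$p_adj - r2$p_raw), 0.02)
  # Bonferroni fallback
  rb <- many_to_one_means(groups, "ctrl", adjust = "bonferroni")
  expect_equal(rb$p_adj, pmin(1, rb$p_raw * 3))
  expect_error(many_to_one_means(list(a = 1:3), "a"), "non-control")
  # cross-check against multcomp's Dunnett contrasts
  set.seed(11)
  dat <- data.frame(
    y = c(rnorm(6), rnorm(6, 1), rnorm(6, 0.3)),
    g = factor(rep(c("ctrl", "a", "b"), each = 6), levels = c("ctrl", "a", "b"))
  )
  ours <- many_to_one_means(split(dat$y, dat$g), "ctrl", n_draws = 1e5, seed = 3)
  fit <- multcomp::glht(stats::aov(y ~ g, dat), linfct = multcomp::mcp(g = "Dunnett"))
  ref <- summary(fit)$test$pvalues
  expect_equal(ours$p_adj[match(c("a", "b"), ours$group)], as.numeric(ref),
               tolerance = 0.02)
})

test_that("pathway Z is a difference of error-weighted means", {
  de <- data.frame(
    gene = sprintf("g%02d", 1:10), baseMean = 1,
    log2FC = c(3, 3, 3, 1, 1, 1, 1, -2, -2, 1),
    SE = rep(0.5, 10), stat = 10, p = 1e-6, padj = 1e-5
  )
  # pathway equal to the whole selected set scores zero
  z_all <- pathway_zscore(de, list(all = de$gene), alpha = 0.01)
  expect_equal(z_all$Z, 0)
  # equal weights: pathway mean 3, global mean 1 -> Z = 2
  expect_equal(mean(de$log2FC), 1)
  z <- pathway_zscore(de, list(top = c("g01", "g02", "g03")), alpha = 0.01)
  expect_equal(z$Z, 2)
  # no selected member: NA
  z_na <- pathway_zscore(de, list(none = "zz"), alpha = 0.01)
  expect_true(is.na(z_na$Z))
  expect_equal(z_na$n_selected, 0)
  # invariant to adding a constant to every log2FC
  de2 <- de
  de2$log2FC <- de$log2FC + 5
  z2 <- pathway_zscore(de2, list(top = c("g01", "g02", "g03")), alpha = 0.01)
  expect_equal(z2$Z, z$Z)
  # unequal weights follow the 1/SE^2 formula
  de3 <- de
  de3$SE <- seq(0.1, 1, length.out = 10)
  w <- 1 / de3$SE^2
  idx <- 1:3
  expected <- sum(w[idx] * de3$log2FC[idx]) / sum(w[idx]) -
    sum(w * de3$log2FC) / sum(w)
  z3 <- pathway_zscore(de3, list(top = c("g01", "g02", "g03")), alpha = 0.01)
  expect_equal(z3$Z, expected)
})

test_that("the interferon program tops the pathway ranking in every GOF line", {
  an <- default_analysis(1)
  pr <- simulate_promoters(an$cfg, an$sim$truth)
  ann <- simulate_annotations(an$cfg, pr$truth)
  for (ln in an$cfg$gof_lines) {
    z <- pathway_zscore(an$de[[ln]], ann$pathways)
    ok <- !is.na(z$Z_standardized)
    expect_equal(z$pathway[ok][which.max(z$Z_standardized[ok])],
                 "interferon_signaling", label = ln)
    # the raw score is positive: the program sits above the selected-gene mean
    expect_gt(z$Z[z$pathway == "interferon_signaling"], 0)
  }
})

test_that("PCA flags constructed outliers and orders variance", {
  sim <- simulate_counts(small_config(n_genes = 400, seed = 41))
  pca <- pca_with_outliers(sim$counts)
  pv <- attr(pca, "percent_var")
  expect_true(all(diff(pv) <= 1e-8))
  expect_lte(sum(pv), 100 + 1e-6)
  # exact duplicate columns: identical coordinates, no outliers
  counts <- sim$counts$counts
  meta <- sim$counts$meta
  idx <- which(meta$line == "WT" & meta$condition == "stim")
  counts_dup <- counts
  for (j in idx[-1]) counts_dup[, j] <- counts_dup[, idx[1]]
  pca_dup <- pca_with_outliers(count_matrix(counts_dup, meta))
  expect_false(any(pca_dup$outlier[idx]))
  expect_equal(pca_dup$PC1[idx], rep(pca_dup$PC1[idx[1]], length(idx)))
  # a replicate with half its genes shifted 8-fold stands out from its group
  counts_out <- counts
  shift_genes <- seq_len(200)
  counts_out[shift_genes, idx[2]] <- as.integer(counts_out[shift_genes, idx[2]] * 8)
  pca_out <- pca_with_outliers(count_matrix(counts_out, meta))
  expect_true(pca_out$outlier[idx[2]])
  expect_error(pca_with_outliers(count_matrix(counts[, 1:2], meta[1:2, ])),
               "3 samples")
})
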