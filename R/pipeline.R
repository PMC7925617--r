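#' Run configuration for the end-to-end pipeline
#'
#' Bundles the simulation block and every analysis threshold into one
#' validated object; [run_all()] echoes it verbatim into the output
#' directory.
#'
#' @param simulate A [sim_config()] describing the synthetic inputs, or
#'   `NULL` when `inputs` provides file paths.
#' @param inputs Optional named list of input file paths (`counts`,
#'   `meta`, `promoters`, `peaks`, `irg`, `pathways`) produced by
#'   [simulate_to_dir()] or supplied by the user.
#' @param lfc_min,alpha_de DE call thresholds (2-fold, adjusted p < 0.01
#'   by default).
#' @param pwm_pvals PWM stringencies scanned (default 1e-3, 1e-4, 1e-5).
#' @param pfm Path to a JASPAR-format PFM; defaults to the synthetic GAS
#'   matrix shipped with the package.
#' @param profile_window,profile_step Occurrence-profile parameters (bp).
#' @param pathway_alpha Gene-selection p cut-off for pathway Z-scores.
#' @param n_control Size of the random control promoter set.
#' @param seed Master seed for every stochastic stage.
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = sim_config(), inputs = NULL,
                       lfc_min = 1, alpha_de = 0.01,
                       pwm_pvals = c(1e-3, 1e-4, 1e-5),
                       pfm = NULL,
                       profile_window = 25, profile_step = 5,
                       pathway_alpha = 0.001,
                       n_control = 100,
                       seed = if (!is.null(simulate)) simulate$seed else 1) {
  if (is.null(simulate) && is.null(inputs)) {
    stopf("run_config needs a simulate block or input paths")
  }
  if (!is.null(inputs)) {
    need <- c("counts", "meta", "promoters", "peaks", "irg", "pathways")
    missing <- setdiff(need, names(inputs))
    if (length(missing)) stopf("inputs missing: %s", paste(missing, collapse = ", "))
    for (f in unlist(inputs[need])) if (!file.exists(f)) stopf("input not found: %s", f)
  }
  if (is.null(pfm)) {
    pfm <- system.file("extdata", "gas_stat1_synthetic.jaspar", package = "stat1gof")
  }
  if (any(pwm_pvals <= 0 | pwm_pvals >= 1)) stopf("pwm_pvals must lie in (0, 1)")
  if (lfc_min < 0 || alpha_de <= 0 || alpha_de >= 1) stopf("invalid DE thresholds")
  structure(list(simulate = simulate, inputs = inputs, lfc_min = lfc_min,
                 alpha_de = alpha_de, pwm_pvals = sort(pwm_pvals, decreasing = TRUE),
                 pfm = pfm, profile_window = profile_window,
                 profile_step = profile_step, pathway_alpha = pathway_alpha,
                 n_control = n_control, seed = as.integer(seed)),
            class = "run_config")
}

# Deterministic polynomial hash of the config echo, stamped on outputs so
# that tables from different configurations are never confused.
config_hash <- function(config) {
  txt <- yaml::as.yaml(rapply(unclass(config), unclass, how = "replace"))
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full transcriptomic-fingerprint pipeline
#'
#' Orchestrates simulate (or load) -> per-line differential expression ->
#' cross-line partitioning and fold summaries -> IRG classification ->
#' promoter GAS scanning, occurrence profiles and Friedman/Dunn contrasts
#' at every stringency -> GAS-presence and ChIP-peak contingency with
#' Yates-corrected chi-squared tests -> pathway Z-scores -> PCA with
#' outlier flags. All tables are written as TSV into `outdir` together
#' with a machine-readable `summary.json` carrying every statistic, the
#' seed and a config hash; re-running with the same config and seed
#' reproduces every file byte for byte.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if missing).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, the summary list (also serialized to
#'   `summary.json`).
#' @export
run_all <- function(config, outdir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  tryCatch(
    run_all_impl(config, outdir, say),
    error = function(e) {
      stopf("pipeline failed at stage [%s]: %s",
            attr(e, "stage") %||% "unknown", conditionMessage(e))
    }
  )
}

with_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    attr(e, "stage") <- name
    stop(e)
  })
}

run_all_impl <- function(config, outdir, say) {
  summary <- list(seed = config$seed, config_hash = config_hash(config),
                  version = as.character(packageVersion("stat1gof")))

  # -- inputs -----------------------------------------------------------
  inp <- with_stage("inputs", {
    if (!is.null(config$inputs)) {
      say("loading inputs from files")
      list(
        counts = read_counts(config$inputs$counts, config$inputs$meta),
        promoters = read_promoters(config$inputs$promoters),
        peaks = read_peaks(config$inputs$peaks),
        irg = read_irg(config$inputs$irg),
        pathways = read_pathways(config$inputs$pathways),
        truth = NULL, sim_cfg = NULL
      )
    } else {
      scfg <- config$simulate
      say("simulating study design (%d genes, seed %d)", scfg$n_genes, scfg$seed)
      sim <- simulate_counts(scfg)
      pr <- simulate_promoters(scfg, sim$truth)
      pk <- simulate_peaks(scfg, pr$truth)
      ann <- simulate_annotations(scfg, pk$truth)
      list(counts = sim$counts, promoters = pr$promoters, peaks = pk$peaks,
           irg = ann$irg, pathways = ann$pathways, truth = pk$truth,
           sim_cfg = scfg)
    }
  })
  yaml::write_yaml(rapply(unclass(config), unclass, how = "replace"),
                   file.path(outdir, "run_config.yaml"))

  meta <- inp$counts$meta
  lines <- unique(meta$line)
  wt <- if (!is.null(inp$sim_cfg)) inp$sim_cfg$wt_line else "WT"
  gof <- if (!is.null(inp$sim_cfg)) inp$sim_cfg$gof_lines else
    setdiff(lines, c(wt, "NT"))
  testable <- lines[vapply(lines, function(ln) {
    all(c("unstim", "stim") %in% meta$condition[meta$line == ln])
  }, logical(1))]

  # -- differential expression -----------------------------------------
  de <- with_stage("diffexpr", {
    say("differential expression: %d lines", length(testable))
    de_all_lines(inp$counts, testable, lfc_min = config$lfc_min,
                 alpha = config$alpha_de)
  })
  for (ln in names(de)) {
    write_de_table(de[[ln]], file.path(outdir, sprintf("de_%s.tsv", ln)))
  }
  summary$de <- lapply(de, function(d) {
    list(n_tested = sum(!is.na(d$result$p)),
         n_up = length(d$calls$up), n_down = length(d$calls$down))
  })

  # -- partition + folds + IRG -----------------------------------------
  part_lines <- intersect(c(wt, gof), names(de))
  part <- with_stage("partition", {
    say("partitioning calls over %s", paste(part_lines, collapse = ", "))
    partition_genes(lapply(de[part_lines], `[[`, "calls"), wt,
                    intersect(gof, part_lines))
  })
  write_partition_tables(part, outdir)
  summary$partition <- as.list(part$counts)

  folds <- with_stage("fold_summary", {
    out <- list()
    for (cls in c("common_up", "gof_shared_up")) {
      members <- part$members[[cls]]
      if (is.null(members) || !length(members)) next
      use_lines <- if (cls == "gof_shared_up") intersect(gof, names(de)) else part_lines
      fs <- average_fold_increase(de[use_lines], members)
      write.table(
        data.frame(gene = rownames(fs$fold_table),
                   round(fs$fold_table, 6), check.names = FALSE),
        file.path(outdir, sprintf("fold_%s.tsv", cls)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      out[[cls]] <- round(fs$mean_fold, 6)
    }
    out
  })
  summary$mean_fold <- lapply(folds, as.list)

  irg_stats <- with_stage("irg", {
    rows <- lapply(part_lines, function(ln) {
      up <- classify_irg(de[[ln]]$calls$up, inp$irg)
      dn <- classify_irg(de[[ln]]$calls$down, inp$irg)
      data.frame(line = ln,
                 up_total = length(de[[ln]]$calls$up),
                 up_non_irg = up$n_non_irg,
                 up_percent_non_irg = round(up$percent_non_irg %||% NA_real_, 1),
                 down_total = length(de[[ln]]$calls$down),
                 down_non_irg = dn$n_non_irg,
                 down_percent_non_irg = round(dn$percent_non_irg %||% NA_real_, 1))
    })
    do.call(rbind, rows)
  })
  write.table(irg_stats, file.path(outdir, "irg_fractions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summary$irg <- split(irg_stats[, -1], irg_stats$line)

  # -- promoter scanning ------------------------------------------------
  scan_res <- with_stage("motif_scan", {
    say("PWM scanning at %s", paste(format(config$pwm_pvals), collapse = ", "))
    pwm <- pfm_to_pwm(read_jaspar(config$pfm))
    sets <- list(WT_up = de[[wt]]$calls$up)
    for (ln in intersect(gof, names(de))) {
      sets[[paste0(ln, "_excl")]] <- setdiff(de[[ln]]$calls$up, de[[wt]]$calls$up)
    }
    set.seed(derive_seed(config$seed, 5L))
    all_genes <- names(inp$promoters$seq)
    sets$control <- sort(sample(all_genes, min(config$n_control, length(all_genes))))
    scan_gene_sets(inp$promoters, pwm, sets, config)
  })
  write.table(scan_res$profiles, file.path(outdir, "occurrence_profiles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(scan_res$gas_counts, file.path(outdir, "gas_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(scan_res$thresholds, file.path(outdir, "pwm_thresholds.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary$gas <- scan_res$summary

  # -- Friedman / Dunn across profile curves ---------------------------
  fried <- with_stage("friedman", {
    rows <- list()
    for (pv in unique(scan_res$profiles$p_value)) {
      sub <- scan_res$profiles[scan_res$profiles$p_value == pv, ]
      mat <- do.call(cbind, lapply(split(sub$percent, sub$set), identity))
      if (is.null(dim(mat)) || ncol(mat) < 2) next
      fr <- friedman(mat)
      dn <- dunn_posthoc(mat, "WT_up")
      rows[[length(rows) + 1L]] <- data.frame(
        p_value = pv, Q = fr$Q, p = fr$p, df = fr$df,
        dunn = paste(sprintf("%s:%.3g", dn$treatment, dn$p_adj), collapse = ";"))
    }
    do.call(rbind, rows)
  })
  if (!is.null(fried)) {
    write.table(fried, file.path(outdir, "profile_friedman.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary$friedman <- lapply(seq_len(nrow(fried)), function(i) as.list(fried[i, ]))
  }

  # -- ChIP peak contingency -------------------------------------------
  chip <- with_stage("peaks", {
    say("ChIP peak / promoter contingency")
    windows <- promoter_windows(inp$promoters$layout,
                                up = inp$promoters$upstream,
                                down = inp$promoters$downstream)
    gene_sets <- c(setNames(list(de[[wt]]$calls$up), wt),
                   lapply(de[intersect(gof, names(de))], function(d) d$calls$up))
    peak_contingency(gene_sets, windows, inp$peaks, wt = wt)
  })
  chip_tab <- do.call(rbind, lapply(names(chip), function(cond) {
    e <- chip[[cond]]
    data.frame(condition = cond, n_with = e$n_with, n_without = e$n_without,
               ratio = round(e$ratio, 4),
               chi2 = if (!is.null(e$test)) round(e$test$statistic, 4) else NA,
               p = if (!is.null(e$test)) signif(e$test$p, 4) else NA)
  }))
  write.table(chip_tab, file.path(outdir, "peak_contingency.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summary$chip <- lapply(split(chip_tab[, -1], chip_tab$condition), as.list)

  # -- pathway Z-scores -------------------------------------------------
  pz <- with_stage("pathways", {
    rows <- lapply(part_lines, function(ln) {
      z <- pathway_zscore(de[[ln]], inp$pathways, lfc_min = config$lfc_min,
                          alpha = config$pathway_alpha)
      cbind(line = ln, z)
    })
    do.call(rbind, rows)
  })
  pz$Z <- round(pz$Z, 6)
  pz$Z_standardized <- round(pz$Z_standardized, 6)
  write.table(pz, file.path(outdir, "pathway_zscores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summary$pathways <- lapply(split(pz[, -1], pz$line), function(d) {
    setNames(as.list(d$Z), d$pathway)
  })

  # -- PCA --------------------------------------------------------------
  pca <- with_stage("pca", pca_with_outliers(inp$counts))
  pca_out <- data.frame(pca)
  pca_out$PC1 <- round(pca_out$PC1, 6)
  pca_out$PC2 <- round(pca_out$PC2, 6)
  write.table(pca_out, file.path(outdir, "pca.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  summary$pca <- list(
    percent_var = round(attr(pca, "percent_var")[1:2], 4),
    outliers = pca$sample[pca$outlier]
  )

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: %s", outdir)
  invisible(summary)
}

scan_gene_sets <- function(promoters, pwm, sets, config) {
  thresholds <- lapply(config$pwm_pvals, function(p) score_threshold(pwm, p))
  thr_tab <- do.call(rbind, lapply(thresholds, function(t) {
    data.frame(p_value = t$p, threshold_bits = round(t$threshold, 4),
               attained_p = signif(t$attained_p, 6))
  }))
  profiles <- list()
  counts <- list()
  summ <- list()
  for (nm in names(sets)) {
    genes <- intersect(sets[[nm]], names(promoters$seq))
    if (!length(genes)) next
    sub <- structure(list(seq = promoters$seq[genes],
                          upstream = promoters$upstream,
                          downstream = promoters$downstream,
                          layout = promoters$layout[match(genes, promoters$layout$gene), ]),
                     class = "promoter_set")
    for (i in seq_along(thresholds)) {
      hits <- scan_promoters(sub, pwm, thresholds[[i]])
      prof <- occurrence_profile(hits, sub, window = config$profile_window,
                                 step = config$profile_step)
      profiles[[length(profiles) + 1L]] <- data.frame(
        set = nm, p_value = config$pwm_pvals[i],
        position = prof$position, percent = round(prof$percent, 6))
      cnt <- count_promoters_with_hit(hits, sub)
      counts[[length(counts) + 1L]] <- data.frame(
        set = nm, p_value = config$pwm_pvals[i],
        n_with = cnt$n_with, n_without = cnt$n_without)
      summ[[nm]][[format(config$pwm_pvals[i])]] <-
        list(n_with = cnt$n_with, n_without = cnt$n_without)
    }
  }
  gas_counts <- do.call(rbind, counts)
  # Yates tests vs the WT set at the strictest stringency
  strict <- min(config$pwm_pvals)
  wt_row <- gas_counts[gas_counts$set == "WT_up" & gas_counts$p_value == strict, ]
  if (nrow(wt_row) == 1) {
    for (nm in setdiff(unique(gas_counts$set), "WT_up")) {
      row <- gas_counts[gas_counts$set == nm & gas_counts$p_value == strict, ]
      if (!nrow(row)) next
      tst <- chi2_yates(rbind(c(row$n_with, row$n_without),
                              c(wt_row$n_with, wt_row$n_without)))
      summ[[nm]]$chi2_vs_wt <- list(statistic = tst$statistic, p = tst$p)
    }
  }
  list(profiles = do.call(rbind, profiles), gas_counts = gas_counts,
       thresholds = thr_tab, summary = summ)
}

write_partition_tables <- function(part, outdir) {
  members <- data.frame(
    gene = c(names(part$up), names(part$down)),
    label = c(unname(part$up), unname(part$down)),
    direction = c(rep("up", length(part$up)), rep("down", length(part$down))),
    stringsAsFactors = FALSE
  )
  write.table(members, file.path(outdir, "partition_members.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  counts <- data.frame(label = names(part$counts), n = as.integer(part$counts))
  write.table(counts, file.path(outdir, "partition_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
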