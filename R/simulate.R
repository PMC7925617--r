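#' Simulate a count matrix with planted expression programs
#'
#' Draws negative-binomial counts for every line x condition x replicate of
#' the configured design and records the planted truth. Baseline per-gene
#' means are log-uniform on `nb_mean_range`; a gene's mean in a sample is
#' `mu * baseline_shift(line) * fold(line)^[stimulated]`. Per-gene planted
#' folds are the class mean times a `Uniform(1 - fold_jitter, 1 + fold_jitter)`
#' jitter (shared across lines for a given gene), so empirical class means
#' match the configured effect sizes. The non-transduced line carries no
#' program: its true fold change is 1 for every gene, emulating a line that
#' cannot respond to IFN-gamma. Common-program folds in GOF lines are the
#' WT fold times the per-line `gof_amplification`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `counts` (a [count_matrix()]) and `truth`
#'   (a `ground_truth` object: per-gene class labels, per-line true fold
#'   changes and baseline shifts, and the synthetic genome layout).
#' @export
#'
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 600, seed = 7))
#' table(sub(":.*", "", sim$truth$class))
simulate_counts <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_genes
  lines <- config$cell_lines
  genes <- sprintf("G%05d", seq_len(n))
  jit <- function(k) runif(k, 1 - config$fold_jitter, 1 + config$fold_jitter)
  # per-gene planted fold: class mean times multiplicative jitter; an effect
  # size of exactly 1 means "not responsive" and plants fold 1, so a
  # configuration with all effects 1 is a true null
  jfold <- function(es, k) if (es == 1) rep(1, k) else es * jit(k)

  cls <- setNames(rep("null", n), genes)
  fold <- matrix(1, n, length(lines), dimnames = list(genes, lines))
  baseline <- matrix(1, n, length(lines), dimnames = list(genes, lines))
  ps <- config$program_sizes
  es <- config$effect_sizes
  wt <- config$wt_line
  gof <- config$gof_lines
  cursor <- 0L
  take <- function(k) {
    if (k == 0) return(character(0))
    idx <- genes[cursor + seq_len(k)]
    cursor <<- cursor + as.integer(k)
    idx
  }

  g <- take(ps$common_up)
  cls[g] <- "common_up"
  f <- jfold(es$common, length(g))
  fold[g, wt] <- f
  for (ln in gof) fold[g, ln] <- f * config$gof_amplification[[ln]]

  g <- take(ps$gof_shared_up)
  cls[g] <- "gof_shared_up"
  f <- jfold(es$gof_shared, length(g))
  for (ln in gof) fold[g, ln] <- f

  g <- take(ps$wt_only_up)
  cls[g] <- "wt_only_up"
  fold[g, wt] <- jfold(es$wt_only, length(g))

  for (ln in names(ps$private_up)) {
    g <- take(ps$private_up[[ln]])
    cls[g] <- paste0("private_up:", ln)
    fold[g, ln] <- jfold(es$private, length(g))
  }

  g <- take(ps$mixed_up)
  cls[g] <- "mixed_up"
  for (gi in g) {
    subset <- sample_mixed_subset(wt, gof)
    fold[gi, subset] <- jfold(es$mixed, 1)
  }

  for (ln in names(ps$down)) {
    g <- take(ps$down[[ln]])
    cls[g] <- paste0("down:", ln)
    fold[g, ln] <- jfold(es$down, length(g))
  }

  for (ln in names(ps$baseline_up)) {
    g <- take(ps$baseline_up[[ln]])
    cls[g] <- paste0("baseline_shift:", ln)
    baseline[g, ln] <- jfold(es$baseline_up[[ln]], length(g))
  }
  for (ln in names(ps$baseline_down)) {
    g <- take(ps$baseline_down[[ln]])
    cls[g] <- paste0("baseline_shift:", ln)
    baseline[g, ln] <- jfold(es$baseline_down[[ln]], length(g))
  }

  mu0 <- exp(runif(n, log(config$nb_mean_range[1]), log(config$nb_mean_range[2])))
  strand <- ifelse(runif(n) < config$minus_strand_fraction, "-", "+")
  layout <- data.frame(
    gene = genes, contig = paste0("ctg_", genes),
    tss = rep(config$tss_position, n), strand = strand,
    stringsAsFactors = FALSE
  )

  conditions <- c("unstim", "stim")
  n_rep <- config$n_replicates
  meta <- expand.grid(replicate = seq_len(n_rep), condition = conditions,
                      line = lines, stringsAsFactors = FALSE)[, 3:1]
  meta$sample <- sprintf("%s_%s_%d", meta$line, meta$condition, meta$replicate)
  meta <- meta[, c("sample", "line", "condition", "replicate")]

  counts <- matrix(0L, n, nrow(meta), dimnames = list(genes, meta$sample))
  size <- 1 / config$nb_dispersion
  for (j in seq_len(nrow(meta))) {
    mu <- mu0 * baseline[, meta$line[j]]
    if (meta$condition[j] == "stim") mu <- mu * fold[, meta$line[j]]
    counts[, j] <- rnbinom(n, size = size, mu = mu)
  }

  truth <- structure(list(
    genes = genes, class = cls, fold = fold, baseline = baseline,
    layout = layout, motif = NULL, peaks = NULL,
    config = config
  ), class = "ground_truth")
  list(counts = count_matrix(counts, meta), truth = truth)
}

# A "mixed" gene responds in >= 2 lines without matching the common,
# GOF-shared, private or WT-only patterns.
sample_mixed_subset <- function(wt, gof) {
  all_lines <- c(wt, gof)
  repeat {
    k <- sample(2:(length(all_lines) - 1), 1)
    s <- sample(all_lines, k)
    if (!setequal(s, gof)) return(s)
  }
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d genes, %d planted\n",
              length(x$genes), sum(x$class != "null")))
  if (!is.null(x$motif)) {
    cat(sprintf("  motifs planted: %d\n", sum(!is.na(x$motif$start))))
  }
  if (!is.null(x$peaks)) {
    cat(sprintf("  peaks placed: %d\n", sum(!is.na(x$peaks$start))))
  }
  invisible(x)
}

#' Simulate TSS-anchored promoter sequences with planted GAS motifs
#'
#' Each gene receives one promoter covering `[-upstream, +downstream)`
#' around its TSS in transcription orientation (default 250 bp spanning
#' -200..+49). Background bases are i.i.d. from the configured composition;
#' the per-class motif policy then plants a canonical consensus copy, a
#' degenerate copy at a fixed Hamming distance, or nothing, at a uniform
#' position inside the policy's placement window. Placements are recorded
#' in the returned truth.
#'
#' @param config A [sim_config()].
#' @param truth The `ground_truth` from [simulate_counts()] under the same
#'   config.
#' @return A list with `promoters` (a `promoter_set`: named
#'   [Biostrings::DNAStringSet] plus window metadata and genome layout) and
#'   the updated `truth`.
#' @export
simulate_promoters <- function(config, truth) {
  validate_sim_config(config)
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(derive_seed(config$seed, 2L))
  n <- length(truth$genes)
  up <- config$promoter_upstream
  down <- config$promoter_downstream
  len <- up + down
  consensus <- strsplit(config$motif_consensus, "")[[1]]
  w <- length(consensus)

  base_mat <- matrix(sample(DNA_BASES, n * len, replace = TRUE,
                            prob = config$base_composition),
                     nrow = n, ncol = len)

  motif <- data.frame(gene = truth$genes, word = NA_character_,
                      start = NA_integer_, strand = NA_character_,
                      mismatches = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    pol <- motif_policy_for(config$motif_policy, truth$class[[i]])
    if (pol$type == "absent") next
    word <- consensus
    n_mm <- 0L
    if (pol$type == "degenerate") {
      n_mm <- if (length(pol$mismatches) == 1) pol$mismatches else sample(pol$mismatches, 1)
      pos <- sample.int(w, n_mm)
      for (p in pos) word[p] <- sample(setdiff(DNA_BASES, word[p]), 1)
    }
    win <- pol$window %||% c(-100, 0)
    lo <- max(win[1], -up)
    hi <- min(win[2] - 1L, down - w)
    if (hi < lo) stopf("placement window [%d,%d) cannot hold a %d bp motif", win[1], win[2], w)
    s <- if (hi == lo) lo else sample(seq.int(lo, hi), 1)
    col <- s + up + 1L  # TSS-relative -> 1-based sequence index
    base_mat[i, col:(col + w - 1L)] <- word
    motif$word[i] <- paste(word, collapse = "")
    motif$start[i] <- s
    motif$strand[i] <- "+"
    motif$mismatches[i] <- n_mm
  }

  seqs <- apply(base_mat, 1, paste, collapse = "")
  dna <- Biostrings::DNAStringSet(setNames(seqs, truth$genes))
  truth$motif <- motif
  promoters <- structure(list(
    seq = dna, upstream = up, downstream = down, layout = truth$layout
  ), class = "promoter_set")
  list(promoters = promoters, truth = truth)
}

motif_policy_for <- function(policy, label) {
  policy[[label]] %||% policy[[sub(":.*$", "", label)]] %||%
    policy[["default"]] %||% list(type = "absent")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("promoter_set: %d promoters, window [-%d, +%d) around TSS\n",
              length(x$seq), x$upstream, x$downstream))
  invisible(x)
}

#' Simulate ChIP-seq peaks over promoters
#'
#' Places one peak per selected promoter, with a per-gene selection
#' probability given by `peak_policy` keyed on the promoter's motif class
#' (canonical planted copy / degenerate copy / no motif). Each peak is a
#' half-open genomic interval guaranteed to overlap its promoter window on
#' the gene's contig.
#'
#' @param config A [sim_config()].
#' @param truth `ground_truth` as updated by [simulate_promoters()] (motif
#'   placements must be present).
#' @return A list with `peaks` (a `peak_set` data frame: contig, start,
#'   end, name, score, strand) and the updated `truth`.
#' @export
simulate_peaks <- function(config, truth) {
  validate_sim_config(config)
  if (is.null(truth$motif)) stopf("run simulate_promoters() before simulate_peaks()")
  set.seed(derive_seed(config$seed, 3L))
  classes <- motif_class(truth)
  prob <- config$peak_policy[classes]
  has_peak <- runif(length(prob)) < prob

  pk <- data.frame(gene = truth$genes, start = NA_integer_, end = NA_integer_,
                   stringsAsFactors = FALSE)
  rows <- list()
  for (i in which(has_peak)) {
    lay <- truth$layout[i, ]
    win <- promoter_window(lay$tss, lay$strand,
                           up = config$promoter_upstream,
                           down = config$promoter_downstream)
    width <- sample(150:400, 1)
    center <- sample(seq.int(win$start, win$end - 1L), 1)
    s <- max(0L, center - width %/% 2L)
    e <- min(config$contig_length, s + width)
    pk$start[i] <- s
    pk$end[i] <- e
    rows[[length(rows) + 1L]] <- data.frame(
      contig = lay$contig, start = s, end = e,
      name = paste0("peak_", lay$gene), score = 0L, strand = ".",
      stringsAsFactors = FALSE
    )
  }
  peaks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               name = character(0), score = integer(0), strand = character(0))
  class(peaks) <- c("peak_set", "data.frame")
  truth$peaks <- pk
  list(peaks = peaks, truth = truth)
}

#' Motif class of each gene's promoter
#'
#' `canonical` if a zero-mismatch consensus copy was planted, `degenerate`
#' for a mismatched copy, `absent` otherwise.
#' @param truth `ground_truth` with motif placements.
#' @return Character vector named by gene.
#' @export
motif_class <- function(truth) {
  if (is.null(truth$motif)) stopf("truth carries no motif placements")
  mm <- truth$motif$mismatches
  setNames(ifelse(is.na(mm), "absent", ifelse(mm == 0, "canonical", "degenerate")),
           truth$genes)
}

#' Simulate the annotation inputs of the analysis
#'
#' Builds a synthetic interferon-regulated-gene (IRG) list and pathway gene
#' sets consistent with the planted truth: the IRG list contains the
#' common, GOF-shared and WT-only programs, a fraction of the mixed
#' program, and a pool of non-responsive genes (IRGs need not respond in
#' this system); the pathway fixture contains an `interferon_signaling` set
#' equal to the common + GOF-shared programs plus random decoy sets.
#'
#' @param config A [sim_config()].
#' @param truth `ground_truth` from [simulate_counts()].
#' @param n_null_irg Number of non-responsive genes added to the IRG list.
#' @param n_decoy_sets,decoy_size Decoy pathway count and size.
#' @return List with `irg` (character vector of gene IDs) and `pathways`
#'   (named list of gene-ID vectors).
#' @export
simulate_annotations <- function(config, truth, n_null_irg = 500,
                                 n_decoy_sets = 5, decoy_size = 40) {
  set.seed(derive_seed(config$seed, 4L))
  base <- sub(":.*$", "", truth$class)
  core <- truth$genes[base %in% c("common_up", "gof_shared_up", "wt_only_up")]
  mixed <- truth$genes[base == "mixed_up"]
  mixed_irg <- mixed[runif(length(mixed)) < 0.3]
  nulls <- truth$genes[base == "null"]
  null_irg <- sample(nulls, min(n_null_irg, length(nulls)))
  irg <- sort(unique(c(core, mixed_irg, null_irg)))

  pathways <- list(
    interferon_signaling = truth$genes[base %in% c("common_up", "gof_shared_up")]
  )
  for (k in seq_len(n_decoy_sets)) {
    pathways[[sprintf("decoy_%02d", k)]] <- sample(truth$genes, decoy_size)
  }
  list(irg = irg, pathways = pathways)
}

#' Write all simulated inputs to a directory
#'
#' Emits the plain-text files every downstream stage reads: counts and
#' sample-metadata TSVs, promoters FASTA (`>gene|contig|tss|strand`
#' headers), promoter-window and peak BED6, the ground-truth ledger TSV,
#' IRG list, pathway TSV and a YAML echo of the configuration.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
simulate_to_dir <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_counts(config)
  pr <- simulate_promoters(config, sim$truth)
  pk <- simulate_peaks(config, pr$truth)
  ann <- simulate_annotations(config, pk$truth)
  truth <- pk$truth

  paths <- c(
    counts = file.path(outdir, "counts.tsv"),
    meta = file.path(outdir, "samples.tsv"),
    promoters = file.path(outdir, "promoters.fasta"),
    windows = file.path(outdir, "promoter_windows.bed"),
    peaks = file.path(outdir, "peaks.bed"),
    truth = file.path(outdir, "ground_truth.tsv"),
    irg = file.path(outdir, "irg.txt"),
    pathways = file.path(outdir, "pathways.tsv"),
    config = file.path(outdir, "config.yaml")
  )
  write_counts(sim$counts, paths["counts"], paths["meta"])
  write_promoters(pr$promoters, paths["promoters"])
  write_promoter_windows(pr$promoters, paths["windows"],
                         up = config$promoter_upstream,
                         down = config$promoter_downstream)
  write_peaks(pk$peaks, paths["peaks"])
  write_ground_truth(truth, paths["truth"])
  writeLines(ann$irg, paths["irg"])
  write_pathways(ann$pathways, paths["pathways"])
  yaml::write_yaml(config_to_list(config), paths["config"])
  invisible(paths)
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$program_sizes <- lapply(out$program_sizes, as.list)
  out
}

#' @rdname simulate_to_dir
#' @param truth A `ground_truth`.
#' @param path Output file.
#' @export
write_ground_truth <- function(truth, path) {
  tab <- data.frame(gene = truth$genes, class = unname(truth$class),
                    truth$layout[, c("contig", "tss", "strand")],
                    stringsAsFactors = FALSE)
  fold <- truth$fold
  colnames(fold) <- paste0("fold_", colnames(fold))
  basl <- truth$baseline
  colnames(basl) <- paste0("baseline_", colnames(basl))
  tab <- cbind(tab, fold, basl)
  if (!is.null(truth$motif)) {
    tab$motif_word <- truth$motif$word
    tab$motif_start <- truth$motif$start
    tab$motif_strand <- truth$motif$strand
    tab$motif_mismatches <- truth$motif$mismatches
  }
  if (!is.null(truth$peaks)) {
    tab$peak_start <- truth$peaks$start
    tab$peak_end <- truth$peaks$end
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_pathways <- function(pathways, path) {
  tab <- data.frame(
    pathway = rep(names(pathways), lengths(pathways)),
    gene = unlist(pathways, use.names = FALSE), stringsAsFactors = FALSE
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pathway gene sets from a two-column TSV (pathway, gene)
#' @param path TSV path.
#' @return Named list of gene-ID vectors.
#' @export
read_pathways <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  split(tab$gene, tab$pathway)
}
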