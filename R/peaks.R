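#' Promoter window around a TSS
#'
#' Genomic interval (0-based, half-open) covering `up` bp upstream and
#' `down` bp downstream of the TSS in transcription orientation:
#' plus strand `[tss - up, tss + down)`; minus strand
#' `[tss - down + 1, tss + up + 1)`, which mirrors the window so the same
#' 200 bp upstream / 50 bp downstream are covered when reading the minus
#' strand. A plus-strand window falling below coordinate 0 is clipped with
#' a `clipped` flag.
#'
#' @param tss TSS coordinate (0-based).
#' @param strand `"+"` or `"-"`.
#' @param up,down Upstream / downstream extent in bp.
#' @return List with `start`, `end`, `strand`, `clipped`.
#' @export
#'
#' @examples
#' promoter_window(1000, "+")  # [800, 1050)
#' promoter_window(1000, "-")  # [951, 1201)
promoter_window <- function(tss, strand, up = 200, down = 50) {
  if (up + down <= 0) stopf("empty promoter window (up + down must be positive)")
  if (!strand %in% c("+", "-")) stopf("unknown strand symbol '%s'", strand)
  if (strand == "+") {
    start <- tss - up
    end <- tss + down
  } else {
    start <- tss - down + 1
    end <- tss + up + 1
  }
  clipped <- FALSE
  if (start < 0) {
    start <- 0
    clipped <- TRUE
  }
  list(start = as.integer(start), end = as.integer(end), strand = strand,
       clipped = clipped)
}

#' Promoter windows for a whole layout
#'
#' @param layout Data frame with `gene`, `contig`, `tss`, `strand`.
#' @inheritParams promoter_window
#' @return Data frame `gene`, `contig`, `start`, `end`, `strand`.
#' @export
promoter_windows <- function(layout, up = 200, down = 50) {
  wins <- lapply(seq_len(nrow(layout)), function(i) {
    w <- promoter_window(layout$tss[i], layout$strand[i], up = up, down = down)
    data.frame(gene = layout$gene[i], contig = layout$contig[i],
               start = w$start, end = w$end, strand = layout$strand[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, wins)
}

windows_to_granges <- function(windows) {
  GenomicRanges::GRanges(
    seqnames = windows$contig,
    ranges = IRanges::IRanges(start = windows$start + 1L, end = windows$end),
    strand = "*"
  )
}

peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$contig,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    strand = "*"
  )
}

#' Does each promoter window overlap any peak?
#'
#' Half-open interval overlap on matching contigs:
#' `max(starts) < min(ends)`.
#'
#' @param windows Data frame of promoter windows (`gene`, `contig`,
#'   `start`, `end`), 0-based half-open.
#' @param peaks A `peak_set` / BED-style data frame (`contig`, `start`,
#'   `end`), 0-based half-open.
#' @return Logical vector named by gene.
#' @export
overlaps_peak <- function(windows, peaks) {
  if (!nrow(peaks)) return(setNames(rep(FALSE, nrow(windows)), windows$gene))
  gr_w <- windows_to_granges(windows)
  gr_p <- peaks_to_granges(peaks)
  # suppress the seqinfo-merge notice when windows and peaks name disjoint
  # contig sets (a legitimate query; every window is then FALSE)
  hit <- suppressWarnings(IRanges::overlapsAny(gr_w, gr_p, ignore.strand = TRUE))
  setNames(hit, windows$gene)
}

#' With-peak / without-peak contingency per condition
#'
#' For each condition's gene set, counts promoters harboring at least one
#' peak versus promoters without one. GOF conditions are first depleted of
#' the WT set's genes (only genes not already up-regulated by WT are
#' scored), and each GOF table is paired with the WT table as a 2x2
#' contingency table for the Yates-corrected chi-squared test.
#'
#' @param gene_sets Named list of gene-ID vectors per condition; must
#'   contain `wt`.
#' @param windows Promoter windows data frame covering every gene in every
#'   set.
#' @param peaks Peak set.
#' @param wt Name of the reference (wild-type) condition in `gene_sets`.
#' @return A `peak_contingency`: per condition `n_with`, `n_without`,
#'   `ratio` (`n_with / n_without`), `depleted` flag, and for non-WT
#'   conditions the 2x2 `table` against WT plus the [chi2_yates()] result.
#' @export
peak_contingency <- function(gene_sets, windows, peaks, wt = "WT") {
  if (!wt %in% names(gene_sets)) stopf("reference set '%s' missing", wt)
  missing <- setdiff(unique(unlist(gene_sets)), windows$gene)
  if (length(missing)) stopf("no promoter window for gene '%s'", missing[1])
  has_peak <- overlaps_peak(windows, peaks)

  count_set <- function(genes) {
    hp <- has_peak[genes]
    c(n_with = sum(hp), n_without = sum(!hp))
  }
  wt_counts <- count_set(gene_sets[[wt]])
  out <- list()
  for (cond in names(gene_sets)) {
    genes <- gene_sets[[cond]]
    depleted <- FALSE
    if (cond != wt) {
      genes <- setdiff(genes, gene_sets[[wt]])
      depleted <- TRUE
    }
    if (!length(genes)) {
      out[[cond]] <- list(n_with = NA_integer_, n_without = NA_integer_,
                          ratio = NA_real_, depleted = depleted, empty = TRUE)
      next
    }
    cnt <- count_set(genes)
    entry <- list(n_with = unname(cnt["n_with"]), n_without = unname(cnt["n_without"]),
                  ratio = unname(cnt["n_with"]) / unname(cnt["n_without"]),
                  depleted = depleted, empty = FALSE)
    if (cond != wt) {
      tab <- rbind(cond = cnt, wt = wt_counts)
      colnames(tab) <- c("with", "without")
      entry$table <- tab
      entry$test <- chi2_yates(tab)
    }
    out[[cond]] <- entry
  }
  structure(out, class = "peak_contingency", wt = wt)
}

#' @export
print.peak_contingency <- function(x, ...) {
  cat("peak_contingency (reference:", attr(x, "wt"), ")\n")
  for (cond in names(x)) {
    e <- x[[cond]]
    if (isTRUE(e$empty)) {
      cat(sprintf("  %-8s empty after depletion (NA)\n", cond))
    } else {
      cat(sprintf("  %-8s with=%d without=%d ratio=%.2f%s\n", cond,
                  e$n_with, e$n_without, e$ratio,
                  if (!is.null(e$test) && !is.na(e$test$p))
                    sprintf("  chi2=%.2f p=%.3g", e$test$statistic, e$test$p) else ""))
    }
  }
  invisible(x)
}

#' Read / write BED6 interval files
#'
#' Thin wrappers over [rtracklayer::import.bed()] /
#' [rtracklayer::export.bed()] converting to the package's 0-based
#' half-open data-frame representation.
#'
#' @param path BED file path.
#' @return `read_peaks`: a `peak_set` data frame (`contig`, `start`,
#'   `end`, `name`, `score`, `strand`), 0-based half-open.
#' @export
read_peaks <- function(path) {
  gr <- rtracklayer::import.bed(path)
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else ".",
    score = if (!is.null(gr$score)) gr$score else 0,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  class(df) <- c("peak_set", "data.frame")
  df
}

#' @rdname read_peaks
#' @param peaks A `peak_set` data frame.
#' @export
write_peaks <- function(peaks, path) {
  strand <- peaks$strand %||% rep(".", nrow(peaks))
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$contig,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    strand = strand
  )
  gr$name <- peaks$name %||% sprintf("peak_%d", seq_len(nrow(peaks)))
  gr$score <- peaks$score %||% 0
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' @rdname read_peaks
#' @param windows Promoter-window data frame (`gene`, `contig`, `start`,
#'   `end`, `strand`).
#' @export
write_promoter_windows <- function(windows, path, up = NULL, down = NULL) {
  if (!("start" %in% names(windows)) && !is.null(up)) {
    windows <- promoter_windows(windows$layout %||% windows, up = up, down = down)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = windows$contig,
    ranges = IRanges::IRanges(start = windows$start + 1L, end = windows$end),
    strand = ifelse(windows$strand %in% c("+", "-"), windows$strand, "*")
  )
  gr$name <- windows$gene
  gr$score <- 0
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' @rdname read_peaks
#' @export
read_promoter_windows <- function(path) {
  df <- read_peaks(path)
  data.frame(gene = df$name, contig = df$contig, start = df$start,
             end = df$end, strand = df$strand, stringsAsFactors = FALSE)
}
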