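#' Read / write a JASPAR-style position frequency matrix
#'
#' Accepts the bracketed four-row JASPAR text layout
#' (`A [ 1 2 ... ]` etc., optionally preceded by a `>` header) and the
#' plain whitespace-separated variant. Any JASPAR-format matrix (e.g. a
#' STAT1 GAS model) can be supplied; the package ships a synthetic GAS
#' fixture in `inst/extdata/gas_stat1_synthetic.jaspar`.
#'
#' @param path Path to the matrix file.
#' @return A `pfm`: 4 x w numeric matrix (rows A, C, G, T) with a `name`
#'   attribute.
#' @export
read_jaspar <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  name <- "PFM"
  if (startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  rows <- list()
  for (ln in lines) {
    base <- sub("^([ACGTacgt]).*$", "\\1", ln)
    nums <- gsub("[^0-9eE.+-]", " ", sub("^[ACGTacgt]", "", ln))
    vals <- as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    rows[[toupper(base)]] <- vals
  }
  if (!all(DNA_BASES %in% names(rows))) stopf("PFM must have A, C, G and T rows")
  counts <- do.call(rbind, rows[DNA_BASES])
  rownames(counts) <- DNA_BASES
  pfm(counts, name = name)
}

#' @rdname read_jaspar
#' @param counts 4 x w non-negative matrix, rows A, C, G, T.
#' @param name Matrix name.
#' @export
pfm <- function(counts, name = "PFM") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stopf("PFM needs 4 rows (A, C, G, T)")
  rownames(counts) <- DNA_BASES
  if (any(counts < 0)) stopf("PFM counts must be >= 0")
  if (any(colSums(counts) <= 0)) stopf("PFM columns must have positive sums")
  structure(counts, name = name, class = c("pfm", "matrix"))
}

#' @rdname read_jaspar
#' @param x A `pfm`.
#' @export
write_jaspar <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", attr(x, "name") %||% "PFM"), con)
  for (b in DNA_BASES) {
    writeLines(sprintf("%s [ %s ]", b, paste(x[b, ], collapse = " ")), con)
  }
  invisible(path)
}

#' Log-odds position weight matrix from a PFM
#'
#' `score(pos, base) = log2( ((count + pseudocount * b_base) /
#' (colsum + pseudocount)) / b_base )`, i.e. log2 of the
#' pseudocount-regularized position probability over the background
#' probability.
#'
#' @param pfm A [pfm()].
#' @param background Background base probabilities (A, C, G, T); must sum
#'   to 1. Default uniform.
#' @param pseudocount Total pseudocount distributed by background
#'   composition.
#' @return A `pwm`: 4 x w matrix of bit scores with the background stored
#'   as an attribute.
#' @export
pfm_to_pwm <- function(pfm, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       pseudocount = 0.5) {
  if (any(colSums(pfm) <= 0)) stopf("zero PFM column sum")
  if (abs(sum(background) - 1) > 1e-8) stopf("background must sum to 1")
  background <- setNames(as.numeric(background), DNA_BASES)
  prob <- sweep(pfm + pseudocount * background, 2, colSums(pfm) + pseudocount, "/")
  scores <- log2(sweep(prob, 1, background, "/"))
  structure(unclass(scores), background = background,
            name = attr(pfm, "name"), class = c("pwm", "matrix"))
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': width %d, max score %.2f bits\n",
              attr(x, "name") %||% "?", ncol(x), sum(apply(x, 2, max))))
  print(round(unclass(x), 3))
  invisible(x)
}

pwm_int_scores <- function(pwm, eps) {
  m <- round(unclass(pwm) / eps)
  storage.mode(m) <- "integer"
  m
}

#' Exact PWM score distribution under the background model
#'
#' Discretizes every position score to a grid of `eps` bits and computes
#' the exact probability mass function of the total score of a random
#' background word by per-position convolution over the four bases. The
#' distribution is exact for the discretized scores; the discretization
#' error of any word's score is at most `w * eps / 2` bits.
#'
#' @param pwm A [pfm_to_pwm()] matrix.
#' @param background Background base probabilities; defaults to the PWM's.
#' @param eps Discretization granularity in bits.
#' @return A `score_distribution`: list with integer `support` (grid
#'   units), `pmf`, `survival` (`P(S >= support)`), and `eps`.
#' @export
score_distribution <- function(pwm, background = attr(pwm, "background"),
                               eps = 0.01) {
  s <- pwm_int_scores(pwm, eps)
  w <- ncol(s)
  b <- setNames(as.numeric(background), DNA_BASES)
  lo <- 0L
  pmf <- 1
  for (k in seq_len(w)) {
    sk <- s[, k]
    new_lo <- lo + min(sk)
    new_hi <- (lo + length(pmf) - 1L) + max(sk)
    new_pmf <- numeric(new_hi - new_lo + 1L)
    for (base in 1:4) {
      off <- lo + sk[base] - new_lo
      idx <- seq_along(pmf) + off
      new_pmf[idx] <- new_pmf[idx] + pmf * b[base]
    }
    pmf <- new_pmf
    lo <- new_lo
  }
  support <- seq.int(lo, lo + length(pmf) - 1L)
  surv <- rev(cumsum(rev(pmf)))
  structure(list(support = support, pmf = pmf, survival = surv, eps = eps),
            class = "score_distribution")
}

#' Map a p-value to a PWM score threshold
#'
#' Exact calibration: the threshold is the smallest grid score `t` with
#' `P(S >= t) <= p` under the background distribution of
#' [score_distribution()]. If even the best possible word exceeds `p`
#' (i.e. no threshold attains the requested p-value), the maximum score is
#' returned with `unattainable = TRUE`.
#'
#' @param pwm A PWM.
#' @param p Target p-value, `0 < p < 1`.
#' @param eps Discretization granularity in bits.
#' @param background Background base probabilities; defaults to the PWM's.
#' @return A `score_threshold` list: `threshold` (bits), `attained_p`
#'   (`P(S >= threshold)`), `p` (requested), `eps`, `unattainable`.
#' @export
#'
#' @examples
#' m <- pfm(matrix(c(10, 0, 0, 0,  0, 10, 0, 0), nrow = 4))
#' score_threshold(pfm_to_pwm(m), 0.1)$threshold
score_threshold <- function(pwm, p, eps = 0.01,
                            background = attr(pwm, "background")) {
  if (!(p > 0 && p < 1)) stopf("p must lie strictly between 0 and 1")
  d <- score_distribution(pwm, background = background, eps = eps)
  ok <- which(d$survival <= p)
  if (!length(ok)) {
    return(structure(list(threshold = max(d$support) * eps,
                          attained_p = d$survival[length(d$survival)],
                          p = p, eps = eps, unattainable = TRUE),
                     class = "score_threshold"))
  }
  i <- ok[1]
  structure(list(threshold = d$support[i] * eps, attained_p = d$survival[i],
                 p = p, eps = eps, unattainable = FALSE),
            class = "score_threshold")
}

#' @export
print.score_threshold <- function(x, ...) {
  cat(sprintf("score_threshold: t = %.2f bits for p < %g (attained p = %.3g)%s\n",
              x$threshold, x$p, x$attained_p,
              if (x$unattainable) " [unattainable]" else ""))
  invisible(x)
}

encode_bases <- function(seqs) {
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  idx <- match(mat, DNA_BASES)
  matrix(idx, nrow = nrow(mat))
}

reverse_complement_pwm <- function(pwm) {
  out <- unclass(pwm)[4:1, ncol(pwm):1, drop = FALSE]
  dimnames(out) <- dimnames(pwm)
  structure(out, background = attr(pwm, "background"),
            name = attr(pwm, "name"), class = c("pwm", "matrix"))
}

#' Scan promoters for PWM hits above a threshold
#'
#' Scores every offset of every promoter on the requested strand(s)
#' against the PWM (scores on the same `eps` grid as the threshold
#' calibration) and reports all hits at or above the threshold. Minus
#' strand hits are scored against the reverse-complemented PWM and
#' reported at the TSS-relative start of the match's leftmost base in plus
#' orientation, so hits at both strands of the same offset are both kept.
#' Windows containing non-ACGT characters are skipped and tallied in the
#' `n_skipped` attribute.
#'
#' @param promoters A `promoter_set` (from [simulate_promoters()] /
#'   [read_promoters()]), a [Biostrings::DNAStringSet], or a named
#'   character vector of equal-length sequences.
#' @param pwm A PWM.
#' @param threshold A [score_threshold()] object or a numeric score in
#'   bits.
#' @param strands Strands to scan (default both).
#' @param eps Grid granularity (taken from the threshold object when
#'   given).
#' @param upstream TSS offset of the first base (position 1 of each
#'   sequence is TSS-relative `-upstream`); taken from a `promoter_set`
#'   automatically.
#' @return A `motif_hits` data frame: `seq_id`, `start` (TSS-relative),
#'   `strand`, `score` (bits), `word`.
#' @export
scan_promoters <- function(promoters, pwm, threshold, strands = c("+", "-"),
                           eps = NULL, upstream = NULL) {
  if (inherits(promoters, "promoter_set")) {
    upstream <- upstream %||% promoters$upstream
    seqs <- as.character(promoters$seq)
  } else if (inherits(promoters, "DNAStringSet")) {
    seqs <- as.character(promoters)
  } else {
    seqs <- as.character(promoters)
  }
  upstream <- upstream %||% 200L
  if (length(unique(nchar(seqs))) != 1) stopf("promoters must have equal lengths")
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  if (inherits(threshold, "score_threshold")) {
    eps <- eps %||% threshold$eps
    t_int <- round(threshold$threshold / threshold$eps)
  } else {
    eps <- eps %||% 0.01
    t_int <- ceiling(threshold / eps - 1e-9)
  }
  w <- ncol(pwm)
  L <- nchar(seqs[1])
  if (L < w) stopf("promoter length < motif width")
  enc <- encode_bases(seqs)
  n_off <- L - w + 1L

  hits <- list()
  n_skipped <- 0L
  for (std in strands) {
    mat <- if (std == "+") pwm_int_scores(pwm, eps) else
      pwm_int_scores(reverse_complement_pwm(pwm), eps)
    S <- matrix(0L, nrow(enc), n_off)
    bad <- matrix(FALSE, nrow(enc), n_off)
    for (k in seq_len(w)) {
      block <- enc[, k:(n_off + k - 1L), drop = FALSE]
      na_blk <- is.na(block)
      bad <- bad | na_blk
      blk <- block
      blk[na_blk] <- 1L
      S <- S + matrix(mat[cbind(as.vector(blk), k)], nrow(enc))
    }
    n_skipped <- n_skipped + sum(bad)
    pass <- which(!bad & S >= t_int, arr.ind = TRUE)
    if (nrow(pass)) {
      starts <- pass[, 2] - 1L - upstream
      hits[[std]] <- data.frame(
        seq_id = names(seqs)[pass[, 1]],
        start = as.integer(starts),
        strand = std,
        score = S[pass] * eps,
        word = substr(seqs[pass[, 1]], pass[, 2], pass[, 2] + w - 1L),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(seq_id = character(0), start = integer(0), strand = character(0),
               score = numeric(0), word = character(0))
  rownames(out) <- NULL
  out <- out[order(out$seq_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  attr(out, "motif_width") <- w
  attr(out, "n_promoters") <- length(seqs)
  attr(out, "seq_ids") <- names(seqs)
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' TSS-relative occurrence profile
#'
#' For each bin center `x` (from `-upstream + w/2` to `+downstream - w/2`
#' in steps of `step`), the percentage of promoters with at least one hit
#' whose start falls in `[x - window/2, x + window/2)`.
#'
#' @param hits A `motif_hits` from [scan_promoters()].
#' @param promoters The promoter set that was scanned (used for the
#'   promoter count and window extent); may be omitted if `hits` carries
#'   them.
#' @param window Sliding window width in bp.
#' @param step Step between bin centers in bp.
#' @return An `occurrence_profile` data frame: `position` (bin center),
#'   `percent`.
#' @export
occurrence_profile <- function(hits, promoters = NULL, window = 25, step = 5) {
  if (window < step) warning("window < step leaves gaps in positional coverage")
  w <- attr(hits, "motif_width") %||% 9L
  if (inherits(promoters, "promoter_set")) {
    up <- promoters$upstream
    down <- promoters$downstream
    n <- length(promoters$seq)
  } else {
    up <- 200L
    down <- 50L
    n <- attr(hits, "n_promoters") %||% length(unique(hits$seq_id))
  }
  centers <- seq(-up + w / 2, down - w / 2, by = step)
  by_seq <- split(hits$start, hits$seq_id)
  pct <- vapply(centers, function(x) {
    lo <- x - window / 2
    hi <- x + window / 2
    100 * sum(vapply(by_seq, function(s) any(s >= lo & s < hi), logical(1))) / n
  }, numeric(1))
  structure(data.frame(position = centers, percent = pct),
            class = c("occurrence_profile", "data.frame"),
            window = window, step = step, n_promoters = n)
}

#' Promoters with and without at least one hit
#'
#' @param hits `motif_hits` from [scan_promoters()].
#' @param promoters The scanned promoter set (or anything with names /
#'   length); may be omitted if `hits` carries the promoter tally.
#' @return List `(n_with, n_without)`; their sum is the promoter count.
#' @export
count_promoters_with_hit <- function(hits, promoters = NULL) {
  n <- if (inherits(promoters, "promoter_set")) length(promoters$seq)
       else if (!is.null(promoters)) length(promoters)
       else attr(hits, "n_promoters")
  if (is.null(n)) stopf("cannot determine the number of scanned promoters")
  n_with <- length(unique(hits$seq_id))
  list(n_with = n_with, n_without = n - n_with)
}

#' Read promoters from FASTA written by the simulator
#'
#' Headers follow `>gene|contig|tss|strand`; plain single-token headers
#' are accepted too (layout columns are then NA).
#'
#' @param path FASTA file.
#' @param upstream,downstream Window extent around the TSS.
#' @return A `promoter_set`.
#' @export
read_promoters <- function(path, upstream = 200, downstream = 50) {
  dna <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(dna), "|", fixed = TRUE)
  genes <- vapply(parts, `[[`, "", 1)
  layout <- data.frame(
    gene = genes,
    contig = vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, ""),
    tss = vapply(parts, function(p) if (length(p) >= 3) as.numeric(p[3]) else NA_real_, 0),
    strand = vapply(parts, function(p) if (length(p) >= 4) p[4] else NA_character_, ""),
    stringsAsFactors = FALSE
  )
  names(dna) <- genes
  structure(list(seq = dna, upstream = as.integer(upstream),
                 downstream = as.integer(downstream), layout = layout),
            class = "promoter_set")
}

#' @rdname read_promoters
#' @param promoters A `promoter_set`.
#' @export
write_promoters <- function(promoters, path) {
  dna <- promoters$seq
  lay <- promoters$layout
  names(dna) <- sprintf("%s|%s|%s|%s", lay$gene, lay$contig, lay$tss, lay$strand)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}
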