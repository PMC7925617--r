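# Independent oracles used across the suite. These deliberately take the
# slow, enumerative route so they share no code path with the package.

# Survival function of the discretized PWM score by brute-force enumeration
# of all 4^w words (probability-weighted by the background).
enum_survival <- function(pwm, eps = 0.01, background = attr(pwm, "background")) {
  w <- ncol(pwm)
  s_int <- round(unclass(pwm) / eps)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- numeric(nrow(words))
  probs <- rep(1, nrow(words))
  for (k in seq_len(w)) {
    scores <- scores + s_int[cbind(words[, k], k)]
    probs <- probs * background[words[, k]]
  }
  support <- sort(unique(scores))
  surv <- vapply(support, function(t) sum(probs[scores >= t]), numeric(1))
  list(support = support, survival = surv)
}

# All-pairs O(N*M) half-open interval overlap.
brute_overlap <- function(windows, peaks) {
  out <- logical(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    for (j in seq_len(nrow(peaks))) {
      if (windows$contig[i] == peaks$contig[j] &&
          max(windows$start[i], peaks$start[j]) <
          min(windows$end[i], peaks$end[j])) {
        out[i] <- TRUE
        break
      }
    }
  }
  setNames(out, windows$gene)
}

# Random promoter set of equal-length sequences. A pyrimidine-only alphabet
# (C/T) makes a background provably free of GAS hits at stringent
# thresholds on either strand.
random_promoters <- function(n, len = 250, seed = 1, upstream = 200,
                             alphabet = c("A", "C", "G", "T")) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, "")
  names(seqs) <- sprintf("p%03d", seq_len(n))
  structure(list(seq = Biostrings::DNAStringSet(seqs),
                 upstream = as.integer(upstream),
                 downstream = as.integer(len - upstream),
                 layout = data.frame(gene = names(seqs),
                                     contig = paste0("c", names(seqs)),
                                     tss = 1000, strand = "+",
                                     stringsAsFactors = FALSE)),
            class = "promoter_set")
}

gas_pwm <- function() {
  pfm_to_pwm(read_jaspar(system.file("extdata", "gas_stat1_synthetic.jaspar",
                                     package = "stat1gof")))
}

# Plant a word into a promoter_set sequence at a TSS-relative start.
plant_word <- function(promoters, idx, word, start) {
  s <- as.character(promoters$seq[[idx]])
  pos <- start + promoters$upstream + 1L
  substr(s, pos, pos + nchar(word) - 1L) <- word
  seqs <- as.character(promoters$seq)
  seqs[idx] <- s
  promoters$seq <- Biostrings::DNAStringSet(setNames(seqs, names(promoters$seq)))
  promoters
}
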