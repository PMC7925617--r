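#' Simulation configuration for the STAT1 GOF study design
#'
#' Builds and validates the configuration object consumed by
#' [simulate_counts()], [simulate_promoters()] and [simulate_peaks()].
#' The defaults emulate the isogenic study design: six cell lines
#' (non-transduced `NT`, `WT`, and the gain-of-function mutants `R274W`,
#' `R321S`, `T419R`, `N574I`), each profiled unstimulated and after 4 h of
#' IFN-gamma, with five replicates per line and condition. Planted
#' expression programs mirror the reported gene-class sizes: 45 genes
#' up-regulated in WT and all GOF lines (mean 5.4-fold in WT, amplified
#' 1.4-fold in R274W/R321S/N574I and 6.4/5.4-fold in T419R), 43 genes
#' shared by all GOF lines only (mean 4.5-fold), private programs of
#' 14/10/51/35 genes, one WT-only gene, line-private down-programs, and
#' unstimulated baseline shifts for T419R and N574I.
#'
#' @param cell_lines Ordered cell-line names. The first is treated as the
#'   non-transduced null line unless `nt_line` says otherwise.
#' @param nt_line,wt_line,gof_lines Roles of the lines. `gof_lines` default
#'   to every line that is neither `nt_line` nor `wt_line`.
#' @param n_replicates Replicates per line x condition.
#' @param n_genes Total number of genes simulated.
#' @param program_sizes Named list of planted program sizes; see Details.
#' @param effect_sizes Named list of mean linear fold changes per program
#'   class (stimulated over unstimulated).
#' @param gof_amplification Multiplier applied to the common-program fold
#'   changes in GOF lines; a scalar or a vector named by GOF line.
#' @param nb_mean_range Range of baseline mean counts; per-gene means are
#'   drawn log-uniformly from it.
#' @param nb_dispersion Negative-binomial dispersion alpha
#'   (variance = mu + alpha * mu^2).
#' @param fold_jitter Half-width j of the per-gene multiplicative jitter:
#'   each planted fold is its class mean times Uniform(1 - j, 1 + j), so
#'   class means are preserved exactly in expectation.
#' @param promoter_upstream,promoter_downstream Promoter window extent in bp
#'   around the TSS; the window is `[-upstream, +downstream)` in
#'   transcription orientation (default `[-200, +50)`).
#' @param base_composition Background base probabilities (A, C, G, T).
#' @param motif_consensus Canonical GAS 9-mer planted for the canonical
#'   policy (an instance of the TTCNNNGAA GAS class).
#' @param motif_policy Named list mapping gene-class labels to a placement
#'   rule: `list(type = "canonical"|"degenerate"|"absent",
#'   mismatches = <int vector>, window = c(from, to))` with the window in
#'   TSS-relative coordinates. The `default` entry covers unlisted classes.
#' @param peak_policy Probability that a promoter receives a ChIP peak, by
#'   motif class (`canonical`, `degenerate`, `absent`).
#' @param minus_strand_fraction Fraction of genes placed on the minus strand
#'   of their contig (exercises strand mirroring in interval logic).
#' @param contig_length,tss_position Synthetic genome layout: one contig per
#'   gene of `contig_length` bp with the TSS at `tss_position` (0-based).
#' @param seed Master seed; every generator stage derives its own stream
#'   from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#'
#' @examples
#' cfg <- sim_config(n_genes = 500, seed = 1)
#' cfg$program_sizes$common_up
sim_config <- function(cell_lines = c("NT", "WT", "R274W", "R321S", "T419R", "N574I"),
                       nt_line = "NT",
                       wt_line = "WT",
                       gof_lines = setdiff(cell_lines, c(nt_line, wt_line)),
                       n_replicates = 5,
                       n_genes = 5000,
                       program_sizes = NULL,
                       effect_sizes = NULL,
                       gof_amplification = NULL,
                       nb_mean_range = c(50, 2000),
                       nb_dispersion = 0.05,
                       fold_jitter = 0.4,
                       promoter_upstream = 200,
                       promoter_downstream = 50,
                       base_composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       motif_consensus = "TTCCGGGAA",
                       motif_policy = NULL,
                       peak_policy = c(canonical = 0.9, degenerate = 0.4, absent = 0.05),
                       minus_strand_fraction = 0.5,
                       contig_length = 2000,
                       tss_position = 1000,
                       seed = 1) {
  sizes <- default_program_sizes(gof_lines, wt_line)
  if (!is.null(program_sizes)) sizes[names(program_sizes)] <- program_sizes
  effects <- default_effect_sizes()
  if (!is.null(effect_sizes)) effects[names(effect_sizes)] <- effect_sizes
  if (is.null(gof_amplification)) {
    gof_amplification <- setNames(rep(1.4, length(gof_lines)), gof_lines)
    if ("T419R" %in% gof_lines) gof_amplification[["T419R"]] <- 6.4 / 5.4
  }
  if (is.null(names(gof_amplification))) {
    gof_amplification <- setNames(rep_len(gof_amplification, length(gof_lines)), gof_lines)
  }
  if (is.null(motif_policy)) motif_policy <- default_motif_policy()

  cfg <- structure(list(
    cell_lines = cell_lines, nt_line = nt_line, wt_line = wt_line,
    gof_lines = gof_lines, n_replicates = as.integer(n_replicates),
    n_genes = as.integer(n_genes),
    program_sizes = sizes, effect_sizes = effects,
    gof_amplification = gof_amplification,
    nb_mean_range = nb_mean_range, nb_dispersion = nb_dispersion,
    fold_jitter = fold_jitter,
    promoter_upstream = as.integer(promoter_upstream),
    promoter_downstream = as.integer(promoter_downstream),
    base_composition = base_composition,
    motif_consensus = toupper(motif_consensus),
    motif_policy = motif_policy,
    peak_policy = peak_policy,
    minus_strand_fraction = minus_strand_fraction,
    contig_length = as.integer(contig_length),
    tss_position = as.integer(tss_position),
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

default_program_sizes <- function(gof_lines, wt_line) {
  private <- c(R274W = 14, R321S = 10, T419R = 51, N574I = 35)
  down <- c(WT = 2, R274W = 11, R321S = 11, T419R = 61, N574I = 18)
  list(
    common_up = 45,
    gof_shared_up = 43,
    private_up = private[intersect(names(private), gof_lines)],
    mixed_up = 30,
    wt_only_up = 1,
    down = down[intersect(names(down), c(wt_line, gof_lines))],
    baseline_up = c(T419R = 1, N574I = 44)[intersect(c("T419R", "N574I"), gof_lines)],
    baseline_down = c(T419R = 21, N574I = 90)[intersect(c("T419R", "N574I"), gof_lines)]
  )
}

default_effect_sizes <- function() {
  list(
    common = 5.4,
    gof_shared = 4.5,
    private = 4,
    mixed = 4,
    wt_only = 4,
    down = 1 / 3,
    baseline_up = c(T419R = 2.65, N574I = 2.96),
    baseline_down = c(T419R = 1 / 2.65, N574I = 1 / 2.70)
  )
}

default_motif_policy <- function() {
  list(
    common_up = list(type = "canonical", window = c(-100, 0)),
    gof_shared_up = list(type = "degenerate", mismatches = 1:2, window = c(-100, 0)),
    default = list(type = "absent")
  )
}

validate_sim_config <- function(cfg) {
  if (anyDuplicated(cfg$cell_lines)) stopf("duplicated cell line names")
  for (ln in c(cfg$nt_line, cfg$wt_line, cfg$gof_lines)) {
    if (!ln %in% cfg$cell_lines) stopf("line '%s' not among cell_lines", ln)
  }
  if (cfg$n_replicates < 2) stopf("n_replicates must be >= 2 for testing")
  if (cfg$nb_dispersion <= 0) stopf("nb_dispersion must be positive")
  if (cfg$fold_jitter < 0 || cfg$fold_jitter >= 1) stopf("fold_jitter must be in [0, 1)")
  n_program <- sum(unlist(cfg$program_sizes))
  if (n_program > cfg$n_genes) {
    stopf("program sizes sum to %d, exceeding n_genes = %d", n_program, cfg$n_genes)
  }
  if (any(cfg$peak_policy < 0 | cfg$peak_policy > 1)) {
    stopf("peak_policy probabilities must lie in [0, 1]")
  }
  if (abs(sum(cfg$base_composition) - 1) > 1e-8) stopf("base_composition must sum to 1")
  w <- cfg$promoter_upstream + cfg$promoter_downstream
  if (nchar(cfg$motif_consensus) > w) stopf("motif longer than promoter window")
  if (!all(strsplit(cfg$motif_consensus, "")[[1]] %in% DNA_BASES)) {
    stopf("motif_consensus must be an A/C/G/T string")
  }
  if (cfg$tss_position < cfg$promoter_upstream ||
      cfg$tss_position + cfg$promoter_upstream + 1 > cfg$contig_length) {
    stopf("tss_position leaves no room for the promoter window on the contig")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("STAT1 GOF study simulation config\n")
  cat("  lines:", paste(x$cell_lines, collapse = ", "), "\n")
  cat("  replicates:", x$n_replicates, " genes:", x$n_genes, "\n")
  cat("  programs:", paste(sprintf("%s=%s", names(x$program_sizes),
    vapply(x$program_sizes, function(p) paste(p, collapse = "/"), "")),
    collapse = "; "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
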