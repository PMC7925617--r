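#' Partition regulated genes across cell lines
#'
#' Classifies the union of per-line up-calls (and, separately, down-calls)
#' into mutually exclusive categories:
#' \describe{
#'   \item{`common_up`}{up in WT and in every GOF line}
#'   \item{`gof_shared_up`}{up in every GOF line but not in WT}
#'   \item{`private_up:<line>`}{up in exactly one GOF line}
#'   \item{`wt_only_up`}{up in WT only}
#'   \item{`mixed_up`}{up in two or more lines without matching any
#'     category above}
#' }
#' and the analogous `*_down` labels. Labels are exhaustive over the union
#' of calls and invariant to the order of the GOF lines.
#'
#' @param calls Named list of `de_calls` (one per line, names = lines), as
#'   produced by [de_all_lines()].
#' @param wt_line Name of the wild-type line.
#' @param gof_lines Names of the GOF lines (must all be present in
#'   `calls`).
#' @return A `partition_result`: list with `up` and `down`, each a named
#'   character vector gene -> label, plus `counts` (label x direction
#'   table) and `members` (list of gene vectors per label).
#' @export
#'
#' @examples
#' mk <- function(line, up) structure(list(line = line, up = up,
#'   down = character(0), lfc_min = 1, alpha = 0.01), class = "de_calls")
#' calls <- list(WT = mk("WT", c("a", "b")), G1 = mk("G1", c("a", "c")),
#'               G2 = mk("G2", c("a", "c", "d")))
#' partition_genes(calls, "WT", c("G1", "G2"))$up
partition_genes <- function(calls, wt_line, gof_lines) {
  lines <- c(wt_line, gof_lines)
  missing <- setdiff(lines, names(calls))
  if (length(missing)) stopf("calls missing for line(s): %s", paste(missing, collapse = ", "))
  for (ln in lines) {
    if (anyDuplicated(calls[[ln]]$up) || anyDuplicated(calls[[ln]]$down)) {
      stopf("duplicate gene IDs in call set for line '%s'", ln)
    }
  }
  lab_up <- label_direction(lapply(calls[lines], `[[`, "up"), wt_line, gof_lines, "up")
  lab_down <- label_direction(lapply(calls[lines], `[[`, "down"), wt_line, gof_lines, "down")
  members <- c(split(names(lab_up), unname(lab_up)),
               split(names(lab_down), unname(lab_down)))
  counts <- c(table(unname(lab_up)), table(unname(lab_down)))
  structure(list(up = lab_up, down = lab_down, counts = counts,
                 members = members, wt_line = wt_line, gof_lines = gof_lines),
            class = "partition_result")
}

label_direction <- function(sets, wt_line, gof_lines, direction) {
  universe <- sort(unique(unlist(sets)))
  if (!length(universe)) return(setNames(character(0), character(0)))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1)
  rownames(member) <- universe
  in_wt <- member[, wt_line]
  gof_hits <- rowSums(member[, gof_lines, drop = FALSE])
  n_hits <- rowSums(member)
  all_gof <- gof_hits == length(gof_lines)

  lab <- rep(NA_character_, length(universe))
  lab[in_wt & all_gof] <- paste0("common_", direction)
  lab[!in_wt & all_gof] <- paste0("gof_shared_", direction)
  only_one <- n_hits == 1
  wt_only <- only_one & in_wt
  lab[is.na(lab) & wt_only] <- paste0("wt_only_", direction)
  solo_gof <- which(is.na(lab) & only_one & !in_wt)
  if (length(solo_gof)) {
    which_line <- gof_lines[apply(member[solo_gof, gof_lines, drop = FALSE], 1, which)]
    lab[solo_gof] <- paste0("private_", direction, ":", which_line)
  }
  lab[is.na(lab)] <- paste0("mixed_", direction)
  setNames(lab, universe)
}

#' @export
print.partition_result <- function(x, ...) {
  cat("partition_result\n")
  print(x$counts)
  invisible(x)
}

#' Per-class average linear fold increase
#'
#' Arithmetic mean, over a gene set and per line, of the linear fold
#' changes `2^log2FC` (stimulated over unstimulated normalized means) --
#' the quantity summarized under expression heatmaps. The per-gene x line
#' fold table is returned alongside for heatmap rendering.
#'
#' @param results Named list of `de_result` data frames (or [de_test()]
#'   outputs), one per line.
#' @param members Gene IDs of the class; must be present in every result.
#' @return A `fold_summary`: list with `mean_fold` (named per line) and
#'   `fold_table` (genes x lines matrix of linear folds).
#' @export
average_fold_increase <- function(results, members) {
  if (!length(members)) stopf("members must be non-empty")
  results <- lapply(results, function(r) if (is.data.frame(r)) r else r$result)
  folds <- vapply(results, function(r) {
    idx <- match(members, r$gene)
    if (anyNA(idx)) stopf("gene '%s' missing from a DE result", members[which(is.na(idx))[1]])
    2^r$log2FC[idx]
  }, numeric(length(members)))
  if (is.null(dim(folds))) folds <- matrix(folds, nrow = length(members))
  dimnames(folds) <- list(members, names(results))
  structure(list(mean_fold = colMeans(folds), fold_table = folds),
            class = "fold_summary")
}

#' @export
print.fold_summary <- function(x, ...) {
  cat("fold_summary over", nrow(x$fold_table), "genes\n")
  print(round(x$mean_fold, 2))
  invisible(x)
}

#' Read an IRG list (one gene ID per line)
#'
#' Membership is by exact ID match after upper-casing, standing in for a
#' type-II interferon-regulated-gene annotation.
#'
#' @param path File with one gene ID per line.
#' @return An `irg_annotation` (character vector of normalized IDs).
#' @export
read_irg <- function(path) {
  ids <- toupper(trimws(readLines(path)))
  structure(unique(ids[nzchar(ids)]), class = "irg_annotation")
}

#' Count IRG / non-IRG membership of a gene set
#'
#' @param members Gene IDs to classify.
#' @param irg An `irg_annotation` from [read_irg()], or a plain character
#'   vector of IRG IDs.
#' @return List with `n_irg`, `n_non_irg`, `percent_non_irg` (NA for an
#'   empty member set) and `n_unannotated` (members absent from the
#'   annotation universe; these count as non-IRG).
#' @export
classify_irg <- function(members, irg) {
  irg <- toupper(as.character(irg))
  members_n <- toupper(members)
  is_irg <- members_n %in% irg
  n <- length(members)
  list(
    n_irg = sum(is_irg),
    n_non_irg = sum(!is_irg),
    percent_non_irg = if (n == 0) NA_real_ else 100 * sum(!is_irg) / n,
    n_unannotated = sum(!is_irg)
  )
}
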