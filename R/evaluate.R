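# Assembly statistics and scaffold accuracy against a truth placement table.

#' N50 of a set of sequence lengths
#'
#' The largest length `L` such that sequences of length at least `L` sum to
#' at least half the total assembly length.
#'
#' @param lengths Positive numeric vector.
#' @return N50 (same units as `lengths`).
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) abort("n50 of an empty length set is undefined")
  stopifnot(all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Scaffold accuracy against a truth placement table
#'
#' A join (adjacent component pair) is correct iff both contigs map to the
#' same reference sequence on the same strand after orientation adjustment,
#' in the scaffold's order, and their reference separation is at most
#' `max_separation` (intercalated reference contigs between them do not
#' invalidate a join). Local link correctness is the fraction of correct
#' joins; scaffold correctness is the fraction of scaffolds with at least
#' one join for which all joins are correct. Contigs absent from the truth
#' table exclude their joins, with a warning.
#'
#' @param scaffolds Scaffold tibble.
#' @param truth Placement tibble (see [read_truth_table()]).
#' @param config An [eval_config()].
#' @return One-row tibble: `n_joins`, `n_correct`, `local_link_correctness`,
#'   `n_scaffolds`, `n_all_correct`, `scaffold_correctness`. Per-join detail
#'   is attached as attribute `"joins"`.
#' @export
scaffold_accuracy <- function(scaffolds, truth, config = eval_config()) {
  joins <- list()
  ti <- match(scaffolds$contig_id, truth$contig_id)
  missing <- unique(scaffolds$contig_id[is.na(ti)])
  if (length(missing) > 0) {
    warn(paste0("contigs missing from truth table: ",
                paste(missing, collapse = ", ")))
  }
  for (sid in unique(scaffolds$scaffold_id)) {
    p <- scaffolds[scaffolds$scaffold_id == sid, ]
    p <- p[order(p$position), ]
    if (nrow(p) < 2) next
    for (i in seq_len(nrow(p) - 1)) {
      a <- p[i, ]; b <- p[i + 1, ]
      ta <- truth[truth$contig_id == a$contig_id, ]
      tb <- truth[truth$contig_id == b$contig_id, ]
      if (nrow(ta) == 0 || nrow(tb) == 0) {
        joins[[length(joins) + 1L]] <- tibble(
          scaffold_id = sid, contig_a = a$contig_id, contig_b = b$contig_id,
          evaluable = FALSE, correct = NA)
        next
      }
      eff_a <- if (a$orientation == ta$strand[1]) "+" else "-"
      eff_b <- if (b$orientation == tb$strand[1]) "+" else "-"
      ok <- ta$reference_id[1] == tb$reference_id[1] && eff_a == eff_b
      if (ok) {
        if (eff_a == "+") {
          ok <- tb$ref_start[1] >= ta$ref_start[1] &&
            max(0, tb$ref_start[1] - ta$ref_end[1]) <= config$max_separation
        } else {
          ok <- ta$ref_start[1] >= tb$ref_start[1] &&
            max(0, ta$ref_start[1] - tb$ref_end[1]) <= config$max_separation
        }
      }
      joins[[length(joins) + 1L]] <- tibble(
        scaffold_id = sid, contig_a = a$contig_id, contig_b = b$contig_id,
        evaluable = TRUE, correct = ok)
    }
  }
  jt <- if (length(joins) == 0) {
    tibble(scaffold_id = character(), contig_a = character(),
           contig_b = character(), evaluable = logical(), correct = logical())
  } else dplyr::bind_rows(joins)
  ev <- jt[jt$evaluable, ]
  per_scaf <- if (nrow(ev) == 0) {
    tibble(scaffold_id = character(), all_correct = logical())
  } else {
    dplyr::summarise(dplyr::group_by(ev, .data$scaffold_id),
                     all_correct = all(.data$correct), .groups = "drop")
  }
  out <- tibble(
    n_joins = nrow(ev), n_correct = sum(ev$correct),
    local_link_correctness = if (nrow(ev) == 0) NA_real_ else
      sum(ev$correct) / nrow(ev),
    n_scaffolds = nrow(per_scaf), n_all_correct = sum(per_scaf$all_correct),
    scaffold_correctness = if (nrow(per_scaf) == 0) NA_real_ else
      sum(per_scaf$all_correct) / nrow(per_scaf))
  attr(out, "joins") <- jt
  out
}
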