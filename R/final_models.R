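# Final gene models: re-align each committed guide protein against its
# scaffolded sequence (gaps as N runs), so the joined context is seen by the
# aligner; blocks spanning a gap are split at the N run.

#' Assemble scaffold sequences
#'
#' Concatenates oriented component sequences with fixed N-run gaps.
#'
#' @param scaffolds Scaffold tibble.
#' @param contigs Sequence tibble covering every component.
#' @param gap_length Gap placeholder length (nt).
#' @return A list: `sequences` (sequence tibble, one row per scaffold) and
#'   `layout` (tibble `scaffold_id`, `contig_id`, `orientation`, `start`,
#'   `end` in 0-based half-open scaffold coordinates).
#' @export
scaffold_sequences <- function(scaffolds, contigs, gap_length = 100L) {
  seq_rows <- list(); layout <- list()
  for (sid in unique(scaffolds$scaffold_id)) {
    p <- scaffolds[scaffolds$scaffold_id == sid, ]
    p <- p[order(p$position), ]
    pieces <- character(0)
    pos <- 0L
    for (i in seq_len(nrow(p))) {
      if (i > 1) {
        pieces <- c(pieces, strrep("N", gap_length))
        pos <- pos + gap_length
      }
      s <- contigs$seq[match(p$contig_id[i], contigs$id)]
      if (is.na(s)) abort(paste0("unknown contig ", p$contig_id[i]))
      if (p$orientation[i] == "-") s <- revcomp(s)
      layout[[length(layout) + 1L]] <- tibble(
        scaffold_id = sid, contig_id = p$contig_id[i],
        orientation = p$orientation[i], start = pos, end = pos + nchar(s))
      pieces <- c(pieces, s)
      pos <- pos + nchar(s)
    }
    seq_rows[[length(seq_rows) + 1L]] <- tibble(
      id = sid, seq = paste(pieces, collapse = ""), kind = "nucleotide")
  }
  list(sequences = dplyr::bind_rows(seq_rows), layout = dplyr::bind_rows(layout))
}

# Split block contig intervals at gap (N-run) intervals of a scaffold.
split_at_gaps <- function(blocks, gaps) {
  if (nrow(gaps) == 0 || nrow(blocks) == 0) return(blocks)
  bir <- IRanges::IRanges(blocks$contig_start + 1L, blocks$contig_end)
  gir <- IRanges::IRanges(gaps$start + 1L, gaps$end)
  out <- list()
  for (i in seq_along(bir)) {
    pieces <- IRanges::setdiff(bir[i], gir)
    w <- blocks[i, ]
    for (j in seq_along(pieces)) {
      r <- w
      r$contig_start <- IRanges::start(pieces)[j] - 1L
      r$contig_end <- IRanges::end(pieces)[j]
      frac <- (r$contig_end - r$contig_start) /
        (w$contig_end - w$contig_start)
      r$raw_score <- w$raw_score * frac
      out[[length(out) + 1L]] <- r
    }
  }
  dplyr::bind_rows(out)
}

#' Re-derive final gene models on scaffolded sequence
#'
#' For every committed protein model, the guide protein is re-aligned
#' (translated alignment plus iterative refinement) against the scaffold
#' sequence that now carries its contigs; CDS intervals are alignment blocks
#' split at gap N-runs, and protein coverage is computed on the protein
#' length. A protein whose alignment is lost after merging yields a model
#' with zero intervals and a warning.
#'
#' @param scaffolds Scaffold tibble (post-merge).
#' @param contigs,proteins Sequence tibbles.
#' @param committed Committed models from [greedy_select()].
#' @param config An [aligner_config()].
#' @param gap_length Gap placeholder length used when building scaffolds.
#' @return A tibble: `scaffold_id`, `protein_id`, `strand`, `cds_intervals`
#'   (list of tibbles `start`, `end`), `score`,
#'   `fraction_of_protein_covered`.
#' @export
final_gene_models <- function(scaffolds, contigs, proteins, committed,
                              config = aligner_config(), gap_length = 100L) {
  empty <- tibble(scaffold_id = character(), protein_id = character(),
                  strand = character(), cds_intervals = list(),
                  score = double(), fraction_of_protein_covered = double())
  if (nrow(scaffolds) == 0 || nrow(committed) == 0) return(empty)
  built <- scaffold_sequences(scaffolds, contigs, gap_length)
  seqs <- built$sequences; layout <- built$layout
  # gap runs per scaffold
  gap_runs <- lapply(stats::setNames(seqs$id, seqs$id), function(sid) {
    l <- layout[layout$scaffold_id == sid, ]
    l <- l[order(l$start), ]
    if (nrow(l) < 2) return(tibble(start = integer(), end = integer()))
    tibble(start = l$end[-nrow(l)], end = l$start[-1])
  })
  rows <- list()
  for (i in seq_len(nrow(committed))) {
    pid <- committed$protein_id[i]
    prot <- proteins[proteins$id == pid, ]
    if (nrow(prot) == 0) abort(paste0("unknown protein ", pid))
    # scaffolds that carry this protein's committed contigs
    gm_ids <- committed$max_set[[i]]
    contig_ids <- unique(vapply(strsplit(gm_ids, "\\|"), `[`, character(1), 1))
    sids <- unique(layout$scaffold_id[layout$contig_id %in% contig_ids])
    for (sid in sids) {
      scaf <- seqs[seqs$id == sid, ]
      hits <- align_proteome(prot, scaf, config)
      if (nrow(hits) == 0) {
        warn(sprintf("alignment of %s lost on %s after merging", pid, sid))
        rows[[length(rows) + 1L]] <- tibble(
          scaffold_id = sid, protein_id = pid, strand = "+",
          cds_intervals = list(tibble(start = integer(), end = integer())),
          score = 0, fraction_of_protein_covered = 0)
        next
      }
      strand <- hits$strand[which.max(hits$raw_score)]
      seed <- hits[hits$strand == strand, ]
      mp <- iterative_refine(prot, scaf, seed, config)
      blocks <- split_at_gaps(mp$blocks[[1]], gap_runs[[sid]])
      blocks <- blocks[order(blocks$contig_start), ]
      covered <- IRanges::reduce(IRanges::IRanges(
        mp$blocks[[1]]$protein_start + 1L, mp$blocks[[1]]$protein_end))
      rows[[length(rows) + 1L]] <- tibble(
        scaffold_id = sid, protein_id = pid, strand = strand,
        cds_intervals = list(tibble(start = blocks$contig_start,
                                    end = blocks$contig_end)),
        score = raw_to_bit_fraction(sum(blocks$raw_score), config$lambda),
        fraction_of_protein_covered =
          sum(IRanges::width(covered)) / nchar(prot$seq[1]))
    }
  }
  if (length(rows) == 0) empty else dplyr::bind_rows(rows)
}
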