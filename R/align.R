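# Built-in translated protein-to-contig aligner plus the iterative flank
# re-search that merges exon-level evidence into one colinear mapping per
# protein/contig/strand. Smith-Waterman itself comes from
# Biostrings::pairwiseAlignment; this module supplies six-frame translation,
# block decomposition (large alignment gaps = putative introns split blocks),
# Karlin-Altschul scoring, and the refinement loop.

MIN_REFINE_SEGMENT <- 8L # aa; shorter unmatched protein stubs are not re-searched

# Decompose one gapped local alignment (pattern = protein, subject = frame
# translation) into gap-free segments, then merge segments separated by small
# gaps (<= max_block_gap residues in both coordinate systems) into blocks.
# Coordinates returned are 0-based half-open in protein aa / frame aa units.
decompose_alignment <- function(pat_str, sub_str, pat_start0, sub_start0,
                                config) {
  m <- blosum62()
  pc <- strsplit(pat_str, "")[[1]]
  sc <- strsplit(sub_str, "")[[1]]
  p_pos <- pat_start0; s_pos <- sub_start0
  segs <- list(); cur <- NULL
  flush <- function() { if (!is.null(cur)) segs[[length(segs) + 1L]] <<- cur; cur <<- NULL }
  for (i in seq_along(pc)) {
    if (pc[i] != "-" && sc[i] != "-") {
      sc_ok <- sc[i] %in% rownames(m) && pc[i] %in% rownames(m)
      s <- if (sc_ok) m[pc[i], sc[i]] else 0
      if (is.null(cur)) {
        cur <- list(p0 = p_pos, s0 = s_pos, p1 = p_pos + 1L, s1 = s_pos + 1L,
                    score = s)
      } else {
        cur$p1 <- p_pos + 1L; cur$s1 <- s_pos + 1L; cur$score <- cur$score + s
      }
      p_pos <- p_pos + 1L; s_pos <- s_pos + 1L
    } else {
      flush()
      if (pc[i] != "-") p_pos <- p_pos + 1L
      if (sc[i] != "-") s_pos <- s_pos + 1L
    }
  }
  flush()
  if (length(segs) == 0) return(NULL)
  # merge across small gaps, charging affine gap penalties within a block
  merged <- list(segs[[1]])
  for (i in seq_along(segs)[-1]) {
    prev <- merged[[length(merged)]]
    gp <- segs[[i]]$p0 - prev$p1
    gs <- segs[[i]]$s0 - prev$s1
    if (max(gp, gs) <= config$max_block_gap) {
      pen <- config$gap_open + config$gap_extend * max(gp, gs)
      prev$p1 <- segs[[i]]$p1; prev$s1 <- segs[[i]]$s1
      prev$score <- prev$score + segs[[i]]$score - pen
      merged[[length(merged)]] <- prev
    } else {
      merged[[length(merged) + 1L]] <- segs[[i]]
    }
  }
  do.call(rbind, lapply(merged, function(b) {
    data.frame(p0 = b$p0, p1 = b$p1, s0 = b$s0, s1 = b$s1, score = b$score)
  }))
}

# Align one protein against the three frames of one strand of a nucleotide
# sequence. Returns a block tibble (forward-strand nt contig coordinates)
# with a frame column; blocks below min_block_score (bits) are dropped.
align_frames <- function(prot_seq, nt_seq, strand, config,
                         translations = NULL) {
  n <- nchar(nt_seq)
  out <- list()
  if (nchar(prot_seq) == 0 || n < 3) return(NULL)
  pat <- Biostrings::AAStringSet(prot_seq)
  for (frame in 0:2) {
    tr <- if (is.null(translations)) translate_frame(nt_seq, strand, frame)
          else translations[frame + 1L]
    if (nchar(tr) < 2) next
    aln <- Biostrings::pairwiseAlignment(
      pat, Biostrings::AAString(tr), type = "local",
      substitutionMatrix = blosum62(),
      gapOpening = config$gap_open, gapExtension = config$gap_extend)
    if (Biostrings::score(aln) <= 0) next
    ap <- Biostrings::pattern(aln); as_ <- Biostrings::subject(aln)
    blocks <- decompose_alignment(
      as.character(ap), as.character(as_),
      Biostrings::start(ap) - 1L, Biostrings::start(as_) - 1L, config)
    if (is.null(blocks)) next
    blocks <- blocks[raw_to_bits(blocks$score, config$lambda, config$K) >=
                       config$min_block_score, , drop = FALSE]
    if (nrow(blocks) == 0) next
    nt <- t(mapply(function(s0, s1) frame_aa_to_nt(s0, s1, strand, frame, n),
                   blocks$s0, blocks$s1))
    out[[length(out) + 1L]] <- tibble(
      contig_start = as.integer(nt[, 1]), contig_end = as.integer(nt[, 2]),
      protein_start = as.integer(blocks$p0), protein_end = as.integer(blocks$p1),
      raw_score = blocks$score, frame = frame)
  }
  if (length(out) == 0) NULL else dplyr::bind_rows(out)
}

#' Translated local alignment of a protein against a contig
#'
#' Aligns the protein against all six reading frames (3 frames x 2 strands)
#' of the contig with Smith-Waterman under BLOSUM62, decomposes each frame's
#' best local alignment into colinear blocks (alignment gaps larger than
#' `max_block_gap` residues, e.g. introns, split blocks), and scores hits in
#' bits via Karlin-Altschul statistics. One hit is returned per strand/frame
#' with at least one block above `min_block_score`.
#'
#' @param protein,contig Single-row sequence tibbles (or any rows with `id`
#'   and `seq`), protein amino acid, contig nucleotide.
#' @param config An [aligner_config()].
#' @return A hit tibble (possibly empty) with a `blocks` list-column.
#' @export
translated_align <- function(protein, contig, config = aligner_config()) {
  if (nchar(protein$seq[1]) == 0 || nchar(contig$seq[1]) == 0) return(empty_hits())
  m <- nchar(protein$seq[1]); n <- nchar(contig$seq[1])
  rows <- list()
  for (strand in c("+", "-")) {
    blocks <- align_frames(protein$seq[1], contig$seq[1], strand, config)
    if (is.null(blocks)) next
    for (fr in unique(blocks$frame)) {
      b <- blocks[blocks$frame == fr, , drop = FALSE]
      b <- b[order(b$protein_start), ]
      raw <- sum(b$raw_score)
      rows[[length(rows) + 1L]] <- tibble(
        protein_id = protein$id[1], contig_id = contig$id[1],
        protein_start = min(b$protein_start), protein_end = max(b$protein_end),
        contig_start = min(b$contig_start), contig_end = max(b$contig_end),
        strand = strand, frame = as.integer(fr),
        raw_score = raw,
        bit_score = raw_to_bits(raw, config$lambda, config$K),
        e_value = evalue_from_raw(raw, m, n, config$lambda, config$K),
        blocks = list(block_tbl(b$contig_start, b$contig_end,
                                b$protein_start, b$protein_end, b$raw_score)))
    }
  }
  if (length(rows) == 0) empty_hits() else dplyr::bind_rows(rows)
}

#' Align a whole guide proteome against a whole contig set
#'
#' A shared-k-mer prescreen (exact amino-acid k-mers between the protein and
#' each frame translation) selects candidate protein/contig/strand triples;
#' [translated_align()]-equivalent scoring then runs only on those.
#'
#' @param proteins,contigs Sequence tibbles.
#' @param config An [aligner_config()].
#' @param k Prescreen k-mer size (aa).
#' @return Combined hit tibble.
#' @export
align_proteome <- function(proteins, contigs, config = aligner_config(), k = 5L) {
  if (nrow(proteins) == 0 || nrow(contigs) == 0) return(empty_hits())
  kidx <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(proteins))) {
    for (km in aa_kmers(proteins$seq[i], k)) {
      kidx[[km]] <- c(kidx[[km]], i)
    }
  }
  rows <- list()
  for (ci in seq_len(nrow(contigs))) {
    n <- nchar(contigs$seq[ci])
    for (strand in c("+", "-")) {
      for (frame in 0:2) {
        tr <- translate_frame(contigs$seq[ci], strand, frame)
        if (nchar(tr) < 2) next
        cand <- integer(0)
        for (km in aa_kmers(tr, k)) {
          hit <- kidx[[km]]
          if (!is.null(hit)) cand <- c(cand, hit)
        }
        cand <- unique(cand)
        if (length(cand) == 0) next
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::AAStringSet(proteins$seq[cand]),
          Biostrings::AAString(tr), type = "local",
          substitutionMatrix = blosum62(),
          gapOpening = config$gap_open, gapExtension = config$gap_extend)
        scores <- Biostrings::score(aln)
        ap <- Biostrings::pattern(aln); as_ <- Biostrings::subject(aln)
        pat_strs <- as.character(ap); sub_strs <- as.character(as_)
        pat_starts <- Biostrings::start(ap); sub_starts <- Biostrings::start(as_)
        for (j in seq_along(cand)) {
          if (scores[j] <= 0) next
          blocks <- decompose_alignment(pat_strs[j], sub_strs[j],
                                        pat_starts[j] - 1L, sub_starts[j] - 1L,
                                        config)
          if (is.null(blocks)) next
          blocks <- blocks[raw_to_bits(blocks$score, config$lambda, config$K) >=
                             config$min_block_score, , drop = FALSE]
          if (nrow(blocks) == 0) next
          nt <- t(mapply(function(s0, s1) {
            frame_aa_to_nt(s0, s1, strand, frame, n)
          }, blocks$s0, blocks$s1))
          b <- tibble(contig_start = as.integer(nt[, 1]),
                      contig_end = as.integer(nt[, 2]),
                      protein_start = as.integer(blocks$p0),
                      protein_end = as.integer(blocks$p1),
                      raw_score = blocks$score)
          b <- b[order(b$protein_start), ]
          raw <- sum(b$raw_score)
          m <- nchar(proteins$seq[cand[j]])
          rows[[length(rows) + 1L]] <- tibble(
            protein_id = proteins$id[cand[j]], contig_id = contigs$id[ci],
            protein_start = min(b$protein_start), protein_end = max(b$protein_end),
            contig_start = min(b$contig_start), contig_end = max(b$contig_end),
            strand = strand, frame = as.integer(frame),
            raw_score = raw,
            bit_score = raw_to_bits(raw, config$lambda, config$K),
            e_value = evalue_from_raw(raw, m, n, config$lambda, config$K),
            blocks = list(block_tbl(b$contig_start, b$contig_end,
                                    b$protein_start, b$protein_end,
                                    b$raw_score)))
        }
      }
    }
  }
  if (length(rows) == 0) empty_hits() else dplyr::bind_rows(rows)
}

# Uncovered protein segments (>= MIN_REFINE_SEGMENT aa) given covered,
# sorted blocks; each with the contig window to search next.
refine_targets <- function(blocks, strand, plen, clen, flank) {
  b <- blocks[order(blocks$protein_start), ]
  targets <- list()
  add <- function(p0, p1, c0, c1) {
    c0 <- max(0L, c0); c1 <- min(clen, c1)
    if (p1 - p0 >= MIN_REFINE_SEGMENT && c1 > c0) {
      targets[[length(targets) + 1L]] <<- list(p0 = p0, p1 = p1, c0 = c0, c1 = c1)
    }
  }
  k <- nrow(b)
  if (strand == "+") {
    add(0L, b$protein_start[1], b$contig_start[1] - flank, b$contig_start[1])
    if (k > 1) for (i in seq_len(k - 1)) {
      add(b$protein_end[i], b$protein_start[i + 1],
          b$contig_end[i], b$contig_start[i + 1])
    }
    add(b$protein_end[k], plen, b$contig_end[k], b$contig_end[k] + flank)
  } else {
    add(0L, b$protein_start[1], b$contig_end[1], b$contig_end[1] + flank)
    if (k > 1) for (i in seq_len(k - 1)) {
      add(b$protein_end[i], b$protein_start[i + 1],
          b$contig_end[i + 1], b$contig_start[i])
    }
    add(b$protein_end[k], plen, b$contig_start[k] - flank, b$contig_start[k])
  }
  targets
}

#' Iteratively refine a protein-to-contig mapping
#'
#' Starting from seed hits (all on one protein/contig/strand), keeps the
#' highest-scoring colinear chain of their blocks, then repeatedly aligns the
#' still-unmatched protein remainder against the contig regions flanking the
#' current blocks (up to `flank_window` nt) until an iteration adds no block.
#' Crossing seed blocks are resolved by dynamic-programming chain selection.
#'
#' @param protein,contig Single-row sequence tibbles.
#' @param seed_hits Hit tibble rows for one protein/contig/strand.
#' @param config An [aligner_config()].
#' @return A single-row mapping tibble (same shape as a hit) whose blocks
#'   are the merged, strictly colinear union.
#' @export
iterative_refine <- function(protein, contig, seed_hits,
                             config = aligner_config()) {
  stopifnot(nrow(seed_hits) >= 1,
            length(unique(seed_hits$strand)) == 1,
            length(unique(seed_hits$protein_id)) == 1,
            length(unique(seed_hits$contig_id)) == 1)
  strand <- seed_hits$strand[1]
  blocks <- dplyr::bind_rows(seed_hits$blocks)
  blocks <- dplyr::distinct(blocks)
  keep <- chain_blocks(blocks, strand)
  if (length(keep) < nrow(blocks)) {
    warn(sprintf("dropped %d crossing seed block(s) for %s on %s",
                 nrow(blocks) - length(keep),
                 seed_hits$protein_id[1], seed_hits$contig_id[1]))
  }
  blocks <- blocks[keep, , drop = FALSE]
  plen <- nchar(protein$seq[1]); clen <- nchar(contig$seq[1])
  for (iter in seq_len(25L)) {
    added <- FALSE
    targets <- refine_targets(blocks, strand, plen, clen, config$flank_window)
    for (tg in targets) {
      pseg <- substr(protein$seq[1], tg$p0 + 1L, tg$p1)
      cseg <- substr(contig$seq[1], tg$c0 + 1L, tg$c1)
      nb <- align_frames(pseg, cseg, strand, config)
      if (is.null(nb)) next
      nb$protein_start <- nb$protein_start + tg$p0
      nb$protein_end <- nb$protein_end + tg$p0
      nb$contig_start <- nb$contig_start + tg$c0
      nb$contig_end <- nb$contig_end + tg$c0
      cand <- rbind(
        blocks[, c("contig_start", "contig_end", "protein_start",
                   "protein_end", "raw_score")],
        nb[, c("contig_start", "contig_end", "protein_start",
               "protein_end", "raw_score")])
      keep <- chain_blocks(cand, strand)
      new_blocks <- cand[keep, , drop = FALSE]
      if (sum(new_blocks$raw_score) > sum(blocks$raw_score) + 1e-9) {
        blocks <- new_blocks
        added <- TRUE
      }
    }
    if (!added) break
  }
  blocks <- blocks[order(blocks$protein_start), ]
  raw <- sum(blocks$raw_score)
  tibble(
    protein_id = seed_hits$protein_id[1], contig_id = seed_hits$contig_id[1],
    protein_start = min(blocks$protein_start),
    protein_end = max(blocks$protein_end),
    contig_start = min(blocks$contig_start),
    contig_end = max(blocks$contig_end),
    strand = strand, frame = seed_hits$frame[1],
    raw_score = raw,
    bit_score = raw_to_bits(raw, config$lambda, config$K),
    e_value = evalue_from_raw(raw, plen, clen, config$lambda, config$K),
    blocks = list(block_tbl(blocks$contig_start, blocks$contig_end,
                            blocks$protein_start, blocks$protein_end,
                            blocks$raw_score)))
}

#' Refine all hits into per-(protein, contig, strand) mappings
#'
#' Groups filtered hits and applies [iterative_refine()] to each group.
#'
#' @param hits Hit tibble.
#' @param proteins,contigs Sequence tibbles covering every id in `hits`.
#' @param config An [aligner_config()].
#' @return A mapping tibble, one row per (protein, contig, strand).
#' @export
refine_mappings <- function(hits, proteins, contigs,
                            config = aligner_config()) {
  if (nrow(hits) == 0) return(empty_hits())
  pidx <- match(hits$protein_id, proteins$id)
  cidx <- match(hits$contig_id, contigs$id)
  if (anyNA(pidx) || anyNA(cidx)) abort("hit refers to unknown protein or contig id")
  key <- paste(hits$protein_id, hits$contig_id, hits$strand, sep = "\r")
  out <- lapply(split(seq_len(nrow(hits)), key), function(ii) {
    iterative_refine(proteins[pidx[ii[1]], ], contigs[cidx[ii[1]], ],
                     hits[ii, ], config)
  })
  dplyr::bind_rows(out)
}
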