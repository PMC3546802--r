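# Mapping filters, PExR construction, and contig gene models: the refined
# contig-protein orthology model that the scaffolder consumes.

# Single-linkage grouping of half-open intervals under "overlap >= t".
# Returns an integer group id per interval. With intervals sorted by start,
# the earlier member attaining the maximum end maximizes overlap with any
# later interval, so tracking max end gives exact single linkage.
link_intervals <- function(start, end, t) {
  n <- length(start)
  if (n == 0) return(integer(0))
  ord <- order(start, end)
  grp <- integer(n)
  g <- 0L
  max_end <- -Inf
  for (i in ord) {
    if (min(end[i], max_end) - start[i] >= t) {
      grp[i] <- g
    } else {
      g <- g + 1L
      grp[i] <- g
    }
    max_end <- max(max_end, end[i])
  }
  grp
}

#' Two-condition e-value filter on protein-to-contig hits
#'
#' Per guide protein, hits are grouped into protein regions by single linkage
#' over "protein intervals overlap by at least `same_region_overlap_aa`".
#' A hit is retained iff (i) its e-value is at most `max_evalue` and (ii) its
#' e-value is within `10^evalue_window_orders` of the most significant hit in
#' its protein region.
#'
#' @param hits Hit tibble.
#' @param config A [filter_config()].
#' @return The retained subset of `hits`.
#' @export
filter_hits <- function(hits, config = filter_config()) {
  if (nrow(hits) == 0) return(hits)
  keep <- logical(nrow(hits))
  for (ii in split(seq_len(nrow(hits)), hits$protein_id)) {
    grp <- link_intervals(hits$protein_start[ii], hits$protein_end[ii],
                          config$same_region_overlap_aa)
    for (jj in split(ii, grp)) {
      best <- min(hits$e_value[jj])
      keep[jj] <- hits$e_value[jj] <= config$max_evalue &
        hits$e_value[jj] <= best * 10^config$evalue_window_orders
    }
  }
  hits[keep, ]
}

#' Build putative exonic regions (PExRs) from refined mappings
#'
#' A PExR is a maximal contig interval in which every base is covered by at
#' least one protein mapping block; the union of all block intervals on a
#' contig is decomposed into maximal contiguous runs. Each PExR records the
#' proteins whose blocks intersect it.
#'
#' @param mappings Mapping tibble (hits with `blocks` list-columns).
#' @return A tibble with `pexr_id`, `contig_id`, `start`, `end`, `proteins`
#'   (list-column of supporting protein ids).
#' @export
build_pexrs <- function(mappings) {
  if (nrow(mappings) == 0) {
    return(tibble(pexr_id = character(), contig_id = character(),
                  start = integer(), end = integer(), proteins = list()))
  }
  nb <- vapply(mappings$blocks, nrow, integer(1))
  all_blocks <- dplyr::bind_rows(mappings$blocks)
  all_blocks$protein_id <- rep(mappings$protein_id, nb)
  all_blocks$contig_id <- rep(mappings$contig_id, nb)
  out <- list()
  for (cid in unique(mappings$contig_id)) {
    blocks <- all_blocks[all_blocks$contig_id == cid, ]
    ir <- IRanges::IRanges(start = blocks$contig_start + 1L,
                           end = blocks$contig_end)
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(red, ir)
    qh <- S4Vectors::queryHits(ov)
    prot <- blocks$protein_id[S4Vectors::subjectHits(ov)]
    s0 <- IRanges::start(red) - 1L
    e0 <- IRanges::end(red)
    sup <- vector("list", length(red))
    for (i in seq_along(qh)) {
      sup[[qh[i]]] <- c(sup[[qh[i]]], prot[i])
    }
    out[[length(out) + 1L]] <- tibble(
      pexr_id = paste0(cid, ":", s0, "-", e0),
      contig_id = cid, start = s0, end = e0,
      proteins = lapply(sup, unique))
  }
  dplyr::bind_rows(out)
}

#' Build contig gene models from refined mappings and PExRs
#'
#' Each (contig, protein, strand) mapping yields one contig gene model: the
#' ordered set of PExRs its blocks intersect, plus a similarity score that is
#' recomputed from the blocks as BLOSUM62 bit fractions (raw block score
#' times lambda/ln 2), so internally and externally produced alignments score
#' on the same scale. Models of different proteins on one contig whose PExR
#' sets intersect are flagged as competing; resolution is left to the alpha
#' filter in the scaffolder.
#'
#' @param mappings Mapping tibble.
#' @param pexrs PExR tibble from [build_pexrs()].
#' @param config An [aligner_config()] (for the lambda scaling).
#' @return A gene-model tibble: `gene_model_id`, `contig_id`, `protein_id`,
#'   `strand`, `pexr_ids` (list), `protein_start`, `protein_end`,
#'   `similarity_score`, `competing`, `blocks` (list).
#' @export
build_gene_models <- function(mappings, pexrs, config = aligner_config()) {
  if (nrow(mappings) == 0) {
    return(tibble(gene_model_id = character(), contig_id = character(),
                  protein_id = character(), strand = character(),
                  pexr_ids = list(), protein_start = integer(),
                  protein_end = integer(), similarity_score = double(),
                  competing = logical(), blocks = list()))
  }
  rows <- list()
  for (i in seq_len(nrow(mappings))) {
    m <- mappings[i, ]
    b <- m$blocks[[1]]
    px <- pexrs[pexrs$contig_id == m$contig_id, ]
    hit_px <- vapply(seq_len(nrow(px)), function(j) {
      any(interval_overlap(b$contig_start, b$contig_end,
                           px$start[j], px$end[j]) > 0)
    }, logical(1))
    ids <- px$pexr_id[hit_px][order(px$start[hit_px])]
    if (length(ids) == 0) {
      warn(sprintf("mapping %s/%s intersects no PExR; dropped",
                   m$protein_id, m$contig_id))
      next
    }
    rows[[length(rows) + 1L]] <- tibble(
      gene_model_id = paste(m$contig_id, m$protein_id, m$strand, sep = "|"),
      contig_id = m$contig_id, protein_id = m$protein_id, strand = m$strand,
      pexr_ids = list(ids),
      protein_start = m$protein_start, protein_end = m$protein_end,
      similarity_score = raw_to_bit_fraction(sum(b$raw_score), config$lambda),
      competing = FALSE, blocks = m$blocks)
  }
  gm <- dplyr::bind_rows(rows)
  if (nrow(gm) == 0) return(gm)
  # competing: same contig, different protein, PExR sets intersect
  for (cid in unique(gm$contig_id)) {
    ii <- which(gm$contig_id == cid)
    if (length(ii) < 2) next
    for (a in ii) for (b2 in ii) {
      if (a >= b2) next
      if (gm$protein_id[a] == gm$protein_id[b2]) next
      if (length(intersect(gm$pexr_ids[[a]], gm$pexr_ids[[b2]])) > 0) {
        gm$competing[c(a, b2)] <- TRUE
      }
    }
  }
  gm
}
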