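# Internal helpers shared across modules. All coordinates inside the package
# are 0-based half-open on the forward strand; conversion happens only at I/O
# boundaries (BLAST tabular, GFF3, AGP are 1-based inclusive).

#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

the <- new.env(parent = emptyenv())

# Karlin-Altschul parameters for gapped BLOSUM62 search (lambda in nats per
# raw score unit, K dimensionless). Literature values for BLOSUM62 with
# gap open 11 / extend 1; exposed through aligner_config().
KA_LAMBDA <- 0.267
KA_K <- 0.041

blosum62 <- function() {
  if (is.null(the$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    the$blosum62 <- e$BLOSUM62
  }
  the$blosum62
}

#' Raw alignment score to bit score
#'
#' Converts a raw substitution-matrix score to bits using Karlin-Altschul
#' statistics: `S' = (lambda * S - ln K) / ln 2`.
#'
#' @param raw Raw score (matrix units).
#' @param lambda,K Karlin-Altschul parameters.
#' @return Bit score (numeric).
#' @export
raw_to_bits <- function(raw, lambda = KA_LAMBDA, K = KA_K) {
  (lambda * raw - log(K)) / log(2)
}

# Per-column bit contribution used for similarity scores: matrix entry times
# lambda/ln2, additive over blocks (no K offset so scores add over disjoint
# blocks).
raw_to_bit_fraction <- function(raw, lambda = KA_LAMBDA) {
  raw * lambda / log(2)
}

#' E-value of a raw local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with `m` the protein length (aa) and
#' `n` the contig length (nt).
#'
#' @param raw Raw score.
#' @param m,n Search space dimensions.
#' @param lambda,K Karlin-Altschul parameters.
#' @return E-value.
#' @export
evalue_from_raw <- function(raw, m, n, lambda = KA_LAMBDA, K = KA_K) {
  K * m * n * exp(-lambda * raw)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# Translate a nucleotide string in a given frame (0,1,2) of a given strand
# via a cached codon lookup (much cheaper than repeated calls into a fuzzy
# translation). Partial trailing codons are dropped; codons containing N
# (scaffold gap runs) become X.
translate_frame <- function(seq, strand = "+", frame = 0L) {
  if (is.null(the$codon_map)) {
    gc <- Biostrings::GENETIC_CODE
    the$codon_map <- stats::setNames(unname(gc), names(gc))
  }
  s <- if (strand == "-") revcomp(seq) else seq
  n <- nchar(s)
  len <- ((n - frame) %/% 3L) * 3L
  if (len < 3L) return("")
  starts <- seq.int(frame + 1L, frame + len - 2L, by = 3L)
  codons <- substring(s, starts, starts + 2L)
  aa <- the$codon_map[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Map an amino-acid interval [aa_start, aa_end) within a frame translation
# back to 0-based half-open forward-strand nucleotide coordinates on the
# original sequence of length n.
frame_aa_to_nt <- function(aa_start, aa_end, strand, frame, n) {
  if (strand == "+") {
    c(frame + 3L * aa_start, frame + 3L * aa_end)
  } else {
    c(n - frame - 3L * aa_end, n - frame - 3L * aa_start)
  }
}

# Overlap length of two half-open intervals.
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# k-mer set of a protein string (used only to prescreen candidate
# protein/frame pairs before running the Smith-Waterman aligner).
aa_kmers <- function(seq, k = 5L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1L), seq(k, n)))
}

# Highest-scoring colinear chain over candidate blocks (weighted LIS-style
# dynamic programme). Blocks must not cross in either coordinate system;
# on "-" strand increasing protein coordinate pairs with decreasing
# forward-strand contig coordinate. Returns row indices of the chain.
chain_blocks <- function(blocks, strand) {
  nb <- nrow(blocks)
  if (nb == 0L) return(integer(0))
  ord <- order(blocks$protein_start, blocks$protein_end)
  b <- blocks[ord, ]
  best <- b$raw_score
  prev <- rep(NA_integer_, nb)
  compatible <- function(i, j) { # j after i?
    if (b$protein_start[j] < b$protein_end[i]) return(FALSE)
    if (strand == "+") b$contig_start[j] >= b$contig_end[i]
    else b$contig_end[j] <= b$contig_start[i]
  }
  for (j in seq_len(nb)) {
    for (i in seq_len(j - 1L)) {
      if (compatible(i, j) && best[i] + b$raw_score[j] > best[j]) {
        best[j] <- best[i] + b$raw_score[j]
        prev[j] <- i
      }
    }
  }
  end <- which.max(best)
  chain <- integer(0)
  while (!is.na(end)) {
    chain <- c(end, chain)
    end <- prev[end]
  }
  ord[chain]
}
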