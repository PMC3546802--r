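# Synthetic data with known truth: a toy eukaryote-like reference with
# multi-exon genes on both strands, fragmentation into contigs that split
# genes across boundaries, and guide proteomes derived from the true
# proteins under a BLOSUM62-compatible substitution process, optionally with
# injected paralogs. Read simulation and assembly are not emulated: the
# algorithm's inputs begin at contigs, so fragmentation is applied directly.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

codon_table <- function() {
  if (is.null(the$codons)) {
    gc <- Biostrings::GENETIC_CODE
    the$codons <- split(names(gc), unname(gc))
  }
  the$codons
}

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE), collapse = "")

back_translate <- function(protein) {
  ct <- codon_table()
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) sample(ct[[a]], 1L), character(1)), collapse = "")
}

random_nt <- function(len) {
  if (len == 0) return("")
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Mutate a protein: each site substituted with probability `divergence`;
# the replacement residue is drawn with probability proportional to
# exp(BLOSUM62 score / 2), excluding identity, keeping the process
# compatible with the scoring matrix.
mutate_protein <- function(protein, divergence) {
  if (divergence == 0) return(protein)
  aa <- strsplit(protein, "")[[1]]
  m <- blosum62()[AA20, AA20]
  hit <- which(stats::runif(length(aa)) < divergence)
  for (i in hit) {
    w <- exp(m[aa[i], ] / 2)
    w[aa[i]] <- 0
    aa[i] <- sample(AA20, 1L, prob = w)
  }
  paste(aa, collapse = "")
}

rint <- function(rng, n = 1L) {
  if (rng[1] == rng[2]) rep(rng[1], n) else sample(rng[1]:rng[2], n, replace = TRUE)
}

#' Simulate a toy reference genome with known gene structure
#'
#' Genes with the configured exon/intron structure are placed on both
#' strands, separated by intergenic sequence; proteins are exact translations
#' of the concatenated exons (coding sequence is generated by
#' back-translation of a random protein, so no internal stop codons arise).
#' Paralogs are injected per `paralog_rate`: duplicated gene copies inserted
#' elsewhere in the genome, whose proteins diverge slightly from the
#' original's.
#'
#' @param config A [sim_config()].
#' @return A list: `reference` (one-row sequence tibble), `genes` (truth
#'   tibble with `gene_id`, `protein_id`, `family_id`, `copy`, `strand`,
#'   `ref_start`, `ref_end`, `exons` list-column, `protein`,
#'   `in_guide_proteome`), `proteins` (true-protein sequence tibble).
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  if (config$exon_len[1] < 3) abort("exons must be at least one codon")
  gene_list <- list()
  for (g in seq_len(config$n_genes)) {
    n_ex <- rint(config$exons_per_gene)
    ex_len <- rint(config$exon_len, n_ex)
    excess <- sum(ex_len) %% 3L
    ex_len[n_ex] <- ex_len[n_ex] - excess
    prot <- random_protein(sum(ex_len) %/% 3L)
    cds <- back_translate(prot)
    gene_list[[g]] <- list(
      gene_id = sprintf("gene_%03d", g), family_id = sprintf("fam_%03d", g),
      copy = "original", protein = prot, ex_len = ex_len,
      in_guide = TRUE, cds = cds)
  }
  n_dup <- floor(config$paralog_rate * config$n_genes)
  if (n_dup > 0) {
    dup_src <- sample(seq_len(config$n_genes), n_dup)
    for (k in seq_along(dup_src)) {
      src <- gene_list[[dup_src[k]]]
      prot <- mutate_protein(src$protein, 0.05)
      gene_list[[length(gene_list) + 1L]] <- list(
        gene_id = sprintf("gene_%03dd", dup_src[k]), family_id = src$family_id,
        copy = "duplicate", protein = prot, ex_len = src$ex_len,
        in_guide = !config$inparalog, cds = back_translate(prot))
    }
  }
  gene_list <- gene_list[sample(seq_along(gene_list))]
  seq_parts <- list()
  pos <- 0L
  rows <- list()
  for (g in gene_list) {
    ig <- random_nt(rint(config$intergenic_len))
    seq_parts[[length(seq_parts) + 1L]] <- ig
    pos <- pos + nchar(ig)
    n_ex <- length(g$ex_len)
    introns <- if (n_ex > 1) rint(config$intron_len, n_ex - 1L) else integer(0)
    pieces <- character(0)
    exon_coords <- matrix(0L, nrow = n_ex, ncol = 2)
    cpos <- 0L  # within-gene offset
    coff <- 0L  # within-cds offset
    for (e in seq_len(n_ex)) {
      exon_coords[e, ] <- c(cpos, cpos + g$ex_len[e])
      pieces <- c(pieces, substr(g$cds, coff + 1L, coff + g$ex_len[e]))
      coff <- coff + g$ex_len[e]
      cpos <- cpos + g$ex_len[e]
      if (e < n_ex) {
        pieces <- c(pieces, random_nt(introns[e]))
        cpos <- cpos + introns[e]
      }
    }
    gene_nt <- paste(pieces, collapse = "")
    strand <- sample(c("+", "-"), 1L)
    glen <- nchar(gene_nt)
    if (strand == "-") {
      gene_nt <- revcomp(gene_nt)
      exon_coords <- cbind(glen - exon_coords[, 2], glen - exon_coords[, 1])
      exon_coords <- exon_coords[rev(seq_len(n_ex)), , drop = FALSE]
    }
    seq_parts[[length(seq_parts) + 1L]] <- gene_nt
    rows[[length(rows) + 1L]] <- tibble(
      gene_id = g$gene_id, protein_id = paste0("P_", g$gene_id),
      family_id = g$family_id, copy = g$copy, strand = strand,
      ref_start = pos, ref_end = pos + glen,
      exons = list(tibble(start = pos + exon_coords[, 1],
                          end = pos + exon_coords[, 2])),
      protein = g$protein, in_guide_proteome = g$in_guide)
    pos <- pos + glen
  }
  seq_parts[[length(seq_parts) + 1L]] <- random_nt(rint(config$intergenic_len))
  reference <- tibble(id = "ref_1",
                      seq = paste(unlist(seq_parts), collapse = ""),
                      kind = "nucleotide")
  genes <- dplyr::bind_rows(rows)
  proteins <- tibble(id = genes$protein_id, seq = genes$protein,
                     kind = "protein")
  list(reference = reference, genes = genes, proteins = proteins)
}

#' Fragment a reference into contigs and derive a diverged guide proteome
#'
#' The reference is cut at random breakpoints into contigs with lengths drawn
#' from `contig_len` (so some breakpoints fall inside exons and split genes
#' across contigs); each contig is randomly reverse-complemented. The guide
#' proteome contains every gene flagged `in_guide_proteome`, mutated at
#' `protein_divergence` under the BLOSUM62-compatible substitution process.
#'
#' @param genome Result of [simulate_genome()].
#' @param config The same [sim_config()].
#' @return A list: `contigs` (sequence tibble), `guide_proteins` (sequence
#'   tibble, ids `guide_<protein_id>`), `truth` (placement tibble as in
#'   [read_truth_table()]), `genes` (the truth gene tibble with a
#'   `guide_id` column).
#' @export
fragment_and_diverge <- function(genome, config = sim_config()) {
  set.seed(config$seed + 1000003L)
  ref <- genome$reference$seq[1]
  n <- nchar(ref)
  cuts <- integer(0)
  pos <- 0L
  while (pos < n) {
    len <- min(rint(config$contig_len), n - pos)
    cuts <- c(cuts, pos + len)
    pos <- pos + len
  }
  starts <- c(0L, utils::head(cuts, -1L))
  ends <- cuts
  flip <- sample(c(TRUE, FALSE), length(starts), replace = TRUE)
  contigs <- tibble(
    id = sprintf("contig_%04d", seq_along(starts)),
    seq = vapply(seq_along(starts), function(i) {
      s <- substr(ref, starts[i] + 1L, ends[i])
      if (flip[i]) revcomp(s) else s
    }, character(1)),
    kind = "nucleotide")
  truth <- tibble(contig_id = contigs$id, reference_id = genome$reference$id[1],
                  ref_start = starts, ref_end = ends,
                  strand = ifelse(flip, "-", "+"))
  genes <- genome$genes
  genes$guide_id <- ifelse(genes$in_guide_proteome,
                           paste0("guide_", genes$protein_id), NA_character_)
  gg <- genes[genes$in_guide_proteome, ]
  guide <- tibble(
    id = gg$guide_id,
    seq = vapply(gg$protein, mutate_protein, character(1),
                 divergence = config$protein_divergence, USE.NAMES = FALSE),
    kind = "protein")
  list(contigs = contigs, guide_proteins = guide, truth = truth, genes = genes)
}

#' One-call synthetic benchmark instance
#'
#' Runs [simulate_genome()] and [fragment_and_diverge()].
#'
#' @param config A [sim_config()].
#' @return Combined list: `reference`, `genes`, `proteins`, `contigs`,
#'   `guide_proteins`, `truth`.
#' @export
simulate_assembly <- function(config = sim_config()) {
  g <- simulate_genome(config)
  f <- fragment_and_diverge(g, config)
  list(reference = g$reference, genes = f$genes, proteins = g$proteins,
       contigs = f$contigs, guide_proteins = f$guide_proteins,
       truth = f$truth)
}
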