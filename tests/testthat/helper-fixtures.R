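# Fixture builders: deterministic toy sequences and hand-made tibbles.

# Deterministic back-translation (first codon of each amino acid).
bt1 <- local({
  gc <- Biostrings::GENETIC_CODE
  map <- vapply(split(names(gc), unname(gc)), `[`, character(1), 1)
  function(protein) {
    paste(map[strsplit(protein, "")[[1]]], collapse = "")
  }
})

rand_protein <- function(len) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

rand_nt <- function(len) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                               collapse = "")

seq_row <- function(id, seq, kind) tibble::tibble(id = id, seq = seq, kind = kind)

revcomp1 <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Hand-made gene model row for scaffolder tests.
make_gm <- function(contig, protein, strand = "+", pexr_ids = character(0),
                    p0 = 0L, p1 = 100L, score = 100) {
  tibble::tibble(
    gene_model_id = paste(contig, protein, strand, sep = "|"),
    contig_id = contig, protein_id = protein, strand = strand,
    pexr_ids = list(pexr_ids), protein_start = as.integer(p0),
    protein_end = as.integer(p1), similarity_score = score,
    competing = FALSE,
    blocks = list(tibble::tibble(contig_start = 0L, contig_end = 3L * (p1 - p0),
                                 protein_start = as.integer(p0),
                                 protein_end = as.integer(p1),
                                 raw_score = score)))
}

# Cluster tibble from a list of member data.frames (id, score).
make_clusters <- function(member_list) {
  rows <- lapply(seq_along(member_list), function(i) {
    m <- member_list[[i]]
    tibble::tibble(
      cluster_id = i, protein_start = (i - 1L) * 100L,
      protein_end = i * 100L - 10L,
      members = list(tibble::tibble(gene_model_id = m$id,
                                    contig_id = paste0("c_", m$id),
                                    strand = "+", score = m$score)))
  })
  dplyr::bind_rows(rows)
}

# Hand-made scaffold tibble.
make_scaffold <- function(sid, contigs, orientations = NULL,
                          protein = "P") {
  if (is.null(orientations)) orientations <- rep("+", length(contigs))
  tibble::tibble(scaffold_id = sid, position = seq_along(contigs),
                 contig_id = contigs, orientation = orientations,
                 gene_model_id = paste0(contigs, "|", protein, "|+"),
                 protein_id = protein)
}

# Hand-made hit row (single block).
make_hit <- function(protein, contig, p0, p1, c0, c1, strand = "+",
                     evalue = 1e-20, bits = 60, raw = NULL) {
  if (is.null(raw)) raw <- (bits * log(2) + log(0.041)) / 0.267
  tibble::tibble(
    protein_id = protein, contig_id = contig,
    protein_start = as.integer(p0), protein_end = as.integer(p1),
    contig_start = as.integer(c0), contig_end = as.integer(c1),
    strand = strand, frame = 0L, raw_score = raw, bit_score = bits,
    e_value = evalue,
    blocks = list(tibble::tibble(contig_start = as.integer(c0),
                                 contig_end = as.integer(c1),
                                 protein_start = as.integer(p0),
                                 protein_end = as.integer(p1),
                                 raw_score = raw)))
}

# Benchmark runs shared by the end-to-end acceptance blocks; computed once
# per test session on first use.
benchmark_runs <- local({
  cache <- NULL
  function(n_seeds = 10) {
    if (!is.null(cache)) return(cache)
    runs <- lapply(seq_len(n_seeds), function(s) {
      sim <- simulate_assembly(sim_config(n_genes = 50, seed = 100 + s))
      run <- suppressWarnings(run_pipeline(sim$contigs, sim$guide_proteins))
      list(sim = sim, run = run,
           acc = evaluate_run(run, sim$truth))
    })
    cache <<- runs
    runs
  }
})
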