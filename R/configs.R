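# Configuration constructors. Defaults follow the published method where it
# states a value (alpha = 0.75, beta = 0.5, e-value window of five orders of
# magnitude, 15 aa protein-region overlap, 15 nt contig cluster overlap,
# 100 kb evaluation separation); everything else is a documented choice.

#' Aligner configuration
#'
#' Parameters of the built-in translated protein-to-contig aligner.
#'
#' @param substitution_matrix Substitution matrix name (only `"BLOSUM62"` is
#'   shipped; similarity scores throughout the package are BLOSUM62 bits).
#' @param gap_open,gap_extend Positive gap penalties in raw matrix units
#'   (BLAST-style 11/1 defaults).
#' @param min_block_score Minimum bit score for a retained alignment block.
#' @param flank_window Nucleotides of contig flank re-searched on each
#'   refinement iteration.
#' @param max_block_gap Largest within-alignment gap (residues, either
#'   coordinate system in aa units) bridged inside one block; larger gaps
#'   (introns) split the alignment into separate blocks.
#' @param lambda,K Karlin-Altschul parameters used to express raw scores in
#'   bits and to compute e-values.
#' @return A list of class `aligner_config`.
#' @export
aligner_config <- function(substitution_matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1,
                           min_block_score = 20,
                           flank_window = 10000L,
                           max_block_gap = 10L,
                           lambda = KA_LAMBDA, K = KA_K) {
  stopifnot(gap_open > 0, gap_extend > 0, flank_window > 0)
  if (!identical(substitution_matrix, "BLOSUM62")) {
    abort("only BLOSUM62 is available as substitution matrix")
  }
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 min_block_score = min_block_score,
                 flank_window = as.integer(flank_window),
                 max_block_gap = as.integer(max_block_gap),
                 lambda = lambda, K = K),
            class = "aligner_config")
}

#' Mapping filter configuration
#'
#' Thresholds of the two-condition e-value filter applied to raw hits.
#' A hit is kept iff its e-value is at most `max_evalue` and at most
#' `10^evalue_window_orders` times the best e-value among hits mapping to the
#' same protein region; two hits share a protein region when their protein
#' intervals overlap by at least `same_region_overlap_aa` amino acids
#' (regions formed by single linkage).
#'
#' @param max_evalue Absolute e-value cutoff.
#' @param evalue_window_orders Orders of magnitude allowed above the regional
#'   best e-value.
#' @param same_region_overlap_aa Protein-interval overlap (aa) defining "same
#'   protein region".
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(max_evalue = 1e-5,
                          evalue_window_orders = 5,
                          same_region_overlap_aa = 15L) {
  stopifnot(max_evalue > 0, evalue_window_orders > 0, same_region_overlap_aa > 0)
  structure(list(max_evalue = max_evalue,
                 evalue_window_orders = evalue_window_orders,
                 same_region_overlap_aa = as.integer(same_region_overlap_aa)),
            class = "filter_config")
}

#' Scaffolder configuration
#'
#' @param alpha Ratio threshold uncoupling a contig gene model from proteins
#'   (and from within-cluster competition) when its similarity score falls
#'   below `alpha` times the best competing score. `alpha = 1` keeps only
#'   strict maxima; `alpha = 0` removes nothing.
#' @param beta Fraction of the best path score a path must reach to enter the
#'   maximal-set intersection.
#' @param cluster_overlap_nt Minimum overlap, in nucleotide-equivalent units
#'   on the protein (i.e. aa overlap * 3), for contigs to cluster on a guide
#'   protein. The default 15 nt equals 5 aa.
#' @param min_scaffolding_power Stop greedy selection when the best remaining
#'   model's power (bits) falls below this.
#' @param max_paths Cap on enumerated paths per protein before the
#'   approximation fallback kicks in (clusters trimmed to top 3 members,
#'   then single-best-path scoring).
#' @param literal_beta_rule If `TRUE`, the maximal scaffoldable set is the
#'   literal intersection over all retained non-empty paths; the default
#'   `FALSE` first discards retained paths that are strict subsets of a
#'   higher-scoring retained path (dominance pruning).
#' @return A list of class `scaffolder_config`.
#' @export
scaffolder_config <- function(alpha = 0.75, beta = 0.5,
                              cluster_overlap_nt = 15L,
                              min_scaffolding_power = 0,
                              max_paths = 10000L,
                              literal_beta_rule = FALSE) {
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 1,
            cluster_overlap_nt > 0, max_paths >= 1)
  structure(list(alpha = alpha, beta = beta,
                 cluster_overlap_nt = as.integer(cluster_overlap_nt),
                 min_scaffolding_power = min_scaffolding_power,
                 max_paths = as.integer(max_paths),
                 literal_beta_rule = isTRUE(literal_beta_rule)),
            class = "scaffolder_config")
}

#' Evaluation configuration
#'
#' @param max_separation Maximum reference separation (nt) between adjacent
#'   scaffold components for a join to count as correct. Eukaryotic introns
#'   are rarely over 100 kb; genomes with long introns warrant 200 kb.
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(max_separation = 100000L) {
  stopifnot(max_separation > 0)
  structure(list(max_separation = as.integer(max_separation)),
            class = "eval_config")
}

#' Simulator configuration
#'
#' Defines the synthetic study conditions: a toy eukaryote-like reference
#' with multi-exon genes on both strands, fragmented into contigs that split
#' genes across boundaries, and a guide proteome derived from the true
#' proteins under a BLOSUM62-compatible substitution process, optionally with
#' injected paralogs.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene Integer range (length-2) of exon counts.
#' @param exon_len,intron_len,intergenic_len Integer ranges (nt).
#' @param contig_len Integer range of contig lengths; breakpoints are random,
#'   so some fall inside exons and split genes.
#' @param protein_divergence Expected amino-acid substitutions per site in
#'   the guide proteome relative to the true proteins, in `[0, 1)`.
#' @param paralog_rate Fraction of genes duplicated in the target genome.
#' @param inparalog If `TRUE`, duplicates arise after the target/guide
#'   divergence (the guide proteome carries only the original copy); if
#'   `FALSE`, duplicates are pre-divergence (the guide proteome carries
#'   both copies).
#' @param seed Integer seed; all outputs are deterministic given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 50L,
                       exons_per_gene = c(2L, 4L),
                       exon_len = c(90L, 240L),
                       intron_len = c(60L, 300L),
                       intergenic_len = c(200L, 600L),
                       contig_len = c(250L, 550L),
                       protein_divergence = 0,
                       paralog_rate = 0,
                       inparalog = FALSE,
                       seed = 1L) {
  rng <- function(x) length(x) == 2 && all(x > 0) && x[1] <= x[2]
  stopifnot(n_genes >= 1, rng(exons_per_gene), rng(exon_len), rng(intron_len),
            rng(intergenic_len), rng(contig_len),
            protein_divergence >= 0, protein_divergence < 1,
            paralog_rate >= 0, paralog_rate <= 1)
  if (exon_len[1] < 3) abort("exons must be at least one codon long")
  structure(list(n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 exon_len = as.integer(exon_len),
                 intron_len = as.integer(intron_len),
                 intergenic_len = as.integer(intergenic_len),
                 contig_len = as.integer(contig_len),
                 protein_divergence = protein_divergence,
                 paralog_rate = paralog_rate,
                 inparalog = isTRUE(inparalog),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Pipeline run configuration
#'
#' Aggregates the stage configurations plus output options.
#'
#' @param aligner,filter,scaffolder,eval Stage configs (see
#'   [aligner_config()], [filter_config()], [scaffolder_config()],
#'   [eval_config()]).
#' @param gap_length Fixed scaffold gap placeholder in N (distances between
#'   contigs are not estimated; the sentinel documents that).
#' @return A list of class `run_config`.
#' @export
run_config <- function(aligner = aligner_config(),
                       filter = filter_config(),
                       scaffolder = scaffolder_config(),
                       eval = eval_config(),
                       gap_length = 100L) {
  stopifnot(inherits(aligner, "aligner_config"),
            inherits(filter, "filter_config"),
            inherits(scaffolder, "scaffolder_config"),
            inherits(eval, "eval_config"), gap_length > 0)
  structure(list(aligner = aligner, filter = filter, scaffolder = scaffolder,
                 eval = eval, gap_length = as.integer(gap_length)),
            class = "run_config")
}
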