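# End-to-end driver: align -> filter -> refine -> PExRs -> gene models ->
# greedy protein scaffolds -> super-scaffold merge -> final gene models,
# plus broom-style accessors and output writers.

#' Run the protein-guided scaffolding pipeline
#'
#' @param contigs Contig sequence tibble (see [read_fasta()]).
#' @param proteins Guide proteome sequence tibble.
#' @param config A [run_config()].
#' @param hits Optional precomputed hit tibble (e.g. from
#'   [read_alignment_table()]); skips the built-in aligner when given, but
#'   refinement still re-aligns flanks internally.
#' @param quiet Suppress stage messages.
#' @return An object of class `scaffold_run`: a list with the stage products
#'   (`hits`, `mappings`, `pexrs`, `gene_models`, `committed`, `scaffolds`,
#'   `final_models`), the input tibbles, `conflicts`, and a one-row `summary`
#'   tibble (see [glance.scaffold_run()]).
#' @export
run_pipeline <- function(contigs, proteins, config = run_config(),
                         hits = NULL, quiet = TRUE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  if (is.null(hits)) {
    say("aligning %d proteins against %d contigs", nrow(proteins), nrow(contigs))
    hits <- align_proteome(proteins, contigs, config$aligner)
  }
  say("%d raw hits", nrow(hits))
  fhits <- filter_hits(hits, config$filter)
  say("%d hits after e-value filter", nrow(fhits))
  mappings <- refine_mappings(fhits, proteins, contigs, config$aligner)
  pexrs <- build_pexrs(mappings)
  gene_models <- build_gene_models(mappings, pexrs, config$aligner)
  say("%d mappings, %d PExRs, %d gene models",
      nrow(mappings), nrow(pexrs), nrow(gene_models))
  committed <- greedy_select(gene_models, config$scaffolder)
  say("%d protein scaffold models committed", nrow(committed))
  scaffolds0 <- scaffolds_from_models(committed, gene_models)
  merged <- merge_scaffolds(scaffolds0)
  conflicts <- attr(merged, "conflicts")
  powers <- stats::setNames(committed$power, committed$protein_id)
  scaffolds <- resolve_shared_contigs(merged, powers)
  final_models <- final_gene_models(scaffolds, contigs, proteins, committed,
                                    config$aligner, config$gap_length)
  scaffolded <- unique(scaffolds$contig_id)
  lens_before <- nchar(contigs$seq)
  scaffold_lens <- vapply(split(scaffolds$contig_id, scaffolds$scaffold_id),
                          function(cc) {
                            sum(nchar(contigs$seq[match(cc, contigs$id)])) +
                              config$gap_length * (length(cc) - 1L)
                          }, double(1))
  leftover <- nchar(contigs$seq[!contigs$id %in% scaffolded])
  lens_after <- c(unname(scaffold_lens), leftover)
  n_joins <- sum(pmax(0L, table(scaffolds$scaffold_id) - 1L))
  summary <- tibble(
    n_contigs = nrow(contigs), n_proteins = nrow(proteins),
    n_hits = nrow(hits), n_gene_models = nrow(gene_models),
    n_committed_models = nrow(committed),
    n_scaffolds = length(scaffold_lens), n_scaffolded_contigs = length(scaffolded),
    n_joins = as.integer(n_joins),
    n_sequences_after = length(lens_after),
    n50_before = if (nrow(contigs)) n50(lens_before) else NA_real_,
    n50_after = if (length(lens_after)) n50(lens_after) else NA_real_,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  say("N50 %s -> %s", summary$n50_before, summary$n50_after)
  structure(list(contigs = contigs, proteins = proteins, hits = hits,
                 filtered_hits = fhits, mappings = mappings, pexrs = pexrs,
                 gene_models = gene_models, committed = committed,
                 scaffolds = scaffolds, conflicts = conflicts,
                 final_models = final_models, summary = summary,
                 config = config),
            class = "scaffold_run")
}

#' @export
print.scaffold_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<scaffold_run> %d contigs + %d guide proteins\n",
              s$n_contigs, s$n_proteins))
  cat(sprintf("  %d gene models -> %d committed protein models\n",
              s$n_gene_models, s$n_committed_models))
  cat(sprintf("  %d scaffolds (%d contigs joined, %d joins)\n",
              s$n_scaffolds, s$n_scaffolded_contigs, s$n_joins))
  cat(sprintf("  N50 %s -> %s\n", s$n50_before, s$n50_after))
  invisible(x)
}

#' Tidy a scaffold run
#'
#' One row per scaffold component, with orientation and provenance.
#'
#' @param x A `scaffold_run`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy scaffold_run
#' @export
tidy.scaffold_run <- function(x, ...) {
  as_tibble(x$scaffolds)
}

#' Glance at a scaffold run
#'
#' @param x A `scaffold_run`.
#' @param ... Unused.
#' @return The one-row summary tibble (contig/protein counts, committed
#'   models, scaffolds, N50 before/after).
#' @method glance scaffold_run
#' @export
glance.scaffold_run <- function(x, ...) {
  x$summary
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a scaffold run
#'
#' Cumulative assembly-length curves (sequences sorted longest first) before
#' and after scaffolding; the x-position where each curve crosses half the
#' total assembly length is its N50.
#'
#' @param object A `scaffold_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot scaffold_run
#' @export
autoplot.scaffold_run <- function(object, ...) {
  before <- sort(nchar(object$contigs$seq), decreasing = TRUE)
  scaffolded <- unique(object$scaffolds$contig_id)
  scaffold_lens <- vapply(
    split(object$scaffolds$contig_id, object$scaffolds$scaffold_id),
    function(cc) {
      sum(nchar(object$contigs$seq[match(cc, object$contigs$id)])) +
        object$config$gap_length * (length(cc) - 1L)
    }, double(1))
  after <- sort(c(unname(scaffold_lens),
                  nchar(object$contigs$seq[!object$contigs$id %in% scaffolded])),
                decreasing = TRUE)
  df <- dplyr::bind_rows(
    tibble(set = "before", idx = seq_along(before), cum = cumsum(before)),
    tibble(set = "after", idx = seq_along(after), cum = cumsum(after)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data$cum,
                                   colour = .data$set)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "sequences (longest first)",
                  y = "cumulative length (nt)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Evaluate a scaffold run against a truth placement table
#'
#' @param run A `scaffold_run`.
#' @param truth Placement tibble (see [read_truth_table()]).
#' @param config An [eval_config()].
#' @return The [scaffold_accuracy()] summary row, extended with the run's
#'   N50 before/after.
#' @export
evaluate_run <- function(run, truth, config = eval_config()) {
  acc <- scaffold_accuracy(run$scaffolds, truth, config)
  out <- dplyr::bind_cols(acc, run$summary[, c("n50_before", "n50_after")])
  attr(out, "joins") <- attr(acc, "joins")
  out
}

#' Write all pipeline products to a directory
#'
#' Writes `scaffolds.fasta` (merged scaffolds plus unscaffolded contigs),
#' `scaffolds.agp`, `gene_models.gff3` and `report.tsv` (per committed
#' protein: scaffold, coverage and score of the final model).
#'
#' @param run A `scaffold_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  built <- scaffold_sequences(run$scaffolds, run$contigs,
                              run$config$gap_length)
  leftover <- run$contigs[!run$contigs$id %in% run$scaffolds$contig_id, ]
  write_fasta(dplyr::bind_rows(built$sequences, leftover),
              file.path(dir, "scaffolds.fasta"))
  lens <- stats::setNames(nchar(run$contigs$seq), run$contigs$id)
  write_agp(run$scaffolds, lens, file.path(dir, "scaffolds.agp"),
            run$config$gap_length)
  write_gff3(run$final_models, file.path(dir, "gene_models.gff3"))
  rep <- run$final_models[, c("scaffold_id", "protein_id", "strand",
                              "score", "fraction_of_protein_covered")]
  utils::write.table(rep, file.path(dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
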