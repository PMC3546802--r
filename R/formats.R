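# I/O for every standard format the pipeline touches. Internal convention is
# 0-based half-open forward-strand coordinates; BLAST tabular, AGP and GFF3
# are converted at these boundaries and nowhere else.

#' Read a FASTA file into a sequence tibble
#'
#' @param path Path to a FASTA file.
#' @param kind `"nucleotide"`, `"protein"` or `"auto"` (guess from alphabet).
#' @return A tibble with columns `id`, `seq`, `kind`. Order of records is
#'   preserved; wrapped sequence lines are concatenated.
#' @export
read_fasta <- function(path, kind = c("auto", "nucleotide", "protein")) {
  kind <- match.arg(kind)
  stopifnot(file.exists(path))
  if (file.size(path) == 0) {
    warn(paste0("empty FASTA file: ", path))
    return(tibble(id = character(), seq = character(), kind = character()))
  }
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", ")))
  }
  seqs <- toupper(as.character(ss))
  k <- if (kind == "auto") {
    vapply(seqs, function(s) {
      if (grepl("^[ACGTN]*$", s)) "nucleotide" else "protein"
    }, character(1), USE.NAMES = FALSE)
  } else rep(kind, length(seqs))
  tibble(id = ids, seq = unname(seqs), kind = k)
}

#' Write a sequence tibble to FASTA
#'
#' @param records Tibble with `id` and `seq` columns.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$seq[i]
    n <- nchar(s)
    starts <- seq(1L, max(n, 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

empty_hits <- function() {
  tibble(protein_id = character(), contig_id = character(),
         protein_start = integer(), protein_end = integer(),
         contig_start = integer(), contig_end = integer(),
         strand = character(), frame = integer(),
         raw_score = double(), bit_score = double(), e_value = double(),
         blocks = list())
}

block_tbl <- function(contig_start, contig_end, protein_start, protein_end,
                      raw_score) {
  tibble(contig_start = as.integer(contig_start),
         contig_end = as.integer(contig_end),
         protein_start = as.integer(protein_start),
         protein_end = as.integer(protein_end),
         raw_score = as.numeric(raw_score))
}

#' Read protein-to-contig hits in BLAST tabular (outfmt 6) dialect
#'
#' Columns: `qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore`, query = protein, 1-based inclusive coordinates.
#' Minus-strand hits are recognised by `sstart > send`. Coordinates are
#' converted to the internal 0-based half-open forward-strand convention.
#' Lines with negative e-value or non-positive bit score are rejected with a
#' warning; otherwise malformed lines raise an error naming the line number.
#'
#' @param path Path to a tab-separated hits file (no header; `#` comments
#'   allowed).
#' @return A hit tibble (one row per hit, single-block `blocks` list-column).
#' @export
read_alignment_table <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(empty_hits())
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t| +")[[1]]
    if (length(f) < 12) {
      abort(sprintf("malformed alignment line %d: expected >= 12 columns, got %d",
                    lineno[i], length(f)))
    }
    num <- suppressWarnings(as.numeric(f[c(7:12)]))
    if (anyNA(num)) {
      abort(sprintf("malformed alignment line %d: non-numeric coordinate/score",
                    lineno[i]))
    }
    qstart <- num[1]; qend <- num[2]; sstart <- num[3]; send <- num[4]
    evalue <- num[5]; bitscore <- num[6]
    if (evalue < 0 || bitscore <= 0) {
      warn(sprintf("rejecting alignment line %d: e-value %g / bit score %g",
                   lineno[i], evalue, bitscore))
      next
    }
    strand <- if (sstart > send) "-" else "+"
    cs <- if (strand == "+") sstart - 1 else send - 1
    ce <- if (strand == "+") send else sstart
    ps <- qstart - 1; pe <- qend
    raw <- (bitscore * log(2) + log(KA_K)) / KA_LAMBDA
    rows[[i]] <- tibble(
      protein_id = f[1], contig_id = f[2],
      protein_start = as.integer(ps), protein_end = as.integer(pe),
      contig_start = as.integer(cs), contig_end = as.integer(ce),
      strand = strand,
      frame = if (strand == "+") as.integer(cs %% 3) else NA_integer_,
      raw_score = raw, bit_score = bitscore, e_value = evalue,
      blocks = list(block_tbl(cs, ce, ps, pe, raw)))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty_hits() else out
}

#' Write hits in BLAST tabular (outfmt 6) dialect
#'
#' Inverse of [read_alignment_table()]; internal coordinates are converted
#' back to 1-based inclusive with `sstart > send` encoding the minus strand.
#'
#' @param hits Hit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_table <- function(hits, path) {
  lines <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (h$strand == "+") { sstart <- h$contig_start + 1; send <- h$contig_end }
    else { sstart <- h$contig_end; send <- h$contig_start + 1 }
    alen <- h$protein_end - h$protein_start
    lines[i] <- paste(h$protein_id, h$contig_id, "100.0", alen, 0, 0,
                      h$protein_start + 1, h$protein_end, sstart, send,
                      format(h$e_value, digits = 6),
                      format(round(h$bit_score, 2), nsmall = 1),
                      sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write scaffolds as AGP v2.1
#'
#' Each scaffold becomes alternating component (`W`) and gap (`N`) lines with
#' 1-based inclusive object coordinates. Gap length is the fixed placeholder
#' used at scaffolding time (contig distances are not estimated).
#'
#' @param scaffolds Scaffold tibble (`scaffold_id`, `position`, `contig_id`,
#'   `orientation`).
#' @param contig_lengths Named integer vector of contig lengths.
#' @param path Output path.
#' @param gap_length Gap placeholder length (nt).
#' @return `path`, invisibly.
#' @export
write_agp <- function(scaffolds, contig_lengths, path, gap_length = 100L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  if (nrow(scaffolds) == 0) return(invisible(path))
  for (sid in unique(scaffolds$scaffold_id)) {
    parts <- dplyr::arrange(scaffolds[scaffolds$scaffold_id == sid, ], .data$position)
    pos <- 0L; part <- 0L
    for (i in seq_len(nrow(parts))) {
      len <- contig_lengths[[parts$contig_id[i]]]
      if (is.null(len) || is.na(len)) {
        abort(paste0("no length known for contig ", parts$contig_id[i]))
      }
      if (i > 1) {
        part <- part + 1L
        writeLines(paste(sid, pos + 1L, pos + gap_length, part, "N",
                         gap_length, "scaffold", "yes", "unspecified",
                         sep = "\t"), con)
        pos <- pos + gap_length
      }
      part <- part + 1L
      writeLines(paste(sid, pos + 1L, pos + len, part, "W",
                       parts$contig_id[i], 1L, len, parts$orientation[i],
                       sep = "\t"), con)
      pos <- pos + len
    }
  }
  invisible(path)
}

#' Write scaffold gene models as GFF3
#'
#' Emits `gene`, `mRNA` and `CDS` features (1-based inclusive, ascending
#' coordinates; biological order on the minus strand is descending as GFF3
#' requires). Phase is derived from cumulative CDS length.
#'
#' @param gene_models Tibble with `scaffold_id`, `protein_id`, `strand` and a
#'   `cds_intervals` list-column of tibbles (`start`, `end`, 0-based
#'   half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(gene_models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(gene_models))) {
    g <- gene_models[i, ]
    cds <- g$cds_intervals[[1]]
    if (is.null(cds) || nrow(cds) == 0) next
    cds <- dplyr::arrange(cds, .data$start)
    gid <- paste0("gene:", g$protein_id, ":", g$scaffold_id)
    mid <- paste0("mRNA:", g$protein_id, ":", g$scaffold_id)
    span <- c(min(cds$start), max(cds$end))
    writeLines(paste(g$scaffold_id, "orthoscaf", "gene", span[1] + 1, span[2],
                     ".", g$strand, ".", paste0("ID=", gid), sep = "\t"), con)
    writeLines(paste(g$scaffold_id, "orthoscaf", "mRNA", span[1] + 1, span[2],
                     ".", g$strand, ".",
                     paste0("ID=", mid, ";Parent=", gid), sep = "\t"), con)
    # phase: number of bases to remove to reach the next codon start, in
    # biological (strand-aware) order
    bio <- if (g$strand == "-") rev(seq_len(nrow(cds))) else seq_len(nrow(cds))
    phase <- integer(nrow(cds))
    acc <- 0L
    for (j in bio) {
      phase[j] <- (3L - (acc %% 3L)) %% 3L
      acc <- acc + (cds$end[j] - cds$start[j])
    }
    for (j in seq_len(nrow(cds))) {
      writeLines(paste(g$scaffold_id, "orthoscaf", "CDS", cds$start[j] + 1,
                       cds$end[j], ".", g$strand, phase[j],
                       paste0("ID=cds:", g$protein_id, ":", g$scaffold_id,
                              ";Parent=", mid), sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a truth placement table
#'
#' Tab-separated with header `contig_id reference_id ref_start ref_end
#' strand`; coordinates 0-based half-open on the reference forward strand,
#' `strand` the orientation of the contig sequence relative to the reference.
#'
#' @param path Path to the TSV.
#' @return A tibble of placements.
#' @export
read_truth_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig_id", "reference_id", "ref_start", "ref_end", "strand")
  if (!all(need %in% names(df))) {
    abort(paste0("truth table must have columns: ", paste(need, collapse = ", ")))
  }
  as_tibble(df[need])
}

#' Write a truth placement table
#'
#' @param truth Placement tibble (see [read_truth_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
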