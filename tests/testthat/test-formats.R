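test_that("read_fasta parses records, preserves order and concatenates wrapped lines", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT"), f)
  rec <- read_fasta(f)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$id, "c1")
  expect_equal(rec$seq, "ACGT")
  expect_equal(rec$kind, "nucleotide")

  long <- paste(rep("ACGTACGTACGT", 10), collapse = "")
  writeLines(c(">w1", substr(long, 1, 60), substr(long, 61, 120), ">w2", "AAA"), f)
  rec <- read_fasta(f)
  expect_equal(nchar(rec$seq[1]), 120)
  expect_equal(rec$id, c("w1", "w2"))
})

test_that("read_fasta rejects duplicate ids by name and warns on empty files", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "AC", ">a", "GG"), f)
  expect_error(read_fasta(f), "a")
  file.create(f)
  expect_warning(rec <- read_fasta(f), "empty")
  expect_equal(nrow(rec), 0)
})

test_that("fasta write/read round-trip is identity", {
  set.seed(11)
  recs <- tibble::tibble(
    id = paste0("s", 1:5),
    seq = vapply(sample(50:200, 5), rand_nt, character(1)),
    kind = "nucleotide")
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, f)
  expect_equal(read_fasta(f), recs)
})

test_that("alignment table converts BLAST 1-based coordinates and infers strand", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "P1\tc1\t100.0\t30\t0\t0\t1\t30\t1\t90\t1e-20\t60.0",
    "P2\tc1\t100.0\t30\t0\t0\t1\t30\t90\t1\t1e-20\t60.0"), f)
  hits <- read_alignment_table(f)
  expect_equal(hits$protein_start, c(0L, 0L))
  expect_equal(hits$protein_end, c(30L, 30L))
  expect_equal(hits$contig_start, c(0L, 0L))
  expect_equal(hits$contig_end, c(90L, 90L))
  expect_equal(hits$strand, c("+", "-"))
})

test_that("alignment table rejects malformed lines with line numbers and bad scores with warnings", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("P1\tc1\t100.0\t30\t0\t0\t1\t30\t1\t90\t1e-20\t60.0",
               "oops\tonly\tthree"), f)
  expect_error(read_alignment_table(f), "line 2")
  writeLines("P1\tc1\t100.0\t30\t0\t0\t1\t30\t1\t90\t1e-20\t0.0", f)
  expect_warning(hits <- read_alignment_table(f), "rejecting")
  expect_equal(nrow(hits), 0)
})

test_that("alignment table round-trips random hits", {
  set.seed(7)
  rows <- lapply(1:100, function(i) {
    p0 <- sample(0:50, 1); plen <- sample(10:60, 1)
    c0 <- sample(0:500, 1)
    make_hit(paste0("P", sample(1:9, 1)), paste0("c", sample(1:9, 1)),
             p0, p0 + plen, c0, c0 + 3 * plen,
             strand = sample(c("+", "-"), 1),
             evalue = 10^-sample(5:40, 1), bits = sample(25:300, 1))
  })
  hits <- dplyr::bind_rows(rows)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_alignment_table(hits, f)
  back <- read_alignment_table(f)
  for (col in c("protein_id", "contig_id", "protein_start", "protein_end",
                "contig_start", "contig_end", "strand")) {
    expect_equal(back[[col]], hits[[col]])
  }
  expect_equal(back$e_value, hits$e_value, tolerance = 1e-6)
  expect_equal(back$bit_score, hits$bit_score, tolerance = 1e-2)
})

test_that("AGP lines account for every base: components, gaps, object span", {
  sc <- make_scaffold("scaf1", c("A", "B"))
  f <- withr::local_tempfile(fileext = ".agp")
  write_agp(sc, c(A = 100L, B = 50L), f, gap_length = 100L)
  lines <- readLines(f)
  expect_equal(lines[1], "##agp-version\t2.1")
  body <- strsplit(lines[-1], "\t")
  expect_equal(length(body), 3)
  expect_equal(vapply(body, `[`, character(1), 5), c("W", "N", "W"))
  expect_equal(as.integer(body[[3]][3]), 250L)
  # object length equals sum of component and gap lengths
  spans <- vapply(body, function(x) as.integer(x[3]) - as.integer(x[2]) + 1L,
                  integer(1))
  expect_equal(sum(spans), 100L + 100L + 50L)
})

test_that("AGP of an empty scaffold set is just the header", {
  f <- withr::local_tempfile(fileext = ".agp")
  write_agp(make_scaffold("x", character(0)), integer(0), f)
  expect_equal(readLines(f), "##agp-version\t2.1")
})

test_that("AGP object length invariant holds on random scaffolds", {
  set.seed(21)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    lens <- stats::setNames(sample(50:400, k), paste0("ct", 1:k))
    sc <- make_scaffold("s1", names(lens),
                        sample(c("+", "-"), k, replace = TRUE))
    f <- withr::local_tempfile(fileext = ".agp")
    write_agp(sc, lens, f, gap_length = 100L)
    body <- strsplit(readLines(f)[-1], "\t")
    object_end <- max(vapply(body, function(x) as.integer(x[3]), integer(1)))
    expect_equal(object_end, sum(lens) + 100L * (k - 1L))
  }
})

test_that("GFF3 output is structurally valid, including minus-strand CDS order", {
  gm <- tibble::tibble(
    scaffold_id = "scaf1", protein_id = "P1", strand = "-",
    cds_intervals = list(tibble::tibble(start = c(10L, 200L),
                                        end = c(100L, 290L))),
    score = 100, fraction_of_protein_covered = 1)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(gm, f)
  lines <- readLines(f)
  expect_equal(lines[1], "##gff-version 3")
  fields <- strsplit(lines[-1], "\t")
  types <- vapply(fields, `[`, character(1), 3)
  expect_equal(types, c("gene", "mRNA", "CDS", "CDS"))
  cds <- fields[types == "CDS"]
  starts <- vapply(cds, function(x) as.integer(x[4]), integer(1))
  ends <- vapply(cds, function(x) as.integer(x[5]), integer(1))
  expect_true(all(diff(starts) > 0))       # ascending file order
  expect_true(all(vapply(cds, `[`, character(1), 7) == "-"))
  expect_true(all(starts <= ends))
  # parent/child links resolve
  attrs <- vapply(fields, `[`, character(1), 9)
  ids <- sub(".*ID=([^;]+).*", "\\1", attrs)
  parents <- sub(".*Parent=([^;]+).*", "\\1", attrs[grepl("Parent=", attrs)])
  expect_true(all(parents %in% ids))
  # parses with an external GFF3 reader
  skip_if_not_installed("rtracklayer")
  gr <- rtracklayer::import(f)
  expect_equal(length(gr), 4L)
})

test_that("truth table round-trips", {
  tr <- tibble::tibble(contig_id = c("c1", "c2"), reference_id = "ref",
                       ref_start = c(0L, 500L), ref_end = c(400L, 900L),
                       strand = c("+", "-"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_truth_table(tr, f)
  expect_equal(read_truth_table(f), tr)
})
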