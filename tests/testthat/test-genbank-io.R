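test_that("coordinate and strand conventions for component sequences", {
  rec <- genome_record("C1", "Org a", label = "Bacteria",
    replicons = list(list(sequence = "AAACGTAA", features = list(
      feature_interval("CDS", c(2, 6), "+")))))
  expect_equal(component_sequences(rec, "CDS"), "ACGT")

  rec <- genome_record("C2", "Org b", label = "Bacteria",
    replicons = list(list(sequence = "AAACGTAA", features = list(
      feature_interval("CDS", c(2, 6), "-")))))
  expect_equal(component_sequences(rec, "CDS"), "ACGT")  # palindromic control

  rec <- genome_record("C3", "Org c", label = "Bacteria",
    replicons = list(list(sequence = "AACCGGTT", features = list(
      feature_interval("tRNA", c(0, 4), "-")))))
  expect_equal(component_sequences(rec, "tRNA"), "GGTT")  # revcomp("AACC")
})

test_that("strand counts count features per strand", {
  rec <- genome_record("S1", "Org d", label = "Bacteria",
    replicons = list(list(sequence = "ACGTACGTACGT", features = list(
      feature_interval("tRNA", c(0, 4), "+"),
      feature_interval("tRNA", c(4, 8), "+"),
      feature_interval("tRNA", c(8, 12), "-")))))
  expect_equal(strand_counts(rec, "tRNA"),
               c(n_plus = 2, n_minus = 1, n_total = 3))
  expect_equal(strand_counts(rec, "ncRNA"),
               c(n_plus = 0, n_minus = 0, n_total = 0))
})

test_that("Bernoulli strand assignment concentrates at its probability", {
  set.seed(31)
  seqlen <- 5000
  strands <- ifelse(runif(10000) < 0.5, "-", "+")
  feats <- lapply(seq_len(10000), function(i)
    feature_interval("tRNA", c(0, 4), strands[i]))
  rec <- genome_record("S2", "Org e", label = "Bacteria",
    replicons = list(list(sequence = strrep("ACGT", seqlen / 4),
                          features = feats)))
  n <- strand_counts(rec, "tRNA")
  expect_equal(n[["n_total"]], n[["n_plus"]] + n[["n_minus"]])
  expect_lt(abs(n[["n_minus"]] / n[["n_total"]] - 0.5), 0.02)
})

test_that("GenBank write/parse round trip is lossless", {
  specs <- tiny_specs()
  set.seed(13)
  rec <- generate_genome(specs$archaea, accession = "RT000001",
                         organism = "Synthetico sp0001")
  path <- file.path(withr::local_tempdir(), "rt.gbk")
  write_genbank(rec, path)
  back <- parse_genbank(path)
  expect_equal(back$accession, rec$accession)
  expect_equal(back$label, rec$label)
  expect_equal(back$replicons[[1]]$sequence, rec$replicons[[1]]$sequence)
  for (k in c("CDS", "rRNA", "tRNA", "ncRNA")) {
    expect_equal(component_sequences(back, k), component_sequences(rec, k))
    expect_equal(strand_counts(back, k), strand_counts(rec, k))
  }
  # parsing is idempotent: write the parsed record again, parse again
  path2 <- file.path(withr::local_tempdir(), "rt2.gbk")
  write_genbank(back, path2)
  expect_equal(parse_genbank(path2)$replicons, back$replicons)
})

test_that("multi-part complement(join(...)) locations are assembled correctly", {
  gb <- c(
    "LOCUS       TWOEXON              40 bp    DNA     linear BCT 01-JAN-2026",
    "DEFINITION  Handus builtus.",
    "ACCESSION   TWOEXON",
    "  ORGANISM  Handus builtus",
    "FEATURES             Location/Qualifiers",
    "     source          1..40",
    "     CDS             complement(join(3..8,13..18))",
    "ORIGIN",
    "        1 aaccggttaa ccggttaacc ggttaaccgg ttaaccggtt",
    "//")
  path <- file.path(withr::local_tempdir(), "twoexon.gbk")
  writeLines(gb, path)
  rec <- parse_genbank(path)
  f <- rec$replicons[[1]]$features[[1]]
  expect_equal(f$kind, "CDS")
  expect_equal(f$strand, "-")
  expect_equal(unname(f$parts), matrix(c(2, 12, 8, 18), 2))
  # genomic parts: [2,8) = "CCGGTT", [12,18) = "GGTTAA"; sense strand is the
  # reverse complement of the concatenation "CCGGTTGGTTAA"
  expect_equal(component_sequences(rec, "CDS"), "TTAACCAACCGG")
})

test_that("records lacking a component or ORIGIN behave as specified", {
  # zero ncRNA features: record parses and validates
  specs <- tiny_specs()
  set.seed(17)
  rec <- generate_genome(specs$bacteria)
  rec$replicons[[1]]$features <- Filter(function(f) f$kind != "ncRNA",
                                        rec$replicons[[1]]$features)
  path <- file.path(withr::local_tempdir(), "noncrna.gbk")
  write_genbank(rec, path)
  back <- parse_genbank(path)
  expect_equal(strand_counts(back, "ncRNA")[["n_total"]], 0)
  expect_error(validate_genome_record(back), NA)

  # missing ORIGIN is a parse error
  bad <- c("LOCUS       BAD              10 bp    DNA     linear BCT 01-JAN-2026",
           "FEATURES             Location/Qualifiers",
           "     source          1..10", "//")
  pb <- file.path(withr::local_tempdir(), "bad.gbk")
  writeLines(bad, pb)
  expect_error(parse_genbank(pb), "ORIGIN")

  # unparseable location: feature skipped with a warning, rest kept
  odd <- c("LOCUS       ODD              12 bp    DNA     linear BCT 01-JAN-2026",
           "ACCESSION   ODD",
           "FEATURES             Location/Qualifiers",
           "     tRNA            1..4",
           "     tRNA            complement(join(1..4,join(5..8)))",
           "ORIGIN",
           "        1 acgtacgtac gt", "//")
  po <- file.path(withr::local_tempdir(), "odd.gbk")
  writeLines(odd, po)
  expect_warning(rec <- parse_genbank(po), "unparseable")
  expect_equal(strand_counts(rec, "tRNA")[["n_total"]], 1)
})

test_that("multi-record files become replicons of one genome record", {
  specs <- tiny_specs()
  set.seed(19)
  r1 <- generate_genome(specs$bacteria, accession = "MR1")
  rec <- genome_record("MR1", "Multus replicus", label = "Bacteria",
                       replicons = c(r1$replicons, r1$replicons))
  path <- file.path(withr::local_tempdir(), "multi.gbk")
  write_genbank(rec, path)
  back <- parse_genbank(path)
  expect_length(back$replicons, 2)
  expect_equal(strand_counts(back, "CDS")[["n_total"]],
               2 * strand_counts(r1, "CDS")[["n_total"]])
  expect_equal(build_feature_vector(back)[["bp_genome_total"]],
               2 * nchar(r1$replicons[[1]]$sequence))
})

test_that("parsed coordinates agree with an independent GenBank reader", {
  py <- Sys.which("python")
  specs <- tiny_specs()
  set.seed(23)
  rec <- generate_genome(specs$archaea, accession = "XV000001")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "xv.gbk")
  write_genbank(rec, path)
  script <- file.path(dir, "read.py")
  writeLines(c(
    "import sys",
    "from Bio import SeqIO",
    "rec = next(SeqIO.parse(sys.argv[1], 'genbank'))",
    "rows = []",
    "for f in rec.features:",
    "    if f.type in ('CDS', 'rRNA', 'tRNA', 'ncRNA'):",
    "        rows.append((f.type, int(f.location.start), int(f.location.end), f.location.strand))",
    "for r in sorted(rows):",
    "    print('%s,%d,%d,%d' % r)",
    "print(str(rec.seq))"), script)
  out <- tryCatch(system2(py, c(script, path), stdout = TRUE, stderr = FALSE),
                  warning = function(w) NULL, error = function(e) NULL)
  expect_false(is.null(out))  # the reference reader must be available and succeed
  seq_py <- out[length(out)]
  expect_equal(seq_py, rec$replicons[[1]]$sequence)
  feats <- rec$replicons[[1]]$features
  mine <- sort(vapply(feats, function(f)
    sprintf("%s,%d,%d,%d", f$kind, f$parts[1, 1], f$parts[1, 2],
            if (f$strand == "+") 1L else -1L), character(1)))
  expect_equal(sort(out[-length(out)]), mine)
})
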