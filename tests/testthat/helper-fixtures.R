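# Small class specs for fast genome generation in tests (worst-case packed
# gene length stays below the minimum genome length).
tiny_spec <- function(label = "Bacteria", parity_skew = 0.02,
                      composition = c(25, 25, 25, 25), ...) {
  class_spec(label = label, composition = composition,
             parity_skew = parity_skew,
             n_genes = list(CDS = c(3, 5), rRNA = c(1, 2),
                            tRNA = c(3, 6), ncRNA = c(1, 3)),
             gene_length = list(CDS = c(300, 600), rRNA = c(400, 800),
                                tRNA = c(70, 90), ncRNA = c(100, 200)),
             genome_length = c(6000, 8000), ...)
}

tiny_specs <- function() {
  list(bacteria = tiny_spec("Bacteria", parity_skew = 0.02,
                            composition = c(25, 25, 25, 25)),
       archaea = tiny_spec("Archaea", parity_skew = 0.15,
                           composition = c(45, 15, 15, 25)))
}

# Brute-force topological-entropy oracle: enumerate the windows of the
# length-(4^n + n - 1) prefix as strings and count distinct ones in a hash.
oracle_topological <- function(seq) {
  L <- nchar(seq)
  n <- 1L
  while (4^(n + 1) + n <= L) n <- n + 1L
  P <- 4^n + n - 1L
  prefix <- substr(seq, 1L, P)
  words <- substring(prefix, 1L:(P - n + 1L), n:P)
  words <- words[!grepl("[^ACGT]", words)]
  log(length(unique(words)), base = 4) / n
}

random_seq <- function(L, p = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p), collapse = "")
}

# Hand-laid-out 68 bp toy genome: CDS(+), tRNA(-), rRNA(+), ncRNA(-), with
# every segment written out literally.
toy_genome <- function(label = "Bacteria") {
  seq <- paste0("AAAATTTT",            # [0,8)   intergenic
                "ATGCATGCATGCATGC",    # [8,24)  CDS +
                "CCGG",                # [24,28) intergenic
                "AAAACCCCGGGGTTTA",    # [28,44) tRNA - (sense TAAACCCCGGGGTTTT)
                "AT",                  # [44,46) intergenic
                "ACGTACGTACGT",        # [46,58) rRNA +
                "AACCGGTT",            # [58,66) ncRNA - (palindromic)
                "GG")                  # [66,68)
  genome_record("TOY00001", "Toyus exemplaris", label = label,
                replicons = list(list(sequence = seq, features = list(
                  feature_interval("CDS", c(8, 24), "+"),
                  feature_interval("tRNA", c(28, 44), "-"),
                  feature_interval("rRNA", c(46, 58), "+"),
                  feature_interval("ncRNA", c(58, 66), "-")))))
}

# independent per-sequence expectations used to cross-check feature vectors
expected_scores <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  cnt <- vapply(c("A", "C", "G", "T"), function(b) sum(ch == b), numeric(1))
  p <- cnt / sum(cnt)
  pp <- p[p > 0]
  skew <- function(x, y) if (x + y == 0) 0 else abs(x - y) / (x + y)
  ratio <- function(x, y) if (max(x, y) == 0) 1 else min(x, y) / max(x, y)
  list(counts = cnt,
       shannon = -sum(pp * log2(pp)),
       topological = oracle_topological(seq),
       pf = skew(cnt[["A"]], cnt[["T"]]) + skew(cnt[["C"]], cnt[["G"]]),
       ct = 0.5 * (ratio(cnt[["A"]], cnt[["T"]]) + ratio(cnt[["C"]], cnt[["G"]])))
}

# minimal genome record with prescribed size and CDS count (filter tests)
sized_record <- function(accession, organism, label, bp, n_cds,
                         with_rnas = TRUE) {
  base <- strrep("ACGT", ceiling(bp / 4))
  seq <- substr(base, 1, bp)
  feats <- lapply(seq_len(n_cds), function(i) feature_interval("CDS", c(0, 12), "+"))
  if (with_rnas)
    feats <- c(feats, list(feature_interval("rRNA", c(0, 12), "+"),
                           feature_interval("tRNA", c(12, 24), "+"),
                           feature_interval("ncRNA", c(24, 36), "-")))
  genome_record(accession, organism, label = label,
                replicons = list(list(sequence = seq, features = feats)))
}
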