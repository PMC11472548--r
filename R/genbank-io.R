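#' Parse a GenBank flat file into a genome record
#'
#' Captures CDS, rRNA, tRNA and ncRNA features with strand and (possibly
#' multi-part) locations; all other feature keys are ignored. Multiple records
#' in one file (chromosome plus plasmids) become multiple replicons of a
#' single genome record. GenBank 1-based inclusive coordinates are converted
#' to the internal 0-based half-open convention on entry.
#'
#' @param path Path to a GenBank flat file with at least one record.
#' @return A [genome_record()].
#' @export
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop(sprintf("empty GenBank file: %s", path))
  ends <- grep("^//\\s*$", lines)
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  accession <- organism <- label <- NULL
  replicons <- list()
  for (i in seq_along(starts)) {
    block <- lines[starts[i]:ends[i]]
    if (!any(grepl("^LOCUS", block))) next
    rep <- parse_genbank_block(block, path)
    if (is.null(accession)) accession <- rep$accession
    if (is.null(organism) && !is.null(rep$organism)) organism <- rep$organism
    if (is.null(label) && !is.null(rep$label)) label <- rep$label
    replicons[[length(replicons) + 1L]] <-
      list(sequence = rep$sequence, features = rep$features)
  }
  if (!length(replicons)) stop(sprintf("no GenBank records found in %s", path))
  genome_record(accession = accession,
                organism = if (is.null(organism)) accession else organism,
                replicons = replicons, label = label)
}

parse_genbank_block <- function(block, path) {
  locus <- grep("^LOCUS", block, value = TRUE)[1]
  accession <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]][1]
  acc_line <- grep("^ACCESSION", block, value = TRUE)
  if (length(acc_line)) {
    acc <- strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]][1]
    if (!is.na(acc) && nzchar(acc)) accession <- acc
  }
  organism <- NULL
  org_line <- grep("^\\s{2}ORGANISM", block, value = TRUE)
  if (length(org_line)) organism <- trimws(sub("^\\s{2}ORGANISM", "", org_line[1]))
  def_line <- grep("^DEFINITION", block, value = TRUE)
  if (is.null(organism) && length(def_line))
    organism <- trimws(sub("\\.?$", "", sub("^DEFINITION", "", def_line[1])))

  fstart <- grep("^FEATURES", block)
  ostart <- grep("^ORIGIN", block)
  if (!length(ostart)) stop(sprintf("missing ORIGIN sequence in %s", path))

  label <- NULL
  features <- list()
  if (length(fstart)) {
    ftab <- block[(fstart[1] + 1L):(ostart[1] - 1L)]
    # feature headers: 5-space indent, key, location (may wrap onto 21-space lines)
    hdr <- grep("^ {5}\\S", ftab)
    for (j in seq_along(hdr)) {
      line <- ftab[hdr[j]]
      key <- sub("^ {5}(\\S+).*$", "\\1", line)
      to <- if (j < length(hdr)) hdr[j + 1L] - 1L else length(ftab)
      body <- ftab[hdr[j]:to]
      quals <- grep("^ {21}/", body)
      locend <- if (length(quals)) min(quals) - 1L else length(body)
      loc <- paste(c(sub("^ {5}\\S+\\s*", "", body[1]),
                     trimws(body[seq_len(locend)][-1])), collapse = "")
      if (key == "source") {
        lab <- grep("/db_xref=\"taxon_domain:", body, value = TRUE)
        if (length(lab))
          label <- sub("^.*taxon_domain:([^\"]+)\".*$", "\\1", lab[1])
        next
      }
      if (!key %in% COMPONENT_KINDS) next
      f <- tryCatch(parse_location(key, loc), error = function(e) NULL)
      if (is.null(f)) {
        warning(sprintf("skipping %s feature with unparseable location '%s' in %s",
                        key, loc, path), call. = FALSE)
      } else {
        features[[length(features) + 1L]] <- f
      }
    }
  }

  oend <- grep("^//\\s*$", block)
  oend <- if (length(oend)) oend[1] - 1L else length(block)
  seqlines <- block[(ostart[1] + 1L):oend]
  sequence <- toupper(gsub("[0-9 \t]", "", paste(seqlines, collapse = "")))
  if (!nzchar(sequence)) stop(sprintf("missing ORIGIN sequence in %s", path))
  list(accession = accession, organism = organism, label = label,
       sequence = sequence, features = features)
}

# "complement(join(12..78,134..202))" etc. -> feature_interval (0-based half-open)
parse_location <- function(kind, loc) {
  loc <- gsub("[ <>]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc)) loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  if (grepl("complement|join|order|\\(|\\)", loc)) stop("nested location not supported")
  parts <- strsplit(loc, ",")[[1]]
  m <- t(vapply(parts, function(p) {
    if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      se <- as.numeric(strsplit(p, "\\.\\.")[[1]])
    } else if (grepl("^[0-9]+$", p)) {
      se <- c(as.numeric(p), as.numeric(p))
    } else stop("bad location element")
    c(se[1] - 1, se[2])  # to 0-based half-open
  }, numeric(2)))
  feature_interval(kind, m, strand)
}

#' Sense-strand sequences of one component kind
#'
#' Returns one string per feature of the kind, in genomic order. Multi-part
#' features are concatenated across parts in annotation order; minus-strand
#' features are returned as the reverse complement of that concatenation
#' (the biological gene sequence).
#'
#' @param record A `genome_record`.
#' @param kind One of CDS, rRNA, tRNA, ncRNA.
#' @return Character vector of sense-strand sequences.
#' @export
component_sequences <- function(record, kind) {
  kind <- match.arg(kind, COMPONENT_KINDS)
  feats <- features_of_kind(record, kind)
  vapply(feats, function(x) {
    seq <- record$replicons[[x$replicon]]$sequence
    f <- x$feature
    s <- paste(apply(f$parts, 1L, function(p) substr(seq, p[1] + 1L, p[2])),
               collapse = "")
    if (f$strand == "-") revcomp(s) else s
  }, character(1))
}

#' Per-strand feature counts of one component kind
#'
#' Counts features (not bases) of the given kind on the plus and minus strand.
#'
#' @param record A `genome_record`.
#' @param kind One of CDS, rRNA, tRNA, ncRNA.
#' @return Named numeric vector (n_plus, n_minus, n_total).
#' @export
strand_counts <- function(record, kind) {
  kind <- match.arg(kind, COMPONENT_KINDS)
  feats <- features_of_kind(record, kind)
  strands <- vapply(feats, function(x) x$feature$strand, character(1))
  n_plus <- sum(strands == "+"); n_minus <- sum(strands == "-")
  c(n_plus = n_plus, n_minus = n_minus, n_total = n_plus + n_minus)
}

#' Write a genome record as a GenBank flat file
#'
#' Emits LOCUS/DEFINITION/ACCESSION/FEATURES/ORIGIN sections with standard
#' `complement(...)`/`join(...)` location syntax, one GenBank record per
#' replicon. The class label, when present, is stored as a
#' `/db_xref="taxon_domain:..."` qualifier on the source feature so that
#' write/parse round trips are lossless.
#'
#' @param record A `genome_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ri in seq_along(record$replicons)) {
    rep <- record$replicons[[ri]]
    L <- nchar(rep$sequence)
    acc <- if (length(record$replicons) > 1L)
      sprintf("%s_R%d", record$accession, ri) else record$accession
    writeLines(sprintf("LOCUS       %-16s %d bp    DNA     circular BCT 01-JAN-2026",
                       acc, L), con)
    writeLines(sprintf("DEFINITION  %s.", record$organism), con)
    writeLines(sprintf("ACCESSION   %s", acc), con)
    writeLines(sprintf("  ORGANISM  %s", record$organism), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", L), con)
    writeLines(sprintf("                     /organism=\"%s\"", record$organism), con)
    if (!is.null(record$label))
      writeLines(sprintf("                     /db_xref=\"taxon_domain:%s\"",
                         record$label), con)
    for (f in rep$features) {
      locs <- apply(f$parts, 1L, function(p) sprintf("%d..%d", p[1] + 1L, p[2]))
      loc <- if (length(locs) > 1L) sprintf("join(%s)", paste(locs, collapse = ",")) else locs
      if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-15s %s", f$kind, loc), con)
    }
    writeLines("ORIGIN", con)
    s <- tolower(rep$sequence)
    pos <- seq(1L, L, by = 60L)
    for (p in pos) {
      chunk <- substr(s, p, min(p + 59L, L))
      groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                          pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
      writeLines(sprintf("%9d %s", p, paste(groups, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}
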