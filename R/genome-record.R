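#' @keywords internal
"_PACKAGE"

COMPONENT_KINDS <- c("CDS", "rRNA", "tRNA", "ncRNA")

#' Reverse complement of a DNA string
#'
#' Ambiguity characters other than A/C/G/T are complemented where IUPAC
#' defines a complement and left unchanged otherwise (N stays N).
#'
#' @param sequence Uppercase DNA string.
#' @return The reverse-complemented string.
#' @export
revcomp <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", sequence)
  intToUtf8(rev(utf8ToInt(comp)))
}

#' Construct a typed, stranded feature interval
#'
#' Coordinates are 0-based half-open internally; GenBank's 1-based inclusive
#' convention is converted at the parse/write boundary.
#'
#' @param kind One of CDS, rRNA, tRNA, ncRNA.
#' @param parts Two-column matrix (start, end), 0-based half-open, one row per
#'   part, in annotation order.
#' @param strand "+" or "-".
#' @return A `feature_interval` object.
#' @export
feature_interval <- function(kind, parts, strand = "+") {
  kind <- match.arg(kind, COMPONENT_KINDS)
  if (is.vector(parts)) parts <- matrix(as.numeric(parts), ncol = 2, byrow = TRUE)
  parts <- matrix(as.numeric(parts), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(parts) < 1L) stop("feature must have at least one part")
  if (any(parts[, 1] >= parts[, 2])) stop("each part must have start < end")
  if (any(parts < 0)) stop("negative coordinates")
  strand <- match.arg(strand, c("+", "-"))
  structure(list(kind = kind, parts = parts, strand = strand),
            class = "feature_interval")
}

#' Construct a genome record
#'
#' One organism's assembled replicon set: identifiers, optional domain label,
#' and per-replicon sequence plus typed feature intervals.
#'
#' @param accession Non-empty accession string.
#' @param organism Organism name.
#' @param replicons List of `list(sequence =, features =)` where `features` is
#'   a list of [feature_interval()] objects.
#' @param label Optional class label (e.g. "Archaea" or "Bacteria").
#' @return A validated `genome_record` object.
#' @export
genome_record <- function(accession, organism, replicons, label = NULL) {
  rec <- structure(list(accession = accession, organism = organism,
                        label = label, replicons = replicons),
                   class = "genome_record")
  validate_genome_record(rec)
  rec
}

#' Validate genome-record invariants
#'
#' Checks accession non-emptiness, uppercase sequences, restricted feature
#' kinds and that every feature part lies within its replicon bounds.
#'
#' @param record A `genome_record`.
#' @return The record, invisibly; stops on violation.
#' @export
validate_genome_record <- function(record) {
  stopifnot(inherits(record, "genome_record"))
  if (!is.character(record$accession) || !nzchar(record$accession))
    stop("accession must be a non-empty string")
  if (length(record$replicons) < 1L) stop("record has no replicons")
  for (rep in record$replicons) {
    seq <- rep$sequence
    if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
      stop("replicon sequence must be a non-empty string")
    if (grepl("[a-z]", seq)) stop("replicon sequence must be uppercase")
    L <- nchar(seq)
    for (f in rep$features) {
      if (!inherits(f, "feature_interval")) stop("features must be feature_interval objects")
      if (any(f$parts[, 2] > L))
        stop(sprintf("feature of kind %s exceeds replicon bounds", f$kind))
    }
  }
  invisible(record)
}

#' @export
print.genome_record <- function(x, ...) {
  nfeat <- vapply(COMPONENT_KINDS, function(k) {
    sum(vapply(x$replicons, function(r) {
      sum(vapply(r$features, function(f) f$kind == k, logical(1)))
    }, numeric(1)))
  }, numeric(1))
  bp <- sum(vapply(x$replicons, function(r) nchar(r$sequence), numeric(1)))
  cat(sprintf("<genome_record> %s (%s)%s\n", x$accession, x$organism,
              if (!is.null(x$label)) paste0(" [", x$label, "]") else ""))
  cat(sprintf("  %d replicon(s), %d bp total\n", length(x$replicons), bp))
  cat(sprintf("  features: %s\n",
              paste(sprintf("%s=%d", names(nfeat), nfeat), collapse = ", ")))
  invisible(x)
}

# genomic-order index of features of one kind across replicons
features_of_kind <- function(record, kind) {
  kind <- match.arg(kind, COMPONENT_KINDS)
  out <- list()
  for (ri in seq_along(record$replicons)) {
    feats <- record$replicons[[ri]]$features
    keep <- vapply(feats, function(f) f$kind == kind, logical(1))
    feats <- feats[keep]
    if (length(feats)) {
      ord <- order(vapply(feats, function(f) min(f$parts[, 1]), numeric(1)))
      for (f in feats[ord]) out[[length(out) + 1L]] <- list(replicon = ri, feature = f)
    }
  }
  out
}
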