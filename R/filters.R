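#' Genome inclusion policy
#'
#' Class-specific minimum genome size and CDS count (defaults are the smallest
#' accepted free-living representatives of each domain: 580,076 bp / 491 CDS
#' for bacteria, 490,885 bp / 493 CDS for archaea; genomes strictly below are
#' removal candidates), required RNA components, and optional one-per-species
#' de-duplication.
#'
#' @param min_bp Named numeric: minimum genome size per class.
#' @param min_cds Named numeric: minimum CDS count per class.
#' @param require_components Gene kinds whose absence excludes a genome.
#' @param dedup_by_species Keep only the longest genome per species.
#' @param size_cds_combination "both": removal requires size AND CDS count
#'   below threshold (the default reading); "either": one suffices.
#' @return A `filter_policy` object.
#' @export
filter_policy <- function(min_bp = c(Bacteria = 580076, Archaea = 490885),
                          min_cds = c(Bacteria = 491, Archaea = 493),
                          require_components = c("rRNA", "tRNA", "ncRNA"),
                          dedup_by_species = TRUE,
                          size_cds_combination = c("both", "either")) {
  stopifnot(all(min_bp > 0), all(min_cds > 0))
  size_cds_combination <- match.arg(size_cds_combination)
  structure(list(min_bp = min_bp, min_cds = min_cds,
                 require_components = require_components,
                 dedup_by_species = dedup_by_species,
                 size_cds_combination = size_cds_combination),
            class = "filter_policy")
}

record_total_bp <- function(record) {
  sum(vapply(record$replicons, function(r) nchar(r$sequence), numeric(1)))
}

species_key <- function(organism) {
  toks <- strsplit(tolower(trimws(organism)), "\\s+")[[1]]
  paste(head(toks, 2L), collapse = " ")
}

#' Apply inclusion/exclusion rules to labelled genome records
#'
#' Rejection reasons are checked in documented order (the first failing one is
#' recorded): `too_small` (class-specific size/CDS rule), then
#' `missing_component:<kind>` for each required component, then
#' `duplicate_species` when de-duplication is on.
#'
#' @param records List of labelled `genome_record` objects.
#' @param policy A [filter_policy()].
#' @return List with `kept` (records) and `rejected` (data.frame accession,
#'   reason).
#' @export
apply_filters <- function(records, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  reasons <- character(length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    if (is.null(rec$label) || is.na(rec$label))
      stop(sprintf("record %s is unlabelled; thresholds are class-specific",
                   rec$accession), call. = FALSE)
    bp <- record_total_bp(rec)
    cds <- unname(strand_counts(rec, "CDS")[["n_total"]])
    small_bp <- bp < policy$min_bp[[rec$label]]
    small_cds <- cds < policy$min_cds[[rec$label]]
    small <- if (policy$size_cds_combination == "both") small_bp && small_cds
             else small_bp || small_cds
    if (small) { reasons[i] <- "too_small"; next }
    miss <- ""
    for (k in policy$require_components) {
      if (strand_counts(rec, k)[["n_total"]] == 0) { miss <- k; break }
    }
    if (nzchar(miss)) reasons[i] <- paste0("missing_component:", miss)
  }
  if (policy$dedup_by_species) {
    pass <- which(reasons == "")
    if (length(pass)) {
      keep <- dedup_longest_per_species(records[pass], index = TRUE)
      dup <- setdiff(seq_along(pass), keep)
      reasons[pass[dup]] <- "duplicate_species"
    }
  }
  kept <- records[reasons == ""]
  rejected <- data.frame(
    accession = vapply(records[reasons != ""], function(r) r$accession, character(1)),
    reason = reasons[reasons != ""], stringsAsFactors = FALSE)
  list(kept = kept, rejected = rejected)
}

#' Keep the longest genome per species
#'
#' The species key is the first two whitespace-delimited tokens of the
#' organism name, lowercased. Among records sharing a key, the one with
#' maximal total bp is retained; ties break to the lexicographically smallest
#' accession.
#'
#' @param records List of `genome_record` objects.
#' @param index Return kept indices instead of records.
#' @return Filtered list (or integer indices, in input order).
#' @export
dedup_longest_per_species <- function(records, index = FALSE) {
  if (!length(records)) return(if (index) integer(0) else records)
  keys <- vapply(records, function(r) species_key(r$organism), character(1))
  bp <- vapply(records, record_total_bp, numeric(1))
  acc <- vapply(records, function(r) r$accession, character(1))
  keep <- integer(0)
  for (k in unique(keys)) {
    idx <- which(keys == k)
    idx <- idx[order(-bp[idx], acc[idx])]
    keep <- c(keep, idx[1])
  }
  keep <- sort(keep)
  if (index) keep else records[keep]
}

#' Write a filter report as delimited text
#'
#' @param filtered Result of [apply_filters()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(filtered, path) {
  kept <- data.frame(
    accession = vapply(filtered$kept, function(r) r$accession, character(1)),
    decision = "kept", reason = "", stringsAsFactors = FALSE)
  rej <- filtered$rejected
  rej$decision <- if (nrow(rej)) "rejected" else character(0)
  rej <- rej[, c("accession", "decision", "reason")]
  utils::write.table(rbind(kept, rej), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
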