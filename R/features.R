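COMPONENT_TOKENS <- c(genome = "genome", CDS = "cds", rRNA = "rRNA",
                      tRNA = "tRNA", ncRNA = "ncRNA")

#' Names of the 77 genomic features, in canonical column order
#'
#' For each of the five components (genome, cds, rRNA, tRNA, ncRNA):
#' `bp_<comp>_total`, `bp_<comp>_{A,T,C,G}`, `fr_<comp>_{A,T,C,G}` (45
#' statistics); for the four gene components: `n_<comp>_{plus,minus,total}`
#' (12 statistics); for all five components: `<comp>_shannon_score`,
#' `<comp>_topological_entropy_score`, `<comp>_chargaff_score_pf`,
#' `<comp>_chargaff_score_ct` (20 scores).
#'
#' @return Character vector of length 77.
#' @export
feature_names <- function() {
  toks <- unname(COMPONENT_TOKENS)
  stats <- unlist(lapply(toks, function(tk)
    c(sprintf("bp_%s_total", tk), sprintf("bp_%s_%s", tk, c("A", "T", "C", "G")),
      sprintf("fr_%s_%s", tk, c("A", "T", "C", "G")))))
  counts <- unlist(lapply(toks[-1], function(tk)
    sprintf("n_%s_%s", tk, c("plus", "minus", "total"))))
  scores <- unlist(lapply(toks, function(tk)
    sprintf("%s_%s", tk, c("shannon_score", "topological_entropy_score",
                           "chargaff_score_pf", "chargaff_score_ct"))))
  c(stats, counts, scores)
}

#' Encode one genome record as the 77-feature vector
#'
#' Per-component nucleotide statistics (totals, counts and relative
#' frequencies over canonical bases), per-strand gene counts, and the four
#' information scores per component. Component sequences are the genomic-order
#' concatenation of sense-strand gene sequences; the genome component is the
#' concatenation of replicon sequences.
#'
#' @param record A `genome_record` with at least one feature of each kind.
#' @return Named numeric vector of length 77 with attributes `accession` and
#'   `label`.
#' @export
build_feature_vector <- function(record) {
  validate_genome_record(record)
  out <- numeric(0)
  for (kind in names(COMPONENT_TOKENS)) {
    tk <- COMPONENT_TOKENS[[kind]]
    seq <- component_concat(record, kind)
    if (!nzchar(seq)) stop_missing_component(record$accession, kind)
    cnt <- count_bases(seq)
    fr <- base_frequencies(cnt)
    v <- c(cnt$acgt_total, cnt$A, cnt$T, cnt$C, cnt$G, fr[["A"]], fr[["T"]],
           fr[["C"]], fr[["G"]])
    names(v) <- c(sprintf("bp_%s_total", tk),
                  sprintf("bp_%s_%s", tk, c("A", "T", "C", "G")),
                  sprintf("fr_%s_%s", tk, c("A", "T", "C", "G")))
    sc <- component_scores(record, kind)
    s <- c(sc$shannon, sc$topological, sc$chargaff_pf, sc$chargaff_ct)
    names(s) <- sprintf("%s_%s", tk, c("shannon_score", "topological_entropy_score",
                                       "chargaff_score_pf", "chargaff_score_ct"))
    out <- c(out, v, s)
    if (kind != "genome") {
      n <- strand_counts(record, kind)
      names(n) <- sprintf("n_%s_%s", tk, c("plus", "minus", "total"))
      out <- c(out, n)
    }
  }
  out <- out[feature_names()]
  attr(out, "accession") <- record$accession
  attr(out, "label") <- if (is.null(record$label)) NA_character_ else record$label
  out
}

#' Build the feature table for a set of genome records
#'
#' One row per genome: accession, class label and the 77 named features in
#' canonical order.
#'
#' @param records List of `genome_record` objects.
#' @param labels Optional character vector overriding per-record labels.
#' @return A data.frame with columns accession, label and the 77 features.
#' @export
build_feature_table <- function(records, labels = NULL) {
  vecs <- lapply(records, build_feature_vector)
  mat <- do.call(rbind, vecs)
  df <- data.frame(
    accession = vapply(vecs, function(v) attr(v, "accession"), character(1)),
    label = if (!is.null(labels)) as.character(labels)
            else vapply(vecs, function(v) attr(v, "label"), character(1)),
    mat, stringsAsFactors = FALSE, check.names = FALSE)
  rownames(df) <- NULL
  df
}

#' Write a feature table as CSV
#'
#' @param features Feature table from [build_feature_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' Also accepts any CSV with `accession`, `label` and the 77 feature columns
#' (e.g. an externally deposited feature table).
#'
#' @param path CSV path.
#' @return Feature table data.frame.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(c("accession", "label", feature_names()), names(df))
  if (length(miss))
    stop(sprintf("feature table is missing columns: %s",
                 paste(head(miss, 5), collapse = ", ")))
  df
}
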