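#' Count nucleotides in a DNA string
#'
#' Exact counts of the four canonical bases; any other character (IUPAC
#' ambiguity codes, N, gap characters) is tallied in `other`. Frequencies and
#' all downstream scores are computed over the canonical (A+C+G+T) total only.
#'
#' @param sequence Uppercase DNA string (may be empty).
#' @return A `base_counts` object with fields A, C, G, T, other and acgt_total.
#' @export
count_bases <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  r <- charToRaw(sequence)
  cnt <- c(A = sum(r == as.raw(65L)), C = sum(r == as.raw(67L)),
           G = sum(r == as.raw(71L)), T = sum(r == as.raw(84L)))
  structure(list(A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]], T = cnt[["T"]],
                 other = length(r) - sum(cnt), acgt_total = sum(cnt)),
            class = "base_counts")
}

as_base_counts <- function(x) {
  if (inherits(x, "base_counts")) return(x)
  stopifnot(all(c("A", "C", "G", "T") %in% names(x)))
  structure(list(A = x[["A"]], C = x[["C"]], G = x[["G"]], T = x[["T"]],
                 other = if ("other" %in% names(x)) x[["other"]] else 0,
                 acgt_total = x[["A"]] + x[["C"]] + x[["G"]] + x[["T"]]),
            class = "base_counts")
}

#' Relative base frequencies
#'
#' @param counts A `base_counts` object (or named vector with A, C, G, T).
#' @return Named numeric vector (A, T, C, G) of proportions summing to 1.
#' @export
base_frequencies <- function(counts) {
  counts <- as_base_counts(counts)
  if (counts$acgt_total <= 0)
    stop("undefined frequencies: no canonical bases", call. = FALSE)
  c(A = counts$A, T = counts$T, C = counts$C, G = counts$G) / counts$acgt_total
}

#' Shannon entropy of a DNA sequence
#'
#' H = -sum(p_i log2 p_i) over the four nucleotide proportions; zero-frequency
#' bases contribute zero. Ranges over \[0, 2\] bits.
#'
#' @param sequence Uppercase DNA string with at least one canonical base.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(sequence) {
  cnt <- count_bases(sequence)
  if (cnt$acgt_total == 0)
    stop("Shannon entropy undefined: no canonical bases", call. = FALSE)
  p <- c(cnt$A, cnt$C, cnt$G, cnt$T) / cnt$acgt_total
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Finite-sequence topological entropy
#'
#' Uses the finite approximation for subword complexity: with n the largest
#' integer such that 4^n + n - 1 <= L, census the distinct n-mers among the
#' 4^n windows of the length-(4^n + n - 1) prefix and return
#' log4(distinct)/n. Windows containing a non-ACGT character are skipped.
#' Ranges over \[0, 1\]: 0 for a homopolymer, 1 when all 4^n words occur.
#'
#' @param sequence Uppercase DNA string of length >= 4.
#' @return Topological entropy in \[0, 1\].
#' @export
topological_entropy <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  L <- nchar(sequence)
  if (L < 4) stop("sequence too short for topological entropy (need >= 4)", call. = FALSE)
  n <- 1L
  while (4^(n + 1) + n <= L) n <- n + 1L  # 4^(n+1) + (n+1) - 1 <= L
  P <- 4^n + n - 1L
  x <- utf8ToInt(substr(sequence, 1L, P))
  code <- integer(length(x))
  code[x == 65L] <- 0L; code[x == 67L] <- 1L
  code[x == 71L] <- 2L; code[x == 84L] <- 3L
  bad <- !(x %in% c(65L, 67L, 71L, 84L))
  N <- 4^n  # number of windows in the prefix
  w <- numeric(N)
  anybad <- logical(N)
  for (j in seq_len(n)) {
    idx <- j:(j + N - 1L)
    w <- w * 4 + code[idx]
    anybad <- anybad | bad[idx]
  }
  w <- w[!anybad]
  if (length(w) == 0L)
    stop("topological entropy undefined: no ambiguity-free window", call. = FALSE)
  k <- length(unique(w))
  log(k, base = 4) / n
}

#' Chargaff parity score, PF method (sum of absolute AT and GC skews)
#'
#' |A - T|/(A + T) + |C - G|/(C + G); 0 indicates perfect intra-strand parity
#' (Chargaff's second rule). The skew of an empty base pool is taken as 0.
#'
#' @param counts A `base_counts` object (or named vector with A, C, G, T).
#' @return Score in \[0, 2\].
#' @export
chargaff_pf <- function(counts) {
  counts <- as_base_counts(counts)
  skew <- function(x, y) if (x + y == 0) 0 else abs(x - y) / (x + y)
  skew(counts$A, counts$T) + skew(counts$C, counts$G)
}

#' Chargaff parity score, CT method (mean min/max ratio of the two base pairs)
#'
#' 0.5 * (min(A,T)/max(A,T) + min(C,G)/max(C,G)); 1 indicates perfect parity.
#' An all-zero pair contributes a ratio of 1 (parity limit).
#'
#' @param counts A `base_counts` object (or named vector with A, C, G, T).
#' @return Score in \[0, 1\].
#' @export
chargaff_ct <- function(counts) {
  counts <- as_base_counts(counts)
  ratio <- function(x, y) {
    if (max(x, y) == 0) return(1)
    min(x, y) / max(x, y)
  }
  0.5 * (ratio(counts$A, counts$T) + ratio(counts$C, counts$G))
}

#' Per-component score set for a genome record
#'
#' Computes the four scores (Shannon entropy, topological entropy, Chargaff PF
#' and CT) on the concatenation, in genomic order, of all sense-strand
#' sequences of one component kind ("genome" concatenates the replicon
#' sequences themselves).
#'
#' @param record A `genome_record`.
#' @param kind "genome", "CDS", "rRNA", "tRNA" or "ncRNA".
#' @return A named list with elements shannon, topological, chargaff_pf,
#'   chargaff_ct.
#' @export
component_scores <- function(record, kind) {
  seq <- component_concat(record, kind)
  if (!nzchar(seq))
    stop_missing_component(record$accession, kind)
  cnt <- count_bases(seq)
  list(shannon = shannon_entropy(seq),
       topological = topological_entropy(seq),
       chargaff_pf = chargaff_pf(cnt),
       chargaff_ct = chargaff_ct(cnt))
}

# concatenated sense-strand sequence of a component ("" if absent)
component_concat <- function(record, kind) {
  if (identical(kind, "genome")) {
    return(paste(vapply(record$replicons, function(r) r$sequence, character(1)),
                 collapse = ""))
  }
  paste(component_sequences(record, kind), collapse = "")
}

stop_missing_component <- function(accession, kind) {
  stop(structure(class = c("prokdomain_missing_component", "error", "condition"),
                 list(message = sprintf("record %s has no %s features", accession, kind),
                      call = NULL, component = kind)))
}
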