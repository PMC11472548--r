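#' Specification of one synthetic genome class
#'
#' Describes how annotated genomes of one class (e.g. "Archaea") are
#' generated: Dirichlet concentrations for per-genome base probabilities of
#' each component, the expected sense-strand parity deviation (which controls
#' the Chargaff scores), gene count and length ranges per component, the
#' minus-strand probability, and the genome length range.
#'
#' @param label Class name.
#' @param composition Named list over components (genome, CDS, rRNA, tRNA,
#'   ncRNA); each element a strictly positive length-4 Dirichlet concentration
#'   (A, C, G, T).
#' @param parity_skew Expected deviation from A=T, C=G on gene sense strands,
#'   in \[0, 1\]; the expected Chargaff-PF score of a long gene concatenation
#'   equals this value.
#' @param n_genes Named list over gene kinds; each a length-2 integer range
#'   (min, max) for the gene count.
#' @param gene_length Named list over gene kinds; each a length-2 integer
#'   range for gene length in bp.
#' @param minus_strand_prob Probability that a gene lies on the minus strand.
#' @param genome_length Length-2 integer range for replicon length in bp.
#' @return A `class_spec` object.
#' @export
class_spec <- function(label,
                       composition,
                       parity_skew = 0,
                       n_genes = list(CDS = c(80, 110), rRNA = c(2, 6),
                                      tRNA = c(20, 40), ncRNA = c(5, 15)),
                       gene_length = list(CDS = c(600, 1000), rRNA = c(1000, 3000),
                                          tRNA = c(70, 90), ncRNA = c(100, 400)),
                       minus_strand_prob = 0.5,
                       genome_length = c(140000, 180000)) {
  comps <- c("genome", COMPONENT_KINDS)
  if (is.numeric(composition)) {
    composition <- stats::setNames(rep(list(composition), length(comps)), comps)
  }
  stopifnot(all(comps %in% names(composition)))
  for (k in comps) {
    a <- composition[[k]]
    if (length(a) != 4L || any(!is.finite(a)) || any(a <= 0))
      stop(sprintf("composition[['%s']] must be 4 strictly positive concentrations", k))
  }
  stopifnot(parity_skew >= 0, parity_skew <= 1,
            minus_strand_prob >= 0, minus_strand_prob <= 1)
  chk_range <- function(r, what) {
    if (length(r) != 2L || r[1] > r[2] || r[1] < 1)
      stop(sprintf("invalid range for %s", what))
  }
  for (k in COMPONENT_KINDS) {
    chk_range(n_genes[[k]], paste("n_genes", k))
    chk_range(gene_length[[k]], paste("gene_length", k))
  }
  chk_range(genome_length, "genome_length")
  structure(list(label = label, composition = composition,
                 parity_skew = parity_skew, n_genes = n_genes,
                 gene_length = gene_length,
                 minus_strand_prob = minus_strand_prob,
                 genome_length = genome_length),
            class = "class_spec")
}

#' Default class specifications for the two prokaryotic domains
#'
#' The contrasts mirror the direction of the reported class differences:
#' bacterial tRNA/rRNA composition is closer to uniform (higher Shannon and
#' topological entropy) and bacterial genes deviate less from intra-strand
#' parity (lower Chargaff-PF, higher Chargaff-CT) than archaeal ones. Effect
#' sizes are the package's own choice of a clearly separable parameterization;
#' they are not calibrated to the real data.
#'
#' @return List with elements `bacteria` and `archaea`, each a [class_spec()].
#' @export
default_class_specs <- function() {
  near_uniform <- c(24, 26, 26, 24)
  skewed <- c(40, 18, 18, 24)
  list(
    bacteria = class_spec(
      label = "Bacteria",
      composition = list(genome = c(25, 27, 27, 25), CDS = near_uniform,
                         rRNA = near_uniform, tRNA = c(25, 25, 25, 25),
                         ncRNA = near_uniform),
      parity_skew = 0.02),
    archaea = class_spec(
      label = "Archaea",
      composition = list(genome = c(30, 22, 22, 26), CDS = skewed,
                         rRNA = skewed, tRNA = c(42, 16, 16, 26),
                         ncRNA = skewed),
      parity_skew = 0.12))
}

#' Draw per-genome base probabilities for one component
#'
#' Samples from the Dirichlet distribution given by the class specification's
#' concentration vector for that component (via normalized gamma draws on the
#' current RNG stream).
#'
#' @param spec A [class_spec()].
#' @param component "genome", "CDS", "rRNA", "tRNA" or "ncRNA".
#' @return Named probability vector (A, C, G, T) summing to 1.
#' @export
sample_composition <- function(spec, component = "genome") {
  stopifnot(inherits(spec, "class_spec"))
  component <- match.arg(component, c("genome", COMPONENT_KINDS))
  a <- spec$composition[[component]]
  g <- stats::rgamma(4L, shape = a, rate = 1)
  stats::setNames(g / sum(g), c("A", "C", "G", "T"))
}

# reweight A vs T and C vs G by +/- skew/4 of each pool so the expected
# sense-strand PF score equals `skew` (each pool's skew is skew/2)
apply_parity_skew <- function(p, skew) {
  wat <- p[["A"]] + p[["T"]]
  wcg <- p[["C"]] + p[["G"]]
  c(A = wat * (0.5 + skew / 4), C = wcg * (0.5 + skew / 4),
    G = wcg * (0.5 - skew / 4), T = wat * (0.5 - skew / 4))
}

random_dna <- function(n, p) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate one annotated synthetic genome
#'
#' A single replicon with non-overlapping, uniformly placed genes of each
#' kind. Gene sense-strand sequences are drawn i.i.d. from the component's
#' per-genome composition, reweighted so the expected A-T and C-G sense-strand
#' imbalance equals `parity_skew`; intergenic sequence is drawn from the
#' (unskewed) genome-level composition. Strands are Bernoulli(minus_strand_prob);
#' minus-strand genes are stored as the reverse complement of the sense
#' sequence.
#'
#' @param spec A [class_spec()].
#' @param accession Accession for the record.
#' @param organism Organism name.
#' @return A [genome_record()] carrying `spec$label` as its label.
#' @export
generate_genome <- function(spec, accession = "SYN000001",
                            organism = "Synthetico sp0001") {
  stopifnot(inherits(spec, "class_spec"))
  L <- sample_range(spec$genome_length)
  p_genome <- sample_composition(spec, "genome")
  comp_probs <- lapply(stats::setNames(COMPONENT_KINDS, COMPONENT_KINDS),
                       function(k) apply_parity_skew(sample_composition(spec, k),
                                                     spec$parity_skew))
  genes <- list()
  for (k in COMPONENT_KINDS) {
    nk <- sample_range(spec$n_genes[[k]])
    for (i in seq_len(nk))
      genes[[length(genes) + 1L]] <-
        list(kind = k, len = sample_range(spec$gene_length[[k]]))
  }
  genes <- genes[sample.int(length(genes))]
  total <- sum(vapply(genes, function(g) g$len, numeric(1)))
  if (total > L)
    stop(sprintf("infeasible packing: %d bp of genes exceed genome length %d",
                 total, L), call. = FALSE)
  free <- L - total
  gaps <- as.vector(stats::rmultinom(1L, free, rep(1, length(genes) + 1L)))
  segs <- character(2L * length(genes) + 1L)
  features <- vector("list", length(genes))
  pos <- 0L
  si <- 1L
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    segs[si] <- random_dna(gaps[i], p_genome); si <- si + 1L
    pos <- pos + gaps[i]
    sense <- random_dna(g$len, comp_probs[[g$kind]])
    minus <- stats::runif(1) < spec$minus_strand_prob
    segs[si] <- if (minus) revcomp(sense) else sense; si <- si + 1L
    features[[i]] <- feature_interval(g$kind, c(pos, pos + g$len),
                                      strand = if (minus) "-" else "+")
    pos <- pos + g$len
  }
  segs[si] <- random_dna(gaps[length(gaps)], p_genome)
  genome_record(accession = accession, organism = organism,
                replicons = list(list(sequence = paste(segs, collapse = ""),
                                      features = features)),
                label = spec$label)
}

sample_range <- function(r) {
  if (r[1] == r[2]) as.integer(r[1]) else
    sample(seq.int(r[1], r[2]), 1L)
}

#' Generate a labelled synthetic dataset of annotated genomes
#'
#' Draws exactly `round(n_total * minority_fraction)` genomes from the
#' minority specification and the remainder from the majority specification,
#' in randomized order. All randomness derives from the single integer seed;
#' each record uses its own derived sub-stream, so regeneration is
#' bit-identical.
#'
#' @param spec_major [class_spec()] of the majority class.
#' @param spec_minor [class_spec()] of the minority class.
#' @param n_total Total number of genomes.
#' @param minority_fraction Minority fraction in (0, 0.5).
#' @param seed Integer seed.
#' @return A `synthetic_dataset`: list with `records`, `labels`, `seed`,
#'   `spec` (majority, minority, minority_fraction).
#' @export
generate_dataset <- function(spec_major, spec_minor, n_total,
                             minority_fraction = 0.041, seed = 1L) {
  stopifnot(inherits(spec_major, "class_spec"), inherits(spec_minor, "class_spec"),
            minority_fraction > 0, minority_fraction < 0.5)
  n_min <- round(n_total * minority_fraction)
  if (n_min < 1L || n_total - n_min < 1L)
    stop("n_total too small to hold at least one record per class", call. = FALSE)
  set.seed(seed)
  is_minor <- sample(c(rep(TRUE, n_min), rep(FALSE, n_total - n_min)))
  subseeds <- sample.int(.Machine$integer.max - 1L, n_total)
  records <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    set.seed(subseeds[i])
    sp <- if (is_minor[i]) spec_minor else spec_major
    records[[i]] <- generate_genome(sp, accession = sprintf("SYN%06d", i),
                                    organism = sprintf("Synthetico sp%04d", i))
  }
  structure(list(records = records,
                 labels = vapply(records, function(r) r$label, character(1)),
                 seed = seed,
                 spec = list(majority = spec_major, minority = spec_minor,
                             minority_fraction = minority_fraction)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d genomes (%s), seed %d\n",
              length(x$records),
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", "),
              x$seed))
  invisible(x)
}

#' Write a synthetic dataset as GenBank flat files
#'
#' One file per record, named `<accession>.gbk`, round-trippable by
#' [parse_genbank()] with lossless recovery of sequences, feature kinds,
#' intervals, strands and labels.
#'
#' @param dataset A `synthetic_dataset`.
#' @param directory Output directory (created if absent).
#' @return Character vector of written file paths.
#' @export
write_genbank_fixtures <- function(dataset, directory) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(directory) && !dir.create(directory, recursive = TRUE))
    stop(sprintf("cannot create directory %s", directory))
  paths <- character(0)
  for (rec in dataset$records) {
    path <- file.path(directory, paste0(rec$accession, ".gbk"))
    ok <- tryCatch(write_genbank(rec, path), error = function(e)
      stop(sprintf("failed writing %s: %s", path, conditionMessage(e)), call. = FALSE))
    paths <- c(paths, ok)
  }
  paths
}

#' Simulate a two-class feature table with planted signal
#'
#' Abstract (non-genomic) benchmark data for the modelling stages: standard
#' normal noise features plus informative features whose minority-class mean
#' is shifted by `effect` standard deviations. Used to test recursive feature
#' elimination recovery and classifier accuracy against a known ground truth.
#'
#' @param n Number of rows.
#' @param p_informative Number of informative features (named `signal_NN`).
#' @param p_noise Number of pure-noise features (named `noise_NN`).
#' @param effect Class-mean shift of informative features, in SD units.
#' @param minority_fraction Minority ("Archaea") fraction.
#' @param seed Integer seed.
#' @return data.frame with `accession`, `label` and the feature columns.
#' @export
simulate_feature_table <- function(n = 200, p_informative = 5, p_noise = 20,
                                   effect = 2, minority_fraction = 0.1,
                                   seed = 1L) {
  set.seed(seed)
  n_min <- round(n * minority_fraction)
  lab <- sample(c(rep("Archaea", n_min), rep("Bacteria", n - n_min)))
  p <- p_informative + p_noise
  x <- matrix(stats::rnorm(n * p), n, p)
  shift <- ifelse(lab == "Archaea", effect, 0)
  for (j in seq_len(p_informative)) x[, j] <- x[, j] + shift
  colnames(x) <- c(sprintf("signal_%02d", seq_len(p_informative)),
                   sprintf("noise_%02d", seq_len(p_noise)))
  data.frame(accession = sprintf("SIM%05d", seq_len(n)), label = lab, x,
             stringsAsFactors = FALSE)
}
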