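revcomp <- function(s) {
  vapply(s, function(x)
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

composition_from_kmers <- function(kmers, k) {
  n <- length(kmers)
  freq <- matrix(NA_real_, k, 4,
                 dimnames = list(seq_len(k) - (k + 1L) %/% 2L,
                                 c("A", "C", "G", "T")))
  if (n > 0L) {
    mat <- do.call(rbind, strsplit(kmers, ""))
    for (j in seq_len(k)) {
      tabs <- table(factor(mat[, j], levels = c("A", "C", "G", "T")))
      freq[j, ] <- as.numeric(tabs) / n
    }
  }
  structure(list(k = k, freq = freq, n_kmers = n),
            class = "composition_matrix")
}

#' @export
print.composition_matrix <- function(x, ...) {
  cat("k-mer composition matrix: k =", x$k, ", n =", x$n_kmers, "\n")
  print(round(x$freq, 4))
  if (!is.null(attr(x, "skipped"))) {
    sk <- attr(x, "skipped")
    cat("skipped:", paste(names(sk), sk, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# Extract reference-strand windows of width k centered on each mutation.
# Returns the kmer strings plus skip tallies; shared by extract_kmers.
mutation_windows <- function(records, genome, k) {
  h <- (k - 1L) %/% 2L
  validate_positions(records, genome)
  chrom_len <- nchar(genome)[records$chrom]
  center <- substring(genome[records$chrom], records$pos, records$pos)
  mismatch <- center != records$ref
  edge <- records$pos - h < 1L | records$pos + h > chrom_len
  kmer <- rep(NA_character_, nrow(records))
  ok <- !mismatch & !edge
  kmer[ok] <- substring(genome[records$chrom[ok]],
                        records$pos[ok] - h, records$pos[ok] + h)
  ambiguous <- !is.na(kmer) & grepl("[^ACGT]", kmer)
  kmer[ambiguous] <- NA_character_
  list(kmer = kmer,
       skipped = c(ref_mismatch = sum(mismatch),
                   edge = sum(edge & !mismatch),
                   ambiguous = sum(ambiguous)))
}

#' Positional nucleotide composition of k-mers centered on mutations
#'
#' Takes the reference-strand window of width `k` around each substitution
#' (no strand flip, so the center column reflects the reference-allele
#' distribution) and tabulates A/C/G/T frequencies by position. Windows
#' crossing a chromosome edge or containing ambiguous bases are skipped and
#' tallied; records whose reference allele disagrees with the genome are
#' excluded as reference mismatches.
#'
#' @param records a `mutation_catalog`.
#' @param genome named character vector of chromosome sequences.
#' @param k odd window width (default 7).
#' @param stratify_by_class if `TRUE`, return one matrix per exposure class.
#' @return a `composition_matrix` (list with `k`, `freq` - a `k x 4`
#'   row-stochastic matrix - and `n_kmers`, plus a `skipped` attribute), or
#'   a named list of them when stratified.
#' @export
extract_kmers <- function(records, genome, k = 7L,
                          stratify_by_class = FALSE) {
  if (k %% 2L == 0L || k < 1L) stop("k must be a positive odd integer")
  if (stratify_by_class) {
    strata <- split(seq_len(nrow(records)), records$exposure_class)
    return(lapply(strata, function(idx)
      extract_kmers(records[idx, , drop = FALSE], genome, k, FALSE)))
  }
  w <- mutation_windows(records, genome, k)
  out <- composition_from_kmers(w$kmer[!is.na(w$kmer)], k)
  attr(out, "skipped") <- w$skipped
  out
}

#' Random k-mers from the genome
#'
#' Samples `n` windows of width `k` with start positions uniform over all
#' edge-safe, ambiguity-free windows of the genome (chromosomes weighted by
#' their number of valid starts) and tabulates positional composition.
#'
#' @param genome named character vector of chromosome sequences.
#' @param n number of k-mers (default 50000).
#' @param k odd window width (default 7).
#' @param seed RNG seed.
#' @return a `composition_matrix`.
#' @export
sample_random_kmers <- function(genome, n = 50000L, k = 7L, seed = NULL) {
  if (k %% 2L == 0L || k < 1L) stop("k must be a positive odd integer")
  lens <- nchar(genome)
  n_starts <- pmax(lens - k + 1L, 0L)
  if (sum(n_starts) == 0L) stop("genome too short for k = ", k)
  kmers <- with_seed(seed, {
    got <- character(0)
    for (tries in 1:100) {
      need <- n - length(got)
      if (need <= 0L) break
      chr <- sample(names(genome), need, replace = TRUE,
                    prob = n_starts / sum(n_starts))
      st <- floor(stats::runif(need, 1, n_starts[chr] + 1))
      cand <- substring(genome[chr], st, st + k - 1L)
      got <- c(got, cand[!grepl("[^ACGT]", cand)])
    }
    if (length(got) < n)
      stop("could not sample ", n, " ambiguity-free k-mers")
    got[seq_len(n)]
  })
  composition_from_kmers(kmers, k)
}

#' Canonical 96-channel substitution labels
#'
#' Pyrimidine-centered convention: six substitution types (C>A, C>G, C>T,
#' T>A, T>C, T>G), each in 16 flanking contexts ordered A, C, G, T on both
#' sides; labels like `"A[C>T]G"`.
#' @return character vector of length 96.
#' @export
sbs96_channels <- function() {
  bases <- c("A", "C", "G", "T")
  types <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  unlist(lapply(types, function(t)
    as.vector(t(outer(bases, bases, function(l, r)
      paste0(l, "[", t, "]", r))))))
}

#' 96-channel trinucleotide mutation spectrum
#'
#' Classifies each substitution by its pyrimidine-centered change and
#' immediate flanking bases: purine-reference changes are mapped through
#' the reverse complement of the trinucleotide context and allele pair.
#' Records with an ambiguous or edge-truncated context, or whose reference
#' allele disagrees with the genome, are excluded and tallied.
#'
#' @param records a `mutation_catalog`.
#' @param genome named character vector of chromosome sequences.
#' @return object of class `sbs_spectrum`: named integer vector over the 96
#'   channels with attributes `total` and `excluded`.
#' @export
trinucleotide_spectrum <- function(records, genome) {
  channels <- sbs96_channels()
  counts <- stats::setNames(integer(96), channels)
  excluded <- c(ref_mismatch = 0L, edge = 0L, ambiguous = 0L)
  if (nrow(records)) {
    w <- mutation_windows(records, genome, 3L)
    excluded <- w$skipped
    ok <- which(!is.na(w$kmer))
    if (length(ok)) {
      ctx <- w$kmer[ok]
      ref <- records$ref[ok]
      alt <- records$alt[ok]
      pur <- ref %in% c("A", "G")
      ctx[pur] <- revcomp(ctx[pur])
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      ref[pur] <- comp[ref[pur]]
      alt[pur] <- comp[alt[pur]]
      lab <- paste0(substring(ctx, 1, 1), "[", ref, ">", alt, "]",
                    substring(ctx, 3, 3))
      tab <- table(factor(lab, levels = channels))
      counts <- stats::setNames(as.integer(tab), channels)
    }
  }
  structure(counts, total = sum(counts), excluded = excluded,
            class = "sbs_spectrum")
}

#' @export
print.sbs_spectrum <- function(x, ...) {
  cat("96-channel substitution spectrum:", attr(x, "total"),
      "eligible SNVs\n")
  top <- sort(unclass(x)[unclass(x) > 0], decreasing = TRUE)
  print(utils::head(top, 10))
  invisible(x)
}

#' @export
plot.sbs_spectrum <- function(x, ...) {
  cols <- rep(c("#03BCEE", "#010101", "#E32926", "#CAC9C9", "#A1CE63",
                "#EBC6C4"), each = 16)
  graphics::barplot(as.numeric(x), col = cols, border = NA,
                    names.arg = names(x), las = 2, cex.names = 0.35,
                    ylab = "count", ...)
  invisible(x)
}

#' Cosine similarity between two spectra
#'
#' @param spectrum,reference non-negative numeric vectors of equal length
#'   (typically 96 channels), not all zero.
#' @return cosine of the angle between the vectors, in `[0, 1]`.
#' @export
cosine_similarity <- function(spectrum, reference) {
  a <- as.numeric(spectrum); b <- as.numeric(reference)
  if (length(a) != length(b)) stop("vectors differ in length")
  if (any(a < 0) || any(b < 0)) stop("vectors must be non-negative")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("all-zero vector")
  sum(a * b) / (na * nb)
}

#' Read a 96-row reference signature matrix
#'
#' Expects a TSV whose first column holds the channel labels (COSMIC
#' convention, any order) and remaining columns one signature each.
#' @param path TSV path.
#' @return numeric matrix, rows ordered as [sbs96_channels()].
#' @export
read_signatures <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  channels <- sbs96_channels()
  rn <- df[[1L]]
  if (!setequal(rn, channels))
    stop("signature file does not cover the 96 channels")
  m <- as.matrix(df[match(channels, rn), -1L, drop = FALSE])
  rownames(m) <- channels
  storage.mode(m) <- "double"
  m
}

#' Length distribution of randomly mutated sequences
#'
#' Models mutation entirely governed by sequence length: `n` positions are
#' sampled uniformly over the concatenation of all target sequences, and
#' the output is the length of the sequence containing each sampled
#' position. This is the comparator distribution for "how long would
#' mutated genes be if mutation were random".
#'
#' @param lengths named numeric vector of sequence lengths (genes or CDS).
#' @param n number of sampled positions (default 100000).
#' @param seed RNG seed.
#' @return numeric vector of `n` hit-sequence lengths, names = sequence id.
#' @export
random_mutation_length_model <- function(lengths, n = 100000L, seed = NULL) {
  if (!length(lengths) || any(lengths <= 0))
    stop("lengths must be positive")
  ids <- with_seed(seed,
    sample(names(lengths), n, replace = TRUE, prob = lengths))
  stats::setNames(as.numeric(lengths[ids]), ids)
}
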