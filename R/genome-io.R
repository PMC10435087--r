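#' Read a genome FASTA into a named character vector
#'
#' Sequences are upper-cased; names are truncated at the first whitespace so
#' they match the chromosome names used in GTF/bedGraph/mutation inputs.
#'
#' @param path path to a (possibly multi-record) FASTA file.
#' @return named character vector, one element per chromosome.
#' @export
read_genome <- function(path) {
  stopifnot(file.exists(path))
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write a genome to FASTA
#' @param genome named character vector of chromosome sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' GC content of a nucleotide sequence
#'
#' Returns (#G + #C) / (#A + #C + #G + #T). Ambiguous bases (N and other
#' IUPAC codes) are excluded from both numerator and denominator, so assembly
#' gaps do not bias the estimate. An all-ambiguous (or empty) sequence has
#' undefined GC content and yields `NA`.
#'
#' @param sequence character vector of nucleotide strings.
#' @return numeric vector of GC fractions in `[0, 1]`, `NA` where undefined.
#' @export
compute_gc <- function(sequence) {
  vapply(sequence, function(s) {
    if (is.na(s) || nchar(s) == 0L) return(NA_real_)
    counts <- Biostrings::letterFrequency(Biostrings::DNAString(toupper(s)),
                                          letters = c("A", "C", "G", "T"))
    total <- sum(counts)
    if (total == 0L) return(NA_real_)
    unname((counts[["C"]] + counts[["G"]]) / total)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read gene models from a GTF file
#'
#' Builds one record per gene: span, strand, merged (union across
#' transcripts) CDS intervals, sequence covariates and, optionally, joined
#' expression. Coordinates are stored 0-based half-open internally; the GTF
#' is parsed as 1-based inclusive. Two length conventions are used on
#' purpose: `gene_length` is the annotation's end minus start (the covariate
#' used downstream, one less than the inclusive span), while `cds_length` is
#' the summed width of the merged CDS intervals.
#'
#' @param gtf path to a GTF with `gene` and `CDS` features.
#' @param genome genome as returned by [read_genome()] (or a FASTA path).
#' @param expression optional data frame with columns `symbol`, `rpkm`, or a
#'   path to a TSV with those columns. Joined by exact symbol match;
#'   unmatched genes get `NA` expression.
#' @return data frame of class `gene_models` with columns `gene_id`,
#'   `symbol`, `chrom`, `strand`, `start`, `end` (0-based half-open),
#'   `gene_length`, `cds_length`, `gene_gc`, `cds_gc`, `expression`, and a
#'   list column `cds_intervals` of two-column (start, end) matrices.
#' @export
read_gene_models <- function(gtf, genome, expression = NULL) {
  stopifnot(file.exists(gtf))
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_genome(genome)
  gr <- rtracklayer::import(gtf, format = "gtf")
  is_gene <- gr$type == "gene"
  is_cds <- gr$type == "CDS"
  if (!any(is_gene)) stop("GTF contains no 'gene' features")
  genes <- gr[is_gene]
  cds <- gr[is_cds]

  gene_id <- as.character(genes$gene_id)
  chrom <- as.character(GenomicRanges::seqnames(genes))
  missing_chr <- setdiff(unique(chrom), names(genome))
  if (length(missing_chr))
    stop("chromosome(s) absent from the genome FASTA: ",
         paste(missing_chr, collapse = ", "))
  start1 <- GenomicRanges::start(genes)  # 1-based inclusive
  end1 <- GenomicRanges::end(genes)
  symbol <- if (!is.null(genes$gene_name)) as.character(genes$gene_name)
            else gene_id
  symbol[is.na(symbol)] <- gene_id[is.na(symbol)]

  # merge CDS across transcripts, per gene
  cds_by_gene <- vector("list", length(gene_id))
  names(cds_by_gene) <- gene_id
  if (length(cds)) {
    cid <- as.character(cds$gene_id)
    unknown <- setdiff(unique(cid), gene_id)
    if (length(unknown))
      stop("CDS features reference unknown gene_id: ",
           paste(unknown, collapse = ", "))
    sp <- split(seq_along(cds), cid)
    for (g in names(sp)) {
      idx <- sp[[g]]
      red <- IRanges::reduce(IRanges::IRanges(GenomicRanges::start(cds)[idx],
                                              GenomicRanges::end(cds)[idx]))
      gi <- match(g, gene_id)
      if (any(IRanges::start(red) < start1[gi] | IRanges::end(red) > end1[gi]))
        stop("gene ", g, ": CDS interval outside the gene span")
      # store 0-based half-open
      cds_by_gene[[g]] <- cbind(start = IRanges::start(red) - 1L,
                                end = IRanges::end(red))
    }
  }

  seqs <- substring(genome[chrom], start1, end1)
  gene_gc <- compute_gc(seqs)
  cds_len <- integer(length(gene_id))
  cds_gc <- rep(NA_real_, length(gene_id))
  for (i in seq_along(gene_id)) {
    m <- cds_by_gene[[i]]
    if (is.null(m) || nrow(m) == 0L) {
      cds_by_gene[[i]] <- cbind(start = integer(0), end = integer(0))
      next
    }
    cds_len[i] <- sum(m[, "end"] - m[, "start"])
    cseq <- paste(substring(genome[[chrom[i]]], m[, "start"] + 1L, m[, "end"]),
                  collapse = "")
    cds_gc[i] <- compute_gc(cseq)
  }

  expr <- rep(NA_real_, length(gene_id))
  if (!is.null(expression)) {
    if (is.character(expression) && length(expression) == 1L)
      expression <- utils::read.delim(expression, stringsAsFactors = FALSE)
    stopifnot(all(c("symbol", "rpkm") %in% names(expression)))
    j <- match(symbol, expression$symbol)
    expr <- as.numeric(expression$rpkm[j])
  }

  out <- data.frame(
    gene_id = gene_id, symbol = symbol, chrom = chrom,
    strand = as.character(GenomicRanges::strand(genes)),
    start = start1 - 1L, end = end1,
    gene_length = end1 - start1,
    cds_length = cds_len,
    gene_gc = gene_gc, cds_gc = cds_gc,
    expression = expr,
    stringsAsFactors = FALSE
  )
  out$cds_intervals <- I(cds_by_gene)
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Read disease gene sets from plain-text symbol lists
#'
#' Each file holds one symbol per line; the file name (without extension)
#' becomes the set name. Duplicate symbols within a file are collapsed.
#'
#' @param paths a directory containing the list files, or a character vector
#'   of file paths.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, full.names = TRUE)
  if (!length(paths)) stop("no gene-set files found")
  sets <- lapply(paths, function(p) {
    x <- readLines(p, warn = FALSE)
    x <- trimws(x)
    unique(x[nzchar(x)])
  })
  names(sets) <- sub("\\.[^.]*$", "", basename(paths))
  empty <- vapply(sets, length, 1L) == 0L
  if (any(empty))
    stop("empty gene set(s): ", paste(names(sets)[empty], collapse = ", "))
  sets
}

#' Read a depth-normalized signal track from bedGraph
#'
#' Validates and sorts a 4-column bedGraph (0-based half-open intervals).
#' Overlapping intervals or negative values are hard errors: the track is
#' expected to be a partition-like, already-normalized coverage signal.
#'
#' @param path path to a bedGraph file.
#' @return data frame of class `signal_track` with columns `chrom`, `start`,
#'   `end`, `value`, sorted by chromosome then start.
#' @export
read_bedgraph <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   value = as.numeric(gr$score),
                   stringsAsFactors = FALSE)
  validate_signal_track(df)
}

validate_signal_track <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(df)))
  if (any(df$value < 0)) stop("signal track contains negative values")
  if (any(df$end <= df$start)) stop("signal track contains empty intervals")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  by_chr <- split(seq_len(nrow(df)), df$chrom)
  for (idx in by_chr) {
    if (length(idx) > 1L &&
        any(df$start[idx][-1L] < df$end[idx][-length(idx)]))
      stop("signal track contains overlapping intervals")
  }
  rownames(df) <- NULL
  class(df) <- c("signal_track", "data.frame")
  df
}

#' Write a signal track to bedGraph
#' @param track a `signal_track` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write gene models to GTF
#'
#' Emits one `gene` feature per gene and one `CDS` feature per merged CDS
#' interval (under a single synthetic transcript per gene), converting the
#' internal 0-based half-open representation back to 1-based inclusive GTF.
#'
#' @param genes a `gene_models` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    attr_g <- sprintf('gene_id "%s"; gene_name "%s";',
                      genes$gene_id[i], genes$symbol[i])
    lines <- c(lines, paste(genes$chrom[i], "mutaset", "gene",
                            genes$start[i] + 1L, genes$end[i], ".",
                            genes$strand[i], ".", attr_g, sep = "\t"))
    m <- genes$cds_intervals[[i]]
    if (!is.null(m) && nrow(m)) {
      attr_c <- sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_name "%s";',
                        genes$gene_id[i], genes$gene_id[i], genes$symbol[i])
      for (j in seq_len(nrow(m))) {
        lines <- c(lines, paste(genes$chrom[i], "mutaset", "CDS",
                                m[j, "start"] + 1L, m[j, "end"], ".",
                                genes$strand[i], "0", attr_c, sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
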