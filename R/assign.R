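#' Assign mutations to genes and coding sequence
#'
#' A substitution at 1-based position `p` is assigned to every gene whose
#' half-open span contains index `p - 1`; overlapping genes each receive the
#' count (no arbitration), and a single gene may contribute many mutations.
#' A mutation additionally counts at CDS level when it falls inside one of
#' the gene's merged CDS intervals. Strand is ignored for counting.
#' Mutations hitting no gene are tallied in an unassigned bucket.
#'
#' @param records a `mutation_catalog` (see [read_mutation_table()]).
#' @param genes a `gene_models` data frame (see [read_gene_models()]).
#' @return data frame of class `mutation_counts` with one row per
#'   (subclone, gene) pair that received at least one mutation: columns
#'   `subclone_id`, `exposure_class`, `gene_id`, `gene_count`, `cds_count`;
#'   attributes `n_unassigned`, `n_records`.
#' @export
assign_mutations <- function(records, genes) {
  if (nrow(records) == 0L) {
    out <- data.frame(subclone_id = character(0),
                      exposure_class = character(0),
                      gene_id = character(0),
                      gene_count = integer(0), cds_count = integer(0))
    return(structure(out, n_unassigned = 0L, n_records = 0L,
                     class = c("mutation_counts", "data.frame")))
  }
  mut_gr <- GenomicRanges::GRanges(records$chrom,
                                   IRanges::IRanges(records$pos, records$pos))
  # gene span [start, end) contains p-1  <=>  1-based [start+1, end] contains p
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1L,
                                                     genes$end))
  ov <- GenomicRanges::findOverlaps(mut_gr, gene_gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  n_unassigned <- nrow(records) - length(unique(qh))

  # CDS membership for each (mutation, gene) hit
  in_cds <- logical(length(qh))
  if (length(qh)) {
    pos0 <- records$pos[qh] - 1L
    for (k in seq_along(qh)) {
      m <- genes$cds_intervals[[sh[k]]]
      if (!is.null(m) && nrow(m))
        in_cds[k] <- any(pos0[k] >= m[, "start"] & pos0[k] < m[, "end"])
    }
  }

  key <- paste(records$subclone_id[qh], genes$gene_id[sh], sep = "\r")
  gene_count <- as.integer(table(key))
  ukey <- names(table(key))
  cds_count <- as.integer(tapply(as.integer(in_cds), key, sum)[ukey])
  parts <- do.call(rbind, strsplit(ukey, "\r", fixed = TRUE))
  sub_id <- parts[, 1L]
  out <- data.frame(
    subclone_id = sub_id,
    exposure_class = records$exposure_class[match(sub_id,
                                                  records$subclone_id)],
    gene_id = parts[, 2L],
    gene_count = gene_count,
    cds_count = cds_count,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$subclone_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_unassigned = n_unassigned, n_records = nrow(records),
            class = c("mutation_counts", "data.frame"))
}

# Total counts per gene over the subclones of one exposure class.
# Returns a named integer vector covering every gene in `gene_ids`
# (zero-filled), at the requested level.
gene_class_totals <- function(counts, manifest, class, gene_ids,
                              level = c("gene", "cds")) {
  level <- match.arg(level)
  subs <- manifest$subclone_id[manifest$exposure_class == class]
  sel <- counts$subclone_id %in% subs
  col <- if (level == "gene") "gene_count" else "cds_count"
  tot <- stats::setNames(numeric(length(gene_ids)), gene_ids)
  if (any(sel)) {
    agg <- tapply(counts[[col]][sel], counts$gene_id[sel], sum)
    agg <- agg[names(agg) %in% gene_ids]
    tot[names(agg)] <- as.numeric(agg)
  }
  tot
}
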