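# Fixture builders shared across test files. Everything is constructed in
# code; no fixture files are stored.

# One gene_models row from 1-based inclusive coordinates (as in a GTF).
toy_gene <- function(gene_id, chrom, start1, end1, cds1 = NULL,
                     symbol = gene_id, gc = NA_real_, cds_gc = NA_real_,
                     expr = NA_real_, strand = "+") {
  cds <- if (is.null(cds1)) {
    cbind(start = integer(0), end = integer(0))
  } else {
    m <- do.call(rbind, cds1)
    red <- IRanges::reduce(IRanges::IRanges(m[, 1], m[, 2]))
    cbind(start = IRanges::start(red) - 1L, end = IRanges::end(red))
  }
  df <- data.frame(gene_id = gene_id, symbol = symbol, chrom = chrom,
                   strand = strand, start = start1 - 1L, end = end1,
                   gene_length = end1 - start1,
                   cds_length = sum(cds[, "end"] - cds[, "start"]),
                   gene_gc = gc, cds_gc = cds_gc, expression = expr,
                   stringsAsFactors = FALSE)
  df$cds_intervals <- I(list(cds))
  df
}

toy_gene_models <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("gene_models", "data.frame")
  out
}

toy_manifest <- function(classes = c("PAH", "radiation"), n_per = 2L) {
  subclone_manifest(data.frame(
    subclone_id = paste0(rep(classes, each = n_per), "_s",
                         rep(seq_len(n_per), length(classes))),
    exposure_class = rep(classes, each = n_per),
    chemical = rep(classes, each = n_per)))
}

toy_catalog <- function(subclone_id, chrom, pos, ref, alt,
                        exposure_class = "PAH", chemical = NA_character_) {
  df <- data.frame(subclone_id = subclone_id,
                   exposure_class = exposure_class, chemical = chemical,
                   chrom = chrom, pos = as.integer(pos), ref = ref,
                   alt = alt, stringsAsFactors = FALSE)
  structure(df, n_skipped = 0L, n_unknown_subclone = 0L,
            class = c("mutation_catalog", "data.frame"))
}

# mutation_counts rows built directly (bypassing position assignment)
toy_counts <- function(subclone_id, gene_id, gene_count,
                       cds_count = 0L, exposure_class = "PAH") {
  df <- data.frame(subclone_id = subclone_id,
                   exposure_class = rep_len(exposure_class,
                                            length(subclone_id)),
                   gene_id = gene_id,
                   gene_count = as.integer(gene_count),
                   cds_count = rep_len(as.integer(cds_count),
                                       length(subclone_id)),
                   stringsAsFactors = FALSE)
  structure(df, n_unassigned = 0L, n_records = sum(df$gene_count),
            class = c("mutation_counts", "data.frame"))
}

# Write a small GTF from rows of (chrom, feature, start1, end1, attrs)
write_toy_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_gene_line <- function(chrom, start1, end1, gene_id,
                          symbol = gene_id, strand = "+") {
  sprintf('%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s";',
          chrom, start1, end1, strand, gene_id, symbol)
}

gtf_cds_line <- function(chrom, start1, end1, gene_id, tx = "t1",
                         strand = "+") {
  sprintf('%s\ttoy\tCDS\t%d\t%d\t.\t%s\t0\tgene_id "%s"; transcript_id "%s.%s";',
          chrom, start1, end1, strand, gene_id, gene_id, tx)
}

write_toy_fasta <- function(genome, path = tempfile(fileext = ".fa")) {
  mutaset::write_genome(genome, path)
  path
}

# a 500 bp chromosome with fixed seed-free composition for reader tests
toy_chromosome <- function(len = 500L, gc = 0.5, seed = 42L) {
  withr_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed(seed, paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                                prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                         (1 - gc) / 2)),
                         collapse = ""))
}

# small homogeneous-rate simulation config used by several tests
small_config <- function(seed = 1L, delta_ndd = 2, n_genes = 120L,
                         ...) {
  simulation_config(
    seed = seed, n_chromosomes = 2L, chrom_length = 6e5, n_genes = n_genes,
    sets = list(
      NDD_like = list(size = 25L, delta = delta_ndd, length_bias = TRUE,
                      damage_mean = 1.5),
      metabolic_like = list(size = 20L, delta = 1.5, length_bias = FALSE,
                            damage_mean = 1.2),
      cardiac_like = list(size = 15L, delta = 1, length_bias = FALSE,
                          damage_mean = 1.0)),
    ...)
}
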