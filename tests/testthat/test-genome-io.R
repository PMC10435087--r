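test_that("compute_gc follows the G+C over unambiguous-bases rule", {
  expect_equal(compute_gc("GGCC"), 1.0)
  expect_equal(compute_gc("ATAT"), 0.0)
  expect_equal(compute_gc("ACGN"), 2 / 3)
  expect_true(is.na(compute_gc("NNNN")))
  expect_true(is.na(compute_gc("")))
  # GC + AT = 1 for ambiguity-free sequences
  set.seed(11)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
               collapse = "")
    at <- (nchar(s) - nchar(gsub("[AT]", "", s))) / nchar(s)
    expect_equal(compute_gc(s) + at, 1)
  }
})

test_that("gene models merge CDS across transcripts and use the stated length conventions", {
  genome <- c(chr1 = toy_chromosome(400))
  gtf <- write_toy_gtf(c(
    gtf_gene_line("chr1", 101, 200, "g1"),
    gtf_cds_line("chr1", 121, 150, "g1", tx = "t1"),
    gtf_cds_line("chr1", 141, 170, "g1", tx = "t2"),
    gtf_gene_line("chr1", 250, 320, "g2")))
  gm <- read_gene_models(gtf, genome)
  g1 <- gm[gm$gene_id == "g1", ]
  # gene_length is the annotation's end minus start, not the span width
  expect_equal(g1$gene_length, 99L)
  expect_equal(g1$end - g1$start, 100L)
  # two transcripts' CDS merge to one interval of width 50
  cds <- g1$cds_intervals[[1]]
  expect_equal(nrow(cds), 1L)
  expect_equal(unname(cds[1, "end"] - cds[1, "start"]), 50L)
  expect_equal(g1$cds_length, 50L)
  # CDS GC agrees with direct computation on the merged subsequence
  expect_equal(g1$cds_gc, compute_gc(substr(genome[["chr1"]], 121, 170)))
  # gene with no CDS features
  g2 <- gm[gm$gene_id == "g2", ]
  expect_equal(g2$cds_length, 0L)
  expect_equal(nrow(g2$cds_intervals[[1]]), 0L)
})

test_that("gene model validation catches bad annotations", {
  genome <- c(chr1 = toy_chromosome(400))
  bad_cds <- write_toy_gtf(c(
    gtf_gene_line("chr1", 101, 200, "g1"),
    gtf_cds_line("chr1", 90, 120, "g1")))
  expect_error(read_gene_models(bad_cds, genome), "outside the gene span")
  wrong_chr <- write_toy_gtf(gtf_gene_line("chr9", 101, 200, "g1"))
  expect_error(read_gene_models(wrong_chr, genome), "absent from the genome")
})

test_that("expression joins by exact symbol and unmatched genes stay in", {
  genome <- c(chr1 = toy_chromosome(400))
  gtf <- write_toy_gtf(c(gtf_gene_line("chr1", 101, 200, "g1", "SYM1"),
                         gtf_gene_line("chr1", 250, 320, "g2", "SYM2")))
  expr <- data.frame(symbol = "SYM1", rpkm = 7.5)
  gm <- read_gene_models(gtf, genome, expr)
  expect_equal(gm$expression[gm$symbol == "SYM1"], 7.5)
  expect_true(is.na(gm$expression[gm$symbol == "SYM2"]))
  expect_equal(nrow(gm), 2L)
})

test_that("mutation table reader validates, skips non-SNVs, rejects unknown subclones", {
  man <- toy_manifest()
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(
    subclone_id = c("PAH_s1", "PAH_s2", "radiation_s1"),
    chrom = "chr1", pos = c(10, 20, 30),
    ref = c("A", "C", "G"), alt = c("T", "T", "A")),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- read_mutation_table(tsv, man)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$exposure_class,
               c("PAH", "PAH", "radiation"))

  # dinucleotide ref -> skipped with count 1
  write.table(data.frame(subclone_id = c("PAH_s1", "PAH_s1"),
                         chrom = "chr1", pos = c(10, 20),
                         ref = c("AT", "C"), alt = c("GC", "T")),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(rec <- read_mutation_table(tsv, man), "non-SNV")
  expect_equal(nrow(rec), 1L)
  expect_equal(attr(rec, "n_skipped"), 1L)

  # malformed row -> hard error naming the line
  write.table(data.frame(subclone_id = "PAH_s1", chrom = "chr1",
                         pos = "xyz", ref = "A", alt = "T"),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_mutation_table(tsv, man), "line 2")

  # unknown subclone -> rejected with count reported
  write.table(data.frame(subclone_id = c("PAH_s1", "ghost"),
                         chrom = "chr1", pos = c(10, 20),
                         ref = c("A", "C"), alt = c("T", "T")),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(rec <- read_mutation_table(tsv, man), "rejected")
  expect_equal(nrow(rec), 1L)
  expect_equal(attr(rec, "n_unknown_subclone"), 1L)
})

test_that("mutation catalogs round-trip through TSV exactly", {
  man <- toy_manifest()
  rec <- toy_catalog(c("PAH_s1", "radiation_s2"), "chr1", c(5, 9),
                     c("A", "G"), c("C", "T"),
                     exposure_class = c("PAH", "radiation"),
                     chemical = c("PAH", "radiation"))
  path <- tempfile(fileext = ".tsv")
  write_mutation_table(rec, path)
  back <- read_mutation_table(path, man)
  expect_equal(as.data.frame(back), as.data.frame(rec))
})

test_that("VCF input yields one record per carrier sample with manifest classes", {
  man <- toy_manifest()
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "##contig=<ID=chr1,length=1000>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "PAH_s1", "radiation_s1", sep = "\t"),
    paste("chr1", 5, ".", "A", "G", ".", "PASS", ".", "GT", "1/1", "0/0",
          sep = "\t"),
    paste("chr1", 10, ".", "C", "T", ".", "PASS", ".", "GT", "0/0", "0/1",
          sep = "\t")), vcf)
  rec <- read_mutation_table(vcf, man)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$subclone_id, c("PAH_s1", "radiation_s1"))
  expect_equal(rec$exposure_class, c("PAH", "radiation"))
  expect_equal(rec$pos, c(5L, 10L))
  expect_equal(rec$ref, c("A", "C"))
  expect_equal(rec$alt, c("G", "T"))
})

test_that("bedGraph reader sorts and validates the signal track", {
  bg <- tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t100\t200\t1.5", "chr1\t300\t400\t2.0"), bg)
  tr <- read_bedgraph(bg)
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$value, c(1.5, 2.0))

  writeLines(c("chr1\t300\t400\t2.0", "chr1\t100\t200\t1.5"), bg)
  tr2 <- read_bedgraph(bg)
  expect_equal(tr2$start, c(100L, 300L))  # sorted output

  writeLines(c("chr1\t100\t250\t1.0", "chr1\t200\t300\t1.0"), bg)
  expect_error(read_bedgraph(bg), "overlapping")

  writeLines("chr1\t100\t200\t-1.0", bg)
  expect_error(read_bedgraph(bg), "negative")
})

test_that("mutation assignment uses half-open gene spans on the 1-based GTF end", {
  genes <- toy_gene_models(toy_gene("g1", "chr1", 101, 200))
  man <- toy_manifest()
  rec <- toy_catalog(rep("PAH_s1", 3), "chr1", c(101, 100, 200),
                     "A", "T")
  cnt <- assign_mutations(rec, genes)
  # pos 101 and pos 200 inside, pos 100 outside
  expect_equal(sum(cnt$gene_count), 2L)
  expect_equal(attr(cnt, "n_unassigned"), 1L)
})

test_that("overlapping genes each receive the mutation; brute force agrees", {
  genes <- toy_gene_models(
    toy_gene("g1", "chr1", 101, 200, cds1 = list(c(121, 150))),
    toy_gene("g2", "chr1", 151, 260),
    toy_gene("g3", "chr1", 400, 450))
  set.seed(3)
  pos <- sample(90:470, 60, replace = TRUE)
  rec <- toy_catalog(rep("PAH_s1", 60), "chr1", pos, "A", "T")
  cnt <- assign_mutations(rec, genes)
  # brute-force per-position scan
  brute <- sapply(seq_len(nrow(genes)), function(i)
    sum(pos - 1 >= genes$start[i] & pos - 1 < genes$end[i]))
  got <- sapply(genes$gene_id, function(g)
    sum(cnt$gene_count[cnt$gene_id == g]))
  expect_equal(unname(got), brute)
  n_genic <- sum(sapply(pos, function(p)
    any(p - 1 >= genes$start & p - 1 < genes$end)))
  expect_gte(sum(cnt$gene_count), n_genic)  # overlaps double-count
  expect_equal(attr(cnt, "n_unassigned"), length(pos) - n_genic)
  # CDS-level counts never exceed gene-level counts
  expect_true(all(cnt$cds_count <= cnt$gene_count))
  # brute-force CDS check for g1
  cds_brute <- sum(pos - 1 >= 120 & pos - 1 < 150)
  expect_equal(sum(cnt$cds_count[cnt$gene_id == "g1"]), cds_brute)
})
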