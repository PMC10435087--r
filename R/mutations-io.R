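#' Build or read a subclone manifest
#'
#' The manifest maps each subclone to its exposure class (and, optionally,
#' the specific chemical). Every mutation record must name a subclone listed
#' here; subclones with zero mutations still contribute to the denominators
#' of per-gene-per-subclone rates, which is why the manifest is a separate
#' input rather than being derived from the catalog.
#'
#' @param x a data frame with columns `subclone_id`, `exposure_class` and
#'   optionally `chemical`, or a path to a TSV with those columns.
#' @return validated data frame of class `subclone_manifest`.
#' @export
subclone_manifest <- function(x) {
  if (is.character(x) && length(x) == 1L)
    x <- utils::read.delim(x, stringsAsFactors = FALSE)
  stopifnot(all(c("subclone_id", "exposure_class") %in% names(x)))
  if (is.null(x$chemical)) x$chemical <- NA_character_
  x$subclone_id <- as.character(x$subclone_id)
  x$exposure_class <- as.character(x$exposure_class)
  if (anyDuplicated(x$subclone_id))
    stop("duplicated subclone_id in manifest")
  x <- x[, c("subclone_id", "exposure_class", "chemical")]
  class(x) <- c("subclone_manifest", "data.frame")
  x
}

#' Number of subclones in an exposure class
#' @param manifest a `subclone_manifest`.
#' @param class exposure class name.
#' @return integer count (error if the class has no subclones).
#' @export
n_subclones <- function(manifest, class) {
  n <- sum(manifest$exposure_class == class)
  if (n < 1L) stop("exposure class '", class, "' has no subclones")
  n
}

valid_bases <- c("A", "C", "G", "T")

#' Read a single-nucleotide substitution catalog
#'
#' Accepts either a TSV with columns `subclone_id`, `chrom`, `pos`, `ref`,
#' `alt` (1-based positions) or a VCF in which sample names are subclone ids
#' and a sample carries a variant when its genotype contains the alternate
#' allele. Only single-base substitutions are kept: indel/MNV rows are
#' skipped and counted. Records naming subclones absent from the manifest
#' are rejected and counted. Exposure class and chemical are joined from the
#' manifest.
#'
#' @param path input TSV or VCF path.
#' @param manifest a [subclone_manifest()].
#' @return data frame of class `mutation_catalog` with columns
#'   `subclone_id`, `exposure_class`, `chemical`, `chrom`, `pos`, `ref`,
#'   `alt`, plus attributes `n_skipped` (non-SNV rows) and
#'   `n_unknown_subclone` (rejected records).
#' @export
read_mutation_table <- function(path, manifest) {
  stopifnot(file.exists(path))
  manifest <- subclone_manifest(manifest)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\\.vcf(\\.gz)?$", path) || startsWith(first, "##fileformat=VCF"))
    return(read_mutation_vcf(path, manifest))

  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("subclone_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("mutation table must have columns: ", paste(need, collapse = ", "))

  pos <- suppressWarnings(as.integer(df$pos))
  ref <- toupper(df$ref)
  alt <- toupper(df$alt)
  bad <- which(is.na(pos) | pos < 1L |
                 !grepl("^[ACGTacgt]+$", df$ref) |
                 !grepl("^[ACGTacgt]+$", df$alt) |
                 (nchar(ref) == 1L & nchar(alt) == 1L & ref == alt))
  if (length(bad))
    stop("malformed mutation row at line ", bad[1L] + 1L,
         " of ", path)
  is_snv <- nchar(ref) == 1L & nchar(alt) == 1L
  n_skipped <- sum(!is_snv)
  if (n_skipped)
    warning(n_skipped, " non-SNV record(s) (indel/MNV) skipped")
  df <- df[is_snv, , drop = FALSE]
  pos <- pos[is_snv]; ref <- ref[is_snv]; alt <- alt[is_snv]

  known <- df$subclone_id %in% manifest$subclone_id
  n_unknown <- sum(!known)
  if (n_unknown)
    message(n_unknown, " record(s) with subclone ids absent from the ",
            "manifest rejected")
  df <- df[known, , drop = FALSE]
  j <- match(df$subclone_id, manifest$subclone_id)
  out <- data.frame(
    subclone_id = df$subclone_id,
    exposure_class = manifest$exposure_class[j],
    chemical = manifest$chemical[j],
    chrom = df$chrom, pos = pos[known],
    ref = ref[known], alt = alt[known],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, n_skipped = n_skipped, n_unknown_subclone = n_unknown,
            class = c("mutation_catalog", "data.frame"))
}

read_mutation_vcf <- function(path, manifest) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field; cannot assign subclones")
  samples <- colnames(gt)
  recs <- list()
  n_skipped <- 0L
  for (i in seq_along(rr)) {
    alts <- as.character(altl[[i]])
    for (s in samples) {
      g <- gt[i, s]
      if (is.na(g) || g %in% c(".", "./.", ".|.")) next
      ai <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
      ai <- unique(ai[!is.na(ai) & ai > 0L])
      for (a in ai) {
        alt <- alts[a]
        if (nchar(ref[i]) != 1L || nchar(alt) != 1L ||
            !ref[i] %in% valid_bases || !alt %in% valid_bases) {
          n_skipped <- n_skipped + 1L
          next
        }
        recs[[length(recs) + 1L]] <- data.frame(
          subclone_id = s,
          chrom = as.character(GenomicRanges::seqnames(rr)[i]),
          pos = GenomicRanges::start(rr)[i],
          ref = ref[i], alt = alt, stringsAsFactors = FALSE)
      }
    }
  }
  if (n_skipped) warning(n_skipped, " non-SNV VCF genotype(s) skipped")
  df <- if (length(recs)) do.call(rbind, recs) else
    data.frame(subclone_id = character(0), chrom = character(0),
               pos = integer(0), ref = character(0), alt = character(0))
  known <- df$subclone_id %in% manifest$subclone_id
  n_unknown <- sum(!known)
  if (n_unknown)
    message(n_unknown, " record(s) with subclone ids absent from the ",
            "manifest rejected")
  df <- df[known, , drop = FALSE]
  j <- match(df$subclone_id, manifest$subclone_id)
  out <- data.frame(
    subclone_id = df$subclone_id,
    exposure_class = manifest$exposure_class[j],
    chemical = manifest$chemical[j],
    chrom = df$chrom, pos = df$pos, ref = df$ref, alt = df$alt,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, n_skipped = n_skipped, n_unknown_subclone = n_unknown,
            class = c("mutation_catalog", "data.frame"))
}

#' Write a mutation catalog to TSV
#'
#' Inverse of the TSV branch of [read_mutation_table()]: re-reading the file
#' with the same manifest reproduces the catalog exactly.
#'
#' @param records a `mutation_catalog` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(records, path) {
  utils::write.table(
    records[, c("subclone_id", "exposure_class", "chemical",
                "chrom", "pos", "ref", "alt")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a mutation catalog against a genome
#'
#' Checks that every position lies within its chromosome. Used by the
#' context module before sequence extraction.
#' @param records a `mutation_catalog`.
#' @param genome named character vector of chromosome sequences.
#' @return `records`, invisibly (errors on violation).
#' @export
validate_positions <- function(records, genome) {
  missing_chr <- setdiff(unique(records$chrom), names(genome))
  if (length(missing_chr))
    stop("chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "))
  len <- nchar(genome)[records$chrom]
  if (any(records$pos > len))
    stop("mutation position beyond chromosome end")
  invisible(records)
}
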