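#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the generator with desk-scale defaults chosen to
#' echo the structure of a mutagen-exposure screen: a small genome, a few
#' hundred non-overlapping genes with log-normal lengths, beta-distributed
#' per-gene GC, log-normal expression, exposure classes with their own
#' subclone counts and intensity multipliers, a log-linear per-gene rate
#' model on length/GC/expression, disease-like gene sets with
#' multiplicative rate excess `delta`, and a per-set damage-track model.
#' With the defaults the realized per-gene-per-subclone mutation rate for
#' the most intense class is about 0.06.
#'
#' @param seed master RNG seed; all stage seeds derive from it.
#' @param n_chromosomes,chrom_length genome dimensions (default 4 x 1 Mb).
#' @param gc_content background genome GC fraction.
#' @param n_genes number of genes (default 400).
#' @param gene_meanlog,gene_sdlog log-normal gene-length parameters.
#' @param gene_length_range clamp on sampled gene lengths.
#' @param gc_beta length-2 vector, beta parameters of per-gene GC.
#' @param expr_meanlog,expr_sdlog log-normal RPKM parameters.
#' @param classes data frame with columns `class`, `n_subclones`,
#'   `multiplier` (class-specific rate intensity).
#' @param beta0,beta_length,beta_gc,beta_expr log-linear rate coefficients
#'   (length in nt, GC as fraction, expression in RPKM).
#' @param sets named list; each element a list with `size`, `delta` (rate
#'   multiplier for member genes), `length_bias` (sample members with
#'   probability proportional to length) and `damage_mean`.
#' @param overdispersion `NULL` for Poisson counts, or a negative-binomial
#'   size parameter (smaller = more overdispersed).
#' @param intergenic_rate expected intergenic mutations per subclone per
#'   megabase (0 disables the background).
#' @param damage_baseline,damage_sd damage-track mean for genes outside all
#'   sets, and Gaussian noise sd (values truncated at 0).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 4L, chrom_length = 1e6,
                              gc_content = 0.5,
                              n_genes = 400L,
                              gene_meanlog = log(6000), gene_sdlog = 0.6,
                              gene_length_range = c(500, 40000),
                              gc_beta = c(14, 14),
                              expr_meanlog = log(10), expr_sdlog = 1,
                              classes = data.frame(
                                class = c("radiation", "PAH", "nitrosamine"),
                                n_subclones = c(10L, 10L, 10L),
                                multiplier = c(1.5, 1.3, 0.6)),
                              beta0 = -3.9, beta_length = 3e-5,
                              beta_gc = 1, beta_expr = 0.002,
                              sets = list(
                                NDD_like = list(size = 90L, delta = 2,
                                                length_bias = TRUE,
                                                damage_mean = 1.5),
                                metabolic_like = list(size = 80L,
                                                      delta = 1.5,
                                                      length_bias = FALSE,
                                                      damage_mean = 1.2),
                                cardiac_like = list(size = 30L, delta = 1,
                                                    length_bias = FALSE,
                                                    damage_mean = 1.0)),
                              overdispersion = NULL,
                              intergenic_rate = 0,
                              damage_baseline = 1.0, damage_sd = 0.3) {
  cfg <- list(seed = seed, n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              gc_content = gc_content, n_genes = as.integer(n_genes),
              gene_meanlog = gene_meanlog, gene_sdlog = gene_sdlog,
              gene_length_range = gene_length_range, gc_beta = gc_beta,
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              classes = classes, beta0 = beta0, beta_length = beta_length,
              beta_gc = beta_gc, beta_expr = beta_expr, sets = sets,
              overdispersion = overdispersion,
              intergenic_rate = intergenic_rate,
              damage_baseline = damage_baseline, damage_sd = damage_sd)
  stopifnot(all(c("class", "n_subclones", "multiplier") %in%
                  names(cfg$classes)),
            all(cfg$classes$n_subclones >= 1L),
            all(cfg$classes$multiplier >= 0))
  class(cfg) <- "simulation_config"
  cfg
}

random_sequence <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a synthetic genome
#'
#' Independent random bases at the configured GC fraction, one chromosome
#' per `n_chromosomes`, named `chr1..chrN`. Reproducible under the config
#' seed.
#'
#' @param config a [simulation_config()].
#' @return named character vector of chromosome sequences.
#' @export
generate_genome <- function(config) {
  with_seed(child_seed(config$seed, 1L), {
    gc <- rep_len(config$gc_content, config$n_chromosomes)
    seqs <- vapply(seq_len(config$n_chromosomes),
                   function(i) random_sequence(config$chrom_length, gc[i]),
                   character(1))
    stats::setNames(seqs, paste0("chr", seq_len(config$n_chromosomes)))
  })
}

#' Generate synthetic gene models, gene sets and expression
#'
#' Places non-overlapping genes with log-normal lengths along the
#' chromosomes, rewrites each gene's sequence at its own beta-distributed
#' GC target (so GC varies between genes), carves 1-3 disjoint internal
#' CDS intervals per gene, samples log-normal expression, and draws
#' disjoint disease-like gene sets - optionally with sampling probability
#' proportional to gene length, emulating disease sets dominated by long
#' genes. Returns the updated genome alongside the annotation.
#'
#' @param config a [simulation_config()].
#' @param genome genome from [generate_genome()].
#' @return list with `genes` (a `gene_models` data frame), `sets` (named
#'   list of symbol vectors), `expression` (data frame `symbol`, `rpkm`)
#'   and `genome` (with gene spans rewritten).
#' @export
generate_annotation <- function(config, genome) {
  with_seed(child_seed(config$seed, 2L), {
    n_chr <- length(genome)
    per_chr <- rep(config$n_genes %/% n_chr, n_chr)
    per_chr[seq_len(config$n_genes %% n_chr)] <-
      per_chr[seq_len(config$n_genes %% n_chr)] + 1L
    rows <- list()
    gi <- 0L
    for (ci in seq_len(n_chr)) {
      cursor <- 1L
      chrom <- names(genome)[ci]
      chrom_len <- nchar(genome[[ci]])
      for (k in seq_len(per_chr[ci])) {
        gap <- sample(100:1000, 1L)
        len <- round(stats::rlnorm(1, config$gene_meanlog,
                                   config$gene_sdlog))
        len <- min(max(len, config$gene_length_range[1L]),
                   config$gene_length_range[2L])
        start0 <- cursor + gap  # 0-based start
        end0 <- start0 + len
        if (end0 + 1L > chrom_len)
          stop("chromosome ", chrom, " too short to place ", per_chr[ci],
               " genes; increase chrom_length or reduce n_genes")
        gi <- gi + 1L
        # rewrite the gene span at its own GC target
        gc_g <- stats::rbeta(1, config$gc_beta[1L], config$gc_beta[2L])
        seq_g <- random_sequence(end0 - start0, gc_g)
        substr(genome[[ci]], start0 + 1L, end0) <- seq_g
        # 1-3 disjoint internal CDS pieces, one per equal block
        n_cds <- sample(1:3, 1L)
        block <- (end0 - start0) %/% n_cds
        cds <- matrix(0L, n_cds, 2L,
                      dimnames = list(NULL, c("start", "end")))
        for (b in seq_len(n_cds)) {
          bw <- max(30L, round(block * stats::runif(1, 0.05, 0.25)))
          bw <- min(bw, block - 2L)
          off <- sample.int(block - bw - 1L, 1L)
          cds[b, ] <- c(start0 + (b - 1L) * block + off,
                        start0 + (b - 1L) * block + off + bw)
        }
        rows[[gi]] <- data.frame(
          gene_id = sprintf("SIMG%04d", gi),
          symbol = sprintf("G%04d", gi),
          chrom = chrom, strand = sample(c("+", "-"), 1L),
          start = start0, end = end0,
          gene_length = end0 - start0 - 1L,  # GTF end minus start
          cds_length = sum(cds[, "end"] - cds[, "start"]),
          stringsAsFactors = FALSE)
        rows[[gi]]$cds_intervals <- I(list(cds))
        cursor <- end0
      }
    }
    genes <- do.call(rbind, rows)
    # covariates from the final sequence
    seqs <- substring(genome[genes$chrom], genes$start + 1L, genes$end)
    genes$gene_gc <- compute_gc(seqs)
    genes$cds_gc <- vapply(seq_len(nrow(genes)), function(i) {
      m <- genes$cds_intervals[[i]]
      compute_gc(paste(substring(genome[[genes$chrom[i]]],
                                 m[, "start"] + 1L, m[, "end"]),
                       collapse = ""))
    }, numeric(1))
    genes$expression <- stats::rlnorm(nrow(genes), config$expr_meanlog,
                                      config$expr_sdlog)
    genes <- genes[, c("gene_id", "symbol", "chrom", "strand", "start",
                       "end", "gene_length", "cds_length", "gene_gc",
                       "cds_gc", "expression", "cds_intervals")]
    class(genes) <- c("gene_models", "data.frame")

    # disjoint disease-like sets
    sets <- list()
    pool <- genes$symbol
    for (nm in names(config$sets)) {
      sc <- config$sets[[nm]]
      if (sc$size > length(pool))
        stop("not enough genes left to draw set '", nm, "'")
      w <- if (isTRUE(sc$length_bias))
        genes$gene_length[match(pool, genes$symbol)] else NULL
      members <- sample(pool, sc$size, prob = w)
      sets[[nm]] <- sort(members)
      pool <- setdiff(pool, members)
    }
    expression <- data.frame(symbol = genes$symbol,
                             rpkm = genes$expression,
                             stringsAsFactors = FALSE)
    list(genes = genes, sets = sets, expression = expression,
         genome = genome)
  })
}

#' Subclone manifest for a simulation config
#'
#' One subclone per class member, ids `<class>_s01 ...`; the chemical label
#' reuses the class name.
#' @param config a [simulation_config()].
#' @return a [subclone_manifest()].
#' @export
generate_manifest <- function(config) {
  cl <- config$classes
  rows <- lapply(seq_len(nrow(cl)), function(i)
    data.frame(subclone_id = sprintf("%s_s%02d", cl$class[i],
                                     seq_len(cl$n_subclones[i])),
               exposure_class = cl$class[i], chemical = cl$class[i],
               stringsAsFactors = FALSE))
  subclone_manifest(do.call(rbind, rows))
}

# Per-gene expected rate per subclone for each class:
# lambda = multiplier * delta^(member) * exp(b0 + bl*len + bgc*gc + be*expr)
simulation_lambda <- function(config, genes, sets) {
  delta <- rep(1, nrow(genes))
  for (nm in names(sets)) {
    d <- config$sets[[nm]]$delta %||% 1
    delta[genes$symbol %in% sets[[nm]]] <- d
  }
  base <- exp(config$beta0 + config$beta_length * genes$gene_length +
                config$beta_gc * genes$gene_gc +
                config$beta_expr * genes$expression)
  lam <- outer(delta * base, config$classes$multiplier)
  dimnames(lam) <- list(genes$gene_id, config$classes$class)
  lam
}

#' Simulate per-(gene, subclone) mutation counts
#'
#' Draws counts from the configured rate model without placing genomic
#' positions: `gene_count ~ Poisson(lambda)` (or negative binomial under
#' overdispersion) and `cds_count ~ Binomial(gene_count, cds width / gene
#' width)`, matching uniform placement of mutations within the gene span.
#' Useful when only the counting layer is needed.
#'
#' @param config a [simulation_config()].
#' @param genes gene models from [generate_annotation()].
#' @param sets gene sets from [generate_annotation()].
#' @param manifest a [subclone_manifest()].
#' @param seed RNG seed (default: derived from the config seed).
#' @return list with `counts` (a `mutation_counts` data frame) and
#'   `lambda` (gene x class matrix of true rates).
#' @export
simulate_gene_counts <- function(config, genes, sets, manifest,
                                 seed = NULL) {
  seed <- seed %||% child_seed(config$seed, 3L)
  lam <- simulation_lambda(config, genes, sets)
  p_cds <- genes$cds_length / (genes$end - genes$start)
  counts <- with_seed(seed, {
    rows <- list()
    for (s in seq_len(nrow(manifest))) {
      cl <- manifest$exposure_class[s]
      lg <- lam[, cl]
      n <- if (is.null(config$overdispersion)) stats::rpois(length(lg), lg)
           else stats::rnbinom(length(lg), size = config$overdispersion,
                               mu = lg)
      hit <- which(n > 0L)
      if (!length(hit)) next
      nc <- stats::rbinom(length(hit), n[hit], p_cds[hit])
      rows[[length(rows) + 1L]] <- data.frame(
        subclone_id = manifest$subclone_id[s], exposure_class = cl,
        gene_id = genes$gene_id[hit], gene_count = n[hit], cds_count = nc,
        stringsAsFactors = FALSE)
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(subclone_id = character(0), exposure_class = character(0),
                 gene_id = character(0), gene_count = integer(0),
                 cds_count = integer(0))
    rownames(out) <- NULL
    out
  })
  list(counts = structure(counts, n_unassigned = 0L,
                          n_records = sum(counts$gene_count),
                          class = c("mutation_counts", "data.frame")),
       lambda = lam)
}

#' Simulate a substitution catalog with genomic positions
#'
#' Expands [simulate_gene_counts()] draws into individual records:
#' positions uniform within the gene span, reference allele read from the
#' genome, alternate allele uniform over the other three bases. An optional
#' intergenic background scatters additional mutations uniformly over the
#' gene-free part of the genome.
#'
#' @inheritParams simulate_gene_counts
#' @param genome the (annotation-updated) genome.
#' @return list with `records` (a `mutation_catalog`), `truth` (list:
#'   `lambda`, coefficient vector, per-set `delta`, seeds) and `counts`.
#' @export
simulate_mutations <- function(config, genes, sets, manifest, genome,
                               seed = NULL) {
  seed <- seed %||% child_seed(config$seed, 3L)
  sim <- simulate_gene_counts(config, genes, sets, manifest, seed = seed)
  counts <- sim$counts
  records <- with_seed(child_seed(seed, 7L), {
    rows <- list()
    for (i in seq_len(nrow(counts))) {
      gi <- match(counts$gene_id[i], genes$gene_id)
      n <- counts$gene_count[i]
      pos <- genes$start[gi] + sample.int(genes$end[gi] - genes$start[gi],
                                          n, replace = TRUE)  # 1-based
      ref <- substring(genome[[genes$chrom[gi]]], pos, pos)
      alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"),
                                                    r), 1L), character(1),
                    USE.NAMES = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        subclone_id = counts$subclone_id[i],
        exposure_class = counts$exposure_class[i],
        chemical = manifest$chemical[match(counts$subclone_id[i],
                                           manifest$subclone_id)],
        chrom = genes$chrom[gi], pos = pos, ref = ref, alt = alt,
        stringsAsFactors = FALSE)
    }
    if (config$intergenic_rate > 0) {
      inter <- intergenic_intervals(genes, genome)
      tot_w <- sum(inter$end - inter$start)
      for (s in seq_len(nrow(manifest))) {
        n <- stats::rpois(1, config$intergenic_rate * tot_w / 1e6)
        if (n == 0L) next
        j <- sample(nrow(inter), n, replace = TRUE,
                    prob = inter$end - inter$start)
        pos <- inter$start[j] +
          vapply(inter$end[j] - inter$start[j],
                 function(w) sample.int(w, 1L), integer(1))
        ref <- substring(genome[inter$chrom[j]], pos, pos)
        alt <- vapply(ref, function(r)
          sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1),
          USE.NAMES = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          subclone_id = manifest$subclone_id[s],
          exposure_class = manifest$exposure_class[s],
          chemical = manifest$chemical[s],
          chrom = inter$chrom[j], pos = pos, ref = ref, alt = alt,
          stringsAsFactors = FALSE)
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(subclone_id = character(0), exposure_class = character(0),
                 chemical = character(0), chrom = character(0),
                 pos = integer(0), ref = character(0),
                 alt = character(0))
    out <- out[order(out$subclone_id, out$chrom, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  records <- structure(records, n_skipped = 0L, n_unknown_subclone = 0L,
                       class = c("mutation_catalog", "data.frame"))
  truth <- list(
    lambda = sim$lambda,
    beta = c(beta0 = config$beta0, beta_length = config$beta_length,
             beta_gc = config$beta_gc, beta_expr = config$beta_expr),
    delta = vapply(config$sets, function(s) s$delta %||% 1, numeric(1)),
    seed = seed)
  list(records = records, truth = truth, counts = counts)
}

intergenic_intervals <- function(genes, genome) {
  rows <- list()
  for (chrom in names(genome)) {
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    bounds <- c(0L, as.vector(rbind(g$start, g$end)), nchar(genome[[chrom]]))
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    keep <- ends > starts
    if (any(keep))
      rows[[chrom]] <- data.frame(chrom = chrom, start = starts[keep],
                                  end = ends[keep],
                                  stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic DNA-damage track
#'
#' Constant signal per gene span: the gene's set damage mean (baseline for
#' genes outside every set) plus Gaussian noise, truncated at zero.
#' Intergenic regions are uncovered.
#'
#' @inheritParams simulate_gene_counts
#' @return a `signal_track` data frame (bedGraph-shaped).
#' @export
generate_damage_track <- function(config, genes, sets, seed = NULL) {
  seed <- seed %||% child_seed(config$seed, 4L)
  mean_g <- rep(config$damage_baseline, nrow(genes))
  for (nm in names(sets)) {
    m <- config$sets[[nm]]$damage_mean %||% config$damage_baseline
    mean_g[genes$symbol %in% sets[[nm]]] <- m
  }
  vals <- with_seed(seed,
                    pmax(0, mean_g + stats::rnorm(nrow(genes),
                                                  sd = config$damage_sd)))
  validate_signal_track(data.frame(chrom = genes$chrom,
                                   start = genes$start, end = genes$end,
                                   value = vals, stringsAsFactors = FALSE))
}

#' Generate a complete synthetic study
#'
#' Runs every generator stage and, when `dir` is given, writes the full
#' fixture bundle in the formats the readers expect: `genome.fa`,
#' `genes.gtf`, `sets/<name>.txt`, `expression.tsv`, `manifest.tsv`,
#' `mutations.tsv`, `damage.bedGraph`.
#'
#' @param config a [simulation_config()].
#' @param dir optional output directory.
#' @return list with `config`, `genome`, `genes`, `sets`, `expression`,
#'   `manifest`, `records`, `counts`, `truth`, `damage`, and `paths` (when
#'   written).
#' @export
simulate_study <- function(config = simulation_config(), dir = NULL) {
  genome <- generate_genome(config)
  ann <- generate_annotation(config, genome)
  manifest <- generate_manifest(config)
  sim <- simulate_mutations(config, ann$genes, ann$sets, manifest,
                            ann$genome)
  damage <- generate_damage_track(config, ann$genes, ann$sets)
  out <- list(config = config, genome = ann$genome, genes = ann$genes,
              sets = ann$sets, expression = ann$expression,
              manifest = manifest, records = sim$records,
              counts = sim$counts, truth = sim$truth, damage = damage)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "sets"), showWarnings = FALSE)
    paths <- list(
      genome = file.path(dir, "genome.fa"),
      gtf = file.path(dir, "genes.gtf"),
      expression = file.path(dir, "expression.tsv"),
      manifest = file.path(dir, "manifest.tsv"),
      mutations = file.path(dir, "mutations.tsv"),
      damage = file.path(dir, "damage.bedGraph"),
      sets = file.path(dir, "sets"))
    write_genome(ann$genome, paths$genome)
    write_gtf(ann$genes, paths$gtf)
    utils::write.table(ann$expression, paths$expression, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(manifest, paths$manifest, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_mutation_table(sim$records, paths$mutations)
    write_bedgraph(damage, paths$damage)
    for (nm in names(ann$sets))
      writeLines(ann$sets[[nm]], file.path(dir, "sets",
                                           paste0(nm, ".txt")))
    out$paths <- paths
  }
  out
}
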