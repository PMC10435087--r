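#' Run the full analysis pipeline
#'
#' Orchestrates every stage on a synthetic study (or on files already on
#' disk): simulate/write, re-read through the standard readers, assign
#' mutations, gene-set enrichment at gene and CDS level, quasi-Poisson
#' mutability models, sequence-context summaries, and damage-enrichment
#' group tests. Results and a machine-readable run manifest
#' (`MANIFEST.json`: version, seeds, decision flags, input digests) are
#' written under `out_dir`.
#'
#' @param config a [simulation_config()] describing the synthetic study.
#' @param out_dir output directory (created if needed).
#' @param n_sets,set_size random-null dimensions for the enrichment stage
#'   (desk-scale defaults 500 x 50; the full-scale analysis uses 1000 x
#'   300).
#' @param monte_carlo also compute Monte-Carlo empirical-null p-values.
#' @return list with `enrichment_gene`, `enrichment_cds`, `fit_gene`,
#'   `fit_cds`, `kmers`, `random_kmers`, `spectrum`, `damage`,
#'   `damage_tests`, `sweep`, `study`, `manifest`, invisibly.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir,
                         n_sets = 500L, set_size = 50L,
                         monte_carlo = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- simulate_study(config, dir = file.path(out_dir, "fixtures"))

  # ingest through the standard readers (round-trip of the written files)
  genome <- read_genome(study$paths$genome)
  genes <- read_gene_models(study$paths$gtf, genome,
                            expression = study$paths$expression)
  manifest <- subclone_manifest(study$paths$manifest)
  records <- read_mutation_table(study$paths$mutations, manifest)
  sets <- read_gene_sets(study$paths$sets)
  track <- read_bedgraph(study$paths$damage)

  counts <- assign_mutations(records, genes)
  seed_enrich <- child_seed(config$seed, 11L)
  enr_gene <- enrich_gene_sets(counts, genes, sets, manifest,
                               level = "gene", n_sets = n_sets,
                               set_size = set_size, seed = seed_enrich,
                               monte_carlo = monte_carlo)
  enr_cds <- enrich_gene_sets(counts, genes, sets, manifest,
                              level = "cds", n_sets = n_sets,
                              set_size = set_size, seed = seed_enrich,
                              monte_carlo = monte_carlo)
  sweep <- setsize_sweep(counts, genes$gene_id,
                         class = config$classes$class[1L],
                         manifest = manifest,
                         sizes = seq(10L, min(300L, nrow(genes)), 10L),
                         n_sets = n_sets,
                         seed = child_seed(config$seed, 12L))

  fit_gene <- fit_mutability(mutations ~ length + expression + gc_percent,
                             mutability_data(counts, genes, "gene"))
  fit_cds <- fit_mutability(mutations ~ length + expression + gc_percent,
                            mutability_data(counts, genes, "cds"))

  kmers <- extract_kmers(records, genome, k = 7L)
  random_kmers <- sample_random_kmers(genome, n = 50000L, k = 7L,
                                      seed = child_seed(config$seed, 13L))
  spectrum <- trinucleotide_spectrum(records, genome)

  damage <- damage_by_set(track, genes, sets, level = "gene")
  damage_tests <- list(
    anova = one_way_anova(damage),
    contrasts = pairwise_contrasts_fdr(damage),
    kruskal = kruskal_wallis(damage),
    dunn = dunns_test(damage))

  # write tabular twins of the main results
  utils::write.table(enr_gene$table,
                     file.path(out_dir, "enrichment_gene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(enr_cds$table,
                     file.path(out_dir, "enrichment_cds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sweep, file.path(out_dir, "setsize_sweep.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(iqr_rate_ratio(fit_gene),
                     file.path(out_dir, "rate_ratios_gene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(iqr_rate_ratio(fit_cds),
                     file.path(out_dir, "rate_ratios_cds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(channel = names(spectrum),
                                count = as.integer(spectrum)),
                     file.path(out_dir, "spectrum.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(damage, file.path(out_dir, "damage_by_set.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  run_manifest <- list(
    tool = "mutaset",
    version = as.character(utils::packageVersion("mutaset")),
    seed = config$seed,
    stage_seeds = list(genome = child_seed(config$seed, 1L),
                       annotation = child_seed(config$seed, 2L),
                       mutations = child_seed(config$seed, 3L),
                       damage = child_seed(config$seed, 4L),
                       enrichment = seed_enrich,
                       sweep = child_seed(config$seed, 12L),
                       random_kmers = child_seed(config$seed, 13L)),
    null = list(n_sets = n_sets, set_size = set_size),
    decisions = list(binomial_tail = "minimum-likelihood",
                     binomial_n = "n_genes x n_subclones",
                     dunn_adjustment = "BH",
                     kmer_strand = "reference",
                     gene_universe = "all annotated genes",
                     glm_response = "counts pooled over classes"),
    input_digests = as.list(tools::md5sum(unlist(study$paths[
      names(study$paths) != "sets"])))
  )
  jsonlite::write_json(run_manifest,
                       file.path(out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(enrichment_gene = enr_gene, enrichment_cds = enr_cds,
                 fit_gene = fit_gene, fit_cds = fit_cds, sweep = sweep,
                 kmers = kmers, random_kmers = random_kmers,
                 spectrum = spectrum, damage = damage,
                 damage_tests = damage_tests, study = study,
                 manifest = run_manifest))
}

#' Render the standard figure set from pipeline results
#'
#' Writes one PDF per figure: the observed-minus-expected heatmaps, the
#' set-size sweep, centered rate-ratio curves, the substitution spectrum
#' and the damage boxplot (sets ordered by decreasing mean enrichment).
#'
#' @param results list returned by [run_pipeline()].
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
render_reports <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  fig <- function(name, expr) {
    p <- file.path(dir, paste0(name, ".pdf"))
    grDevices::pdf(p, width = 7, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    force(expr)
    paths <<- c(paths, p)
  }
  fig("enrichment_gene_heatmap", plot(results$enrichment_gene))
  fig("enrichment_cds_heatmap", plot(results$enrichment_cds))
  fig("setsize_sweep", plot(results$sweep))
  for (v in names(results$fit_gene$iqr))
    fig(paste0("rr_curve_gene_", v),
        plot(centered_rr_curve(results$fit_gene, v)))
  fig("spectrum", plot(results$spectrum))
  fig("damage_by_set", plot_damage_by_set(results$damage))
  invisible(paths)
}
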