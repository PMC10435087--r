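# mutaset

Environmental mutagens do not hit all genes equally. Whole-genome catalogs
of single-nucleotide substitutions from clonal cultures exposed to defined
carcinogen classes (radiation, polycyclic aromatic hydrocarbons, aromatic
amines, ...) make it possible to ask a pointed question: **are the genes
implicated in a disease mutated by a given exposure more often than genes
picked at random from the genome?** `mutaset` implements that analysis as a
tested, reusable R pipeline, for statistical geneticists and environmental
health researchers working with mutagen-exposure screens or comparable
somatic-mutation catalogs.

## The statistics at the core

**Random gene-set null.** For each exposure class, draw `N` random sets of
`k` genes from the annotation (defaults `N = 1000`, `k = 300`) and compute
each set's mutations per gene per treated subclone. The mean over sets,
`p0`, is the expected per-gene-per-subclone mutation rate. Per-subclone
burden grows linearly with set size while the per-gene rate stays flat, so
the null need not be size-matched to each disease set.

**Exact binomial burden test.** A disease set with `G` genes observed over
`S` subclones defines `n = G x S` trials; its total mutation count `X` is
compared against `Binomial(n, p0)` with a two-sided exact test
(minimum-likelihood tail), reported as observed − expected
(`X − p0·G·S`) with table-wide Bonferroni correction over all set × class
cells. A Monte-Carlo empirical null from size-matched random sets
(two-tailed: smaller tail proportion times two) is available as a
sensitivity analysis.

**Quasi-Poisson mutability regression.** Per-gene mutation counts are
modeled as `log mu = b0 + b1·length + b2·expression + b3·GC%`, fitted by
IRLS with dispersion `phi = Pearson X² / df` inflating the standard errors.
Effects are reported as rate ratios per interquartile-range increase,
`exp(b_j · IQR_j)`, with Wald 95% intervals, separately for whole genes and
merged coding sequence.

**Sequence context and DNA damage.** 7-mer windows centered on mutations
(reference strand) versus random genomic 7-mers; COSMIC-convention
96-channel trinucleotide spectra with cosine similarity to reference
signatures; and per-gene averages of a depth-normalized DNA-damage signal
track compared between gene sets by one-way ANOVA with FDR pairwise
contrasts (genes) or Kruskal–Wallis with Dunn's test (CDS).

A synthetic-data generator (`simulate_study()`) produces a complete
desk-scale study — genome FASTA, GTF, gene sets, expression table, subclone
manifest, mutation catalog with known per-gene rates, damage track — so
every stage runs and is verifiable without external downloads.

## Worked example

A fully synthetic study with three exposure classes (10 subclones each) and
three disease-like gene sets, one of which (`NDD_like`) is generated with a
twofold rate excess and a bias toward long genes:

```r
library(mutaset)

cfg   <- simulation_config(seed = 7)
study <- simulate_study(cfg)
counts <- assign_mutations(study$records, study$genes)

enr <- enrich_gene_sets(counts, study$genes, study$sets, study$manifest,
                        n_sets = 500, set_size = 300, seed = 7)
enr
#> Gene-set mutation enrichment (gene level)
#>   null: 500 random sets of 300 genes; Bonferroni over m = 9 cells
#>             set       class obs   exp obs-exp        p sig
#>        NDD_like   radiation 119 76.96   42.04 2.93e-06  **
#>  metabolic_like   radiation  77 68.41    8.59 2.82e-01
#>    cardiac_like   radiation  17 25.65   -8.65 7.87e-02
#>        NDD_like         PAH 124 69.95   54.05 7.44e-10  **
#>  metabolic_like         PAH  65 62.17    2.83 6.92e-01
#>    cardiac_like         PAH  13 23.32  -10.32 2.31e-02   †
#>        NDD_like nitrosamine  41 26.14   14.86 5.25e-03  **
#>  metabolic_like nitrosamine  23 23.23   -0.23 1.00e+00
#>    cardiac_like nitrosamine   9  8.71    0.29 8.63e-01
```

The generated twofold-enriched set is flagged `**` (Bonferroni-significant,
mutated more than expected) in every class; the dagger marks a nominally
significant deficit. `obs` is the set's total mutation count over the
class's subclones, `exp` is `p0 x genes x subclones` from the random-set
null.

The mutability regression on the same study (pooled counts per gene):

```r
fit <- fit_mutability(mutations ~ length + expression + gc_percent,
                      mutability_data(counts, study$genes, "gene"))
summary(fit)
#> Quasi-Poisson mutability model: mutations ~ length + expression + gc_percent
#> n = 400, residual df = 396, dispersion = 1.155
#> ...
#> Rate ratios per IQR increase (95% CI):
#>   length           RR = 1.225 [1.141, 1.316]
#>   expression       RR = 1.038 [0.983, 1.097]
#>   gc_percent       RR = 1.152 [1.042, 1.274]
```

Each IQR of extra gene length multiplies the mutation rate by about 1.2 in
this simulation — length-driven mutability, as encoded by the generator
(the enriched set also concentrates long genes, which inflates the length
effect above its generative value). `run_pipeline(cfg, "results/")` runs
all stages (enrichment at gene and CDS level, regressions, 7-mer and
spectrum summaries, damage tests) and writes tables plus a `MANIFEST.json`
recording seeds and analysis decisions; `render_reports()` turns the
results into the standard figure set.

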