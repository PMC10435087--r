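---
title: "Methods: mutagen vulnerability of disease gene sets"
author: "mutaset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutagen vulnerability of disease gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutaset)
```

## The question and the data model

A mutagen-exposure screen yields, for each clonal culture ("subclone")
exposed to a chemical, a catalog of single-nucleotide substitutions called
against the parental line. Subclones are grouped into exposure classes
(radiation, PAHs, nitrosamines, ...). Given gene models, a genome, per-gene
expression, and disease gene sets, the pipeline asks whether each disease
set accumulates more substitutions under each exposure than random genes
would, and what sequence properties drive per-gene mutability.

`mutaset` represents these inputs as plain data frames: a
`mutation_catalog` (one row per substitution, validated single-base A/C/G/T
changes only), `gene_models` (one row per gene with merged CDS intervals
and covariates), a `subclone_manifest` (exposure class per subclone — kept
separate from the catalog so zero-mutation subclones still count in rate
denominators), gene sets as symbol lists, and a `signal_track` for damage
data.

### Coordinate conventions

Internally all intervals are 0-based half-open; GTF input is parsed as
1-based inclusive and VCF/TSV positions are 1-based. A substitution at
1-based position $p$ belongs to a gene when index $p-1$ lies in the gene's
half-open span, so the annotated end base is included. Two deliberate
length conventions coexist: `gene_length` is the annotation's *end minus
start* (one base less than the inclusive span) because that is the
covariate definition used downstream, while `cds_length` is the summed
width of the union of CDS intervals across transcripts. The one-base
difference is immaterial at gene scale but is applied consistently.

### Consequence-free CDS assignment

CDS-level counts are defined by coordinate containment in the merged CDS
intervals, not by variant-effect prediction. This removes an external-tool
dependency at the cost of ignoring synonymous/missense distinctions and
isoform structure; it is an approximation we consider acceptable because
the analysis only needs "landed in coding sequence", not functional
consequence. Mutations overlapping several genes count once per overlapping
gene (sets are tallied independently, so no arbitration is defensible), and
strand is ignored for counting.

## The enrichment test

For exposure class $c$ with $S_c$ subclones, the empirical null draws $N$
random sets of $k$ genes uniformly without replacement from the annotation
(defaults $N = 1000$, $k = 300$; desk-scale analyses in this package often
use $500 \times 50$). Each set's rate is
$r_i = T_i / (k\,S_c)$ where $T_i$ is the set's total mutation count among
the class's subclones, and $p_0 = \bar r$. Because the unit is mutations
per gene per subclone, the null is not size-matched; the set-size sweep
(`setsize_sweep()`) verifies that the per-gene rate is flat in set size
while per-subclone burden grows linearly with slope equal to the per-gene
rate.

A disease set with $G$ annotated genes is tested by treating its total
count $X$ as $\mathrm{Binomial}(n = G S_c,\; p_0)$. The two-sided p-value
uses the minimum-likelihood rule — the sum of probabilities of all outcomes
whose point mass does not exceed that of $X$, with relative tie tolerance
$1 + 10^{-7}$ — which is the convention of standard exact-test
implementations; a central (doubled one-tail) option exists. The binomial
$n$ is not uniquely dictated by "per-gene per-subclone rate"; we define
$n = G \times S_c$ and record it in output metadata. Since single genes may
contribute many mutations, $X > n$ is possible in principle; the binomial
cannot represent that, so the test then falls back to an exact Poisson test
with mean $p_0 n$, with a warning.

Significance is assessed at $\alpha = 0.05$ with a table-wide Bonferroni
divisor $m$ equal to the number of cells in one results table (gene sets
$\times$ exposure classes); gene-level and CDS-level tables are corrected
separately. The Monte-Carlo alternative compares $X$ with totals of $N$
random sets matched to $G$:
$p = 2\min\left(\tfrac{\#\{T_i \ge X\}}{N}, \tfrac{\#\{T_i \le X\}}{N}\right)$,
ties counted in both tails, truncated at 1, no pseudo-count. Keeping the
formula literal means $p = 0$ when $X$ falls outside the whole null sample;
such values are flagged as below the $2/N$ resolution rather than patched,
so users can raise $N$ when they need finer resolution. The random null
universe is all annotated genes, including disease-set members (their
exclusion is negligible at genome scale, and including them keeps the null
literal: sets sampled "from the genome").

Length-quartile stratification (`quartile_stratify()`) ranks genes longest
first, breaking ties by symbol, and splits at the empirical quartiles; when
the size is not divisible by four the extra genes go to the longer
quartiles, so sizes differ by at most one.

## The mutability regression

`fit_mutability()` fits $\log \mu = X\beta$ to per-gene counts by IRLS on
the Poisson score equations (convergence $\max_j |\Delta\beta_j| <
10^{-8}$, at most 100 iterations; rank deficiency, separation and
non-convergence are hard errors). The quasi-likelihood dispersion is
$\hat\phi = \sum_g (y_g - \hat\mu_g)^2/\hat\mu_g \,/\, (n - p)$, and every
standard error is the Poisson-model standard error times
$\sqrt{\hat\phi}$; $\hat\phi = 0$ (a perfect fit) is flagged degenerate.
The response pools counts over all subclones and classes — one gene-level
and one CDS-level model, no exposure offset — mirroring how the screen's
observation counts are reported; the choice is recorded in the run
manifest. Covariates enter untransformed (length in nucleotides, expression
in RPKM, GC as percent); a near-null expression effect per IQR at gene
level is only interpretable on the raw scale, which is why no log
transform is applied by default. Genes with any missing covariate are
dropped before fitting, and at CDS level genes without coding sequence are
excluded.

Effects are summarized as rate ratios per interquartile range,
$RR_j = \exp(\hat\beta_j\,\mathrm{IQR}_j)$ with Wald 95% limits
$\exp((\hat\beta_j \pm 1.96\,SE_j)\mathrm{IQR}_j)$ — invariant to linear
rescaling of the covariate. Centered curves show
$RR_j(x) = \exp(\hat\beta_j (x - \bar x_j))$ with a pointwise band from
$SE_j$ alone (coefficient uncertainty, not full prediction uncertainty),
equal to 1 exactly at the covariate mean.

## Sequence context

7-mer windows are taken on the reference strand with no pyrimidine
orientation — the composition figures show raw A/C/G/T content, and whether
the original analysis strand-oriented its windows is not stated, so the
reference-strand default is recorded in output metadata. Windows crossing a
chromosome edge or containing ambiguous bases are skipped and tallied;
records whose stated reference allele disagrees with the genome are
excluded as reference mismatches rather than silently kept. Random
comparator 7-mers are drawn uniformly over all valid windows of the whole
genome (not genic regions only). Trinucleotide spectra *do* collapse
strands to the pyrimidine-centered 96-channel convention, matching
signature practice; totals are conserved (every eligible substitution lands
in exactly one channel). Signature decomposition is out of scope — only
spectra and cosine similarity to user-supplied reference matrices.

The random-mutation length model samples positions uniformly over the
concatenation of all target sequences, so a sequence's hit probability is
proportional to its length; the mean hit length for lengths $\{100, 300\}$
is analytically $0.25 \cdot 100 + 0.75 \cdot 300 = 250$, which the tests
verify by simulation.

## Damage enrichment

Per-region damage is the base-pair-weighted mean of a piecewise-constant
depth-normalized track: $\sum_i v_i w_i / W$ over overlaps, uncovered bases
contributing zero. For piecewise-constant tracks this equals scaled-region
binning exactly while being deterministic and splitting-invariant, which is
why it is computed directly rather than through binned interpolation; the
choice is recorded in metadata. Gene-level comparisons between sets use
one-way ANOVA with pooled-variance pairwise contrasts and
Benjamini–Hochberg adjustment; CDS-level values are compared by
Kruskal–Wallis with tie correction and Dunn's test. The adjustment for
Dunn's pairwise p-values is not standardized in this setting; we default to
Benjamini–Hochberg (consistent with the FDR language used for the ANOVA
contrasts) with Bonferroni and unadjusted selectable, and flag the choice
in output.

## The synthetic generator

The generator encodes the minimal structure the analyses assume, not any
specific biology: non-overlapping genes with log-normal lengths
(`meanlog = log 6000`, `sdlog = 0.6`, clamped to 0.5–40 kb) placed along
4 x 1 Mb chromosomes; per-gene GC from Beta(14, 14) (mean 0.5, sd ≈ 0.09),
realized by rewriting each gene's sequence; log-normal RPKM
(`meanlog = log 10`, `sdlog = 1`); and per-gene, per-class rates
$$\lambda_{gc} = m_c\, \delta^{[g \in \mathrm{set}]}
  \exp(\beta_0 + \beta_L L_g + \beta_{GC} GC_g + \beta_E E_g)$$
with defaults $\beta_0 = -3.9$, $\beta_L = 3\times10^{-5}$ per nt,
$\beta_{GC} = 1$ per GC fraction, $\beta_E = 0.002$ per RPKM and class
multipliers 1.5 (radiation), 1.3 (PAH), 0.6 (nitrosamine). These values
were chosen once so the most intense class realizes roughly 0.06 mutations
per gene per subclone — the magnitude reported for the most mutagenic
classes in screens of this kind — with three classes of 10 subclones each.
Default sets emulate the screen's structure: a 90-gene set with a twofold
rate excess sampled with length bias (disease sets dominated by long
genes), an 80-gene set at 1.5x, and a 30-gene neutral set. Counts are
Poisson, or negative binomial when an overdispersion size parameter is
set; positions are uniform within the gene span, the reference allele is
read from the genome and the alternate is uniform over the other three
bases. Damage tracks are constant per gene at the set's mean plus
truncated Gaussian noise.

What the generator does *not* emulate — realistic chromosome organization,
signature-shaped substitution biases, transcription-coupled repair,
isoform structure, chromatin covariates — bounds what passing tests mean:
they certify the statistical machinery (calibration, power against a known
multiplicative excess, parameter recovery, conservation laws), not the
biological conclusions one would draw from real catalogs.

## Verification sizes and numerical choices

The test suite and acceptance script run at desk scale, sized so the full
battery completes in a few minutes on one CPU while keeping Monte-Carlo
error well inside the asserted bands: the calibration study uses 1000
genes, 10 classes x 10 subclones and 500 set-by-class cells with a
500-set null; power uses 100 simulated studies at the default
configuration; regression recovery uses 5000 genes and 200 replicates; the
sweep uses 1000 sets per size. Statistical checks use 3-standard-error
bands (3.5 where many cells are tested jointly); fixture identities
(ANOVA F = 3, Kruskal–Wallis H = 32/7) are asserted to 10^-6 or tighter.
Resampling is reproducible: every sampling function takes a seed, stage
seeds are derived from one master seed, and the caller's RNG state is
restored afterwards.

## Known limitations

Gene universes and symbol joins are exact-match and case-sensitive;
mis-matched annotation/expression vocabularies surface as missing data, not
fuzzy joins. The Poisson fallback for multiplicity beyond the binomial
range is a documented deviation kept for continuity of the test family.
The Monte-Carlo p-value's zero floor is intentional (see above). The
quasi-Poisson model cannot distinguish overdispersion from omitted
covariates; the dispersion estimate absorbs both. `simulate()` on a fitted
model draws Poisson counts at the fitted means and therefore does not
reproduce estimated overdispersion.
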