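# matequant

Comparative quantitative proteomics of mating-transferred proteins.

`matequant` implements an analysis pipeline for multiplexed
isobaric-label (TMT) experiments that identify the **transferred male
ejaculate proteome** by contrasting the lower female reproductive tract
of mated versus virgin females, across three closely related species
quantified in a single 16-plex run. It is written for evolutionary
biologists studying reproductive protein divergence: the pipeline
classifies ejaculate versus female reproductive tract (FRT) proteins,
quantifies between-species divergence in protein abundance within each
class, and relates abundance classes to secretion signals (signal
peptides), gene-family membership, evolutionary rates (dN/dS) and
tissue mRNA expression.

Because raw spectral data are not desk-scale inputs, the package starts
from peptide-level reporter-intensity tables (the output of an upstream
search/quantitation pipeline) and ships a synthetic-data generator that
emulates the full experimental design with planted ground truth, so
every statistical property of the pipeline is testable end to end.

## The model

For protein *g* with summed reporter intensity *x<sub>gj</sub>* in
channel *j* (channel library size *N<sub>j</sub>*, TMM scaling factor
*f<sub>j</sub>*), the normalized abundance is

> y<sub>gj</sub> = log2( (x<sub>gj</sub> + c) / (N<sub>j</sub> f<sub>j</sub>) × 10⁶ ),  c = 0.5

TMM factors are doubly trimmed (M: 30%, A: 5%), precision-weighted mean
log-ratios against a reference channel, rescaled to geometric mean 1.
Each two-group contrast fits a per-protein linear model with empirical
Bayes variance shrinkage: the pooled variance s²<sub>g</sub> on
d = n<sub>A</sub>+n<sub>B</sub>−2 df is shrunk towards a prior
(d₀, s₀²) estimated by method of moments on log s²
(digamma/trigamma matching),

> s̃²<sub>g</sub> = (d₀ s₀² + d s²<sub>g</sub>) / (d₀ + d),
> t<sub>g</sub> = log2FC<sub>g</sub> / (s̃<sub>g</sub> √(1/n<sub>A</sub> + 1/n<sub>B</sub>)),

with p-values on d₀+d df and Benjamini–Hochberg adjustment within each
contrast family. A protein is differentially abundant at
|log2FC| > 1 and FDR < 0.05. The **ejaculate set** is the union over
species of mated-biased calls on the orthogroup-merged table, minus a
curated exclusion list of known female postmating-response proteins;
the **FRT proteome** is the quantified complement. Downstream analyses:
pairwise species divergence (mated channels for ejaculate, virgin for
FRT), k-means clustering of median-centred replicate-averaged profiles
(k = 7 ejaculate, k = 4 FRT), Fisher association of signal peptides
with divergence, a 99,999-draw resampling test of gene-family
representation (with hypergeometric closed-form tails), Mann–Whitney
comparisons of dN/dS between protein classes, GO enrichment (one-sided
Fisher, ≥15 annotated genes per term), mRNA–protein Pearson
correlations and PCA of the 500 most variable proteins.

## Worked example

```r
library(matequant)
cfg <- pipeline_config(params = sim_params(n_orthogroups = 500, seed = 42))
res <- run_pipeline(cfg)
```

The run logs every stage (counts in/out), e.g.:

```
stage merge: combined table has 1197 rows (497 orthogroups)
stage classify: ejaculate=119, excluded=25, FRT=1049, virgin-biased=4
stage diverge: ejaculate americana_virilis: 29 differentially abundant
stage diverge: tract novamexicana_virilis: 218 differentially abundant
stage pca: PC1 explains 46.6% of variance
```

Headline results live in `res$summary`; with this seed:

```r
str(res$summary$combined)
#> $ rows                        : int 1197
#> $ ejaculate_proteins          : int 119
#> $ ejaculate_orthogroups       : int 51
#> $ frt_proteins                : int 1053
#> $ virgin_biased               : int 4
#> $ excluded                    : int 25
```

119 of the 1197 quantified rows are classified as transferred ejaculate
proteins (51 orthogroups); the 25 excluded rows are the planted female
postmating-response proteins, which respond to mating but are not
male-derived. Signal peptides are more frequent among ejaculate (0.588)
than tract (0.459) proteins, mirroring their planted secretion
probabilities:

```r
res$sig_fraction
#>           class    n n_signal fraction ci_lower ci_upper
#>             FRT 1049      482    0.459    0.420    0.500
#>       ejaculate  119       70    0.588    0.466    0.703
```

Because the generator records ground truth, recovery is measurable:

```r
recovery_metrics(res$classification, res$truth)
#> $sensitivity 1    $fdr 0    $n_called 119
```

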