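---
title: "Methods: models, parameters and design choices in matequant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in matequant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(matequant)
```

## The analysis problem

`matequant` analyses a single multiplexed isobaric-label (TMT 16-plex)
experiment in which the lower reproductive tracts of virgin and
just-mated females from three related *Drosophila* species are
quantified together. Proteins more abundant in mated than virgin
samples are, on this short post-copulation timescale, overwhelmingly
male-derived: the transferred ejaculate (seminal fluid and sperm
proteins). The pipeline identifies that set, treats the quantified
complement as the female reproductive tract (FRT) proteome, and asks
how protein abundance in each class diverges between species and how
divergence relates to secretion signals, gene families and molecular
evolutionary rates.

All channels are labeled and measured in one run, so there are no
batch effects to model; between-channel differences are composition
and loading differences, handled by scaling normalization.

## Statistical model

**Aggregation.** Protein abundance per channel is the sum of reporter
intensities of all assigned peptides. Shared (non-unique) peptides
contribute intensity to every protein they map to, but only distinct
unique peptide sequences count toward the identification filter
(default: at least 2 unique peptides). This keeps the uniqueness filter
literal while retaining the summed-intensity quantitation; whether
shared-peptide intensity belongs in protein sums is genuinely open, and
the choice is declared here rather than inferred.

**Normalization.** Trimmed mean of M-values (TMM) against a reference
channel (default: the channel whose total intensity is closest to the
mean total), with 30% trimming on M-values, 5% on A-values, and
inverse-asymptotic-variance weights; factors are rescaled to geometric
mean 1. Normalized abundance is
`log2((x + 0.5) / (libsize * factor) * 1e6)`. The pseudocount of 0.5
(intensity units) only matters near zero intensity and is configurable;
intensities are kept continuous, never rounded to counts.

**Moderated two-group fit.** Each contrast fits per-protein two-group
means; the pooled residual variance (d = nA + nB − 2 df) is shrunk
toward a prior estimated by method of moments on log s² using
digamma/trigamma matching, exactly the scaled-F moment relations. The
trigamma inversion is a Newton iteration with asymptotic endpoints
(1/y for small y, 1/sqrt(y) for large). Rows with s² = 0 are excluded
from moment estimation and assigned the prior variance. When the excess
variance of log s² is non-positive the prior df is infinite and every
row is tested against the common prior. The estimator is numerically
identical to `limma::eBayes` on the same data (the test suite verifies
this), but is implemented here independently so the pipeline's core
statistic is self-contained; limma and edgeR appear only as
cross-checks in tests. One subtlety: when all row variances are exactly
equal, the moment estimator's log-scale bias correction makes the prior
a fixed multiple of the common s², so moderated t is a constant
multiple of the ordinary t rather than equal to it — this is a property
of the estimator, not a defect, and is asserted as such in the tests.

The design has two virgin replicates for two of the species, so the fit
must (and does) work at n = 2 per group; moderation is what makes
those contrasts usable.

**Calling and classification.** Differential abundance requires
|log2FC| > 1 and Benjamini–Hochberg FDR < 0.05, with BH applied within
each contrast family separately (each species' mated-vs-virgin
contrast; each species-pair divergence contrast within a protein set),
matching how per-contrast candidate counts are reported. The ejaculate
set is the **union** over species of mated-biased calls on the
combined orthogroup table: species-unique candidates exist, which an
intersection rule could not produce. A curated exclusion list of known
female postmating-response proteins is removed from the ejaculate set
into an `excluded` class; virgin-biased proteins are reported
separately but kept inside the FRT set for divergence analyses. The
four classes partition the quantified table exactly.

**Divergence, clustering and association.** Species-pair contrasts use
mated channels for the ejaculate set and virgin channels for the FRT
set (the FRT comparison must not be contaminated by transferred
material). Heatmap-style profiles are per-row group means (species ×
status) minus the per-row median across groups. K-means uses the
squared-Euclidean objective with fixed k (7 for ejaculate, 4 for FRT
profiles) and best of 100 random restarts under a fixed seed; restarts
rather than k-means++ seeding because with k ≤ 7 and a hundred
restarts the global optimum is reached reliably and determinism is
governed by the seed either way. Signal-peptide × divergence
association uses two-sided Fisher tests.

**Gene-family resampling.** Whether ejaculate proteins over- or
under-represent gene families is tested by drawing the observed set
size without replacement from the pool of quantified rows, B = 99,999
times, reporting both add-one tail estimates
`(1 + #{draws ≥ k_obs}) / (B + 1)` (and the lower analogue) alongside
closed-form hypergeometric tails. Both tails are always reported
because depletion and enrichment are both of interest and a one-sided
convention invites misreading. The resampling unit is **rows** of the
combined table (duplicated genes counted separately) and the pool is
all rows passing the unique-peptide filter — a declared choice, since
orthogroups would be an equally defensible unit. Note that ejaculate
calls are correlated within orthogroups (members of an orthogroup rise
and fall together), so row-level resampling p-values are overdispersed
relative to an orthogroup-level null; the package reports what it
computes and leaves the unit explicit.

**Rates, enrichment, correlation, PCA.** Pairwise dN/dS values are
compared between protein classes (ejaculate ± signal peptide, FRT ±
signal peptide, secreted FRT serine-type endopeptidases, genome
background) with Mann–Whitney tests — exact by enumeration when
n1 + n2 ≤ 12 without ties, otherwise the tie- and continuity-corrected
normal approximation. GO enrichment is a one-sided Fisher
(hypergeometric upper tail) over pre-propagated term sets with a
minimum of 15 annotated background genes per term and BH across tested
terms; no DAG traversal or term weighting is attempted. mRNA–protein
correlations are Pearson correlations of log-scale values within
protein classes per species. PCA takes the 500 most variable proteins,
mean-centres each protein and projects samples, without unit-variance
scaling (scaling is not obviously right for abundances on a common
log2 scale, and the choice is declared).

## The synthetic-data generator

The generator fabricates everything the pipeline consumes, with ground
truth. Its defaults encode the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_orthogroups` | 2000 | orthogroups across three species |
| `frac_multicopy` | 0.05 | orthogroups with a duplicated member (gene families) |
| `frac_ejaculate` | 0.10 | transferred ejaculate orthogroups |
| `ejaculate_log2_shift` | 3 | log2 mating shift of ejaculate proteins |
| `ejaculate_baseline_offset` | −2 | ejaculate proteins less abundant than the tract proteome |
| `frac_species_divergent` | 0.25 | orthogroups with a planted species effect |
| `divergent_log2_effect` | 2 | planted between-species log2 effect |
| `channel_noise_sd` | 0.5 | per-peptide, per-channel log2 noise |
| `peptide_offset_sd` | 0.8 | per-peptide ionization offset (shared across channels) |
| `baseline_log2_mean`, `baseline_log2_sd` | 20, 2 | log2-intensity scale |
| `sig_peptide_prob_by_class` | 0.52 / 0.41 | signal-peptide probability (ejaculate / FRT) |
| `mrna_protein_r_target` | 0.45 | mRNA–protein correlation for secreted ejaculate proteins |
| `n_postmating_response` | 12 | planted female mating-responsive proteins (exclusion list) |

The 16-channel design is three mated replicates per species, three
virgin replicates for *D. virilis* and two each for the other species.
Within-group variance is not something the source experiment reports,
so `channel_noise_sd = 0.5` log2 units is a declared default in the
realistic range for reporter-ion data, stated in configuration rather
than asserted as an empirical value. The mRNA–protein target of 0.45
sits mid-range of the weak correlations typical for secreted
reproductive proteins. Peptide counts are shifted-Poisson (minimum 1)
with mean 3, and 5% of proteins get exactly one unique peptide to
exercise the identification filter. There is no missingness by default
(isobaric multiplexing is near-complete); a peptide dropout rate is
available for robustness experiments.

Two structural choices deserve emphasis:

* **The mating shift applies in mated channels of every species.** A
  combined-table row tracks its orthogroup's abundance across all 16
  channels — conserved peptides report every sample in the multiplexed
  mixture, and every mated sample received a conspecific ejaculate. If
  the shift were applied only in the protein's own species' mated
  channels, every ejaculate protein would carry a spurious
  between-species difference equal to the shift, and divergence
  analyses on mated channels would be meaningless. Species differences
  therefore enter only through the planted divergence offsets.
* **Gene-family orthogroups are always planted divergent**, emulating
  the empirical pattern that duplicated-family proteins essentially
  always differ between species; the remaining orthogroups are
  divergent with probability `frac_species_divergent`, in one species,
  with random sign.

What the generator does **not** emulate: ratio compression from
co-isolation interference, isotopic impurity, retention-time effects,
missingness structure, correlated peptide noise within proteins beyond
the shared ionization offset, or orthology errors. Passing recovery
tests therefore demonstrates that the statistical pipeline is correct
and well calibrated under its own assumptions — not that those
assumptions capture every pathology of real reporter-ion data.

## Numerical choices and degenerate inputs

* TMM: rows with a zero in either channel of a pair leave that pair's
  trim set; an all-zero channel is an error naming the channel; if all
  M-values are below 1e−6 in magnitude the factor is exactly 1.
* Trimming is rank-based; the independent test oracle uses sort-order
  trimming, which agrees for continuous data.
* A zero standard error (constant row within both groups) yields p = 1
  rather than NaN: a constant row carries no evidence.
* Mann–Whitney with all observations tied returns p = 1 (the normal
  approximation's variance is zero).
* k-means labels and the resampling draws are deterministic given the
  configured seeds; the full pipeline is byte-identical across reruns
  with the same configuration, which the tests verify by hashing all
  written outputs.

## Problem sizes used by the test suite

The suite calibrates the classifier on 200 null datasets of 667
orthogroups (about 2000 combined rows each) — enough replication for a
3-standard-error Monte-Carlo bound on the empirical FDR — and measures
recovery on a single 2000-orthogroup dataset at the default planted
effects (mating shift 3, divergence ±2, noise SD 0.5), where the
expected operating point is sensitivity above 0.9 at FDR below 0.1 for
the ejaculate set and sensitivity above 0.85 for divergence calls.
These sizes are the package's own choice of a well-powered,
quick-to-run configuration.

## Known limitations

* The pipeline starts from peptide-level tables: spectral search,
  protein inference, orthology inference and signal-peptide prediction
  are upstream producers of its inputs, not part of the package.
* Precision weights (mean–variance modeling) are deliberately not
  implemented: reporter-ion intensities are not counts, and the
  TMM + log2 + moderated-t path covers every contrast coherently. Data
  with strong intensity-dependent variance would benefit from weights
  this package does not provide.
* The union-over-species ejaculate definition, the row-level resampling
  pool and the unscaled PCA are declared conventions; alternatives are
  defensible and would change numerical results.
* With only two virgin replicates in two species, FRT divergence
  contrasts involving those species lean heavily on variance
  moderation; their per-row df is small and calls near the thresholds
  should be read accordingly.
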