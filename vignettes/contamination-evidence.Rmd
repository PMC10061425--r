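---
title: "Contamination evidence for microbiome count tables: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contamination evidence for microbiome count tables: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kitomeR)
```

kitomeR computes converging lines of contamination evidence from a raw
observation × sample count table. This vignette explains the underlying
models and their assumptions, the parameters that matter, what the bundled
synthetic-study generator does and does not emulate, and the numerical and
design choices made where the problem left room.

## The two contamination signatures

The scoring model rests on two empirical regularities of reagent and
laboratory contamination:

1. **Inverse frequency–concentration relation.** A contaminant arrives in a
   roughly fixed number of DNA molecules per reaction, regardless of how
   much sample DNA is present. After sequencing to a depth proportional to
   input DNA, its *relative frequency* $f$ scales as $1/c$ with the DNA
   concentration $c$. A genuine community member's relative frequency is
   independent of $c$.
2. **Control enrichment.** Negative controls (blanks, water, air) contain no
   biological signal, so anything present there — and more prevalent there
   than in biological samples — is suspect.

### Frequency score

For one observation, let $f_s > 0$ be its relative frequency and $c_s > 0$
the concentration in sample $s$ (both conditions are required for a sample
to enter the fit; $n$ is the number of usable samples). Two intercept-only
linear models in $\log_{10}$ space formalise the hypotheses:

* not a contaminant: $y_0 = \log_{10} f$ fitted by its mean (slope 0);
* contaminant: $y_1 = \log_{10} f + \log_{10} c$ fitted by its mean
  (equivalent to fixing slope $-1$).

With residual sums of squares $\mathrm{SS_{non}}$ and $\mathrm{SS_{cont}}$,
the score is the CDF of an F distribution with $(n-1, n-1)$ degrees of
freedom evaluated at $\mathrm{SS_{cont}}/\mathrm{SS_{non}}$. Degenerate
cases are fixed by continuity: a perfect contaminant fit
($\mathrm{SS_{cont}} = 0$, $\mathrm{SS_{non}} > 0$) scores 0, a perfect
constant-frequency fit scores 1, and both zero (a single effective point
pattern) scores 0.5. Below `min_samples` usable samples (default 5) the
score is *undefined* rather than unreliable; undefined scores never flag.

When no concentration field is given, per-sample total counts (assigned +
unassigned) stand in as an indirect concentration proxy — low-biomass
samples yield few reads.

**Controls are excluded from the frequency fit.** In controls the
contaminants *are* the composition, so their relative frequencies saturate
and no longer follow $1/c$; including them would flatten the very signal
the test looks for. This was a genuinely open design point; the package
fits on biological samples only.

### Prevalence score

Presence (count > `presence_threshold`, default 0) is tabulated for the
designated control group (default: the union of all groups) against the
remaining samples, and the one-sided exact hypergeometric tail gives the
probability of a control presence count at least as extreme under the null
of no association. The test is exact at any sample size; the test suite
checks it against full enumeration for all tables with up to 12 samples.

### Combined score

Fisher's method: $X = -2(\ln p_{\mathrm{freq}} + \ln p_{\mathrm{prev}})$
referred to the upper tail of $\chi^2_4$. Independence of the two
components is an approximation — both are computed from the same counts —
so the combined value is an evidence *score* for ranking and flagging, not
a calibrated p-value. If either component is undefined the combination is
undefined.

## Compositional machinery

* **clr transform.** Per sample (a composition), zeros are replaced by the
  pseudo-count and $\mathrm{clr}(x_i) = \ln x_i - \overline{\ln x}$. Each
  sample's clr values sum to zero (tested at 1e-9). Natural log is used
  internally; the display-oriented `log_transform()` uses log10.
* **Proportionality.** $\rho_{ij} = 1 - \mathrm{var}(a_i - a_j) /
  (\mathrm{var}\,a_i + \mathrm{var}\,a_j)$ on clr rows, with the $n-1$
  variance (hence at least 3 samples). $\rho$ is computed on the clr of the
  *full* table and then subset to the top observations: subsetting first
  would change every per-sample geometric mean and silently alter the
  compositional reference.
* **Rank decomposition** sums counts into each observation's ancestor at the
  requested rank. Mass with no ancestor at that rank is kept visible under
  the reserved `"(unannotated)"` observation, so per-sample totals
  (including unassigned) are conserved exactly at every rank — a property
  the tests assert for every generated study.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `pseudo_count` | 0.5 | zero replacement before log/clr; the conventional half count. Results for observations with many zeros are sensitive to it; it is recorded in every transform and in the bundle provenance. |
| `threshold` | 0.1 | flagging cutoff on the governing score (the combined method's conventional default). |
| `min_samples` | 5 | minimum usable samples for the frequency fit. |
| `presence_threshold` | 0 | minimum count for "present"; raise it to ignore singletons. |
| `top_n` | 50 | observations entering the proportionality matrix and heatmap display, selected by total count with lexicographic tie-break. |
| `metrics`, `methods` | euclidean+braycurtis × complete+average | the clustering grid; every valid axis × metric × method combination is computed. |
| `include_unassigned` | TRUE | denominator of relative frequencies includes the unassigned count, so normalised values reflect the fraction of *all* sequenced material. |
| filters | off | `min_total_count`, `min_prevalence`, `min_sample_total`; observation filters run before sample filters, once, in that documented order. |

## The synthetic-study generator

`generate_study()` builds a study in which both contamination signatures
hold *by construction*, so score recovery is a fair, ground-truthed test:

* concentrations: biological samples log-normal around 10 (arbitrary
  units, sdlog 0.6), controls log-normal around 0.5 — controls are
  low-biomass;
* sequencing depth is Poisson with mean proportional to concentration
  (`depth_mean`, default 20000, is the expected depth at the reference
  biological concentration — a typical shallow amplicon depth);
* biological taxa follow a log-normal community with per-sample log-normal
  noise, present in controls only through a rare, heavily diluted
  carry-over (probability 0.1, factor 0.01);
* each contaminant has a per-taxon level drawn log-normally
  (median 8e-5, sdlog 0.7) and contributes expected relative frequency
  `level / concentration` with log-normal noise (`noise_sd`, default 0.3).
  The median level puts its expected count in a biological sample near
  1–2 reads: strong enough to fit the inverse law, weak enough that
  contaminants are only partially prevalent in biological samples while
  dominating the low-biomass controls;
* counts are drawn multinomially per sample; a small unassigned count
  (3% of depth) exercises the assigned+unassigned bookkeeping; a two-rank
  toy taxonomy (about one genus per four species) is attached with
  contaminants scattered across genera.

All randomness flows through one seed; two calls with the same parameters
are identical. Defaults are 80 biological + 16 control samples, 100
observations, 20 contaminants.

What the generator does **not** emulate: amplicon error and chimeras, index
hopping, batch structure in the contamination itself, taxon-correlated
efficiency biases, and compositional interactions between contaminant and
community (contamination is injected in relative-frequency space and
renormalised). Passing recovery tests therefore demonstrate that the
estimator detects the modelled signatures at realistic depths and noise —
not that real studies are this clean. On real data the scores should be
read as evidence to weigh alongside the reference-list, biome and
clustering tracks, never as a classifier.

## Numerical choices and degenerate inputs

* Exact-zero residual sums (not a tolerance) trigger the 0 / 1 / 0.5 edge
  returns of the frequency score; in floating point a perfect inverse law
  underflows the F CDF to 0 anyway.
* Clustering items are sorted lexicographically by id before the distance
  computation, so equal-height merge candidates resolve to the smallest id
  pair and repeated runs are byte-identical; reported leaf orders come from
  a smaller-subtree-first traversal (ties: subtree containing the
  lexicographically smallest leaf first).
* Ward linkage is restricted to euclidean distances; Bray–Curtis is
  rejected on negative-valued input, so the evidence assembly runs the
  Bray–Curtis part of the grid on relative abundances and the
  euclidean/correlation part on clr values (the heatmap's data).
* Annotation tracks are normalised per track by their maximum (an all-zero
  track stays zero), making heterogeneous tracks share one color scale and
  the normalised values invariant under rescaling all hit counts.
* Homonym taxon names resolve to the unique node carrying a ladder rank,
  otherwise the observation is flagged unresolved and *kept* (it still
  appears, and its mass lands in `"(unannotated)"` at every rank).
* Duplicate ids, negative, fractional or non-numeric counts, empty tables,
  zero-total samples under normalisation, orphaned or cyclic taxonomy nodes
  are all hard errors with stage-labelled messages.
* Bundle JSON is written with 17 significant digits, so
  `read_bundle(write_bundle(b))` reproduces `b` exactly and identical
  inputs give byte-identical files (no timestamps enter the bundle).

## Validation problem sizes

The test suite validates the core statistics against independent oracles
(direct clr evaluation; both algebraic forms of $\rho$; an explicit
constrained least-squares + incomplete-beta F CDF; full hypergeometric
enumeration up to 12 samples) on hundreds of seeded random tables, and runs
recovery on the default 100 × 96 study across 10 seeds. The end-to-end
pipeline check uses a 500-observation, 100-sample study, assembled and
rendered in well under a minute on one core with a report of a few MB.

## Known limitations

* The combined score's chi-square reference assumes independent components;
  treat it as a ranking score.
* Frequency fitting needs real variation in concentration; studies with
  near-constant totals and no measured concentrations yield weak frequency
  evidence (scores near 0.5), leaving prevalence as the main signal.
* Reference matching is name/lineage-based across taxonomies; entries that
  cannot be resolved into the supplied taxonomy match by name only.
* Biome summaries count occurrences among top-N taxa of contributed study
  profiles; they reflect whatever corpus was summarised upstream, and the
  bundled machinery only aggregates locally supplied profiles.
* The HTML report is a static rendering of the bundle (tabs, tables and SVG
  charts); the bundle, not the report, is the canonical machine-readable
  surface.
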