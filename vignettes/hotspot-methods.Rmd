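---
title: "Detecting somatic mutation hotspots: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic mutation hotspots: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutdomino)
```

## The detection model

A hotspot residue is a single protein position that concentrates a
disproportionate share of a gene's somatic missense mutations. The
detector works on per-residue counts of *distinct* missense events — one
event per (patient, alternate amino acid, residue), so a mutation reported
twice for one patient counts once, while two different substitutions of the
same residue in one patient count twice.

A residue with count $k \ge m$ (default $m = 5$) becomes a candidate. For
each window length $W \in \{200, 300\}$ a window $[c - W/2,\ c + W/2]$ is
centered on the candidate and clipped to $[1, L]$. The window lengths
bracket the size of a typical protein domain (structural domains are
mostly 100–250 residues), so the window estimates the local, domain-scale
background rather than the whole-protein average. The candidate is called
when its share $k / n_w$ of the clipped window's mutations reaches
$f = 0.15$ in **every** window. An alternative mode replaces the share
rule with fold-overrepresentation against the window rate
($k \ge c\,\lambda$, $c$ configurable, default 10), for cohorts where a
fixed share is too blunt.

Each candidate receives a Poisson tail p-value per window: under a uniform
local background the per-residue expectation is $\lambda = n_w / W_{\rm
eff}$ and

$$p = P(X \ge k), \qquad X \sim \text{Poisson}(\lambda),$$

computed as one minus the CDF at $k - 1$ and clamped to $(0, 1]$. The
reported p-value is the **maximum** across window lengths — the most
conservative window governs — and Benjamini–Hochberg correction is applied
once across all candidates of the whole run, because the analysis produces
a single hotspot list rather than per-gene lists.

Three boundary conventions deserve a note, since published descriptions of
such detectors rarely state them:

* **Window clipping.** Near the termini the window is intersected with
  $[1, L]$ and both the share denominator and $\lambda$ use the clipped
  totals and length. This keeps denominators honest for short proteins
  instead of pretending mutations could fall outside the sequence.
* **The candidate's own events stay in $n_w$.** This inflates $\lambda$
  and is therefore conservative; excluding them would anti-conservatively
  shrink the background precisely at strong hotspots.
* **Ties.** Multiple residues clearing the rules produce independent
  calls; there is no per-gene cap.

## The filter funnel

Recurrent artifacts and germline leakage are the dominant false-positive
sources. Two filters flag (never silently drop) each call, so the full
flag history survives to the output and the filters commute:

* **Common variants** — a call matching a population variant whose
  frequency in any source is *strictly greater* than 1% is excluded;
  a variant at exactly 1% is retained, keeping germline risk variants.
  Genomic (chromosome, position, allele) keys are preferred; protein-keyed
  variant tables fall back to (gene, residue) matching.
* **Deleteriousness** — a call is kept when at least one underlying change
  at the residue carries a damaging label (`possibly_damaging` or
  `probably_damaging` in PolyPhen-2-style vocabularies; the mapping is
  configurable). Calls with no prediction at all are flagged `unscored`
  and excluded by default — a documented, configurable choice: treating
  missing evidence as insufficient keeps the final list conservative.

Feature annotation (domains, phosphosites, interfaces, transmembrane
segments) is transferred only after a sequence-agreement check between the
annotation source protein and the protein the mutations were mapped to:
global identity ≥ 95% *and* an identical residue at the hotspot position.
The 95% value is this package's choice (the requirement itself is
standard; a specific number rarely is); the hotspot-residue identity is
mandatory regardless, since a single mismatched residue at the position of
interest invalidates the transfer no matter how similar the rest is.

## Tumor-suppressor signatures

Suppressors are inactivated rather than activated, so their selection
signature is an excess of truncating over neutral changes: a gene with at
least 25 deleterious events (premature nonsense + out-of-frame indels) and
a deleterious/synonymous ratio above 0.7 is a suppressor candidate.
Synonymous counts approximate the local background mutation rate —
imperfectly, since synonymous sites are not fully neutral, which is a
known limitation of the signature. With zero synonymous events the ratio
is treated as $+\infty$, so the count rule alone decides; missense and
in-frame indels enter neither count.

## Interface mutation clusters

Structure-derived interfaces come in as PISA-style per-residue tables.
An interface is considered only when its complexation significance score
(CSS) strictly exceeds 0.3 for protein–protein contacts or 0.05 for
ligand / nucleic-acid contacts (weaker ligand interfaces are still
biologically meaningful, hence the lower bar); within passing interfaces,
residues burying strictly more than 25 Å² are interface residues, and
contiguous runs merge into segments.

Segments are transferred onto the analysis protein by Smith–Waterman local
alignment under BLOSUM62 with affine gaps (open 10, extend 0.5). Identity
is counted over *all* alignment columns, gaps included. A transfer is
accepted at identity ≥ 80%, or ≥ 60% when the alignment spans more than
ten columns; segments shorter than five residues are padded symmetrically
with flanking residues (clipped at sequence ends, with the lost padding
compensated on the other side) before alignment, because a 3-mer alone
cannot align reliably. Note one numerical convention: a gap of length
$\ell$ costs $10 + 0.5\,\ell$ here (the first gap position pays both
penalties), which is the convention of the alignment library used; tools
that charge the opening penalty *instead of* the first extension will
differ by 0.5 per gap run.

Mutation clustering on the transferred interfaces is tested per protein
with a binomial-logistic model over residues:

$$\text{mutated}_i \sim \text{Binomial}(N,\ \pi_i), \qquad
  \text{logit}(\pi_i) = \beta_0 + \beta_1 I_i^{\rm interface}
  + \beta_2 I_i^{\rm disorder},$$

where $N$ is the cohort size and the disorder indicator is a precomputed
binary track (disorder predictors are consumed as input, thresholded at
0.5 upstream). The disorder covariate absorbs the systematically different
mutation tolerance of disordered segments. The interface effect is
assessed with a one-sided likelihood-ratio test in the enrichment
direction ($p_{2}/2$ when $\hat\beta_1 > 0$, else $1 - p_2/2$); proteins
are BH-corrected and selected at adjusted $p < 0.05$. The
binomial-response construction is this package's documented choice — the
regression family is standard for region-clustering tests, but the exact
response construction varies between tools; a per-residue Poisson variant
would be the natural alternative. One test pools all passing interfaces of
a protein; per-interface attribution is reported descriptively afterwards.
Proteins with zero mutations are returned `untestable` with $p = 1$.

## Cohort-level analyses

**Frequency matrix.** Tumor types sharing a name abbreviation are merged
(a `COHORT:` prefix is stripped), types with fewer than 50 patients are
excluded, and each cell is the fraction of a type's patients carrying the
hotspot mutation.

**Clustering with bootstrap support.** Columns (tumor types) are clustered
on $1 - r$ Pearson distance with median linkage; the distance is this
package's documented choice, correlation distance being the default of the
standard bootstrap-clustering tool in R. Rows (hotspots) are resampled
with replacement $B = 10{,}000$ times and each internal node's support is
the plain bootstrap probability — the fraction of replicate dendrograms
containing the identical leaf set. The multiscale, approximately unbiased
correction of that tool is deliberately out of scope. Constant columns
have no defined correlation and are dropped with a warning; in replicates,
undefined correlations are treated as zero (distance 1). Median linkage
can invert heights; the Newick export tolerates that.

**Heatmap display.** Rows are shown only when the hotspot reaches one
third of the patients in some type; values are percentages on a log2
scale (so 78% displays as $\log_2 78 = 6.29$), and zeros are drawn as the
lowest display value — the minimum over positive entries minus one log2
unit, a concrete rendering of "zeros as the lowest values".

**Coverage and enrichment nulls.** Patient coverage of a gene/hotspot set
counts each patient once. Its null resamples same-size sets from all
positions with ≥ 5 mutations (1,000 draws) and reports a normal-tail p
plus the empirical bound $(1 + \#\{ \ge \text{obs}\})/(n+1)$.
Network-neighborhood enrichment fixes the query nodes and permutes the
identities of all other nodes over the unchanged topology
(degree-preserving), reporting a z-score and normal-tail p. Fraction
comparisons between gene sets use chi-squared with continuity correction
when all expected counts reach 5, Fisher's exact test otherwise, BH-
corrected across a batch.

## The synthetic-data generator

`simulate_cohort()` emulates the statistical structure the detector
assumes: per-residue missense counts follow a Poisson background at a
per-residue-per-sample rate, optionally inflated by a constant factor on
interface residues; planted hotspots draw
$H \sim \text{Poisson}\!\big(\tfrac{s}{1-s}\,B\big)$ extra events, where
$B$ is the expected background mass of the clipped 300-residue window —
the wider default window is the binding constraint under a uniform
background — so the expected local share is $s$; carriers are distinct
patients, optionally biased by tumor type. Truncating and synonymous
events arrive at gene-level per-sample rates with uniform positions, and
common variants contaminate each sample independently at their population
frequency. Everything is reproducible from one seed, and truth tables
(planted hotspots with realized event counts, suppressor rates, interface
masks, variant frequencies) accompany the mutation table.

What the generator does *not* emulate: trinucleotide-context mutational
signatures, regional mutation-rate covariates (replication timing,
expression), copy-number events, and sample-to-sample mutation-burden
heterogeneity. Passing tests on synthetic cohorts therefore demonstrate
the statistical machinery — calibration, sensitivity at stated shares,
filter behavior — not robustness to every systematic bias of real tumor
sequencing.

**Codon-substitution simulation.** To estimate how often a substitution
arises by chance, each event draws an amino acid with equal weight, one of
its codons uniformly, and one of the codon's nine single-nucleotide
changes uniformly; 10,000 events are tallied and the exact distribution is
also computed by enumeration over the 61 sense codons. Under this
weighting the glutamate-to-lysine probability is exactly
$\tfrac{1}{20}\cdot\tfrac19 = \tfrac{1}{180} \approx 0.56\%$ (each Glu
codon, GAA and GAG, converts to lysine by exactly one of its nine
changes). A codon-equal weighting mode is also provided
($P(\text{E}\to\text{K}) = \tfrac{2}{61}\cdot\tfrac19 \approx 0.36\%$)
because descriptions of such simulations alternate between the two
conventions; both all-events and amino-acid-changing denominators are
reported, as the choice shifts rates by ~20%.

```{r codon}
sim <- simulate_codon_substitutions(n_events = 10000, seed = 1)
sim
```

**Uniform null at titin scale.** `simulate_uniform_null()` scatters
mutations uniformly over a 34,350-residue protein (titin's length — the
most heavily mutated human gene by sheer size) and runs the detector.
At a load of 1,000 mutations per replicate, 1,000 replicates produce no
calls: with ~0.03 mutations per residue, reaching $k \ge 5$ *and* a 15%
window share is essentially impossible, confirming that uniform background
alone does not generate hotspot calls even in the largest genes.

## Problem sizes and numerical choices in the test suite

The suite validates calibration and power at deliberately moderate sizes,
chosen once as realistic desk-scale analogues: detector-vs-oracle
equivalence on 200 random profiles up to 500 residues; Poisson tails
against direct series summation to $10^{-12}$ absolute; the GLM's type-I
error on 1,000 null proteins (binomial 99% acceptance band around 0.05)
and its power on 200 proteins with 5× interface enrichment at 10%
coverage and ~40 mutations; planted-share grids on cohorts of 2,000
patients and a 500-residue gene whose total event count (~500) matches a
heavily mutated gene in a pooled pan-cancer cohort; alignment scores
against a full Gotoh dynamic-programming oracle on random 8–15-mers.
Headline pan-cancer figures (hundreds of hotspots, tens of percent patient
coverage) require the complete public mutation corpora plus external
annotation services and are intentionally not reproduced; the property
checks above are the package's evidence instead.

## Known limitations

* Only single-nucleotide substitutions feed hotspot counts; indels are
  kept solely for the suppressor signature, and multi-nucleotide events
  are not phased.
* The sequence-agreement and transfer identity thresholds (95%, 80%/60%)
  are sensible defaults, not optimized values.
* The share threshold $f$ is a plain configuration parameter here; tuning
  it against pathway enrichment (as one might with curated cancer-pathway
  sets) is out of scope.
* Bootstrap clade support is the plain bootstrap probability and inherits
  its known bias relative to multiscale corrections.
* One transcript table per run: overlapping transcript annotations across
  assemblies must be reconciled upstream.
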