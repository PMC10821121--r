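---
title: "Quantifying donor bacteria engraftment after fecal microbiota transplant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying donor bacteria engraftment after fecal microbiota transplant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmtengraft)
```

## The problem

Fecal microbiota transplantation (FMT) transfers a healthy donor's gut
community into a recipient, for example as oral capsules of lyophilized
stool given to dogs with chronic digestive disease. A basic question for any
FMT study profiled with 16S rRNA amplicon sequencing is: *how much of the
donor's community actually established itself in the recipient?* This
package answers that question at the resolution of amplicon sequence
variants (ASVs), given three samples per recipient — the donor's stool, the
recipient before FMT, and the recipient a few weeks after — which we call a
**triad**.

## The engraftment estimator

Let $D$, $P$ and $Q$ be the ASV presence sets of the donor, pre-FMT and
post-FMT samples of one triad, called on counts $\geq$ 1 read after rare-ASV
filtering (below). ASVs already shared between donor and recipient carry no
information about transfer, so they are excluded from both numerator and
denominator:

$$\text{eligible} = D \setminus P, \qquad
  \text{engrafted} = (Q \cap D) \setminus P, \qquad
  \text{rate} = 100\cdot\frac{|\text{engrafted}|}{|\text{eligible}|}\,\%$$

A triad whose eligible set is empty (the recipient already harboured every
donor ASV) has an undefined rate; such triads are flagged and excluded from
cohort means and medians rather than scored as 0 or 100. Cohort aggregates
are unweighted across recipients, so a recipient with 30 eligible ASVs
counts as much as one with 170.

Because presence/absence is the currency here, one or two stray reads could
fabricate a "shared" ASV. Before any engraftment computation the pipeline
therefore removes ASVs whose summed count across the *entire dataset* is at
most 2 (singletons and doubletons; `remove_rare_asvs()`, threshold
configurable). This filter is deliberately applied to the engraftment branch
only: rarefaction (below) serves the alpha-diversity branch, and the two are
never chained, because each correction targets a different artefact.

## Provenance partition

From the recipient's side, every ASV present post-FMT is attributed to one
of four sources:

| class | definition |
|---|---|
| always-shared | in $D \cap P$ — present in donor and recipient from the start |
| donor-derived | in $D \setminus P$ — can only have come from the capsules |
| recipient-derived | in $P \setminus D$ — the recipient's own flora |
| environmental/stochastic | in neither $D$ nor $P$ |

`provenance_fractions()` weights each class by its share of the sample's
reads (relative abundance within that sample, not rarefied, since the
quantity of interest is the proportion of the microbiome each source
constitutes). The four fractions sum to 1 by construction; pre-FMT samples
can only contain the first and third classes. Whether to average these
fractions over recipients or pool over samples is a genuine choice; the
package averages over recipients, consistent with how it aggregates rates.

The pre- vs post-FMT shift of the recipient-derived and always-shared
fractions is tested with a two-sided Wilcoxon rank-sum test
(`rank_sum_test()`). The test is reported as the Mann–Whitney $U$ of each
group ordering plus the raw rank sum, because "W" denotes different
statistics in different software. Pre/post samples are paired by dog, so an
unpaired rank-sum test is conservative here; it is used because it is the
convention in the field for this comparison, and a paired signed-rank
alternative is a one-line change (`stats::wilcox.test(..., paired = TRUE)`).

## Overlap and priority effects

Community ecology predicts a priority effect: the more of the donor's
community the recipient already holds, the less room newly arriving donor
bacteria have to establish. The package quantifies donor–recipient overlap
as weighted UniFrac *similarity* (1 − normalised distance) between the
donor and pre-FMT samples, and correlates it with the post-FMT
donor-derived abundance fraction using Spearman's rank correlation
(`spearman_cor()`). A negative correlation is the priority-effect
signature. Without a phylogeny the overlap falls back to Bray–Curtis
similarity on proportions, clearly recorded in the fitted object.

## Diversity machinery

The estimators the analyses consume are implemented from their defining
formulas and validated against independent brute-force oracles and, where
applicable, vegan:

* **Chao1**: $S + F_1^2/(2F_2)$, with the $S + F_1(F_1-1)/2$ fallback when
  $F_2 = 0$; bias-corrected variant behind a flag.
* **Shannon** in nats; **Gini–Simpson** $1 - \sum p_i^2$.
* **Jaccard** on presence sets, **Bray–Curtis** on proportions,
  **Aitchison** as Euclidean distance on CLR-transformed counts
  (pseudocount 0.5 by default; the data are compositional and zeros must be
  offset — 0.5 is the customary half-count).
* **Weighted UniFrac**: each branch contributes its length times the
  absolute difference in the fraction of reads descending from it;
  normalised by $\sum_b l_b (p_b(x) + p_b(y))$ so the distance lies in
  $[0,1]$. Inputs are rescaled to relative abundances internally, making the
  distance depth-invariant. Implementation is a single postorder
  accumulation over edges; the test oracle instead enumerates every
  branch's descendant leaf set recursively.

Rarefaction (`rarefy()`) subsamples each sample to a fixed depth (default
26,000 reads) *without replacement* — a multivariate hypergeometric draw —
and excludes, rather than up-samples, shallower samples. A seed is a
required argument: silent irreproducibility is the main practical hazard of
rarefaction. Alpha diversity is computed on rarefied counts; UniFrac and the
other beta metrics use unrarefied relative abundances by default, since
they are proportion-based.

## The synthetic cohort generator

Real cohort data cannot validate an engraftment pipeline because the true
origin of each post-FMT ASV is unobservable. `simulate_cohort()` therefore
generates triads with known ground truth. Per triad:

1. the donor community is a log-normal rank-abundance profile
   ($\sigma = 1.5$, a standard long-tailed model for gut communities) over
   taxa drawn from a global pool;
2. the pre-FMT community shares a fraction `overlap` of its taxa with its
   donor;
3. the post-FMT community keeps each pre-FMT taxon with probability
   `persist_prob`, engrafts each eligible donor taxon independently with
   probability `engraft_prob` at `engraft_strength` times its donor
   abundance, adds `n_env` novel low-abundance environmental taxa, and is
   read-sampled multinomially at the sample's depth.

Defaults mirror a 54-recipient / 7-donor oral-capsule study design: donor
richness 33–170 ASVs, depths 26,000–60,000 reads, `overlap = 0.6` (pre-FMT
shared abundance around 60%), `engraft_prob = 0.18` (mean measured rates
around 18%), `persist_prob = 0.9`, and 20 environmental taxa at mean
relative abundance 0.006 (roughly a 10–15% environmental share post-FMT).
`engraft_strength = 0.5` encodes that newly arriving taxa typically
establish below their donor abundance.

What the generator emulates: presence/absence structure, long-tailed
abundances, donor reuse across recipients, depth heterogeneity, and
sequencing dropout (low-abundance taxa receiving zero reads). What it does
not emulate: post-FMT blooms of engrafted taxa (engrafted abundance stays
tied to donor abundance, so synthetic donor-derived *abundance* fractions
run a few percent, lower than real cohorts where engrafted taxa expand over
weeks), taxonomic misassignment, chimeras, or strain-level variation.
Passing the recovery tests therefore demonstrates correctness of the
set-algebra and estimators under realistic noise — not that any real cohort
will show a particular donor-derived abundance.

Two test-relevant consequences of multinomial sampling are worth naming.
First, a donor∩pre taxon that drops out of the *pre* sample is counted
eligible and, if it persists, "engrafts" — inflating measured rates — while
an engrafted taxon dropping out of the *post* sample deflates them; at the
default conditions these roughly cancel (measured mean rates sit within the
95% binomial envelope of the generating probability at 200 triads). Second,
provenance classification is exact only without dropout, so the exactness
test runs the generator in its deterministic-count mode
(`multinomial = FALSE`), which preserves presence of every true taxon.

## Numerical and design choices

* Presence threshold 1 read (after the dataset-wide rare filter); exposed
  as `min_presence`.
* Donors with several stool samples are resolved by `donor_policy`:
  `"single"` (metadata-flagged sample), `"pool"` (element-wise sum into a
  pseudo-sample) or `"error"`; the default is `"single"` because pooling
  manufactures a community no capsule ever contained.
* Count-table orientation is auto-detected by intersecting axis labels with
  metadata sample ids; ties are an error, not a guess.
* Newick trees without branch lengths get unit lengths with a warning.
* Taxon labels for engraftment summaries use the lowest classified rank,
  with `"unclassified <family>"`-style labels when the genus is unknown.
* Two empty presence sets are at Jaccard distance 0 by convention (logged).
* All RNG flows through explicit seeds; `rarefy()` and `simulate_cohort()`
  restore the caller's RNG state.

## Problem sizes used by the test suite

The suite validates estimators on 100-instance oracle sweeps (vectors of
20–25 taxa, trees of 8–20 leaves), engraftment set algebra on 100 random
3-sample tables of up to 20 ASVs, rate recovery on one 200-triad cohort at
depth 50,000, provenance exactness on a 30-triad deterministic cohort, the
priority-effect sign on a 9-level overlap sweep (8 triads per level), and
the end-to-end run on the default 54-triad cohort. These sizes keep the
whole suite under a minute while leaving Monte-Carlo margins wide enough to
be stable across seeds.

## Limitations

ASV-level sharing is an upper bound on true transfer: two hosts can carry
an identical V4 fragment from different strains, and conversely a
transferred strain can be missed below the detection limit. Rates from
different studies are not directly comparable, since eligibility rules and
filters differ. The estimator also inherits the compositionality of
relative-abundance data; the provenance fractions describe shares of the
sequenced community, not absolute loads. Strain-resolved metagenomics is
the natural follow-up where these distinctions matter.

## A worked example

```{r example}
cohort <- simulate_cohort(n_triads = 12, n_donors = 3, seed = 7)
fit <- fmt_engraftment(cohort)
fit
head(coef(fit))
summary(fit)
```
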