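---
title: "Comparing the seven human 14-3-3 paralog interaction networks"
author: "paralognet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing the seven human 14-3-3 paralog interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralognet)
```

## The scientific question

The seven human 14-3-3 paralogs (beta, gamma, epsilon, eta, sigma, theta,
zeta) are phospho-serine/threonine-binding adaptors so conserved that they
were long assumed interchangeable. `paralognet` implements a comparative,
systems-level interrogation of that assumption: assemble one
14-3-3/kinase/kinase-substrate interaction network, carve out the seven
hub-centred subnetworks, and ask — through motif composition, structural
disorder, PTM composition, domain repertoires and GO enrichment — whether
the paralogs' partner sets are statistically distinguishable.

The package is organised as an analysis workflow: the numbered scripts under
`analysis/` narrate the stages, while every computation lives in exported
package functions so that the test suite and `scripts/acceptance.R` exercise
the identical code paths.

## Network model

An `annotated_network` couples an undirected interaction list (deduplicated
per unordered pair; self-interactions dropped, since 14-3-3 dimerization is
orthogonal to a between-paralog comparison) with per-protein annotation:
length, domain segments, intrinsic-disorder segments, PTM sites, GO terms,
localization labels, kinase-group membership and domain-club clades. All
coordinates are 1-based inclusive. Isoform suffixes (`-2`) are stripped from
accessions so protein isoforms collapse onto one gene-product record. When a
protein's true length is unavailable the largest annotated coordinate stands
in; synthetic cohorts always supply true lengths.

A paralog subnetwork consists of the hub's direct neighbours (the
*partners*) plus, optionally, one further hop restricted to kinases — the
published network was built exactly by adding kinases and kinase substrates
to the client list, and the hop rule is exposed as a flag because the
original description fixes only the full-network behaviour. Network
similarity is the Jaccard index of *partner sets* (not edge sets): partner
identity is the only set defined for every isoform, and the published
similarity table compares isoform networks as sets of interactors.

## Edge orientation

The motif census needs a directed network. Interactions of known direction —
curated kinase→substrate pairs — train a categorical naive Bayes classifier
over an ordered node pair (a, b) with five features: relative undirected
degree (greater/less/equal), kinase flags of both ends, and tercile bins of
each end's total PTM count (bin boundaries estimated on the training pool).
Conditional probabilities use add-α smoothing with α = 1, with a reserved
level for categories unseen in training; exact posterior ties are broken
toward the lexicographically smaller source identifier, deterministically.
Curated edges keep their known direction regardless of the classifier
(override on by default). We make no attempt to reproduce any specific
external classifier's numeric output; the downstream census only requires a
deterministic, better-than-chance orientation procedure, which the held-out
accuracy property (≥ 0.7 on feature-generated truth) verifies.

## Motif census and null model

Connected directed three-node subgraphs fall into 13 isomorphism classes.
The dictionary is hard-coded as a lookup over the 64 possible 3-node
adjacency masks, reduced by all six node permutations, and self-validates at
construction: exactly 13 connected classes, class sizes summing to the
number of connected masks, and the three anchor topologies matching their
standard descriptions — class 3 the linear chain, class 7 the feed-forward
loop (X→Y, X→Z, Y→Z), class 10 the mutual pair co-regulating a third. The
census visits each connected triple exactly once (Batagelj–Mrvar edge
iteration) in a small C++ kernel.

Significance is assessed against an ensemble of degree-preserving
randomizations. The switching null model swaps unidirectional edges and
reciprocal pairs within their own subsets, so every node's in-degree and
out-degree *and* the count of reciprocal edges are preserved exactly, and no
self-loop or multi-edge is ever introduced; the default is Q = 10 successful
swaps per edge with a bounded retry budget (a network too rigid to reach the
target is returned with a warning). Enrichment is one-sided — motifs that
occur more often in the data than in the ensemble — with the empirical
p-value (1 + #{random ≥ observed})/(R + 1), never zero; depletion is visible
through the z-score but not flagged. Classes with zero ensemble variance get
a flagged, undefined z.

## PTM composition and crosstalk

Every residue position maps to exactly one structural region: domain,
disordered, or other. When curated domains and predicted disorder overlap
the domain label wins — domains are the more specific curated annotation —
and the precedence is configurable. Composition tables count modified
residues per (class × region) cell with "total" recomputed as the sum of the
three regions; per-region phospho percentages share a single denominator
(all phospho sites in that region), which is the one self-consistent reading
of the published per-region percentages.

Cross-isoform contrasts are two-sided Fisher exact tests on 2×2 tables, with
raw p-values reported (matching the published uncorrected ranges) and
Benjamini–Hochberg q-values as an optional extra column. The disorder
comparison reports three families at once — Kruskal–Wallis across all seven
networks, pairwise Wilcoxon rank-sum on partner disorder fractions, and
pairwise Fisher tests after binarizing partners at a disorder fraction of
0.5 (the threshold behind the published dichotomous tests is unstated, so it
is a configurable parameter) — because the original analysis mixed the three
test types. Crosstalk between phosphorylation and lysine acetylation is a
protein-level association: does carrying ≥ 1 phospho site of a given residue
co-occur with carrying ≥ 1 acetyl-lysine.

The statistical kernels are thin, oracle-validated wrappers over R's own
`fisher.test`, `wilcox.test`, `kruskal.test` and `p.adjust`: the original
analysis was run in R, so R's conventions (point-probability two-sided
Fisher with the 1 + 1e-7 tolerance factor; mid-ranks with tie and continuity
correction) are the reference behaviour. The test suite checks them against
independent brute-force enumeration, not against themselves.

## Domains, clades and GO

Domain profiles count protein-level presence (a partner with three copies of
a domain counts once) because every downstream Fisher table needs binary
per-protein states; instance counts are retained for totals.
Coiled-coil (CC) and transmembrane (TM) segments are excluded by default as
super-numerary in every network. The domain–isoform bipartite graph links a
domain to an isoform when that isoform differs from at least one other at
p ≤ 0.01 (two-sided, so both significant presence and significant absence
are kept, labelled by sign). Modified-domain profiles count a domain as
phospho- or acetyl-modified only when a matching site falls within its
coordinates. Clade ("domain club") assignment is consumed as an external
lookup (1–1250); clades from 1081 up count as isolated domains, a boundary
kept configurable because the published split is approximate.

GO over-representation follows the BiNGO-style recipe: parse OBO 1.2
(obsolete terms dropped and counted; only `is_a` traversed by default,
`part_of` behind a flag), propagate annotations to all ancestors
(true-path rule, set semantics on diamonds), and test each term with the
upper-tail hypergeometric distribution, BH-adjusted within the namespace.
The universe defaults to the full assembled network's node set — the
original study compared isoforms against their common network, and a
genome-wide universe would require external data; it is configurable. The
exact test variant used by the original BiNGO runs is unstated;
hypergeometric is the implemented default. Adaptive thresholding picks the
largest p cutoff that retains a target window of terms (35–50 by default)
for report-graph sizing.

## The synthetic cohort

The generator emits every input format the pipeline reads, plus the ground
truth, as a deterministic function of a configuration and seed. Defaults are
the reference study conditions:

* 800 proteins, 15% kinases; log-normal lengths (median 450, sdlog 0.45,
  clipped to 80–3000).
* Seven partner sets of 120, built from a core shared by all seven (sized to
  a baseline Jaccard of 0.10) plus an extra theta–beta block targeting the
  published 0.273; the construction is exact in expectation and errors when
  the requested overlaps are infeasible for the set size.
* Per-protein domain counts geometric with mean 1.6, lengths uniform 60–250;
  a drawn architecture is kept while it fits within 85% of the chain and the
  remaining slack is distributed as random inter-domain gaps, so drawn
  domains are always realized and effect multipliers act at full strength.
  Disorder fractions are Beta(1.5, 3) (mean 1/3), placed in the gaps between
  domains with a 10% chance of running into a domain edge.
* PTM sites are per-residue Bernoulli draws at region-dependent densities
  (per residue position: pS 0.020 disordered / 0.004 domain / 0.008 other;
  pT half of pS; pY 0.002 / 0.003 / 0.002; acK 0.002 / 0.006 / 0.003) — the
  simplest mechanism consistent with phosphorylation concentrating in
  disorder and lysine acetylation in ordered regions. The "other"-region
  phospho densities are not fixed by any published number and were set to
  intermediate values once.
* Planted effects: epsilon's partners get 2.5× the domain-pY density, zeta's
  partners 2× the acK density everywhere, gamma's partners an 8× RRM
  selection weight, one biological-process GO term a 5× annotation rate in
  gamma's partners, and 40 feed-forward loops are planted in the directed
  layer. `null_config()` resets all of these for calibration.
* Edge directions are generated from the classifier's own default feature
  schema through a logistic model (kinase-flag difference 2.2, degree-sign
  1.4, PTM-bin difference 0.5), so direction recovery is well-posed;
  kinase→substrate edges are fixed and serve as the curated training set.
* Localization couples to acetylation (P(nuclear) 0.25 base vs 0.65 for
  acetylated proteins) and NLS motifs to nuclear localization (0.55 vs
  0.08), emulating the published association between acetylated partners,
  nuclear residence and NLS content.

What the generator does **not** emulate: literature-curation biases, the
marginal degree distributions of real interactome databases, realistic
amino-acid composition, or correlated placement of sites within motifs.
Passing the suite therefore demonstrates that the *statistical machinery*
is correct and calibrated, not that the biological conclusions transfer to
any particular database snapshot.

### Power design for the planted effects

Detection of each planted effect, for the power checks, is a single
pre-registered contrast per seed: the planted isoform's partners against the
pooled partners of the other six (matching the published claims of one
isoform exceeding *all* others). With 120 partners per set and the densities
above, normal-approximation arithmetic gives z ≈ 4–6 for the epsilon, zeta
and gamma contrasts (power > 0.95 at α = 0.01), while the weakest *pairwise*
contrasts sit near z ≈ 3 (power ≈ 0.7) — which is why the pooled contrast,
not the pairwise matrix, defines detection. The zeta burden is detected with
a Wilcoxon rank-sum on per-partner acK site counts: the carrier proportion
is nearly saturated at baseline (0.83), and a site-level 2×2 would treat
correlated sites within one protein as independent draws — calibration on
null cohorts shows that test is anti-conservative, while the protein-level
rank test holds its nominal level exactly. Planted feed-forward loops
are detected through the empirical motif p with an ensemble of 199
(minimum attainable p = 0.005 < 0.01).

## Numerical and reproducibility choices

* Empirical motif p-values use the +1 correction; ensemble seeds are
  explicit arguments and all generator randomness is confined to a local
  RNG scope, so identical configuration and seed give byte-identical
  outputs (hash-checked in the tests).
* Degenerate inputs are flagged, not silently dropped: empty∪empty Jaccard
  pairs are defined as 0, crosstalk tables with an empty margin return
  p = 1 with a degeneracy flag, zero-kinase networks yield flagged zero
  rows, and all-tied rank tests return p = 1.
* Problem sizes in the checks: oracle equivalence runs on 200 random
  digraphs (n ≤ 12), all 2×2 tables with N ≤ 40, and all hypergeometric
  configurations with N ≤ 25; type-I calibration uses 200 null cohorts of
  400 proteins with 60-partner hubs (the same shared-core construction,
  scaled so the partner demand fits the client pool); power uses 100 seeds
  at the full default conditions. These sizes are the package's reference
  settings and are stated here so results are reproducible as published.

## Known limitations

* The published network snapshot (2230 nodes, 4870 edges, 741 clients) was
  assembled from 2010-era databases and disorder predictions; the checks
  against its printed counts require the deposited table under `data-raw/`
  and cannot run from synthetic data.
* The dictionary ordering of the 13 triad classes is fixed by three
  published anchors (3, 7, 10); the remaining ten positions follow the
  standard dictionary layout but no published statement in the source
  constrains them.
* The hierarchical clustering behind the clade mapping and the external
  direction-classifier training corpus are consumed as inputs, never
  recomputed.
* The published per-region phospho percentages add to slightly more than
  100 for disordered regions; this package defines one denominator (all
  phospho sites in the region) and documents the discrepancy rather than
  reproducing it.
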