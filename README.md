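# paralognet

Comparative analysis of the seven human 14-3-3 paralog interaction
networks.

The 14-3-3 family — beta, gamma, epsilon, eta, sigma, theta and zeta — are
phospho-Ser/Thr-binding adaptor proteins so strictly conserved across
mammals that their seven paralogs were long considered redundant.
`paralognet` implements a systems-level comparison designed to detect
subfunctionalization: it assembles one 14-3-3 + kinase + kinase-substrate
protein–protein interaction network, extracts the seven hub-centred
subnetworks, and contrasts them through

* **partner-set overlap** — the Jaccard index J(A,B) = |A∩B| / |A∪B| over
  each paralog's direct interactors;
* **directed 3-node motifs** — edges are oriented with a naive Bayes
  classifier trained on curated kinase→substrate directions, every
  connected triad is classified into the 13 standard classes (7 = the
  feed-forward loop X→Y, X→Z, Y→Z; 3 = the linear chain), and per-class
  counts are compared with a degree-preserving switching ensemble using the
  one-sided empirical p = (1 + #{random ≥ observed}) / (R + 1);
* **region-stratified PTM composition** — every phospho-Ser/Thr/Tyr and
  acetyl-Lys site is assigned to a domain, disordered, or other region
  (domain precedence on overlap) and isoform networks are contrasted with
  two-sided Fisher exact tests;
* **phospho/acetyl crosstalk, domain enrichment, domain-club (clade)
  profiles and hypergeometric GO over-representation** with true-path
  propagation and Benjamini–Hochberg adjustment.

Because the original network snapshot came from database versions that
cannot be re-downloaded, the package ships a fully parameterised synthetic
cohort generator (`sim_config()`, `simulate_cohort()`, `generate_bundle()`)
that emulates the statistical structure of the study — seven overlapping
partner sets (theta–beta targeted at the published Jaccard 0.273),
phosphosites enriched in disordered segments, acetyl-lysines in ordered
ones, isoform-specific planted effects, and planted feed-forward loops —
with complete ground truth, so every stage is testable and its error rates
calibratable offline.

## Worked example

The numbered scripts under `analysis/` run the full workflow on the default
synthetic cohort (seed from `PARALOGNET_SEED`, default 1) and write their
tables under `results/analysis/`:

```sh
Rscript analysis/01_simulate.R      # inputs + ground truth
Rscript analysis/02_build_network.R # assembly + Jaccard
Rscript analysis/03_orient.R        # naive Bayes edge orientation
Rscript analysis/04_motifs.R        # triad census vs switching null
Rscript analysis/05_ptm_composition.R
Rscript analysis/06_domains.R
Rscript analysis/07_go_enrichment.R
Rscript analysis/08_report.R
```

With the default seed this prints, among other things:

```
annotated network: 802 nodes, 1470 edges, 679 clients of 7 paralog hub(s)
most similar pair: theta-beta            # Jaccard 0.270 (target 0.273)
enriched classes: 7                      # the planted feed-forward loop,
                                         # z = 45.0, empirical p = 0.001
largest acetylated-partner count: zeta   # 112/120 partners, 397 acK sites
highest RRM carrier frequency: gamma (0.29; min pairwise p = 0.00012)
top gamma term: GO:S0016 (boost term was GO:S0016)
```

i.e. each planted isoform-specific effect — the theta–beta overlap, the
feed-forward-loop excess, zeta's acetylation burden, gamma's RRM domain
excess and gamma's boosted GO term — is recovered by the corresponding
stage of the pipeline. The same computations are available
programmatically:

```r
library(paralognet)
b   <- simulate_cohort(sim_config(seed = 1))
net <- bundle_network(b)
pn  <- paralog_subnetworks(net)
jaccard_matrix(pn)["theta", "beta"]          # 0.2698
ms  <- motif_significance(directed_layer(b), ensemble_size = 999, seed = 11)
subset(as.data.frame(ms), class_id == 7)     # count 41, p = 0.001
```

## Input formats

Tab-separated, 1-based inclusive coordinates throughout:
`interactions.tsv` (`id_a`, `id_b`[, `source`]), `ptm.tsv` (`protein_id`,
`position`, `residue`, `modification`), `domains.tsv` (`protein_id`,
`domain_name`, `start`, `end`), `disorder.tsv` (`protein_id`, `start`,
`end`), `go.tsv` (`protein_id`, `term_id`) plus an OBO v1.2 ontology,
`localization.tsv` (`protein_id`, `label`), `kinase_groups.tsv`
(`protein_id`, `group`), `clades.tsv` (`protein_id`, `clade_id` 1–1250).
Networks are exported to GraphML (Cytoscape-ready; node attributes carry
per-class PTM counts and per-paralog membership flags, edge attributes the
orientation and posterior).

See `vignettes/paralog-network-comparison.Rmd` for the model, the
generator's assumptions, and the design decisions.
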