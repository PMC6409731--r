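---
title: "Methods: models, parameters and validation in famevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and validation in famevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famevol)
```

famevol reconstructs the evolutionary history of a gene family — the
motivating case is the plant vacuolar iron transporter (VIT) family,
whose members sequester iron into the vacuole — from sequences, gene
coordinates, synteny blocks and expression tables. This vignette
documents the models behind each stage, the tunable parameters and their
defaults, the synthetic-data generators used for validation, and the
numerical choices a maintainer would want written down.

## Phylogeny

Trees are built by neighbor joining on protein p-distances. The
p-distance between two aligned sequences is the fraction of mismatching
positions among columns ungapped in *both* sequences (pairwise
deletion). A pair sharing no ungapped column has no defined distance and
is an error rather than a silent `NaN`. Agglomeration uses the standard
Saitou–Nei Q-criterion via `ape::nj()`; negative branch-length estimates
(a known NJ artifact) are clamped to zero. Bootstrap support resamples
alignment columns with replacement, rebuilds the NJ tree per replicate,
and reports for each internal bipartition of the full-data tree the
percentage of replicates containing it, stored as integer node labels
(0–100). NJ is provably consistent on additive matrices; the test suite
exercises this with 200 random trees whose exact patristic matrices are
fed back to `nj_tree()`.

Alignment construction is deliberately *input*: real families should be
aligned with a dedicated aligner beforehand. Because downstream
reconciliation needs a rooted tree and no rooting procedure is implied
by the data, midpoint rooting is the documented default (`midpoint_root()`),
with the caveat that it assumes a roughly clock-like family. Family
groups (e.g. Group I–VII in the VIT literature) are defined as smallest
clades spanning user-chosen anchor leaves; overlapping group clades are
rejected rather than resolved silently.

## Duplication–loss reconciliation

`lca_reconcile()` embeds a rooted gene tree into a rooted species tree
by the classic last-common-ancestor mapping: each internal gene node
maps to the LCA of its children's images and is a duplication precisely
when its image equals a child's image. Losses are read off the species
path skipped between a node's image and each child's image; every
skipped species node implies one lost copy in its other descendant
branch. Duplications and losses carry equal unit cost (the common
parsimony default); the LCA mapping minimizes this cost, which the test
suite verifies against an exhaustive dynamic program over *all* valid
mappings for every rooted topology with 3–6 leaves over 2–4 species.

Ancestral copy numbers follow the bookkeeping recurrence
`copies(child) = copies(parent) + gains(branch) − losses(branch)`,
anchored at one ancestral copy plus any duplications mapped to the root.
Clade-wise ancestral counts reported in the VIT literature depend on an
unstated clade decomposition of the family tree, so they are not
reproduced as fixed numbers here; `family_census()` reports the full
per-branch table for whatever subtree the user supplies instead.

## Duplication classification and dating

Paralog pairs are classified from gene order and synteny blocks:

* **tandem** — same chromosome and separated by fewer than five genes
  (at most 4 intervening genes; adjacency included). The boundary is
  read strictly: exactly five intervening genes is *not* tandem.
* **segmental** — not tandem, but the two genes share a synteny
  `block_id` (either as a registered pair or both members of one block).
* **transposition** — neither; the explicit interpretation of
  relocation-based paralogy used when neither proximity nor block
  membership explains the pair.

Gene order is by start coordinate, strand-agnostic, because intervening
genes are counted irrespective of orientation, and uses *all* genes in
the supplied table (not family members only).

Synonymous divergence is estimated with the Nei–Gojobori (1986) method:
fractional synonymous/nonsynonymous site counts per codon (changes to
stop codons count as nonsynonymous), equal-weight enumeration of all
mutational pathways for codons differing at 2–3 positions (pathways
through stop codons are excluded and the weights renormalized), and the
Jukes–Cantor correction d = −(3/4)·ln(1 − 4p/3), undefined (flagged as
saturated) when p ≥ 3/4. This estimator was chosen because every count
can be checked against a brute-force pathway-enumeration oracle, which
the test suite does on random codon pairs; K<sub>s</sub> from other
estimators on real sequences will differ numerically, so published
K<sub>s</sub> values can be injected directly into the pair report,
isolating the dating stage from the estimator.

Dating uses the molecular clock T = K<sub>s</sub> / (2λ) with
λ = 1.5×10⁻⁸ synonymous substitutions per site per year by default, the
clock rate under which every published tomato and soybean VIT divergence
time in the package's bundled table is reproduced exactly to two
decimals. (The VIT literature prints the rate as "15 × 10⁻⁸", which is
inconsistent with its own printed times by two orders of magnitude; we
treat that as a typographic slip and keep λ configurable.) Times are
reported in Mya rounded to two decimals with round-half-even.

## Site-specific selection

Selection heterogeneity across codon sites is modeled with discretized
ω-distribution models on a fixed tree:

* **M5** — ω ~ gamma(shape α, scale β);
* **M7** — ω ~ beta(p, q) on (0, 1);
* **M8** — with probability p₀, ω ~ beta(p, q); with probability
  1 − p₀, ω = ω_s ≥ 1 (the positive-selection class).

Each continuous distribution is approximated by K = 8 equal-probability
classes whose ω is the class median (quantile at (k − ½)/K); M8 appends
the point mass as a ninth class. Site likelihoods use a GY94-style codon
process over the 61 sense codons — rate ∝ π_j, ×κ for transitions, ×ω
for nonsynonymous changes, zero for multi-nucleotide changes — with the
class matrices jointly rescaled so the mixture-average rate is one
substitution per codon per unit branch length. Likelihoods are computed
by Felsenstein pruning with per-node rescaling and alignment-pattern
compression; matrix exponentials use the symmetric eigendecomposition
available for reversible rate matrices. A 3-taxon exhaustive sum over
all 61 internal states validates the pruning to 10⁻¹⁰.

Free parameters — the distribution parameters, κ (initialized at 2), and
one global branch-length multiplier (so the input tree may be in any
units, e.g. protein p-distance) — are maximized with `nlminb` on
log/logit-transformed scales from two default starts (plus any
user-supplied starts; passing an M7 optimum as an M8 start makes the
nesting inequality logL(M8) ≥ logL(M7) structurally guaranteed).
Equilibrium codon frequencies default to F3x4 estimated from the
alignment, floored at 10⁻⁸ so low-diversity alignments keep an
irreducible rate matrix; uniform frequencies are available and used in
tests. Alignments of identical sequences leave ω unidentifiable and are
returned flagged `degenerate` rather than optimized. Model comparison
defaults to AIC across fits; the conventional M7-vs-M8 likelihood-ratio
test (χ², 2 df) is available as `m7_m8_lrt()`.

Per-site selection is summarized by empirical Bayes: posterior class
weights ∝ prior weight × class likelihood, E[ω|site] is the reported
site-specific Ka/Ks, and a site is *called* positively selected under M8
when E[ω|site] > 1 (the Selecton-style convention; no multiple-testing
adjustment, which the output states). The count of positively selected
sites in any real data set depends on the sequences themselves, so the
package validates calling by simulation instead: at the study scale used
in the tests (p₀ = 0.9, ω_s = 4, 12 taxa, 300 codons, 20 replicates —
sizes chosen to exercise the estimator well inside a laptop budget),
over 80% of truly positive sites are called and the fitted ω_s and p₀
bracket the truth.

## Gene structure

Intron positions and phases are derived from CDS intervals in
transcription order (minus-strand models are reversed): the phase is the
cumulative upstream CDS length mod 3. Intron retention between paralogs
is detected structurally rather than by homology search: paralog Y is
reported as retaining an intron of paralog X when X has an intron
boundary at a protein position where Y instead carries an in-frame
insertion (a gap run in X's row of the protein alignment) of at least 6
codons starting within 2 alignment columns of the boundary, with no
intron of Y's own inside the run. The 6-codon floor suppresses spurious
single-codon indel calls and is configurable; pairs below a 30% identity
floor are rejected as unalignable.

## Expression

FPKM matrices are transformed as log10(x + 1); the pseudocount (default
1, so FPKM 0 maps to 0) handles zeros, and optional per-gene z-scoring
(the default normalization reading of "normalized" heatmaps; min–max is
also offered) serves heatmap display via `autoplot()`. qPCR relative
expression uses the Livak 2^−ΔΔCT method with replicates averaged on the
CT scale (a per-replicate variant is available through the returned
components); replicate standard errors of the four CT means propagate in
quadrature to ΔΔCT and by the delta method to the fold scale. The
estimator is exactly invariant to machine-wide CT offsets.

## Synthetic data and what validation does (and does not) show

Every generator is a pure function of (parameters, seed), with one
pseudorandom stream per generator derived from (seed, stream name) so
adding a generator never perturbs another:

* `simulate_family()` — exact Gillespie birth–death along the species
  tree with a full event log plus the *observable* history (duplications
  with survivors on both sides; one loss per maximal extinct subtree
  hanging off a surviving speciation) — exactly what reconciliation of
  the pruned tree can recover. Default validation rates (0.1 births,
  0.05 deaths per unit branch) keep most histories parsimonious.
* `simulate_codon_alignment()` — GY94 evolution with per-site ω drawn
  from a mixture, true class recorded.
* `simulate_genome_layout()` — background genes on three chromosomes
  with a planted tandem array (0–4 intervening genes), a copied
  segmental block registered in the block table, a relocated gene with
  no block entry, and an exactly-five-intervening boundary pair.
* `simulate_expression()` — CT = 30 − log2(expression) + N(0, σ) with a
  constant reference gene; σ defaults to 0.1 CT cycles, a realistic
  qPCR technical noise level.
* `simulate_retention_pair()` — a paralog pair with one in-frame intron
  retained (default 15 codons) at a known coordinate.

These generators deliberately idealize real data: no indels or
alignment error, no rate variation among lineages, no codon-usage bias
beyond F3x4, no incomplete annotations, and birth–death events
independent across lineages. Passing the recovery studies therefore
demonstrates correctness of the *algorithms* under their own model
assumptions, not robustness to everything real plant genomes do; results
on real families inherit the usual caveats of alignment quality,
rooting, and clock constancy.

## Numerical choices

* Gene-order ties at identical start coordinates break by lexicographic
  gene id, making `order_index` deterministic.
* NJ Q-matrix ties are resolved by `ape::nj`'s deterministic scan order.
* Likelihood optimization: `nlminb`, relative tolerance 10⁻⁷, iteration
  cap 300 per start; non-convergence is flagged in the fit object, never
  silent.
* Pruning rescales partial likelihoods to unit column sums at every
  internal node, accumulating the log scale, so deep trees cannot
  underflow.
* Bootstrap supports round half away from zero to integers, matching
  the usual display convention.
* The dating stage rounds to 2 decimals with R's round-half-even.

## Pipeline sizes used in the packaged studies

The validation studies run at: 200 additive matrices (5–8 leaves);
all 1,314 rooted gene-tree topologies with 3–6 leaves against the
exhaustive reconciliation oracle; 100 birth–death families; 50 planted
genome layouts; 100 random codon pairs against the pathway oracle; 20
M8 recovery replicates (12 taxa × 300 codons); 50 noisy qPCR tables.
These sizes give stable rates while keeping a full run comfortably
inside a coffee break on one core.
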