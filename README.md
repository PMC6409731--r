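# famevol

Tools for reconstructing how a plant gene family evolved. The motivating
case is the vacuolar iron transporter (**VIT**) family — membrane
proteins that sequester iron into the vacuole, with paralog-rich
clusters in soybean and tomato — but every stage is generic:

* **Phylogeny** — neighbor-joining trees from protein p-distances with
  pairwise gap deletion, bootstrap support, midpoint rooting, and
  anchor-based family group assignment.
* **Reconciliation** — duplication–loss parsimony of a rooted gene tree
  against a species tree (LCA mapping), with per-branch gains, losses
  and ancestral copy numbers.
* **Duplication dating** — classification of paralog pairs into tandem
  (fewer than five intervening genes on one chromosome), segmental
  (shared synteny block) or transposition; Nei–Gojobori Ka/Ks with
  Jukes–Cantor correction; molecular-clock dating **T = Ks / 2λ**
  (default λ = 1.5×10⁻⁸ synonymous substitutions/site/year).
* **Site-specific selection** — discretized ω-distribution codon models
  M5 (gamma), M7 (beta) and M8 (beta + ω_s ≥ 1) with K = 8 classes on a
  fixed tree (GY94 rate matrix, Felsenstein pruning), empirical-Bayes
  E[ω | site], and positive-site calls at E[ω] > 1.
* **Gene structure** — intron positions/phases from gene models, and
  structural detection of intron retention between paralogs.
* **Expression** — log10 FPKM matrices with optional per-gene scaling,
  and qPCR relative expression by the Livak 2^−ΔΔCT method.
* **Synthetic data** — seeded generators with recorded ground truth
  (birth–death families, codon alignments with site-specific ω, genome
  layouts with planted duplication types, CT/FPKM tables, retained
  introns) that back the package's validation studies.

Tabular results are tibbles; fitted objects have `tidy()`, `glance()`
and `autoplot()` methods; trees are `ape::phylo`.

## Worked example

Date the published tomato/soybean VIT paralog pairs from their
synonymous divergences (bundled as a plain-text table), then classify a
planted synthetic layout:

```r
library(famevol)

tab <- read.delim(system.file("extdata", "vit_paralog_pairs.tsv",
                              package = "famevol"))
head(cbind(tab[c("gene_a", "gene_b", "ks")],
           mya = date_duplication(tab$ks)))
#>             gene_a           gene_b      ks   mya
#> 1 Solyc01g104780.2 Solyc01g104830.2 0.78947 26.32
#> 2 Solyc01g104830.2 Solyc01g104820.2 0.61314 20.44
#> 3 Solyc01g104820.2 Solyc01g104810.2 0.52749 17.58
#> 4 Solyc01g104810.2 Solyc01g104800.2 0.34785 11.60
#> 5 Solyc01g091850.2 Solyc04g008060.2 0.87754 29.25
#> 6  Glyma.08G075900  Glyma.08G076300 1.25353 41.78
```

`mya` is the age of each duplication in million years under the
λ = 1.5×10⁻⁸ clock: e.g. the oldest tomato tandem pair diverged ~26.32
Mya, the oldest soybean pair ~41.78 Mya.

```r
lay <- simulate_genome_layout(seed = 42)
classify_pair("famT1", "famT2", lay$gene_table, lay$blocks)
#> [1] "tandem"
classify_pair("famS1", "famS1_cp", lay$gene_table, lay$blocks)
#> [1] "segmental"
classify_pair("famB1", "famB2", lay$gene_table, lay$blocks)  # 5 intervening
#> [1] "transposition"
```

Reconciliation and selection in two calls each:

```r
fam  <- simulate_family(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"),
                        birth_rate = 0.3, death_rate = 0.1, seed = 7)
recon <- lca_reconcile(fam$gene_tree,
                       ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"),
                       fam$species_map)
glance(recon)           # duplications, losses, root copies
tidy(recon)             # per-branch census

cats <- discretize_omega("M8", list(p0 = 0.9, p = 0.5, q = 1.5, ws = 4), 8)
sim  <- simulate_codon_alignment(tr <- ape::rtree(12), cats, L = 300, seed = 1)
fit  <- fit_site_model(sim$alignment, tr, model = "M8")
tidy(fit)               # per-site E[omega], P(positive class), call flag
autoplot(fit)           # site-wise selection profile
```

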