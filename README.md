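# vtaxa

Virtual-taxon delimitation and large-scale distribution analysis of fungal
ITS sequences.

## What this package is for

Arbuscular mycorrhizal fungi (Glomeromycota) colonise the roots of most
land plants, but the ITS rDNA region (ITS1-5.8S-ITS2) that barcodes them is
too variable for a single similarity cutoff to define species.  A workable
species proxy is the **ITS virtual taxon (VT)**: a sequence group delimited
jointly by phylogenetic clade support and a similarity envelope.  `vtaxa`
is for researchers who want to bin whole-ITS sequences into VTs and then
ask distribution questions — how host-specific are the fungi, how endemic
are they to continents, realms, climatic zones and ecosystems, and whether
host plants mediate the apparent spatial patterns.

The delimitation rule is a two-step procedure:

1. cluster sequences into OTUs at **97% similarity** (distance 0.03,
   agglomerative, average linkage) and pick one representative per OTU;
2. build a neighbor-joining phylogeny of the representatives from
   Jukes-Cantor distances, attach nonparametric **bootstrap support** to
   every internal edge, and agglomerate representatives bottom-up along
   clades with **support >= 50%**, gating every merge on all-pairs
   representative identity **>= 90%**; representatives left without a
   supported grouping are assigned by the same 90% similarity rule.

Downstream statistics operate on VT-by-category incidence matrices:
rarefaction (with the hypergeometric closed form
`E[S_n] = Σ_v (1 − C(N−N_v, n)/C(N, n))` as cross-check), endemism and
host-specificity indices, Bray-Curtis dissimilarity
`BC(x,y) = 1 − 2Σmin(x_i,y_i)/(Σx+Σy)`, NMDS ordination minimising
Kruskal's stress-1, one-sided Mantel permutation tests, OLS regressions of
geographic range on host range and of compositional similarities, and a
recursive path model over PCA location scores with standardized direct and
indirect effects (`total = direct + indirect` exactly) and
likelihood-based fit indices (chi-square, RMSEA, TLI).

Because public-archive corpora are neither stable nor redistributable,
`vtaxa` ships a seeded generator that plants known taxa (controlled
within- and between-taxon divergence), known metadata structure
(controlled endemism fraction) and linear-Gaussian path-model tables, so
the whole chain is validated against ground truth.

## Worked example

Plant four taxa (400 bp; within-taxon identity ~0.96, between ~0.65),
delimit VTs at the default 0.03 / 50 / 0.90 thresholds, and analyse an
ecosystem incidence matrix:

```r
library(vtaxa)

cfg <- synth_config(n_taxa = 4, members = 5, seq_length = 400,
                    intra_mut = 0.02, inter_div = 0.20, seed = 1)
g   <- generate_taxa(cfg)
asn <- delimit_vts(g$records, vt_config(seed = 42))
asn
#> vt_assignment: 20 sequences in 4 VTs (0 singletons, 0 doubletons)

meta <- attach_metadata(g$truth, meta_config(endemism_fraction = 0.75, seed = 2))
m <- incidence_matrix(asn, meta, "ecosystem")
m
#>          anthropogenic forest grassland shrubland
#>   VT0001             0      0         2         3
#>   VT0002             0      5         0         0
#>   VT0003             5      0         0         0
#>   VT0004             0      0         5         0

specificity(m)$overall
#> [1] 0.75
```

The four planted taxa come back as exactly four VTs (adjusted Rand index
1.0 against the truth file).  Three of the four VTs occur in a single
ecosystem, so overall endemism is 0.75 — precisely the planted fraction
(3 of 4 taxa endemic).  Per-ecosystem specificity is the share of an
ecosystem's VTs found nowhere else: here 1.0 for anthropogenic and forest
(private VTs), 0.5 for grassland (one of its two VTs also occurs in
shrubland), 0.0 for shrubland.  A rarefaction curve of the same assignment
reaches its observed richness of 4 at full depth with a degenerate
confidence interval, matching the closed form.

`run_pipeline(out_dir, seed)` chains every stage —
simulate → delimit → incidence matrices → rarefaction / specificity /
NMDS / Mantel → path model — writing plain-text artefacts (FASTA, TSV,
JSON, Newick) that are byte-identical across runs with the same master
seed.  A thin command-line wrapper lives in `inst/scripts/run_pipeline.R`.

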