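# coopmods

Discovery of **cooperative functional module pairs** in integrated
molecular networks.

Cellular processes such as the cell cycle are driven not by isolated
protein complexes or pathways but by *pairs* of functional modules that
cooperate — exchanging signals through crosstalk interactions and
shared partner genes. `coopmods` is an R toolkit for systems biologists
who want to find such cooperating module pairs by integrating three
standard data types:

1. a gene-by-condition **expression matrix** (e.g. cell cycle time
   courses),
2. an undirected **protein–protein interaction** edge list (e.g. a
   BioGRID export), and
3. a directed **TF → target regulatory** edge list (e.g. ChIP-chip
   calls).

## The model

All three data types are fused into a **weighted physical interaction
(WPI) network**: genes are nodes; protein interactions contribute
undirected links and regulatory relationships directed links (a pair
connected by both kinds carries two links); and each gene's weight
`CopL_i` is its degree in a co-expression network built by thresholding
pairwise Pearson correlation at `|r| >= 0.683`.

Four scores drive the search, for modules `m1`, `m2` of sizes `M1`,
`M2` in a network of `N` genes:

- **Consistency score** `CT(m1, m2)`: over genes `i` outside both
  modules, compare the observed link counts `N_m1,i`, `N_m2,i` with the
  expectations `(M1/N)·NL_i`, `(M2/N)·NL_i`; genes above expectation to
  *both* modules add `+CopL_i`, genes above expectation to exactly one
  add `-CopL_i`.
- **CMRatio(i, j)**: the shared-partner ratio of two genes — the
  Jaccard index of their WPI neighbor sets.
- **Mediation score** `CoopMed(j, m) = R · max_i CMRatio(i, j) ·
  CT({i}, {t_opp})` over mediators `i` in `m`, with link reliability
  `R = 0.9`.
- **Cooperation score** `MCoop(m1, m2)`: the seed's consistency score
  plus, per non-anchor member, the better of its direct consistency
  with the opposite anchor and its mediation score.

Discovery proceeds by scoring all gene pairs, taking the pairs above
the 99th percentile of non-zero consistency scores as **seeds**,
growing each seed with a greedy **spanning algorithm** that maximizes
`MCoop`, merging modules that overlap by more than two-thirds, and
dropping pairs whose modules merged or fell below 3 genes.  For every
retained pair, **correlated genes** — candidate mediators of the
cooperation — are detected by comparing each gene's protein and
regulatory link counts into both modules against 1000 degree-preserving
rewired networks (add-one empirical p-values, alpha = 0.05), and
classified into five cooperation types (A–E) by the pattern of
significant undirected/directed evidence.  Phase-specific cooperation
is assessed with an upper-tail hypergeometric test of the correlated
genes against phase-regulated gene sets, and the results are exported
as a cooperative module network (CMN) plus per-phase regulator-mediated
relationship graphs.

## Worked example

The package ships a synthetic data generator that plants two dense
modules, three mediator genes linked to both, and a TF regulating both,
inside a sparse background — so the whole pipeline can be exercised
without external downloads:

```r
library(coopmods)

fix <- generate_fixture(fixture_config(rng_seed = 1))
net <- build_wpi_network(fix$expr, fix$ppi, fix$reg)
net
#> wpi_network: 205 genes, 303 protein links, 18 regulatory links, total weight 392

res <- discover(net)
res
#> cm_discovery: 70 merged modules, 24 retained pairs

top <- res$pairs[[1]]
cg  <- identify_correlated_genes(net, top,
                                 null_model_config(n_random = 1000,
                                                   rng_seed = 7))
head(cg[, c("gene", "coop_type", "p_ppi_m1", "p_ppi_m2")])
#>          gene coop_type   p_ppi_m1    p_ppi_m2
#> modB06 modB06         C 0.02497502 0.008991009
#> modB07 modB07         C 0.01398601 0.001998002
#> modB08 modB08         C 0.02697303 0.013986014

pair_geneset_significance(cg$gene, fix$gene_sets$cell_cycle,
                          universe = length(net$genes))
#>     G C  B b     p_value significant
#>   205 3 25 3 0.001625545        TRUE
```

The consistency score of the retained pair's seed, the shared-partner
ratio of its genes and the final cooperation score can be inspected
with `consistency_score()`, `cmratio()` and `cooperation_score()`; the
correlated genes above are type "C" mediators — genes with
significantly many protein links into *both* modules of the pair.

(Counts vary slightly with the seed; the numbers above are from
`rng_seed = 1`.)  `run_all()` executes the same stages from files and
writes TSV/GMT/GraphML artifacts; `inst/cli/coopmods.R` wraps it for
shell use:

```sh
Rscript inst/cli/coopmods.R simulate --seed 1 --out demo
Rscript inst/cli/coopmods.R run-all --expression demo/expression.tsv \
    --ppi demo/ppi.tsv --reg demo/reg.tsv --gene-sets demo/genesets.gmt \
    --out demo/results --seed 1
```

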