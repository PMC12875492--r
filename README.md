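# netcent

Normalized network centralization measures, with an axiomatic and numerical
evaluation framework.

## The problem

Centralization is the graph-level counterpart of node centrality: it asks how
strongly a network's structure is dominated by one or a few hubs. Hubs shape
communication efficiency, robustness and dynamics in systems from
protein–protein interaction networks and brain connectomes to social and
ecological networks, so a reliable *global* summary of hub dominance matters
wherever those systems are compared. Many such summaries exist — Freeman-style
centralization of degree, betweenness or closeness, degree variance, degree
entropy, the Gini coefficient of the degree sequence, hub dominance, hub
formation tendency, assortativity- and spectrum-based indices — but they rest
on different normalizations and behave very differently on the same graphs.

`netcent` is for network scientists who need to (a) compute these indices on
their own graphs and (b) decide which index to trust. It implements eleven
measures, each normalized to [0, 1] for a simple undirected graph
G = (V, E) with |V| = n, |E| = m and degrees *d&#7522;*:

| id  | measure | definition |
|-----|---------|------------|
| NDC | degree centralization | n(d_max − d̄) / ((n−1)(n−2)) |
| NBC | betweenness centralization | Σᵢ (C_B* − C_B(i)) / (n−1), C_B normalized by (n−1)(n−2)/2 |
| NCC | closeness centralization | (2n−3) Σᵢ (C_C* − C_C(i)) / ((n−1)(n−2)), C_C(i) = (n−1)/Σⱼ dist(i,j) |
| NHD | hub dominance | d_max / (n−1) |
| NHT | hub formation tendency | (Σ dᵢ² / Σ dᵢ) / ((m+1)/2) |
| NDV | degree variance | Var(d) / DV_max(n) (star for n < 7, two-hub graph for n ≥ 7) |
| NDE | degree entropy | Shannon entropy of the degree histogram / ln n |
| NGC | Gini coefficient | Σᵢⱼ \|dᵢ−dⱼ\| / (2n²d̄) over its maximum (n−2)/n |
| ABH | assortativity-based hubness | (1 − r)/2, r the degree assortativity |
| ECD | eigenvector centrality dispersion | Var(C_E) / ((n−1)/n²), C_E the L2-normalized principal eigenvector |
| NNC | natural connectivity | (λ_max − λ̄(G)) / λ_max, λ̄(G) = ln((1/n) Σ e^{λᵢ}) |

Two batteries judge them. The **axiom battery** checks six postulates — P1:
value 0 on single-node, complete and empty graphs; P2: value 1 on stars; P3:
isomorphism invariance; P4: value < 1 without a saturated node (one of degree
n−1); P5/P6: saturating a node may not raise (when a saturated node already
exists) or lower (when none exists) the value — over every labeled graph on
up to 5 nodes plus a registry of curated counterexamples. The **numerical
battery** tracks each measure over stars, rings, complete graphs and their
single-edge perturbations as n grows, and checks the expected limiting
behavior. A weighted total, `wA·S_A + wN·S_N` on the 0–6 scale, ranks the
measures; with equal weights the degree, betweenness and closeness
centralizations come out on top.

## Worked example

The 6-node graph with edge list (0,1), (0,3), (0,4), (0,5), (1,2) — a star
whose spoke to node 2 was rewired onto node 1 — is strongly centralized:

```r
library(netcent)
g <- graphFromEdgeList(c(0,1, 0,3, 0,4, 0,5, 1,2))
round(measureAll(g), 4)
#>    ABH    ECD    NBC    NCC    NDC    NDE    NDV    NGC    NHD    NHT    NNC
#> 0.8696 0.1553 0.8200 0.7313 0.7000 0.4842 0.5500 0.4500 0.8000 0.8000 0.7642
```

NBC = 0.82 says 82% of the maximum possible betweenness concentration is
present; NDC = 0.7 that the hub's degree advantage is 70% of a star's.
Saturating node 3 (connecting it to every other node) *adds* edges yet
*drops* both values — the hub is no longer unique — which is exactly the
monotonicity postulate P6 failing for these measures:

```r
y <- saturateNode(g, 3)
c(NBC = nbc(y), NDC = ndc(y))
#>  NBC  NDC
#> 0.36 0.60
```

The full evaluation pipeline:

```r
ax <- runAxiomBattery()        # ~30 s: 1099-graph corpus + registry
nm <- runNumericalBattery()    # seconds: 6 families x n up to 200
scoreTable(scoreCards(ax, nm))
#>    measure axiomatic numerical  wA  wN total
#> 1      NBC         5         6 0.5 0.5   5.5
#> 2      NCC         5         6 0.5 0.5   5.5
#> 3      NDC         5         6 0.5 0.5   5.5
#> 4      NHD         5         3 0.5 0.5   4.0
#> 5      ABH         3         4 0.5 0.5   3.5
#> ...
#> 11     ECD         2         3 0.5 0.5   2.5
```

For real (possibly disconnected) networks, `tripletReport()` applies the
three top measures on the largest connected component and reports degree
summaries alongside; `readGraph()` accepts whitespace edge lists, GML and
GraphML. A thin command-line front end over the same functions ships in
`inst/scripts/netcent-cli.R` (subcommands `measure`, `axioms`, `benchmark`,
`score`, `triplet`).

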