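# adnet

Microbial association networks for anaerobic digester communities: from
taxon-by-sample abundance tables to the network-level statistics that link
community interaction structure to digester performance.

Anaerobic digestion converts organic waste to biogas through a relay of
microbial guilds ending in methanogenic archaea. `adnet` infers potential
interactions among community members as a signed association network and
asks whether the *structure* of that network — not just the taxa in it —
tracks operating conditions and performance. The package implements:

* **Network inference**: prevalence filtering, all-pairs Spearman
  correlation with Benjamini–Hochberg FDR control (edge cutoff
  q ≤ 0.001), and a correlation threshold chosen by random matrix theory —
  the smallest cutoff at which the thresholded correlation matrix's
  nearest-neighbour eigenvalue spacings become Poisson (modular signal)
  rather than GOE (correlated noise).
* **Topology**: average connectivity 2E/N, harmonic geodesic distance
  N<sub>pairs</sub>/Σ 1/d<sub>ij</sub> (finite on disconnected graphs),
  average clustering, power-law R² of the degree distribution, Freeman
  centralizations, fast-greedy modularity Q, and Zi–Pi node roles (module
  hubs z > 2.5, P ≤ 0.62 — candidate keystone taxa).
* **Null models**: ensembles of uniform simple random graphs G(n, m)
  matched to each network's node and edge counts, per-metric z-scores and
  empirical p-values, and between-taxa edge effect sizes
  (observed − random mean)/SD with the >2 significance convention.
* **Group-specific edges**: the omission-score permutation procedure —
  recompute each edge's correlation without one phase group's samples,
  compare against 500 random same-size omissions, and flag edges whose
  correlation the group carries (|OS| < |ρ| and p < 0.05); subnetworks per
  phase group.
* **Gene significance and Mantel tests**: GS = r² of each taxon's
  abundance against environmental (ammonia, acetate, pH, VS load) and
  performance (biogas, methane, VS removal) parameters; Mantel and partial
  Mantel tests between node-connectivity distances and GS distances, for
  the whole network, each domain, and every class with ≥ 3 nodes.
* **A synthetic community generator** with planted correlation modules,
  group-specific couplings and performance-driver archaea — ground truth
  for every stage (66 samples = 2 groups × 3 digesters × 11 days,
  log-normal → multinomial counts at 11,558 reads/sample).

S4 classes (`AbundanceExperiment` extends `SummarizedExperiment`;
`CorrelationSet`, `ThresholdScan`, `AssociationNetwork`, `PlantedTruth`)
carry the data between stages; `runPipeline(config)` orchestrates the whole
chain from a single YAML/list config with per-stage seeds and
byte-reproducible artifacts.

## Worked example

```r
library(adnet)

com  <- generateCommunity(seed = 1)            # planted community + truth
meta <- generateMetadata(com$table, com$truth, seed = 2)
com$table
#> AbundanceExperiment (count): 150 taxa x 66 samples
#>   domains: Archaea=45, Bacteria=105

tab  <- prevalenceFilter(com$table, 9)         # detected in > 9 of 66 samples
cs   <- spearmanAllPairs(tab)
scan <- rmtThreshold(cs)
net  <- buildNetwork(cs, qCutoff = 0.001, rhoCutoff = chosenCutoff(scan),
                     taxonomy = taxonomyTable(tab))
net
#> AssociationNetwork: 54 nodes, 350 edges, 100.0% positive

compareToRandom(summarizeTopology(net),
                randomEnsemble(nNodes(net), nEdges(net), reps = 100, seed = 3))
#>       metric empirical randomMean randomSD      z      p direction
#> 1         GD     3.878      1.620  0.00218 1037.7 0.0198     above
#> 2      avgCC     0.923      0.244  0.01007   67.4 0.0198     above
#> 3 modularity     0.629      0.179  0.00892   50.4 0.0198     above

connectivityMantelTable(net, tab, meta, seed = 4, byClass = FALSE)[, 1:8]
#>     subset  n    rEnv  pEnv   rPerf pPerf rPartial pPartial
#> 1      All 54 -0.0340 0.752  0.7030 0.001   0.7035    0.001
#> 2  Archaea 26  0.0172 0.344  0.9344 0.001   0.9344    0.001
#> 3 Bacteria 28  0.2007 0.032 -0.0542 0.656  -0.0758    0.732
```

Reading the output: the inferred network keeps the planted modules (54
nodes ≈ the 54 module taxa; all edges positive, as planted), and its
clustering and modularity sit tens of ensemble SDs above the random
expectation — the planted community is far from a random graph. The Mantel
table reproduces the scientific contrast the analysis is designed to
detect: archaeal node connectivity correlates with performance-based gene
significance even with environmental GS controlled (r = 0.93, p = 0.001),
because the planted performance drivers are high-degree archaea, while the
bacterial subset stays at the null.

The same chain runs from one config:

```r
res <- runPipeline(defaultConfig())   # or runPipeline("run.yaml")
```

writing the network (GraphML + edge list), threshold scan, topology,
null comparison, effect sizes, edge classification, node roles and Mantel
table to `outDir` with a JSON run report.

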