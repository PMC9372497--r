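# netfuse

Fusion of multi-atlas cognitive networks by graph discriminability.

Brain atlases disagree about which regions make up a cognitive network:
the fronto-parietal network (FPN) is variously defined with 10 (AAL-based),
21 (Dosenbach-160), 25 (Power-264) or — as an "executive control
network" — 24 (Willard-499) regions. netfuse is for researchers who
want to analyse such a network without committing to one atlas. It

1. **combines** all atlas instances of one network into a combined
   network CCN = ⋃ᵢ CNᵢ after clipping each instance to a common
   anatomical boundary (frontal + parietal by default); same-coordinate
   ROIs from different atlases stay distinct, so |CCN| = Σ|CNᵢ|;
2. builds the condition × subject stack of functional-connectivity
   matrices (Pearson r with two-sided t-distribution p-values) and
   thresholds each slice into a binary graph by Benjamini–Hochberg FDR
   control over the edge p-values (q = 0.05, positive edges by default);
3. scores every instance by the discriminability of its graph property
   across conditions — degree centrality deg(v)/(n−1) by default,
   evaluated per (condition, subject) cell and compared with a paired
   t test (two conditions) or one-way ANOVA (more) — and **selects**
   the instance with minimum p-value as the *main* network;
4. **ranks** the remaining ROIs ascending by the discriminability of
   their nodal degree centrality in the full CCN graph, and
5. **fuses**: evaluates main ∪ prefix for every prefix length
   0..|SuppROIs| of the priority list and keeps the prefix with the
   minimum p-value, FCN = MCN ∪ Sub(SuppROIs, fusedIndex).

A planted-subnetwork Gaussian generator (`plantedDesign()` /
`generatePlanted()`) emulates the intended study design (2 conditions ×
21 subjects × 72 ROIs) so the entire pipeline is testable and
calibratable without fMRI recordings.

## Worked example

A reduced-scale synthetic run (2 conditions × 8 subjects × 24 ROIs,
t = 60) with a condition effect planted in the second mock instance
plus one ROI of each other instance:

```r
library(netfuse)
design <- plantedDesign(nSubjects = 8L, nRois = 24L, nTime = 60L, seed = 3L)
sim    <- generatePlanted(design)
ccn    <- combineInstances(sim$instances)
stack  <- buildStack(sim$series, ccn)
sel    <- selectMain(stack, sim$instances)
sel
#> SelectionResult: main instance 'atlasB' (7 ROIs), 17 supplementary ROIs
#>   instance p-values:
#>    atlasA    atlasB    atlasC    atlasD
#> 3.506e-01 7.257e-05 3.548e-01 2.133e-01
fus <- fuseNetworks(stack, sel)
fus
#> FusionResult: 11 ROIs (fusedIndex = 4), p = 1.63e-05
str(evaluateRecovery(sel, fus, sim))
#> List of 5
#>  $ precisionFused       : num 0.909
#>  $ recallFused          : num 1
#>  $ topkRecall           : num 1
#>  $ k                    : int 3
#>  $ mainIsPlantedInstance: logi TRUE
```

Reading the output: the planted instance `atlasB` is the only candidate
whose degree centrality separates the two conditions (p = 7.3e-05 vs
p > 0.2 for the others), so it becomes the main network. The greedy
search absorbs the 4 highest-priority supplementary ROIs (fusedIndex = 4),
improving the discriminability p-value to 1.6e-05 — never worse than
the main network alone, since the empty prefix is part of the search —
and the fused 11-ROI network contains all 10 planted ROIs (recall 1.0).

`fusionReport(sel, fus, stack)` returns the machine-readable run
report (instance p-values, priority table with atlas/lobe provenance,
p-value trace, composition breakdowns); `writeFusionReport()` and
`writeReportTables()` serialize it as JSON and TSV.

A thin command-line interface wraps the same functions:

```sh
netfuse simulate    --out sim/ --seed 5 --n-subjects 8 --n-rois 24 --t 60
netfuse report      --atlas-table sim/atlas.tsv \
                    --timeseries-dir sim/timeseries --out results/
```

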