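# netcc — control centrality of gene-regulatory networks

`netcc` asks a network-medicine question: *which pathways could, in
principle, steer a tissue's regulatory program?* Given expression data from
a tissue of interest (the motivating application is pancreatic islets in
type 2 diabetes), the package

1. infers a directed gene-regulatory network (GRN) from expression profiles
   — MRMR parent selection by mutual information, collider ("v-structure")
   causality scoring, and weighted combination with a prior regulatory
   network — and extends it with kinase and signaling edges (EGRN);
2. computes every gene's **control centrality**: for a directed network
   seen as a structured linear system, C_c(i) is the generic dimension of
   the subspace controllable by driving gene *i* alone — equivalently the
   generic rank of the Kalman matrix [b, Ab, …, A^(N−1)b] with b = e_i, or
   one plus the most edges in any vertex-disjoint union of one directed
   path from *i* ("stem") and cycles inside *i*'s reachable set;
3. flags **HiCc pathways**, whose members' C_c distribution is
   stochastically greater than the rest of the network (one-sided
   Mann–Whitney, p < 0.05, cancer-named pathways excluded);
4. contrasts disease-gene enrichment between HiCc and non-HiCc pathways
   (two-tailed Fisher exact test);
5. maps **cis-eQTLs** for HiCc-pathway genes (OLS with age and sex
   covariates, 250 kb windows, joint BH-FDR, permutation p-values); and
6. connects the eQTL genes inside an interaction network with the
   **Klein–Ravi** node-weighted Steiner tree approximation.

Control centrality is computed exactly: randomized Krylov rank over
GF(2^31−1) (Rcpp), cross-checked in the test suite against an independent
pure-R finite-field oracle and a brute-force stem-cycle enumeration.
Because the motivating cohort data are restricted, the package ships a
first-class synthetic-data generator (layered regulatory network,
linear-Gaussian structural-equation expression model, planted controller
pathway, planted cis effects) so every stage has a ground-truth recovery
test.

## Worked example

```r
library(netcc)

gen  <- generateRegulatoryNetwork(nGenes = 300, nLayers = 5, seed = 7)
cc   <- controlCentralityAll(gen$network, seed = 7)
cc
#> CcResult over 300 nodes; mean Cc = 19.363 ; max Cc = 48

sets <- generatePathways(gen$truth, nDecoys = 20, seed = 7)
h    <- hiccPathways(cc, sets)
h[h$pathway == "CONTROLLER", ]
#>      pathway n_in_network      U            p mean_cc_in tested is_hicc
#> 1 CONTROLLER           15 3664.5 1.462321e-06   38.66667   TRUE    TRUE
```

The planted controller pathway (15 of the layer-1 regulators) holds a mean
C_c of 38.7 against a network mean of 19.4 and is flagged HiCc at
p ≈ 1.5e-6; decoy pathways are flagged at roughly the nominal 5% rate, and
the `CANCER_DECOY` set is removed by the name filter before testing. The
enrichment contrast step reproduces printed contingency-table statistics
exactly — e.g. a 24/66 vs 26/120 enrichment split gives a two-tailed Fisher
p of 0.038:

```r
res <- hiccEnrichmentContrast(
  c(rep(TRUE, 66), rep(FALSE, 120)),
  c(rep(TRUE, 24), rep(FALSE, 42), rep(TRUE, 26), rep(FALSE, 94)))
round(res$p, 3)
#> [1] 0.038
```

An end-to-end run over a written input bundle:

```r
d <- tempfile()
writeSyntheticBundle(d, seed = 1)
cfg <- pipelineConfig(
  paths = list(expression = file.path(d, "expression.tsv"),
               covariates = file.path(d, "covariates.tsv"),
               prior = file.path(d, "prior_edges.tsv"),
               kinase = file.path(d, "kinase_edges.tsv"),
               signaling = file.path(d, "signaling_edges.tsv"),
               pathways = file.path(d, "pathways.gmt"),
               gold = file.path(d, "gold_genes.txt"),
               genotypes = file.path(d, "genotypes.tsv"),
               annotation = file.path(d, "gene_annotation.bed")),
  outDir = file.path(d, "out"), seed = 1)
manifest <- runPipeline(cfg)
```

Each stage writes a TSV under `outDir` and `manifest.json` records
parameters, per-stage seeds and row counts; rerunning with the same seed
reproduces every table byte for byte. A thin shell wrapper with
`simulate` / `cc` / `hicc` / `steiner` / `run-all` subcommands ships in
`inst/scripts/netcc.R`.

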