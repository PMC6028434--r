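---
title: "Finding high-control pathways in regulatory networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding high-control pathways in regulatory networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcc)
```

## The scientific question

Complex diseases such as type 2 diabetes rarely trace back to a single gene;
they emerge from perturbations that propagate through a tissue-specific
regulatory network. If a group of genes sits high in the regulatory
hierarchy — if driving those genes could, in principle, steer much of the
rest of the network — then the pathways they belong to are natural candidates
for controlling disease-relevant downstream programs. `netcc` implements a
complete pipeline around that idea: infer a directed gene-regulatory network
from expression data, quantify each gene's *control centrality*, rank
pathways by the control centrality of their members, test whether
high-control pathways concentrate known disease genes, map cis-eQTLs for
their genes, and connect the eQTL genes inside an interaction network.

## Control centrality

For a directed network interpreted as a structured linear system
$\dot{x} = Ax + b u$, with $A$ carrying a free (generic) weight on every
edge and $b = e_i$ attaching a single input to gene $i$, the control
centrality $C_c(i)$ is the generic dimension of the controllable subspace:
the generic rank of the Kalman matrix $[b, Ab, \dots, A^{N-1}b]$.
Combinatorially, $C_c(i)$ equals one plus the largest number of edges over
vertex-disjoint unions of one directed path starting at $i$ (a *stem*) and
directed cycles inside the set reachable from $i$. A chain head controls
the whole chain ($C_c = N$), a chain tail only itself ($C_c = 1$), every
node of a $k$-cycle controls the full cycle ($C_c = k$), and the hub of an
out-star controls only two dimensions, because all leaves receive the same
mixed signal.

`controlCentrality()` computes the rank exactly over the finite field
GF($p$), $p = 2^{31}-1$, with random edge weights: incremental Gaussian
elimination adds one Krylov vector at a time and stops as soon as a vector
adds no rank (the Krylov space is then $A$-invariant, so the rank is
final). Random evaluation of the generic rank can only fail by landing on a
root of a nonzero polynomial of degree at most $N$; by the Schwartz–Zippel
bound that happens with probability at most $N/p$ per draw, and the
default of 3 independent draws brings the per-call failure probability
below $10^{-6}$ for networks up to $10^4$ nodes. There is no floating-point
rank tolerance anywhere.

Two independent oracles guard the implementation. `krylovRankOracle()` is a
second, pure-R implementation of the same definition with a different prime
(46337, the largest prime whose square is below $2^{31}$, so plain double
arithmetic stays exact) and R's own RNG. `stemCycleCc()` is a brute-force
bitmask dynamic program over the combinatorial characterization: it
enumerates simple cycles, computes the best disjoint-cycle cover of every
vertex subset, and maximizes path-plus-cover edge counts. The test suite
requires exact three-way agreement across hundreds of random digraphs.

## Network inference

The GRN stage mirrors a prior-informed mutual-information pipeline:

* **Feature selection** keeps the `nVariance = 2000` most variable genes,
  adds supplied GWAS genes, and fills to `nTotal = 2500` with the top
  differentially expressed genes (nominal $p < 0.05$ in the disease or
  HbA1c contrast). Differential ranking uses a moderated $t$ with
  empirical-Bayes variance shrinkage — prior df 4, prior variance equal to
  the mean gene-wise variance. This deliberately replaces a B-statistic
  ranking: only the ordering matters downstream, any statistic monotone in
  evidence preserves the pipeline, and this one has a closed form that is
  easy to test (the suite checks its size under permuted labels and its
  rank agreement with limma's moderated $t$).
* **MRMR parent selection** discretizes profiles into 3 equal-frequency
  bins (ties share a bin via average ranks, so constant genes carry zero
  information) and greedily picks up to `maxParents = 3` parents per
  target, maximizing MI with the target minus the mean MI with the parents
  already chosen. All ties break by gene id, making inference independent
  of input order.
* **Causality scoring** rates each selected parent by collider evidence:
  for each co-parent $q$, $[\mathrm{CMI}(p; q \mid t) - \mathrm{MI}(p;q)]$
  normalized by $\min(H(p), H(q))$, averaged and clipped to $[-1, 1]$.
  Conditioning on a common child induces dependence between independent
  parents, so a positive score anchors the edge toward the target. The
  exact functional form is this package's concrete instantiation of a
  v-structure score; the tests pin down its sign behavior on planted
  colliders and chains rather than its numeric value.
* **Prior combination**: combined score
  $= 0.75 \times \text{causality} + 0.25 \times \text{prior indicator}$,
  retaining edges with score $> 0$. A prior-only edge survives at 0.25; a
  data edge needs non-negative causality evidence unless the prior backs
  it.

When a prior is supplied, candidate parents are restricted to genes with
outgoing prior edges. This keeps the search biased toward regulators, which
matters because mutual information is symmetric: in a deep hierarchy a
target's *children* typically carry at least as much MI as its parent, and
no marginal-dependence method can orient that edge. That is also why the
planted-parent recovery experiment in the acceptance suite uses a two-layer
regulator–target design — it isolates the parent-selection step the
criterion is about, rather than asking MRMR to do orientation work that
belongs to the prior and the causality score.

## Pathway ranking and enrichment contrasts

`hiccPathways()` compares the $C_c$ distribution of each pathway's network
genes against all other network genes with a one-sided (greater)
Mann–Whitney test; pathways with $p < 0.05$ are flagged HiCc. Pathways
with fewer than 5 network genes are reported untested — tiny overlaps make
a rank-sum degenerate — and pathways whose names match a configurable
cancer keyword list (`cancer`, `carcinoma`, `leukemia`, `melanoma`,
`glioma`) are excluded to avoid the annotation bias toward heavily studied
cancer pathways. Disease-gene enrichment per pathway is a one-sided Fisher
exact test against the network gene universe (the paper-scale analysis
does not state its universe; using the analyzed network's genes makes the
contrast self-contained), and the HiCc versus non-HiCc contrast is a
two-tailed Fisher test on the 2×2 enrichment table. The ensemble
comparison (`ccVsRandomEnsemble()`) and this contrast are two-sided; only
the HiCc flag itself is one-sided, matching the directional "higher
control" hypothesis.

A caution on the randomized-ensemble comparison
(`ccVsRandomEnsemble()`): the *direction* of the mean-Cc shift under
degree-preserving rewiring is a property of the particular network, not of
hierarchies in general. Rewiring a layered network tends to create cycles
and long-range reach, which can *raise* the mean control centrality of the
randomized ensemble above the layered original. The function therefore
reports the per-randomization rank-sum p-values and means and leaves the
interpretation of direction to the analyst; on the synthetic generator the
distributions separate decisively, but the randomized side is the larger
one.

Two further method properties surfaced by the synthetic experiments and
worth knowing before interpreting real runs. First, under a linear SEM the
*upstream* regulators are the lowest-variance genes (downstream genes
accumulate propagated variance), so a variance-based feature filter can
remove exactly the controller genes a control-centrality analysis is
after; the end-to-end recovery experiment therefore feeds the full gene
panel to inference and exercises the variance filter separately. Second,
the hierarchy signal survives network inference only to the extent that
edges are correctly *oriented*: with a partial prior, symmetric-MI parent
selection adds enough reversed edges to weld the top layers into one large
cycle component and equalize their control centralities. With a
comprehensive directional prior the planted controller pathway is
recovered decisively (rank-sum p below 0.005 across seeds).

## cis-eQTL mapping

`fitEqtl()` fits ordinary least squares
`expression ~ intercept + dosage + age + sex` for every SNP within 250 kb
(inclusive) of a gene body, reporting the dosage $t$ statistic, its
two-sided $p$, and Benjamini–Hochberg $q$ computed jointly across all
tested cis pairs (the convention of matrix-based eQTL tools; a per-gene
alternative would change the meaning of the 1% FDR threshold).
`permutationP()` residualizes expression and dosage on the covariates
(Frisch–Waugh), permutes the residualized expression, and reports
$(1 + \#\{|t^\ast| \ge |t|\})/(n_{\mathrm{perm}}+1)$. Under the default
*legacy floor* convention a pair that beats every permutation reports
$1/n_{\mathrm{perm}}$ — the convention behind published floors of
$10^{-4}$ at 10,000 permutations; disable `legacyPermFloor` for the
strictly add-one estimate.

## Steiner connection

`kleinRaviSteiner()` implements the Klein–Ravi greedy approximation of the
node-weighted Steiner tree: terminal trees are repeatedly merged through
the node minimizing (node cost + node-cost shortest-path distances to
$k \ge 2$ trees)/$k$. Nodes already in the solution cost zero, so directly
interacting terminals merge first for free; degree-1 non-terminals are
pruned at the end; all ties break by node id. Node costs default to 1 —
the published analysis names no weighting scheme, and unit costs make the
objective "fewest linker genes". The guarantee is the classical
$2\ln k$ factor; the tests verify it against an exhaustive subset-search
optimum on graphs small enough to solve exactly.

## The synthetic-data generator

Because the original islet cohort is restricted, every stage is exercised
on generated data with known ground truth:

* `generateRegulatoryNetwork()` — 300 genes in 5 layers by default, mean
  forward out-degree 2, 10% feedback edges. Layer-1 genes are the planted
  controller set; a fixed 30% of the deepest layer is the disease gene
  set.
* `simulateExpression()` — linear-Gaussian SEM
  $x = (I - W)^{-1}\varepsilon$ with planted edge weight 0.8 and noise sd
  1 (rescaled if the spectral radius reaches 1). Chosen over nonlinear
  kinetics because its covariance is closed-form — the test suite checks
  $\mathrm{cor}(A,B) = 0.8/\sqrt{1.64}$ for an isolated edge — while still
  giving MRMR a nontrivial redundancy structure. 15% of samples are cases
  (mirroring a 9/63 cohort imbalance); cases shift the disease genes by
  one noise sd; HbA1c tracks disease status with sd 0.5 around means 5.5
  and 7.2.
* `generateGenotypes()` — genes placed 1 Mb apart (10 kb bodies) so 250 kb
  cis windows never overlap; Binomial(2, MAF) dosages with MAF uniform in
  [0.1, 0.4]; planted SNPs sit inside their gene's window and add
  $\beta \times$ dosage to its expression.

What the generator does *not* emulate: linkage disequilibrium, array probe
effects, nonlinear regulation, measurement batch structure, and realistic
pathway-size distributions. Passing recovery tests therefore demonstrate
that the machinery is correct and calibrated under the stated model, not
that the biological conclusions of any particular cohort transfer.

## Numerical and design choices worth knowing

* Degree-preserving randomization uses directed double edge swaps (10
  attempted swaps per edge by default; the rewiring depth is a convention,
  not a published constant), rejecting self-loops and duplicate edges.
* Connectivity, shortest paths and clustering are computed on the
  undirected projection; the "largest connected component" is the weak
  one. This matches the small-world metrics reported for such networks
  ("average number of neighbors"), and is a documented convention rather
  than an inference about directed path lengths.
* Duplicate edges collapse to one (simple digraph); the controllability
  theory assumes simple structure. Merged networks union provenance tags
  instead.
* Rank-sum tests use the normal approximation with tie correction except
  where the smaller group has at most 8 untied values, where the exact
  distribution is used; the suite validates both regimes against explicit
  enumeration.
* The pipeline derives per-stage seeds by hashing stage names into the
  global seed (`stageSeed()`), so inserting a stage never shifts another
  stage's random stream, and a manifest records every seed, parameter and
  row count for reproduction.
* Problem sizes in the test and acceptance suites (300-gene networks, 50
  simulation replicates, 2000 null eQTL pairs, 10k permutations for the
  floor check) were chosen as the smallest sizes at which the calibration
  bands are statistically meaningful.

## Worked example

```{r example, eval = FALSE}
gen <- generateRegulatoryNetwork(nGenes = 300, nLayers = 5, seed = 7)
cc <- controlCentralityAll(gen$network, seed = 7)
sets <- generatePathways(gen$truth, nDecoys = 20, seed = 7)
head(hiccPathways(cc, sets))
```

The planted `CONTROLLER` pathway is flagged HiCc (its members, the layer-1
regulators, hold the largest control centralities), decoy pathways are
flagged at roughly the nominal 5% rate, and the `CANCER_DECOY` set never
reaches the table because the name filter removes it first.

## Known limitations

* Control centrality is a *structural* quantity: it assumes independent
  generic weights and says nothing about control energy or about
  weighted dynamics with constrained parameters.
* MI-based inference cannot orient edges without the prior or collider
  evidence; inferred networks inherit the prior's biases.
* The exhaustive Steiner and stem-cycle oracles are exponential and
  guarded (22 reachable vertices for the stem-cycle DP); they exist for
  validation, not production use.
* `fitEqtl()` assumes hard-call or imputed dosages on matched samples; no
  genotype QC, imputation, trans analysis or conditional analysis is
  provided.
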