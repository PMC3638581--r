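---
title: "Methods: network pharmacology of multi-ingredient herbal formulae"
author: "herbnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network pharmacology of multi-ingredient herbal formulae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
```

# The problem

A multi-herb formula contains hundreds of small-molecule ingredients, each
binding weakly to many proteins. The working hypothesis of network
pharmacology is that the therapeutic unit is not a single protein but a
*network target*: the disease-specific molecular network, which the
formula's ingredients perturb at many points simultaneously. `herbnet`
implements the computational workflow this view requires: per-ingredient
target-profile prediction, clustering of ingredients by those profiles,
construction of a disease-specific network and per-herb target networks,
functional enrichment, and mechanism-based detection of synergistic
ingredient pairs.

# Target-profile prediction by similarity-closeness concordance

For a query ingredient $q$ and an ordered panel of $n$ reference drugs
with known targets, two vectors are built over the same reference order:

* the **drug-space vector** $s(q) \in [0,1]^n$, where
  $s_i = T(q, d_i)$ is the Tanimoto coefficient
  $|a \wedge b| / |a \vee b|$ between hashed path fingerprints
  (OpenBabel FP2, 1024 bits, by default; FP3/FP4/MACCS are accepted);
* the **target-space vector** $\phi(g) \in \mathbb{R}_{\ge 0}^n$ for each
  candidate gene $g$, where
  $\phi_i = \sum_{t \in T_i} e^{-d(g,t)^2}$ sums a Gaussian kernel of the
  unweighted shortest-path distance from $g$ to each target $t$ of
  reference drug $i$ in the protein-interaction network.

The likelihood score of the pair $(q, g)$ is the Pearson correlation
$\mathrm{cor}(s(q), \phi(g))$: under the "like attracts like" assumption,
genes network-close to the targets of drugs structurally similar to $q$
are likely targets of $q$. The top $k$ genes (default $k = 100$, the
published operating point) form the ingredient's target profile.

Conventions that make results reproducible bit-for-bit:

* **Kernel.** $e^{-d^2}$ by default ($e^{-d}$ as an option). Unreachable
  gene-target pairs and genes absent from the network contribute 0
  (disconnection is absence of evidence, not a capped distance);
  $d(g,g)=0$ contributes 1 even for isolated genes.
* **Degenerate scores.** If either vector has zero variance the
  correlation is undefined; the score is set to exactly 0 and flagged, and
  flagged genes sort after all scored genes. No evidence must not
  masquerade as negative evidence, and must not enter profiles ahead of
  scored genes.
* **Ties.** Ranking is by decreasing score, then lexicographic gene
  symbol, so profiles are identical across runs and input orders.
* **All-zero fingerprints.** Two featureless fingerprints get similarity 1
  with a warning: 0/0 is avoided while degenerate inputs stay visible.
* **Correlation type.** Pearson by default, Spearman as an option.

# PCA of ingredient profiles

Profiles are assembled into an ingredient-by-gene matrix; the default
encoding is binary top-$k$ membership (profiles are gene sets; a score
encoding is available). The matrix is column-mean-centered but not
variance-scaled — the transform is a plain linear projection
$z_i = \sum_j \omega_{ij} x_j$ and binary columns are already on one
scale. Loadings satisfy $\sum_j \omega_{ij}^2 = 1$ and
$\sum_j \omega_{ij}\omega_{kj} = 0$ ($i \ne k$) by construction of the
singular value decomposition; the package verifies both to $10^{-8}$ in
its tests. Each loading's sign is fixed so its largest-magnitude element
is positive, removing the backend-dependent sign ambiguity. Ingredient
groups are k-means clusters (default $k = 3$, mirroring the three
chemical classes — saponins, glycosides, alkaloids — of the worked
example; a parameter, not a claim) on the first two component scores,
reported against user labels as a contingency table with purity. When
$k$ equals the number of distinct points, each point is its own cluster
analytically (base `kmeans` rejects that boundary case).

# Disease-specific and herb target networks

Seed genes carry one or more provenance labels — *known* disease genes,
*predicted* disease genes, and *drug targets* of approved therapies — and
are expanded by exactly one hop ("first interaction partners"; deeper
expansion is a config option, not the default) to the disease-specific
network, taking all induced edges. Seeds absent from the interaction
network are retained as isolated nodes so their provenance survives into
every report. A herb's target network is the induced subgraph on the
union of its ingredients' profile genes intersected with the
disease-network nodes; because the published construction is ambiguous
about paths through non-target genes, a `bridge = TRUE` option adds
connector nodes adjacent to two or more mapped targets, and the default
(no bridging) is documented as such. Mapped targets on a user-supplied
adverse-gene list are flagged as off-targets, and other herbs hitting the
same gene are reported as potential counter-acting herbs.

# Gene-set enrichment

Over-representation uses the one-sided Fisher test (upper hypergeometric
tail, the DAVID convention; two-sided tests are deliberately not offered)
against GMT collections, with Benjamini-Hochberg adjustment across terms
and the reporting rule *adjusted p < 0.05*. The default background is the
node set of the supplied interaction network. The category labels of the
worked example (angiogenesis, inflammatory response, immune response,
NF-kB activity) travel in the GMT description field as
`category|term name`. Published enrichment p-values from the DAVID
service depend on its internal annotation snapshot and are therefore not
reproduction targets; the machinery here is calibrated instead — on
random queries the family-wise rate of any adjusted p below 0.05 stays at
the nominal level (verified by simulation in the test suite).

# Synergy mechanisms on a curated pathway model

The synergy track runs on a directed signaling model whose edges carry
pathway labels and whose self-reinforcing complexes are declared as
feedback loops. Two conventions anchor all four mechanism predicates:

* a node is a *member* of pathway $L$ iff it has an outgoing $L$-labelled
  edge — pathway members regulate something downstream, while a node with
  only incoming $L$ edges is an *output regulated by* $L$ (this matches
  the worked example's reading of "the AKT1-SRC-PTK2 pathway that
  regulates the NFKB1": AKT1, SRC, PTK2 are members, NFKB1 the output);
* downstream reach follows edges of a single label, so crossing into a
  differently-labelled edge is what constitutes cross-talk.

For ingredients with target sets $A$ and $B$:

1. **same_pathway** — distinct targets that are members of one common
   pathway.
2. **crosstalk_convergence** — distinct targets on differently-labelled
   pathways whose label-restricted reaches share a node.
3. **compensation** — distinct targets on differently-labelled pathways
   that feed *distinct members* of one declared feedback loop: two
   compensatory supply arms of the same self-reinforcing system are
   blocked.
4. **feedback_loop** — the ingredients directly hit distinct members of a
   declared loop *and* a compensation pattern on the same loop holds for
   non-loop targets.

The conjunction in predicate 4 is the central design decision of this
module. Direct engagement of two complex subunits is not treated as
synergistic by itself: a transcription-factor complex fed by intact
upstream pathways can regenerate, so the mechanism additionally requires
the upstream arms to be disabled. Formally this is also what makes the
taxonomy identifiable — in the worked example two ingredients (Kurarinone
and Sinomenine) both inhibit NFKB1 while Diosgenin inhibits NFKB2, and
only the pair whose remaining targets (PTK2 via the NF-kB-labelled edge,
RAF1 via the TNF route) independently feed the complex is reported as a
feedback-loop synergy. A purely loop-membership-based predicate cannot
make that distinction.

A pair's edge weight is the number of *distinct mechanism kinds* (1-4),
not the raw record count, so evidence permutations are not double-counted;
pairs with both feedback and compensation evidence are exactly the
heavier edges. Detection is symmetric in the two ingredients, monotone
under target-set growth, and is tested against exhaustive enumeration of
all (target pair, label pair, node) triples on small random models.

## The packaged worked example

`qly_fixture()` ships a transcription of the published
rheumatoid-arthritis example for the four-herb formula Qing-Luo-Yin: five
major ingredients (Matrine and Kurarinone from Ku-Shen, Sinomenine from
Qing-Feng-Teng, Berberine from Huang-Bai, Diosgenin from Bi-Xie), the
IL1B/TNF/VEGFA-to-NF-kB signaling model with the NFKB1-NFKB2-RELA-RELB
complex declared as the feedback loop, and PTGS1 as the adverse-effect
gene. Transcription choices: Kurarinone is recorded with all three
reported targets (AKT1, PTK2, NFKB1, mentioned in separate sentences of
the source text); Diosgenin with NFKB2 and RAF1 (the complex member and
pathway target attributed to it in the pairwise mechanism descriptions);
the edge PTK2 -> NFKB1 carries the NF-kB label rather than the IL1B label
because the source describes the kinase cascade as a pathway *regulating*
NFKB1. On this model the package reports exactly the six published
synergistic pairs among the ten candidate pairs, with
Kurarinone-Diosgenin as the only double-mechanism (feedback +
compensation) edge:

```{r qly}
fx <- qly_fixture()
build_synergy_network(fx$major_targets, fx$pathway_model)
```

The fixture's miniature interaction network, seed lists and annotation
collection are synthetic stand-ins shaped around the published gene names
(the upstream databases are not redistributable); the ingredient targets
and the pathway model are the transcribed content.

# The synthetic-data generator

`generate_space()` materializes the statistical structure the concordance
method assumes, as a controlled world with known ground truth:

* the interaction network is a stochastic block model — dense
  Bernoulli(0.15) edges within each module, 200 uniformly random edges
  between modules;
* reference drugs come in structural families, one per module: each
  family has a random 256-bit template (density 0.3) and each drug flips
  template bits independently at rate 0.1;
* each drug's 10 targets are drawn from its family's module, so
  structural similarity tracks target-module proximity by construction.

The defaults — 5 families x 10 drugs, 80-gene modules (a 50-drug
reference panel over a 400-gene network) — are the panel size at which
the concordance correlation is stable while a full validation run stays
in seconds; they are the conditions used throughout the tests. A query
from family $f$ (template perturbed at the same noise rate) has that
module's 80 genes as planted truth, giving the analytic random baseline
$k \cdot m / N$ for precision-at-$k$ (with defaults,
$100 \cdot 80/400 = 20$ planted genes expected in a random top-100, i.e.
precision 0.2). Recovery well above this baseline, its decline as
fingerprint noise grows, and reproducibility under a fixed seed are all
asserted in the tests; all randomness flows from the single integer seed.

What the generator deliberately does **not** emulate: real chemistry (the
fingerprints are abstract bit sets; real structures enter through the
SMILES/SDF loader), the heavy-tailed degree distribution and study bias
of curated interactomes, overlapping target modules, and
annotation-driven correlation between terms and network position. Passing
tests therefore demonstrate the correctness and calibration of the
machinery under the method's own assumptions, not the accuracy of target
prediction on real compounds — the published real-data figures (235
ingredients, herb-level profile counts, DAVID p-values) depend on
proprietary database snapshots and are out of scope by design.

# Validation problem sizes

The test suite validates each quantity against an independent oracle:
Pearson concordance against the closed-form sum formula; breadth-first
closeness against Floyd-Warshall all-pairs distances on graphs of up to
20 nodes; Fisher p-values against exhaustive hypergeometric enumeration
on backgrounds of up to 50 genes; one-hop expansion against a brute-force
adjacency union; mechanism detection against exhaustive triple
enumeration on models of up to 10 nodes — all at $10^{-12}$ or exact.
Monte-Carlo checks use 20 seeds for planted-target recovery and 200
simulations for null enrichment calibration.

# Known limitations

* The concordance score has no per-gene significance (no permutation
  p-values); profile membership is a rank cutoff, not a test.
* The closeness functional form and fingerprint are the documented
  defaults of this implementation; alternative kernels or descriptors can
  change profile composition, which is why both are configuration
  options.
* The synergy taxonomy is a topological reading of four worked mechanism
  descriptions; it is falsifiable (each predicate is independently
  testable) but not exhaustive — dose-response synergy (Loewe, Bliss) is
  intentionally absent, as no concentrations exist in this framework.
* Enrichment treats gene sets as flat (no ontology-graph propagation).
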