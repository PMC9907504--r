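---
title: "Methods: mycobiont isolation, BGC families and diversity statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mycobiont isolation, BGC families and diversity statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lichenbgc)
library(dplyr)
```

This vignette records the models behind `lichenbgc`, the assumptions they
make, the tunable parameters that matter, and the design decisions taken
where the methodology left genuine choices open. Nothing here reports an
empirical number that the test suite or `scripts/acceptance.R` does not
itself recompute.

## 1. The problem

A lichen thallus is a symbiosis: sequencing it yields a metagenome in
which the fungal mycobiont is mixed with a green-algal photobiont and
bacteria. On a GC-versus-coverage "blob" plot the mycobiont typically
forms a linear cloud between roughly 30% and 50% GC at a consistent read
depth, with an AT-rich low-GC tail of repeat-derived contigs. Those
AT-rich contigs rarely hit sequence databases, so taxonomy alone cannot
recover them; composition/coverage clustering alone, conversely, tends to
split the cloud into several bins. The pipeline combines both: taxonomy
anchors the main bin, and an explicit merge rule recovers the tail.

Downstream, the isolated genomes are compared through their secondary
metabolite gene clusters: clusters are grouped into families by a
composite similarity, family presence–absence profiles are analysed with
beta-diversity and permutation statistics, and candidate anthraquinone
families are screened for a conserved four-gene architecture.

## 2. The synthetic-data generators

All tests run against simulators with known truth; their defaults are the
study conditions.

**Metagenome.** `default_community()` encodes: mycobiont core 5 Mbp at
GC 0.50 ± 0.02 and depth 60×; an AT-rich tail of 1.25 Mbp (20% of the
mycobiont) at GC 0.33, same depth, with `label_miss_prob = 0.8` (80% of
tail contigs absent from the taxonomy table); a photobiont (3 Mbp,
GC 0.60, 15×); and two bacteria at distinct GC/coverage corners (240× and
7×). Sizes are ~tenfold below real assemblies so a full run takes seconds;
the geometry of the blob plot — which is what the pipeline consumes — is
preserved. Contig lengths are geometric (mean 20 kbp, floor 1 kbp),
per-contig depth lognormal around the organism mean (heavy-tailed and
strictly positive, like mapped read depth).

Sequences follow a constrained order-2 Markov chain: each base is first
assigned strong (G/C) or weak (A/T) by an independent Bernoulli draw with
the contig's GC target — so realized GC is exactly targeted in
expectation — and the choice *within* {G,C} or {A,T} depends on the
strong/weak classes of the two preceding bases through eight
organism-specific probabilities derived from `markov_seed`. This factored
parameterization vectorizes (a 13 Mbp community simulates in seconds) and
gives every organism a tetranucleotide signature beyond GC, which is what
makes composition clustering testable. It does *not* emulate codon
structure, repeats, or horizontal transfer; conclusions about those
features cannot be drawn from these simulations.

**BGC panels.** `simulate_bgc_panel()` derives genome-specific cluster
instances from family archetypes by per-gene loss, adjacent-transposition
domain shuffling, and per-residue substitution (defaults 0.1 each).
"Shuffling" is implemented as swapping a domain with its right neighbour:
it perturbs the adjacency index while leaving domain content intact,
which separates the three distance components in tests. Reference
(database-like) archetypes are emitted unmutated with compound
annotations; in `anthraquinone_archetypes()` they are diverged copies of
the lichen archetype minus the ABC-transporter, so reference-family
flagging has a positive case by construction.

**Trees and profiles.** `simulate_tree_pa()` grows a Yule tree
(`ape::rphylo`, birth 1) and evolves each family as a two-state Markov
process with gain/loss rates per unit branch length, root state from the
stationary distribution. Slow rates (≈0.3) preserve phylogenetic signal;
only *very* fast rates erase it. One subtlety worth recording: at
moderate rates (e.g. 5) sibling tips on short terminal branches remain
correlated (the transition probability over a branch of length *t* is
bounded by 1 − e^(−(g+l)t)), so the Mantel correlation does not vanish —
it is genuine residual signal, not noise. The decorrelation property is
therefore tested at rate 50.

## 3. Mycobiont isolation

Fragments of 10 kbp (terminal remainders appended to the previous window,
so no undersized fragment dilutes a k-mer profile; 0-based half-open
coordinates throughout) are described by 136 canonical tetranucleotide
frequencies (+1 pseudocount) plus the parent contig's standardized
log10(coverage + 1). PCA reduces this to the components covering ≥ 90% of
variance, capped at 20 (a homogeneous cloud needs ~100 components to
reach 90%, and mixture fits in that dimension are degenerate; the cap is
the package's choice). Gaussian mixtures with k = 1..`max_bins` are
fitted and k selected by BIC; a contig takes the bin owning most of its
fragment length.

BIC routinely *over*-segments even a single-organism cloud: per-contig GC
and coverage variation is real between-contig heterogeneity, and the
mixture models it. This mirrors what composition binners do to real
mycobiont clouds (one large ~50%-GC bin plus several tail bins). The
pipeline therefore does not rely on k being "right"; correctness lives at
the pipeline level:

- **anchor**: the bin with the most bases called as the target taxon
  (default *Ascomycota*, best-sum of bitscores per taxon across protein
  and nucleotide hit tiers, e-value cutoff 1e-25, ties lexicographic);
- **merge**: a bin joins the anchor iff its median coverage is within a
  2.0-fold ratio, its median GC at most the anchor's + 0.02, and at most
  20% of its bases carry a contaminant call. The three thresholds
  automate a manual curation step that the original workflow describes
  only qualitatively ("consistent coverage, lower GC"); they are
  configuration, surfaced per bin in the run report, not literature
  values. Bins are judged independently against the anchor — no
  chaining — so a contaminant bin cannot ride in behind a tail bin.
- **filter**: keep contigs whose call is the target taxon or NO_HIT.

The AT-tail guarantee — recall above 0.9 even when every tail contig
lacks taxonomy — holds because the merge rule only uses coverage and GC;
the tests verify this by setting `label_miss_prob = 1`.

## 4. BGC distance, network, families

For clusters A and B of the same class (cross-class pairs are never
compared; RiPP/saccharide classes are excluded if present):

- **J**: Jaccard of pooled domain-label sets (two domainless clusters
  score 1, with a warning).
- **DSS**: for each shared label, copies are paired greedily by
  descending global-alignment identity of their parent-gene sequences;
  DSS = 2·Σ(paired identities) / (total copies in A and B). Identical
  clusters score 1, disjoint label sets 0, unpaired copies dilute. The
  alignment is Needleman–Wunsch with match +1 / mismatch −1 / linear gap
  −2, identity = matches over alignment columns, implemented as a small
  compiled kernel (tens of thousands of short alignments per panel; the
  kernel is verified against Biostrings in the tests).
- **AI**: Jaccard of unordered adjacent domain pairs after linearizing
  each cluster in gene order (reversal-invariant by construction;
  clusters with fewer than two domains score 0).
- **d** = 1 − (0.2 J + 0.7 DSS + 0.1 AI), weights configurable. The
  triple is one global setting — no class-specific weight sets, no
  anchor-domain boost — because the downstream contract only needs a
  symmetric [0,1] dissimilarity with d(A,A) = 0.

Edges link pairs with d ≤ cutoff (inclusive, so grid selection is well
defined), except that d = 1 is never an edge: complete dissimilarity
carries no evidence of homology even at the most permissive cutoff (this
also keeps "a pair at d = 1 never co-clusters" true on the full grid).

Within each connected component of size ≥ 3, affinity propagation on
s = 1 − d partitions the members (damping 0.9, ≤ 1000 iterations, seeded
tie-break noise; non-convergent components collapse to one family).
The exemplar preference is fixed at 0.5 on the similarity scale rather
than the median similarity: with preference ≈ typical within-family
similarity, affinity propagation fragments a coherent family into
arbitrary shards (each point is as good an exemplar as its neighbour),
while a preference below within-family similarity but above between-family
similarity keeps families whole and still splits mixed components. The
0.5 default matches common practice for this network type and is
configurable in `network_config()`. Family ids are canonicalized to the
smallest member cluster id, so the partition is invariant to input order.

`select_cutoff()` walks the 0.30–1.00 grid (step 0.01, the finest grid on
which the 0.46 default is representable) and returns the smallest value
co-clustering the reference pair, verifying the next step as well so a
knife-edge value is not chosen.

## 5. Diversity statistics

**Beta partition.** Pairwise: β<sub>sor</sub> = (b+c)/(2a+b+c),
β<sub>sim</sub> = min(b,c)/(a+min(b,c)), β<sub>sne</sub> their
difference. Multisite: the min/max-sum generalization over all site
pairs, with the pooled-richness core term. The two-site multisite case
reduces algebraically to the pairwise formulas and the tests hold this to
1e-12, alongside a brute-force double-loop oracle coded independently in
the test file.

**PCoA** Gower-centers the squared dissimilarities and eigendecomposes;
negative eigenvalues (non-Euclidean input such as Jaccard) are reported,
never corrected, and axes are signed so the first non-zero loading is
positive (a deterministic orientation). On Euclidean input the embedded
distances reproduce the originals to 1e-8.

**Mantel** is one-tailed for positive association (the direction the
phylogenetic-signal hypothesis predicts) with the standard
(1 + exceedances)/(1 + permutations) estimator; 999 permutations by
default, making 0.001 the attainable floor.

**PERMANOVA** uses sequential (Type-I) sums of squares via traces of hat
matrices against the Gower-centered matrix, term R² = SS/tr(G), and
permutes the distance matrix labels (unrestricted exchangeability — the
simplest scheme consistent with an unconstrained model). On Euclidean
distances of univariate data it reproduces classical ANOVA F exactly, and
it matches vegan's `adonis2(..., by = "terms")` to machine precision in
the tests; the permutation p-values differ only through permutation
draws.

**Phylogenetic PCs** (`phylo_pcs()`) treat the distance-matrix rows as
raw feature vectors, column-center and SVD, selecting the smallest k
whose cumulative variance reaches 80%. Whether such an analysis should
instead double-center (making it PCoA-equivalent) is genuinely ambiguous;
both are implemented behind `center =`, with raw rows as the default, and
the choice is recorded here rather than hidden.

No multiple-testing correction is applied anywhere: the statistics are
reported as single planned tests.

**Partial F-test** (`partial_f_test()`) compares nested least-squares
fits; an exact fit of the full model reports F = ∞, p = 0 rather than an
overflow. It is generic over supplied covariates because the exact nested
model for, e.g., an assembly-fragmentation (N50) effect on cluster counts
is an analysis choice, not a package decision.

## 6. The anthraquinone screen

A gene counts as NR-PKS on KS + AT co-occurrence (full SAT-KS-AT-ACP
order is checked separately and reported as `pks_domain_order_ok`), so
partially annotated PKSs still screen. The PT domain is optional
throughout: it is the domain most often missed by annotation even in
confirmed anthraquinone synthases. The four-gene order check
(ABC-transporter, MβL-TE, PKS, EthD) tolerates intervening genes and
accepts the whole-cluster reversal, since gene order is read off an
arbitrary strand; both tolerances are on by default and the per-cluster
report carries the flags so a stricter reading can be applied downstream.
The decision table maps role sets to exactly one variant per cluster:
COMPLETE, MISSING_ETHD, MISSING_ABC (each missing exactly that gene),
PKS_ONLY, ETHD_IN_PKS (the EthD domain inside the PKS gene), with
OTHER_PARTIAL and NOT_CANDIDATE as fallbacks. Endocrocin and clavorubin
appear as separate entries in the default compound set even though they
share one reference cluster.

Exclusivity assertions ("role R observed only in clade C") are computed
over screened candidates, not all clusters — the same scope in which such
statements are scientifically meaningful.

## 7. Numerical choices and problem sizes

- Ties: taxonomy calls break lexicographically; bin votes to the lower
  bin id; alignment traceback prefers diagonal, then up, then left (any
  optimal path yields an optimal score; identity on tied paths is
  checked against an independent aligner in the tests).
- All permutation procedures and simulators are deterministic given
  their seed; byte-identical outputs for identical seeds are asserted.
- Test problem sizes: full 13 Mbp communities for binning (five seeds),
  a 200-cluster panel (20 families × 10 genomes) for family recovery,
  500 replicates × 199 permutations × 20 taxa for null calibration, 1000
  random matrices for the beta identities. These sizes keep the complete
  suite under a few minutes on one CPU while leaving each property
  statistically sharp.

## 8. Known limitations

- The sequence simulator's organisms are compositionally stationary;
  real genomes have isochores, repeats and mobile elements, so binning
  performance on real data will be worse than the simulated F1 ≈ 1.
- DSS aligns whole parent-gene sequences, not extracted domain
  subsequences, and uses one weight triple for all classes — a
  simplification of production BGC-network tools that preserves the
  distance contract but not their exact scores.
- The screen trusts the provided domain annotations; it has no HMM
  fallback for unannotated domains.
- PERMANOVA's unrestricted permutation scheme ignores phylogenetic
  non-exchangeability; its p-values on tree-structured data are
  anti-conservative in the same way as the standard tools it mirrors.
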