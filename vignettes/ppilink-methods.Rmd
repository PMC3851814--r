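---
title: "Methods: heterogeneous similarity features for PPI prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterogeneous similarity features for PPI prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppilink)
```

## The problem

Experimentally measured protein–protein interaction (PPI) sets are
incomplete and noisy: high-throughput screens report pairs that do not
interact in vivo (false positives) and miss pairs that do (false
negatives).  `ppilink` treats interaction refinement as supervised
classification.  Seven similarity features are computed for each protein
pair — three Gene Ontology (GO) semantic similarities, each evaluated per
GO aspect, a co-pathway similarity, and three network-topology
similarities — and an RBF-kernel support vector machine is trained on a
gold standard of curated positive pairs and constructed negative pairs.
The trained classifier then scores query pairs: low-scoring reported
interactions are candidate false positives, and high-scoring non-edges are
candidate false negatives.

## Information content on the ontology

Each GO aspect (biological process BP, molecular function MF, cellular
component CC) is a DAG over terms joined by `is_a` and `part_of` edges;
other relation types are dropped at parse time.  Annotations obey the
true-path rule: a protein annotated to a term implicitly carries every
ancestor of that term, and `annotation_set()` materializes this closure.
The information content of a term is

$$IC(t) = -\ln p(t),$$

where $p(t)$ is the fraction of the aspect's annotated proteins carrying
$t$.  Natural logarithms are used throughout (the base cancels in every
normalized ratio the package computes).  Two conventions for $p(t)$ exist
in the literature; `compute_ic(counts = "propagated")` (the default, and
the field standard) counts a protein for $t$ if any of its annotations
lies at or below $t$, while `counts = "direct"` counts only direct
annotations.  Terms annotating no protein have no probability mass and are
excluded from the IC table rather than given infinite IC; similarity
operations treat proteins annotated only to such terms as unannotated.
Missing annotation is always reported as `NA`, never as similarity 0 — the
distinction matters downstream, where `NA` is imputed from training data.

## The three GO semantic similarities

**TCSS.**  Term similarity is normalized within *topological clusters* of
the aspect DAG.  `tcss_ica()` computes the information content of
annotation (ICA), which under the default propagated convention equals
$IC$.  A threshold on ICA cuts the DAG: because $p$ can only shrink from
parent to child, every root-to-leaf path crosses the threshold at most
once, and the terms at or above the cut whose parents are all below it
become subgraph roots.  Each subgraph is a root plus its
annotation-bearing descendants; roots with ICA within a merge tolerance
are merged; subgraph edge sets are cleaned by transitive reduction and a
term reachable from several roots is duplicated into each subgraph.  The
terms below the cut, together with the roots, form the meta-graph.  Within
subgraph $m$, $ICS(t) = ICA(t) / \max_{s \in m} ICA(s)$, and on the
meta-graph $ICM(t) = ICA(t) / \max_{s \in meta} ICA(s)$.  Two proteins are
compared over all pairs of their annotation terms: a pair sharing a
subgraph scores the ICS of its best (max-ICA) common ancestor, a pair in
different subgraphs scores the ICM of its best common ancestor among meta
terms, and the protein similarity is the maximum over term pairs.  The
published description of the two-branch scoring rule is ambiguous about
which subgraph each branch condition references; the reading implemented
here — same subgraph ⇒ ICS, different subgraphs ⇒ ICM — follows the
method's prose description and is documented as an interpretation.  The
threshold and merge tolerance are nowhere given numerically in the source
method, so the package defaults them to $0.35 \times \max ICA$ and
$0.05 \times \max ICA$; both are arguments of `tcss_partition()`.  When a
merged subgraph contains two terms with no common ancestor inside it, the
pair falls back to the meta-graph score.

**IntelliGO.**  Each protein is a vector over its *direct* annotation
terms (evidence codes exist only on direct annotations, which is why
propagation is not used here).  The coefficient of term $t$ for protein
$g$ is $\alpha_t = w(g, t) \cdot IAF(t)$: the evidence-code weight times
the inverse annotation frequency $IAF(t) = \ln(N / n_t)$.  When a protein
carries the same term under several codes the best weight is used.  The
default weight table — experimental codes 1.0, computational and
curator-assigned codes 0.8, IEA and unknown codes 0.6 — follows the
convention of the original measure, which publishes the scheme but not a
full table; it is fully overridable.  Similarity is the cosine under a
non-orthogonal basis whose term-pair inner product is

$$e_s \cdot e_t = \frac{2\,d(LCA)}{minSPL(s,t) + 2\,d(LCA)},$$

with $d$ the shortest-path depth of the max-IC common ancestor below the
aspect root and $minSPL$ the shortest path $s \to LCA \to t$.  This basis
formula is adopted from the original IntelliGO publication (the framework
reimplemented here delegates it to that reference).  Degenerate cases are
pinned explicitly: $e_t \cdot e_t = 1$, and the product is 0 when the only
common ancestor is the depth-0 root.  Because the weights enter both the
numerator and the norms, a global rescaling of the evidence-code table
leaves the similarity unchanged (tested).  Cosines are clamped to
$[0, 1]$ against floating-point overshoot, since the basis Gram matrix is
not guaranteed positive semidefinite on arbitrary DAGs.

**Wang.**  For an anchor term $t$, the semantic contribution of ancestor
$n$ is $S_t(t) = 1$ and $S_t(n) = \max \{ w_e \cdot S_t(n') \}$ over
children $n'$ of $n$ inside the anchor's ancestor DAG, with edge weights
$w_{is\_a} = 0.8$ and $w_{part\_of} = 0.6$ (the values conventionally used
with this measure; the framework source does not restate them).  Term
similarity sums the contributions of shared ancestors, normalized by the
two contribution totals, and the protein similarity is the maximum over
the cross product of the two proteins' direct term sets.  The
implementation is a memoized dynamic program; the test suite checks it
against an independent exhaustive path-enumeration oracle on random DAGs.

## Co-pathway and topological similarities

The pathway feature is the Jaccard index of two proteins' pathway sets.
A protein absent from every pathway is unannotated in this channel: when
both proteins are absent the feature is `NA` (the measure "cannot work"),
and when exactly one is absent it is 0.

On the PPI network (undirected, simple; self-loops and duplicates dropped
at load time), for neighborhoods $N(i)$ and degrees $k_n$:

* Jaccard: $|N(i) \cap N(j)| \, / \, |N(i) \cup N(j)|$
* Adamic–Adar: $\sum_{n \in N(i) \cap N(j)} 1 / \ln k_n$ (natural log,
  configurable; a common neighbor has $k_n \ge 2$, so terms are finite)
* Resource allocation: $\sum_{n \in N(i) \cap N(j)} 1 / k_n$

When a gold-standard pair is itself an edge, its own edge is *not* removed
before computing neighborhoods (the source framework states no
leave-one-out protocol); `mask_edge = TRUE` enables the leave-one-out
variant.  Topological features are computed on whatever network the user
supplies; proteins absent from it get `NA`.

## Gold standard and classifier

Negatives are sampled from the proteins of the positive set so that every
protein's incidence count among negatives equals its degree among
positives, by seeded stub shuffling with partner-swap repair: invalid
pairs (self-pairs, duplicates, known positives) swap partners with random
pairs, which preserves the degree multiset, until no invalid pair remains;
after 100 failed restarts the best attempt is returned with a warning.
The positive and negative sets have equal size by construction.

The classifier is a C-classification SVM with RBF kernel at library
defaults (cost 1, $\gamma = 1/\#features$), the configuration the source
framework found sufficient.  Missing features are imputed with per-column
training medians, zero-variance columns are dropped with a warning, and
columns are standardized with training statistics; queries are always
transformed with the stored training statistics, never their own.
Evaluation is stratified seeded $k$-fold cross-validation (stratification
is a deliberate strengthening of plain $k$-fold: it prevents single-class
folds on small fixtures), with decision values pooled across folds before
the ROC is computed; per-fold AUCs are reported alongside, since pooling
versus averaging is a genuine choice and the source does not say which it
used.  AUC follows the Mann–Whitney convention with half credit for ties —
stated explicitly because topology features are heavily tied at zero and
the tie convention changes the number — and equals the trapezoidal area
under the returned step curve.  The decision threshold for labeling query
pairs is 0 on the signed decision value, configurable in
`predict_query()`.

## Synthetic benchmarks: what they emulate and what they do not

`make_cocomplex_benchmark()` emulates a complex-derived gold standard:
disjoint complexes are rendered as full cliques (the matrix model of
expanding a complex into pairs; the spoke model is not implemented),
positives are all within-complex pairs, and degree-preserving negatives
are therefore necessarily cross-complex.  Members of a complex share a
deep CC signature term with probability `annotation_coherence` and carry
random BP/MF terms, and pathway membership is correlated with complexes.
Because the network is a disjoint union of cliques, a cross-complex pair
has no common neighbors and scores exactly 0 on all three topological
measures, while a within-complex pair in a size-$s$ clique has Jaccard
$(s-2)/s$ — so topology separates the two classes perfectly.  This is the
structural mechanism that makes topological features near-perfect on
co-complex data, and the package's acceptance checks reproduce it at a
desk scale (30 complexes, sizes 5–10) rather than at the scale of the
original curated complex set.

`make_binary_benchmark()` emulates a binary (pairwise-measured) gold
standard: a duplication–divergence growth process (new proteins copy a
random anchor's neighbors with probability `p_copy`, giving overlapping
neighborhoods) trimmed or padded to an exact edge count.  Defaults are
1078 proteins and 1263 interactions, the size of the published binary
yeast gold standard this generator mirrors.  Interacting pairs share a
deep BP term with probability `annotation_coherence` (default 0.8) and
deep MF/CC terms at 0.3 times that rate, reflecting the biological
expectation that interaction aligns first with biological process; this
is what makes BP-aspect features outpredict MF-aspect features on
binary-style data, a direction the test suite checks across seeds at a
reduced scale (150 proteins, 180 interactions) chosen so the full suite
stays fast.

Coherent terms are drawn from the deepest third of the toy DAG so that
shared annotations are high-IC and informative; noise terms are drawn
uniformly.  The generators are deterministic given their seed, and their
OBO/GAF/TSV serializations round-trip through the package parsers.

The emulation is deliberately minimal.  The toy networks are not
scale-free, annotation sizes per protein are small and homogeneous, the
ontology is a near-tree of a few hundred terms, and no noise model beyond
optional label-flipping exists.  Passing tests on these benchmarks
demonstrate that the *mechanisms* (formulas, propagation, separation
arguments, degree preservation) are implemented correctly — not that the
package will reach any particular AUC on real interactome data, where
annotation sparsity, evidence-code composition and network topology differ
substantially.

## Numerical choices and degenerate inputs

* Ties when choosing a max-IC common ancestor break to the
  lexicographically smallest term id, so results are deterministic.
* A TCSS threshold exceeding every ICA yields a single whole-aspect
  subgraph (not an error); a subgraph whose terms all have ICA 0 gets ICS
  0 everywhere (there is nothing to normalize by).
* `kegg_sim` distinguishes "both unannotated" (`NA`) from "one
  unannotated" (0).
* The sampler's swap repair runs 200 sweeps per restart; infeasible degree
  sequences degrade to a smaller negative set with a warning rather than
  an error.
* All file readers tolerate CRLF line endings and trailing whitespace.

## Problem sizes

The test suite and the reproduction script use: the 30-complex co-complex
benchmark (about 200 proteins, roughly 1300 gold pairs, 13 features),
binary benchmarks of 80–180 interactions, 100-DAG oracle sweeps at up to
15 terms, and 1000-pair symmetry sweeps.  These sizes were chosen as the
smallest at which every mechanism under test is exercised
non-degenerately; the full suite runs in well under a minute on one core.
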