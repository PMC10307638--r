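---
title: "Dissecting phylogenomic signal and reconstructing ancestral genome content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting phylogenomic signal and reconstructing ancestral genome content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and motivation

Deep phylogenomic questions -- such as which archaeal lineage is the
closest relative of eukaryotes -- are decided on concatenated protein
supermatrices whose strongest artefact modes are compositional
convergence and mutational saturation. The standard defensive toolkit is
(i) reduced-alphabet recoding (SR4: the 20 amino acids collapsed into
four exchange-similar groups), (ii) stepwise fast-evolving-site removal
(FSR) guided by posterior-mean site rates, (iii) taxon-deletion
experiments, and (iv) per-taxon compositional diagnostics. Downstream of
the species tree, ancestral genome content is reconstructed by
reconciling per-family gene trees with the species tree under an undated
duplication-transfer-loss (DTL) model, with a correction for incomplete
(metagenome-assembled) genomes, and ancestors are compared through
normalized event rates.

`phylodissect` implements this entire chain as tested, reusable R code,
and -- because the real datasets at the scale of the motivating analyses
require cluster-scale inference -- validates every stage on synthetic
data with recorded ground truth. The package therefore contains two
tightly coupled halves: the analysis operators themselves, and
generative simulators that are *exact counterparts* of the inference
models.

## Sequence-level machinery

**Likelihood engine.** All sequence likelihoods use Felsenstein pruning
over compressed site patterns under simple reversible models: an
exchangeability matrix (or Poisson equal exchangeabilities) combined
with equilibrium frequencies, normalized to one expected substitution
per site, optionally with discrete-gamma rate variation (four
equal-probability categories whose rates are the conditional bin means;
the category mean is exactly 1). Gaps `-`, `?` and amino-acid ambiguity
codes are fully ambiguous. Per-pattern scaling guards against
underflow. The engine is verified against brute-force enumeration of
internal-state assignments on small trees and against an independent
implementation on larger ones. The deliberately simple model family is
a design decision: the mixture models used for final inference in real
analyses (C60, CAT+GTR) are out of scope, and the treatment logic under
test -- recoding and site removal -- does not depend on them.

**SR4 recoding.** The built-in scheme is the canonical four-state
grouping \{A,G,N,P,S,T\}, \{C,H,W,Y\}, \{D,E,K,Q,R\}, \{F,I,L,M,V\},
written as A/C/G/T so recoded data flow through four-state machinery
unchanged. Recoding preserves taxa, column count and gap positions;
ambiguity codes and the rare residues U/O collapse to `?`. Custom
schemes load from a two-column TSV.

**Site rates and FSR.** The gamma shape is estimated by bracketed 1-D
optimization of the discrete-gamma log-likelihood on `[0.02, 100]`
(tolerance `1e-4`; rate-homogeneous data drive the estimate to the
upper region of that interval). Posterior-mean site rates are
`r_i = sum_c r_c L_i(r_c) / sum_c L_i(r_c)` with equal category priors.
Columns are ranked by decreasing rate with ties broken by column index,
split into ten near-equal categories (fastest first), and removed in
nested steps of `floor(f * L)` columns. The normative order for the
combined treatment is: estimate rates on the amino-acid alignment,
remove columns, then recode -- rates are never estimated on recoded
data. The guide tree for rate estimation is an explicit input; nothing
triggers a tree search implicitly.

**Composition diagnostics.** Per-taxon frequencies exclude gaps and
missing symbols. The heterogeneity statistic is
`X2_t = N_t * sum_s (f_ts - fbar_s)^2 / fbar_s` with the unweighted
across-taxon mean as `fbar` (users wanting length-weighted means can
compute them from the returned table). Pairwise distances are Euclidean
or the square-root Jensen-Shannon divergence (a metric); UPGMA ordering
uses average-linkage clustering with deterministic tie-breaks. No
p-values are attached to the composition statistic: its null
distribution under realistic alignments is dubious, and the package
uses it only as a ranking diagnostic (e.g. mutual compositional nearest
neighbours).

**Distances, trees, placement.** LogDet/paralinear distances are
computed from pairwise joint count matrices with pseudocount 0.5 on
zero cells (a pair with no shared ungapped columns, or a saturated
non-positive determinant, is flagged missing); neighbour joining and
bootstrap proportions come from `ape`. Because full maximum-likelihood
tree searches are out of scope, the package exercises treatment logic
through *constrained placement*: the query clade (held monophyletic,
its internal topology fixed from an NJ subtree) is attached to each
candidate backbone edge and candidates are ranked by log-likelihood.
Branch-length handling follows the placement literature (EPA-style):
one global branch-length scale is optimized first -- essential because
the backbone lengths come from a different substitution scale than,
say, SR4-recoded data -- followed by per-branch Brent coordinate ascent
on the attachment region (`optimize_edges = "all"` re-optimizes every
branch; convergence tolerance `1e-4`, at most 50 sweeps). Placement
bootstrap support counts the fraction of column-resampled replicates a
candidate wins; replicates whose two best candidates differ by less
than `1e-6` log units count for neither.

## The undated DTL reconciliation

Rates `(delta, tau, lambda)` define per-branch event probabilities
through `Z = 1 + delta + tau + lambda`: speciation-or-leaf-arrival
`P_S = 1/Z`, duplication `P_D = delta/Z`, transfer `P_T = tau/Z` (the
copy lands on a uniformly chosen other branch; undated, so no time
consistency is imposed), loss `P_L = lambda/Z`. Genome incompleteness
enters at the leaves: a surviving copy at leaf `e` is observed with
probability `1 - m_e`, where `m_e` is one minus the genome completeness.

Extinction probabilities solve the per-branch fixed point

    E_e = P_L + P_S * s_e + P_D * E_e^2 + P_T * E_e * Ebar_-e

with `s_e = E_f E_g` on internal branches and `s_e = m_e` at leaves,
iterated from zero to a residual below `1e-10`.

The family likelihood is a dynamic program over gene-tree clades x
species branches. Gene trees enter as a *clade graph*: a rooted tree
contributes one split per clade; an unrooted tree contributes a top
clade whose splits are the edge bipartitions with uniform weights,
which is algebraically identical to averaging the likelihood over all
rootings; a conditional-clade-probability (CCP) set built from a tree
sample contributes frequency-weighted splits, amalgamating the
likelihood over topologies. Families of size 2-3 without trees are
reconciled from their copy-count profile using the unresolved topology
(documented as an approximation; they must still contribute to copy
numbers). Families with a single protein are scored directly as an
origination at their leaf, with no DP. Families above a configurable
size cap (default 2,000 members) are skipped with a warning. The
origination prior is uniform over species branches, and by default the
likelihood is conditioned on the family being observed at all (division
by `1 - mean(E)`), since families are defined from observed proteins.

One convention deserves emphasis: the DP scores the observed *labelled*
gene tree, treating leaves as distinguishable named sequences. For a
gene tree with genome-label automorphisms (e.g. a same-genome cherry)
the DP value equals the generative probability of the unordered
genealogy multiplied by the automorphism count
(`genome_label_automorphisms()`). The factor depends only on the
topology, never on the rates, so rate estimation, reconciliation
sampling and all downstream statistics are unaffected; the package's
enumeration oracles divide by it when comparing against generative
outcome frequencies.

Rate estimation maximizes the pooled conditioned log-likelihood by
Nelder-Mead in log-rate space (relative tolerance `1e-3`).
Reconciliation histories are drawn by stochastic backtracking of the DP
proportional to each term's contribution; events are recorded per
(type, species branch, gene clade), so an event's sampled frequency --
the fraction of draws containing it -- lies in `[0, 1]`, and per-branch
copy numbers count the lineages surviving each branch. Following common
reporting practice, events are considered at a minimum frequency of
0.3.

**Copy-number correction.** Raw copy numbers are conditional
expectations given that the family was observed; families that escaped
observation entirely (all copies lost or unsampled) are invisible.
Dividing each family's copies by its observability
`O_g = 1 - mean(E)` is a Horvitz-Thompson-style correction that makes
*sums over families* -- ancestral genome sizes -- approximately
unbiased. It is an aggregate device: for a single observed family the
raw conditional expectation is already close to unbiased, so the
corrected value typically overshoots that family's own truth even
though the aggregate improves. Both columns are therefore reported,
with corrected copies used downstream. Presence at a node is scored
when the copy number exceeds 0.3, "maybe present" between 0.1 and 0.3,
absent below 0.1.

## Ancestral statistics

A node's proteome size is the number of families whose corrected copy
number clears the presence threshold (the sum of expected copies is
also available from the copy tables, since a size definition by
thresholded counts versus summed expectations is a genuine ambiguity).
Normalized event rates divide per-node event totals by proteome size.
Groups of ancestors are compared by a two-sided one-sample Wilcoxon
signed-rank test of their per-ancestor rates against the median rate of
the reference ancestors -- matching the reporting convention of the
analyses this package emulates, which state explicitly that no
multiple-testing correction is applied. The reference grouping is an
explicit input file, never inferred. The test uses the exact null
distribution for n <= 25, computed by convolution over doubled midranks
(so ties are exact too); beyond that, the normal approximation with
continuity and tie corrections. A two-sample Mann-Whitney alternative
is available through `stats::wilcox.test` on the same profile tables if
a user prefers it; the one-sample-versus-reference-median form is the
default because it matches the stated convention.

## The synthetic generators, and what they do not emulate

`simulate_gene_family()` is the generative mirror of the DP: per-lineage
discrete event draws with the same normalized probabilities, uniform
transfer targets, leaf sampling with probability `1 - m_e`, and
optional redraw-on-extinction to match the conditioned likelihood. The
mirror is exact by construction -- the package's central testing
contract -- and is verified two ways: extinction probabilities against
Monte-Carlo extinction frequencies, and family likelihoods against a
memoized exhaustive enumeration of the truncated process on three-leaf
species trees (truncation at six auxiliary events; with the small rates
used, the neglected mass is below `1e-7`).

`simulate_alignment()` draws per-site rates from the discrete-gamma
categories and evolves states branch by branch; selected branches can
override the equilibrium frequencies, with the rate matrix rebuilt
around the overridden equilibrium (exchangeabilities kept), so the
lineage genuinely drifts toward the target composition.

Two canned experiments define the package's study conditions:

* **`artifact_scenario()`** -- a 17-taxon tree in which an in-group
  lineage, an out-group lineage and the query clade share a strong
  compositional override on elongated branches (about 1 expected
  substitution per site, query stem 0.8), while the true sister of the
  query is a short-branch in-group lineage; alignments are 500 columns
  with `alpha = 0.5`. The override concentrates 85% of each SR4 bin's
  total frequency on one residue *within* the bin, so the amino-acid
  level bias is strong but bin-level composition stays at background:
  recoding removes the convergence while fast-site removal strips the
  saturated columns that carry most of the residual attraction. This
  within-bin construction is the scenario's key design choice -- it
  makes the treatments' rescue mechanistic rather than accidental.
* **`clade_contrast_scenario()`** -- a 22-genome tree whose 10-leaf
  focal clade duplicates at 3x and loses at 0.5x the base rates
  (defaults `delta = 0.05`, `tau = 0.03`, `lambda = 0.3`), with 150
  families originated on the root branch. Root origination emulates
  core-genome families that traverse every ancestor; with uniform
  origination most families never touch a given node, per-ancestor
  event counts fall to a handful, and no per-node statistic can
  separate a factor-two rate shift from counting noise at desk scale.
  The base duplication rate is kept low because a large duplication
  excess inflates per-family copy numbers and thereby *absolute* loss
  counts, masking a per-copy loss deficit when rates are normalized by
  proteome size (family counts, not copy counts).

What the simulators deliberately do not emulate: indels and alignment
uncertainty, profile-mixture (site-heterogeneous) amino-acid
preferences, dated transfers, gene conversion, and any
empirical-parameter mimicry of real archaeal datasets. Passing the
package's tests therefore demonstrates that each inference stage
recovers truth *under its own model assumptions* (plus the specific
stationarity violations injected); it does not certify behaviour on
real data, where the artefact modes are richer.

## Numerical choices and degenerate inputs

* Columns are 0-based and partition intervals half-open; markers absent
  from a taxon are padded with `?` (fully ambiguous), not `-`, so
  likelihoods treat them as missing data.
* The relaxed sequential PHYLIP dialect accepts whitespace-delimited
  names up to 250 characters and wrapped sequence lines.
* Removal counts use `floor(f * L)`; all tie-breaks (site ranking,
  UPGMA joins, NJ) are deterministic, and every stochastic function
  takes an explicit seed.
* Alignments with no variable sites make the gamma shape undefined and
  are rejected; a taxon with zero ungapped symbols is rejected by the
  composition table; dropping all taxa, empty candidate sets, zero
  observability and negative inputs all raise immediate errors rather
  than propagating NaNs.
* The extinction and null-event fixed points iterate to `1e-10` and
  `1e-14` respectively with hard iteration caps.

## Problem sizes used in the validation suite

The shipped experiments run at sizes chosen to exercise every code path
while remaining desk-scale: pruning oracles on 2-4 taxa x 5 columns;
reconciliation oracles on 3-leaf species trees with 100,000-replicate
Monte-Carlo checks; rate recovery on 200 families over 8 leaves;
site-rate recovery on 32 taxa x 1,000 columns; the artefact experiment
on 20 seeds; and the clade-contrast experiment on 20 seeds of 150
families with 100 sampled reconciliations per family. The acceptance
script reruns the same experiments with fewer seeds (8 and 6 for the
two multi-seed experiments) to keep a full from-scratch reproduction
fast; all quantities it reports are recomputed at run time from the
given seed.

## Known limitations

* The placement surrogate ranks a fixed candidate set on a fixed
  backbone; it does not search topologies, and its bootstrap supports
  are placement supports, not comparable to supports from full tree
  searches.
* Likelihood models are single-matrix reversible models; recoded data
  are analysed under a general four-state model, not a recoded mixture.
* Star-topology handling of treeless size-2-3 families is an
  approximation, flagged as such.
* The observability correction is aggregate-unbiased, not per-family
  (see above); per-family corrected copies should not be interpreted as
  improved point estimates for that family.
* CCP sets are built from rooted binary tree samples; unrooted samples
  should be rooted (any rooting) before counting, which changes clade
  frequencies only through the root clade's splits.
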