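---
title: "Methods: ancestral kinase reconstruction and specificity analytics"
author: "kinasr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancestral kinase reconstruction and specificity analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinasr)
```

# Scope

`kinasr` implements the computational core of an ancestral-kinase
"resurrection" workflow: maximum-likelihood marginal ancestral sequence
reconstruction on a fixed protein phylogeny, and the biochemical analytics
used to follow substrate specificity along that phylogeny — positional
scanning peptide library (PSPL) quantification, Michaelis–Menten kinetics,
ratiometric +1-position statistics, and mapping of specificity states and
the DFGx activation-loop residue onto the tree. Tree topology search,
multiple-alignment inference and all wet-lab steps are out of scope: the
alignment and topology are inputs.

# The substitution model

Sequence evolution is modelled as a reversible continuous-time Markov
process on the 20 amino acids. An empirical exchangeability matrix $S$
(LG, WAG or JTT, shipped as plain-text files in the classic lower-triangle
layout with citations) and equilibrium frequencies $\pi$ define the rate
matrix $Q_{ij} = s_{ij}\pi_j$, scaled so that $-\sum_i \pi_i Q_{ii} = 1$;
branch lengths are then expected substitutions per site. Transition
probabilities $P(t) = e^{Qt}$ are computed through the symmetric
eigendecomposition of $\Pi^{1/2} Q \Pi^{-1/2}$, which has a real spectrum
for every reversible model; the decomposition is cached per model, so a
$P(t)$ costs one 20×20 reconstruction.

Among-site rate variation uses the discrete-gamma approximation: $K$
equal-probability categories of a unit-mean gamma distribution with shape
$\alpha$, each represented by its **category mean** (computed in closed
form from the incomplete-gamma identity). Means rather than medians were
chosen because the mean-represented discretization has unit mean exactly,
with no rescaling step. The default is $K = 4$, the standard compromise
between accuracy and cost; the count is exposed everywhere it matters.
Model fit can be compared by AIC ($2k - 2\ln L$), where $k$ counts branch
lengths plus one parameter for an estimated $\alpha$ and zero for the
fixed empirical matrices; with gamma present, $\alpha$ is optimized by
bounded search on $[0.05, 50]$ with tolerance $10^{-4}$. Input branch
lengths are held fixed across AIC candidates — rankings compare models on
the same tree, which keeps the comparison cheap and symmetric; the $k$
convention is stated so scores line up with common tools.

# Likelihood, branch lengths, and marginal reconstruction

The alignment likelihood is computed by Felsenstein pruning with
column-pattern compression. Gaps and unknowns (`X`) are missing data:
their tip partials are all-ones, so an all-gap column has likelihood 1.
Ancestral *residues* and ancestral *gaps* are deliberately separate
problems (see below), mirroring standard resurrection practice.

Branch lengths on the fixed topology are optimized by cyclic coordinate
ascent. For the branch under optimization the likelihood is factored
through the conditional partials above and below that branch, so each
trial length costs a single transition-matrix product; each branch is
solved by Brent search on $[10^{-8}, 20]$ and a sweep repeats until the
total log-likelihood improves by less than $10^{-4}$. Improvements are
accepted only if they increase the likelihood, making the optimization
monotone by construction.

Marginal posteriors at an internal node combine inside (pruning) partials
with outside partials computed by a preorder pass; rate categories are
mixed with their equal prior weights, which weights each category by how
well it explains the site. The per-site posterior over the 20 residues is
normalized to 1; the ML residue is the argmax with **ties broken in the
fixed package-wide alphabet order** (A R N D C Q E G H I L K M F P S T W Y
V), making reconstruction deterministic. Correctness is checked against
exhaustive enumeration over all internal-node assignments on trees of up
to five leaves, at tolerance $10^{-10}$, and the total likelihood is
cross-checked against an independent phylogenetics package.

Insertion/deletion characters are placed by Fitch parsimony on each
column's binary presence/absence pattern, treated independently per
column: set-intersection up-pass (one change per empty intersection),
then a down-pass in which each node takes its parent's state whenever its
state set allows it — this keeps the labelling cost-minimal. The root's
free choice is resolved toward *presence*, which retains residues and is
the conservative choice when the goal is to resurrect a sequence;
ambiguous assignments are flagged per node and site rather than hidden. A
site whose indel character is absent is reported as a gap regardless of
the residue posterior.

Alternate ancestors are drawn by sampling **every** site independently
from its marginal posterior. Whether resampling should touch all sites or
only ambiguous ones is a genuine fork; all-site sampling is the default
because it is the distributionally faithful choice, and the per-sample
count of differences from the ML sequence is reported so users can
compare against expectations or post-filter to low-support sites.

Support is summarized by binning the per-site posterior probability of
the ML residue, PP(ML), into twenty 5%-wide bins with the mean and
variance reported. Branch support is an approximate likelihood ratio: the
likelihood of the input topology over the better of the two NNI
rearrangements of the branch, each re-optimized; a two-child root is
handled as the unrooted edge it really is, and values below 1 (input not
locally optimal) are reported, not clamped. Rooting with an outgroup
requires the outgroup to be monophyletic on the unrooted tree, and splits
the attachment branch equally between the two root-adjacent edges — the
placement within the branch is not identifiable from a reversible model,
so the midpoint is a declared convention.

# PSPL quantification

The library is the standard 182-mixture design on the scaffold
Y-A-x-x-x-x-x-[S/T]-x-x-x-x-A-G-K-K: nine degenerate positions (−5..−1,
+1..+4 relative to the phosphoacceptor at 0; scaffold stored 0-based
internally with this mapping) × 20 fixed residues, plus two all-degenerate
mixtures with the acceptor fixed to Ser or Thr. Degenerate positions
exclude Ser/Thr/Cys, which matters for interpretation but not for the
bookkeeping here.

Quantification follows the field's normalization: each spot intensity is
divided by the mean of its position group (the 20 mixtures sharing a
fixed position; the two acceptor mixtures form their own group), making
each group average exactly 1 and the result invariant to exposure
scaling. Replicates are combined by averaging normalized values and then
log2-transforming — that order is the default because averaging before
the log matches how such arrays are usually reported; log-then-average is
available as a flag for sensitivity checks. Zero means are floored at
$10^{-6}$ with a warning rather than dropped. Mixtures with Ser or Thr
fixed at a degenerate position carry a second phosphoacceptor and read
artificially high; they are masked (18 entries), never silently removed,
and masked operands refuse to enter downstream statistics. A
whole-profile centering mode (profile mean zero after log2) is provided
for kinase-centred displays.

The +1 statistic is the difference of log2 selectivities of the fixed +1R
and +1P mixtures; $2^{\text{ratio}}$ is reported as the array's fold
preference and labelled as such — how a fold preference is assembled from
array entries varies between studies, so the package states its
definition explicitly.

# Kinetics and ratio statistics

Initial velocities are fit to $V_0 = V_{max}[S]/(K_M + [S])$ by
unweighted nonlinear least squares (Levenberg–Marquardt), seeded by the
double-reciprocal linearization with fallback starts, requiring at least
four distinct substrate concentrations. $k_{cat} = V_{max}/[E]$ requires
velocities and enzyme concentration on the same concentration scale; the
declared conversion (default: velocities in µM/min, enzyme in nM) is an
explicit argument rather than an assumption. Standard errors come from
the fit's local curvature and propagate first-order into
$k_{cat}/K_M$ and fold ratios. Fold comparisons between peptides are
made on catalytic efficiency, the standard single-number summary of
substrate preference. For published tables without raw velocities,
`mm_fit_from_params()` builds the same object from $K_M$ and $k_{cat}$;
note that a table's printed efficiency can differ slightly from the
ratio of its printed means when the study averaged per-replicate ratios,
so both routes are labelled.

Ratiometric specificity is $\log_2$ of the ratio of mean initial
velocities of two peptides measured in parallel (+1R vs +1P, or Ser vs
Thr acceptor), with the standard error propagated from the replicate
standard errors of the means; the parallel-assay flag exists because the
ratio is only interpretable within a batch.

# Trajectory mapping

A kinase's +1 state is classified from its log2(R/P) ratio with a default
threshold of 1: more than twofold toward arginine is `R_pref`, more than
twofold toward proline is `P_pref`, anything within twofold is `dual_PR`.
Twofold is the conventional boundary at which such preferences are called
"similar"; the threshold is a parameter. The DFGx residue — immediately
C-terminal to the conserved DFG motif at the start of the activation
loop — is located by exact string match, disambiguated by requiring an
APE motif 15–45 residues downstream (a window covering observed
activation-loop lengths); an extended xAPE pattern mode is deliberately
not required. Transitions are reported per branch where the parent and
child residues differ; nodes without an extractable motif are flagged,
never skipped. States are reported only for measured/reconstructed nodes;
no parsimony interpolation of specificity states is attempted, because a
state is an experimental property of a resurrected protein, not a
character to infer. Annotated trees are written as NHX text (state, log2
ratio, DFGx residue as tags) with a parser that round-trips annotations
and branch lengths.

# Synthetic data and what passing tests mean

Every consumed data type has a generator with recorded truth: Yule trees;
sequence evolution under the full model (root from $\pi$, uniform
category assignment, per-branch transition sampling) with indels as
independent per-site binary presence/absence characters toggling at a
requested rate — matching the analysis-side assumption that each indel
character is independent, not a model of multi-residue indel events;
PSPL arrays as `scale · w(position, residue) · lognormal(1, CV)`
(lognormal because intensities are positive and spot noise is
multiplicative); and Michaelis–Menten velocities with multiplicative
noise. Generator defaults mirror the study conditions the package is
aimed at: two array replicates at 10% CV, velocity triplicates, kinetic
parameters in the low-µM $K_M$ / ~10 min⁻¹ $k_{cat}$ range, 5% kinetic
noise, eight-point concentration series spanning 0.25–50 µM.

The packaged fixture study is a desk-scale analog of a resurrection
project: an eight-taxon, 120-site tree with three clades whose planted +1
preferences are P (4-fold), dual (1-fold) and R (4-fold) and whose DFGx
character is L except in the R clade (S). DFG/APE motifs are implanted at
fixed columns (APE 21 residues downstream of DFG) and spurious DFG
occurrences are edited out so motif extraction is unambiguous. The
end-to-end test requires the pipeline to recover the planted P → PR → R
trajectory and the single L → S transition.

These simulations share the analysis model's assumptions (correct
substitution matrix, independent sites, single-column indels,
well-behaved multiplicative noise). Passing them shows the machinery is
self-consistent and calibrated under those assumptions; it does not show
robustness to alignment error, model misspecification, site-correlated
indels, or array artifacts beyond the masked fixed-S/T effect.

# Numerical choices and problem sizes

Transition matrices clip tiny negative eigen-roundoff and renormalize
rows; posteriors are normalized per site; branch lengths are clamped to
$[10^{-8}, 20]$; the zero-intensity floor is $10^{-6}$; gamma
discretization guards round-off so the discrete mean is exactly 1. Exact
two-way posterior ties resolve to the alphabetically earlier residue.
The test suite runs enumeration oracles on trees of ≤5 leaves (50 random
instances), branch-length recovery on 8 taxa × 600 sites, root-sequence
recovery on 16 taxa × 300 sites, and 200-replicate kinetic recovery —
sizes chosen to exercise every code path at interactive cost while
keeping the statistical checks well-powered.

# Known limitations

Joint (as opposed to marginal) reconstruction, codon/nucleotide models,
+F frequency estimation, invariant-site categories, topology search and
divergence dating are not implemented. The aLR is the literal
likelihood-ratio definition, without SH-like corrections. Specificity
prediction from sequence beyond DFGx bookkeeping — including the other
residues known to modulate +1 preference — is out of scope.
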