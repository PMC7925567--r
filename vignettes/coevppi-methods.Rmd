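---
title: "Methods: coupling inference and interaction scoring in coevppi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupling inference and interaction scoring in coevppi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

`coevppi` predicts which residues of two proteins touch, and whether the
proteins interact at all, from the covariation of a species-paired
concatenated sequence alignment. This vignette documents the statistical
model, every tunable parameter that matters, the numerical choices made
where the design was genuinely open, what the synthetic benchmark generator
does and does not emulate, and the package's known limitations.

## The alignment layer

**Pairwise identity.** All identity computations — sequence weighting,
paralog exclusion, ortholog pairing — use one definition: matches divided by
the number of columns where *both* rows are non-gap. This is symmetric,
standard in coupling pipelines, and avoids penalizing partial coverage
twice. Nonstandard letters (B, Z, U, O, X) are treated as missing (gap-like)
for all statistics but preserved in written output.

**Sequence weights.** Each row's weight is `1 / |{t : identity(s,t) >= θ}|`
(self included), with θ = 0.8: sequences with homologs above 80% identity
are downweighted. The effective sequence count N_eff is the sum of weights,
and N_eff/L (L = columns) is the diversity measure used everywhere.
Rows above 50% gaps are removed *before* weights are computed — the row
filter and the weighting are stated together in the coupling-calculation
protocol, and filtering first keeps N_eff a property of the sequences that
actually enter the fit.

**Coverage and eligibility.** An alignment has sufficient coverage when at
least 80% of its columns are below 50% gaps. Monomer alignments qualify for
analysis when they additionally satisfy N_eff/L ≥ 2.5 (inclusive at the
boundary); concatenated alignments use the looser floor N_eff/L ≥ 0.2,
reflecting that paired alignments are necessarily shallower.

**Conservation.** Per column, `C = 1 − H/log2(20)` with
`H = −Σ f_k log2 f_k` over the 20 canonical amino acids. Gap mass is
excluded and the frequencies renormalized, because the entropy sum runs
over amino acids only; an all-gap column returns `NA` rather than raising,
so downstream feature rows can drop it.

## Species pairing

Species labels come from UniProt mnemonics (the token after `_`) or
`OX=`/`OS=` fields. Per species, the member with the highest identity to
the query is the candidate (ties break to the lowest row index — any
deterministic rule works; the lowest index is reproducible across runs).
Query-genome paralogs above 90% identity to the query are excluded from
candidacy outright. The reciprocity guard then requires each remaining
candidate to be closer to the query than to *every* retained query-genome
paralog in its alignment; candidates failing against any paralog are
dropped, taking the conservative, literal reading of the pairing rule. The
two query rows are always concatenated as row 1.

Four homology guards protect the concatenated alignment: shared
domain-family identifiers, overlapping hits to the same PDB chain (both
supplied as external two-column annotation tables — the package performs no
live database queries), a coevolution diagonal between the two segments
(below), and nonstandard amino acids in either query sequence.

## The Potts model and its fit

The joint distribution over aligned sequences is a pairwise Markov random
field on q = 21 states (20 amino acids + gap; synthetic alphabets may be
smaller). Because the partition function is intractable, the package
maximizes the *pseudo-likelihood*: the weighted sum over sites of the
conditional log-likelihood of each residue given the rest of its sequence,

> Σ_s w_s Σ_i −log softmax(h_i(a) + Σ_{j≠i} J_ij(a, x_j^s))[x_i^s]
> + λ_h‖h‖² + λ_J‖J‖².

Choices, and why:

- **Symmetric parameterization.** One coupling block J_ij is shared between
  the conditionals of sites i and j, rather than fitting asymmetric blocks
  and averaging. This halves the parameters, keeps the objective a single
  well-defined function with an exact gradient, and empirically recovers
  planted couplings as well as the asymmetric variant at these problem
  sizes.
- **Regularization.** λ_J = λ_base (q−1)(L−1), the standard scaling that
  keeps the per-coupling penalty commensurate with the number of competing
  parameters; λ_h = λ_base = 0.01 by default. The coupling-penalty scaling
  rule is fixed by the method; the base weights are conventional values,
  exposed as arguments.
- **Optimizer.** L-BFGS from a zero initialization, so the fit is
  deterministic given the data: zero is a stationary-friendly, basin-neutral
  start, and the objective is convex. Convergence is declared at a
  projected-gradient tolerance of 1e−4 with an iteration cap of 500;
  hitting the cap raises a condition carrying the final gradient norm
  rather than silently returning a half-converged model. The objective and
  exact analytic gradient are computed in C++ (O(n L² q) per evaluation)
  and verified against central finite differences in the test suite.
- **Gauge and scoring.** Coupling blocks are shifted to the zero-sum gauge
  over amino-acid states — the gap state is excluded, since gap "couplings"
  reflect alignment geometry, not contacts — and scored by Frobenius norm.
  The average product correction removes the rank-one background
  (row mean × column mean / grand mean over off-diagonal entries); a
  constant matrix maps exactly to zero. Note that a single nonzero entry c
  in a q-state block has gauge-fixed norm |c|(q−1)/q, not |c|: the gauge
  spreads the mass.
- **Diagonal exclusion.** Intra-segment pairs with |i−j| ≤ 5 are dropped
  from the coupling table: short-range couplings are dominated by chain
  geometry. Cross-segment pairs are never excluded.

## Scores and classifiers

**EVcomplex normalization.** Inter-protein corrected scores are divided by
the absolute value of the most negative inter-protein score, anchoring the
minimum at −1 and making the raw score invariant under uniform rescaling.
The published diversity normalization is defined in earlier work and not
restated in the protocol this package follows; `coevppi` uses
`g(N_eff/L) = min(1, sqrt(N_eff/L))` — identity for deep alignments, a
smooth shrink for shallow ones — records g in the table metadata, and
exposes it as a documented choice. A nonnegative minimum inter score makes
the transform degenerate; the scores are then flagged missing rather than
silently divided.

**Residue features.** The top-10 inter-protein couplings feed the contact
classifier with: the EVcomplex score; the conservation of the more
conserved of the two residues; the row's relative rank among *all* rows
(strictly-greater count + 1, over table size); and the larger of the two
residues' intra-protein enrichment. Enrichment is computed per segment —
the sum of corrected scores over the segment's top-L intra rows touching a
residue, normalized by the segment mean — because the feature is defined on
*intra-protein* couplings; a global variant would mix the two proteins'
score scales. The structure-aware model adds the smaller of the two
relative accessibilities and the precision of couplings ranked above the
row (evaluated over intra rows with known distances). With fewer than 10
inter rows, feature rows are padded with zeros and flagged.

**Regularization convention.** "Regularization weight" follows the
LIBLINEAR `C` convention: the penalized objective is
`penalty(w) + C · Σ log-loss`, equivalently a glmnet lambda of `1/(nC)`.
The residue model uses L1 at C = 0.05; the interaction model selects
features with L1 at C = 0.1 and refits the survivors with L2 (C = 1).
Class balancing for interaction training downsamples the larger class
without replacement under a fixed seed. Cross-validation folds are assigned
under the seed, making training bit-reproducible for a fixed row order.

**Calibration.** Thresholds are calibrated by exhaustive enumeration over
the observed score values (a prediction is positive at `score ≥ t`):
precision mode returns the smallest threshold reaching the target
precision, FPR mode the smallest threshold keeping FPR at or below target.
The returned threshold is the midpoint to the next lower score, so
perfectly separated classes yield the gap midpoint. Unattainable targets
are flagged and the best achievable operating point is returned — the
numeric value of any precision threshold is data-dependent and must be
recalibrated on the user's own benchmark.

**Diagonal artifact.** The check flags a table when at least half of the
top-10 inter rows satisfy |pos_A − pos_B| ≤ 2 in segment-local coordinates.
The band and fraction are exposed: on realistic protein lengths
(L ≳ 100) random tables false-flag well under 1%, but on very short
segments the ±2 band covers a large fraction of the plane and the check is
correspondingly conservative.

## Structure comparison

Distances are minimum heavy-atom distances, minimized again across all
supplied structures, so adding a structure can only decrease or preserve a
distance; residues unresolved everywhere stay missing and are excluded from
both numerator and denominator of precision. Contacts use distance < 8 Å
(strict); the "contacting pair" convention at the protein level is ≥ 20
inter-residue pairs under 5 Å. Solvent accessibility is computed directly
by Shrake–Rupley sphere sampling: 960 deterministic golden-spiral points
per atom (no RNG), probe 1.4 Å, Bondi-style van der Waals radii, hydrogens
excluded, normalized by the Tien et al. theoretical per-residue maxima. An
adapter ingests externally computed per-residue accessibility tables for
parity checks. Alignment-position-to-residue mapping is an explicit input
table; automatic structure mapping is out of scope.

## The synthetic generator

`make_planted_potts` plants Gaussian fields (sd 0.1) and rank-one
±strength coupling blocks (pre-gauge Frobenius norm exactly q·strength) on
randomly chosen intra- and inter-segment pairs, keeping intra pairs outside
the diagonal-excluded band. `gibbs_sample` runs a single-site Gibbs chain
with a 500-sweep burn-in and thinning of 10 — single-chain thinning leaves
mild autocorrelation between consecutive samples, which slightly depresses
the effective N_eff of the output; the defaults are documented for exactly
that reason. Species fixtures mutate query sequences by a bounded
per-species rate (5–25%) and derive decoy paralogs by at least 30% further
mutation, so the true ortholog is provably the species member closest to
the query. Feature fixtures are unit-variance Gaussian classes whose Bayes
AUC is `Φ(d/√2)` in closed form.

What the generator does **not** emulate: phylogenetic correlation between
sequences (real alignments are trees, not i.i.d. samples — APC absorbs part
of that bias but tests cannot certify it), insertions/deletions (synthetic
alignments are gap-free), biased amino-acid composition, alignment errors,
and paralog interleaving more adversarial than the decoy construction.
Passing tests therefore demonstrate correctness of the inference machinery
under the model's own assumptions, not performance on real proteomes.

## Test problem sizes

The suite exercises the chain at sizes chosen to make ground-truth recovery
decisive yet quick: gradient checks at L ≤ 5, q ≤ 4; planted-coupling
recovery at L1 = L2 = 30, q = 8, 2000 sequences (coupling strength 1.5);
pipeline determinism at L1 = L2 = 30, q = 6, 400 sequences; classifier
recovery at n = 5000; pairing at 25 species with two decoys each. The
brute-force weight oracle runs on ~200 rows.

## Known limitations

- The PLM fit is dense in L²q² parameters: memory and time grow quickly
  beyond a few hundred concatenated columns; the implementation targets
  single pairs, not proteome scans.
- Classifier coefficients shipped by a user must be trained on their own
  benchmark; the package deliberately ships no fitted coefficients, because
  contact models are only as transferable as their training distance
  distributions.
- The EVcomplex diversity normalization g is a documented package choice
  (see above); scores across pipelines that use a different g are not
  directly comparable, though rankings within a pair are unaffected.
- Species parsing covers UniProt conventions; other header dialects need a
  pre-pass.
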