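---
title: "Assessing predicted protein complexes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing predicted protein complexes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capriqa)
```

This vignette explains what capriqa computes, the assumptions behind each
quantity, the numerical choices made where the protocol leaves room, and
what the synthetic test data does and does not establish about behaviour on
real structures.

## The assessment model

A predicted complex is compared to a reference (target) structure through
quantities defined on a *common residue set*. Submission formats allow
arbitrary residue numbering, so the correspondence between model and target
residues is established by global sequence alignment (identity +1, mismatch
0, linear gap penalty 1), never by residue numbers. Aligned positions enter
the common set only if both residues carry backbone atoms; models below a
per-target sequence-identity gate (default 70%) are not assessed at all.
The gate is inclusive (exactly 70% passes). A batch mode
(`intersect_common_residues()`) restricts the set to residues present in
every model of a submission round, which is the whole-experiment
convention; per-model mapping is the default because it is the more useful
library primitive.

With the correspondence fixed, one model/target interface comparison
produces:

* **f(nat)**, **f(non-nat)** — residue–residue contacts are heavy-atom
  pairs within 5 Å (inclusive). Target contacts are computed over *all*
  target residues, not just the common set; a model contact is native if
  its residues map onto a target contact pair. f(non-nat) divides by the
  number of model contacts; model contacts involving unmapped residues
  count as non-native, since they cannot correspond to anything in the
  target.
* **L-rms, θ_L, d_L** — the model receptor is superposed onto the target
  receptor by least squares (Kabsch, uniform weights, reflections
  excluded); L-rms is the unfitted backbone RMSD of the ligand that
  results, θ_L the rotation angle of the residual ligand-on-ligand fit,
  and d_L the residual displacement of the ligand centre of mass. For
  homodimers, where receptor and ligand roles are arbitrary, both role
  assignments are evaluated and the lower L-rms kept, so a symmetric model
  is never penalised by an arbitrary role choice.
* **I-rms** — backbone RMSD over the target-defined interface residues
  (any heavy atom within 10 Å of the partner subunit) after those residues
  are themselves optimally superposed. The re-fit means any error a rigid
  motion can absorb does not count.
* **clashes** — cross-subunit heavy-atom pairs strictly below 3 Å. The
  contact rule is inclusive ("within 5 Å") while the clash rule is strict
  ("below 3 Å"); both readings are taken literally from the protocol.

The tier criteria (high/medium/acceptable/incorrect) are cumulative with
an OR between the L-rms and I-rms conditions, thresholds inclusive on the
admitting side (≥ for f(nat), ≤ for the RMSDs). A model satisfying a
higher tier is never demoted by the band bounds of a lower one.
Disqualification is a population property: the threshold is the mean clash
count of the submitted set plus two standard deviations (sample SD, n−1;
the protocol does not specify the estimator, so this choice is documented
and configurable), models strictly above it are flagged and classified
incorrect. With fewer than two models there is no population to calibrate
and the threshold is +Inf with a warning.

The I-rms interface cutoff deserves a note: the protocol defines the I-rms
residue set "less stringently" than the contact rule but does not print a
number. This package uses the protocol's stated residue-level cutoff of
10 Å, configurable via `capri_config(interface_cutoff =)`.

## Homo-oligomers

For homo-oligomeric targets the package makes no attempt to decide the
biologically relevant assembly. Candidate interfaces are enumerated from
the (possibly symmetry-augmented) target: every chain pair's buried area is
computed, pairs above a configurable floor (default 400 Å², the
conventional size below which crystal-packing contacts dominate) are kept,
symmetry-equivalent duplicates are merged, and the survivors are ranked by
decreasing area. Crystallographic neighbours are generated only from
explicitly supplied operators (4×4 transforms); improper operators are
rejected because the molecules are chiral.

Duplicate merging is a place where the protocol is silent. Two pairs are
considered equivalent when their areas agree within 1 Å² *and* their
residue-number contact fingerprints are identical. Because the
Shrake–Rupley quadrature is not exactly rotation invariant, every pair's
area is evaluated in a canonical intrinsic frame (axes through the pair's
extremal atoms); congruent pairs then receive numerically identical areas
and the 1 Å² tolerance is meaningful. Mirror-congruent pairs intentionally
do not merge.

Model chains are matched to target subunits exhaustively: every model
chain pair, against every assessed interface, under both role assignments,
restricted to assignments that pass the sequence-identity gate. Per
interface the best metrics are kept with the tie-break chain: higher tier,
then lower I-rms, then lower L-rms, then higher f(nat). When the model has
as many chains as the target, whole-model bijections are also enumerated
(≤ 4! = 24 for the tetramers this protocol covers, so exhaustive search is
exact and cheap); `simultaneous_capture()` then asks whether a *single*
bijection reaches a required tier on all required interfaces — the
question that separates "predicted both tetramer interfaces" from
"predicted each interface in a different, mutually incompatible way".
Heterocomplexes are the degenerate case: the identity gate leaves one
valid assignment per chain and the same code path applies.

## Subunit accuracy

`gdt_ts()` scores an individual subunit against its target in
sequence-dependent mode: for each cutoff (1, 2, 4, 8 Å) it searches for
the rigid superposition placing the most corresponded CA atoms within the
cutoff, and averages the four percentages. The search seeds fits from all
contiguous windows of lengths 3, 5, 7 and the full chain and refines each
seed by iterating "fit on inliers, recollect inliers" to convergence (at
most 20 iterations); fits found at smaller cutoffs seed larger ones, which
makes the per-cutoff fractions non-decreasing by construction. Chains of
at most 12 residues are scored by exhaustive subset search instead — one
fit per subset serves all cutoffs — so tiny instances are exact. The
sequence-independent LGA_S score of the external LGA program is *not*
reimplemented; on real CASP data this GDT_TS analogue is expected to track,
not equal, values produced by LGA, whose exact search schedule is not
public.

## Surface areas

Buried areas come from a Shrake–Rupley implementation: each heavy atom is
inflated by the probe radius (1.4 Å) and sampled with a deterministic
golden-spiral lattice (960 points by default; the quadrature error on an
isolated sphere is well under 1%). Van der Waals radii are an element-keyed
table shipped as plain text, with a 1.8 Å fallback for unlisted elements —
a fixed table keeps results deterministic across environments. The
interface area follows the PISA convention of half the total buried area;
both numbers are reported to avoid convention confusion. No free-energy or
complexation-significance estimate is attempted: interface size alone does
not decide biological relevance, and the package deliberately reports
areas and leaves the oligomeric-state call to the user.

## Synthetic data: what it emulates and what it does not

The generator builds backbone-only (N, CA, C, O) subunits with ideal local
geometry — an α-helix, an extended strand, or a compact self-avoiding
walk — assembles exactly C2-symmetric dimers and exactly D2-symmetric
tetramers (the four chains are the literal D2 orbit of one subunit), and
produces decoys by rotating the ligand about its centre of mass and
translating it, optionally with Gaussian coordinate noise or swapped chain
labels. Everything is seeded and regenerates byte-identically.

The value of these fixtures is that their ground truth is analytic: a pure
translation t must yield L-rms = d_L = |t| and θ_L = 0 *exactly*; a pure
rotation φ about the ligand centre must yield θ_L = φ and d_L = 0; a
relabelled symmetric model must score identically to the original; the D2
tetramer must expose exactly two interface classes. The test suite and the
acceptance script verify these closed forms to 10⁻⁶ and check the fast
implementations against independent oracles (an O(N²) contact search, a
quaternion-method superposition, a truth-table classifier, an exhaustive
GDT subset search).

What passing these tests does **not** show: behaviour on real structures
with side chains, missing atoms and loops (the fixtures are backbone-only,
so side-chain-mediated contacts are never exercised), realistic decoy
energetics (perturbations are rigid-body, not docking-generated), or
agreement with any specific historical assessment, which depended on
per-target assessor choices (which interfaces to assess, per-target
identity gates) that are inputs here, not outputs.

## Problem sizes and tolerances

The shipped tests run on 10–60-residue subunits, decoy populations of a
few dozen models, 240–1920 quadrature points, and 100-fixture oracle
sweeps — sizes chosen so the full suite completes in about a minute while
still exercising every code path at meaningful scale. Superposition
rejects sets with fewer than 3 points or collinear geometry (no unique
rotation); near-planar sets are handled with the standard sign correction
so reflections can never be returned. Classification rejects non-finite or
out-of-range metrics rather than guessing. θ_L is clamped into [0°, 180°]
via the trace formula; ties in the receptor/ligand role choice go to the
lower L-rms; ranking ties break by group identifier so orderings are total
and reproducible from any input order.
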