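---
title: "Inverse estimation of m6A stacking energies from base-pairing probabilities"
author: "stackGrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse estimation of m6A stacking energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stackGrad)
```

## The problem

Thermodynamic RNA secondary-structure prediction rests on nearest-neighbor
energy parameters.  For modified nucleotides such as N6-methyladenosine
(m6A, written `6` here) these parameters are scarce: measuring them by
optical melting or molecular dynamics is laborious.  Base-pairing
probabilities, however, are becoming measurable at scale through chemical
probing.  `stackGrad` solves the corresponding inverse problem: given
sequences and their (marginalized) base-pairing probabilities, recover the
m6A-containing stacking energies that generated them.

The forward model is the McCaskill partition function; the inverse machinery
is analytic differentiation of that dynamic program with respect to the
energy parameters, driving plain gradient descent on an L1 loss.

## The energy model

Sequences live on the alphabet `{A, C, G, U, 6}` with allowed pairs AU, UA,
GC, CG, GU, UG, 6U and U6, a minimum hairpin loop of 3 nt, and free energies
(kcal/mol, 37 °C):

* **Hairpins** (`f1`): loop-length initiation table (Turner 2004), with
  Jacobson–Stockmayer extrapolation `E(n) = E(30) + 1.75 RT log(n/30)` past
  30 nt.
* **Two-loops** (`f2`): adjacent pairs form a *stack* — a canonical Turner
  value, or one of the **15 trainable m6A classes** when any participating
  base is `6`; non-adjacent pairs are bulges/internal loops scored by total
  loop length.
* **Multiloops**: the linear model `f3 + f4·(#unpaired) + f5·(#branches)`
  with base-type-independent constants (9.3, 0.0, −0.9 kcal/mol).

Deliberately absent: terminal mismatches, AU/GU helix-end penalties,
dangles, special hairpins, coaxial stacks.  Recovery experiments are
self-consistent (the ground truth is generated under the same model), so
this simplification does not bias the inverse problem — but it does make
ensembles *softer* than a full Turner model, which matters below.

The 15 m6A stack classes follow the standard duplex notation: `6CUG` is
5'-6C-3' paired with 3'-UG-5', i.e. a 6·U pair stacked on a C·G pair.  Each
physical stack read from either strand resolves to one canonical class
(12 singly modified = 6 canonical pairs × 2 orientations, plus 3 unique
doubly modified).  The packaged reference values (`gtTheta()`) are the
optical-melting determinations of Kierzek et al. (2022).

## Forward recursions and their derivatives

Inside quantities `Z`, `Z1`, `Zb`, `Zm`, `Zm1` and the outside quantity
`Wb` are filled by the usual O(N^4) recursions (the two-loop double sum is
unrestricted — no 30-nt interior cap), giving

    P_ij = Zb_ij · Wb_ij / Z_1N ,    MBPP_i = Σ_j P_ij .

Two conventions needed fixing where the textbook notation is abridged;
both are validated against exhaustive enumeration (below):

* every unpaired multiloop stretch of length ℓ contributes `f4·ℓ`, and
  each branch contributes `f5` exactly once — which requires an explicit
  branch factor for the last branch in the multiloop terms of both `Zb`
  and `Wb`;
* the exterior split in `Z` runs over all prefix lengths including the
  empty one.

Because theta enters the model *only* through the stack case of `f2`, the
derivative of every recursion with respect to a stack class is obtained by
the product rule with a single nonzero seed: the 0/1 indicator of that
class.  One extra table set per requested class is filled in the same cell
order as the forward pass, reusing the forward tables (`dZb` vanishes
wherever `Zb` does, and `f1`, `f3`, `f4`, `f5` have zero derivative, which
prunes most terms).  All classes realizable in a sequence are swept
jointly; classes whose stack cannot occur are skipped and their gradients
are exactly zero.  Finally

    dP_ij = ((dZb·Wb + Zb·dWb)·Z − Zb·Wb·dZ) / Z² .

No rescaling or log-space arithmetic is used, so sequence length is capped
at 200 nt (a hard validity guard, comfortably above the 150-nt sequences
the package targets).

## The optimizer

Training minimizes `loss = Σ_i |MBPP_i^GT − MBPP_i|` per sequence, with one
parameter update per sequence per epoch (strict SGD in fixed order;
optional seeded shuffling), subgradient `sign(0) = 0`, no momentum or
schedules, and a divergence guard at |theta| > 50 kcal/mol.  The default
initial value is −1.00 kcal/mol for all 15 classes.

**Units of the learning rate.**  The descent operates on theta expressed in
centi-kcal/mol — the integer energy quantum used by compiled thermodynamic
folding engines — so the update in kcal/mol is

    theta ← theta − lr · (0.01)² · ∂loss/∂theta ,

exposed as the `energyUnit` argument (default 0.01).  The measured loss
gradients of 50-nt designs are of order 0.1–2.5 per kcal/mol; with the
default `lr = 50.0` this yields kcal-scale steps of 5·10⁻⁴–10⁻², which
descends smoothly, whereas a literal kcal-unit step of 50 would overshoot
by three orders of magnitude and trip the divergence guard within one
epoch.  The conversion is a units convention, not a tuned hyperparameter.

## The sequence designers

`designMinimumSet()` emulates a minimal training corpus: 50-nt stem-loops
with 10 random flanking bases on each side, a 10-bp stem (bases 11–20
paired to 40–31) and a 10-nt random loop.  One designated m6A stack
occupies stem offsets p, p+1 for p = 1…9; the remaining stem positions are
random Watson–Crick fillers.  9 positions × 15 classes = 135 sequences, and
every class is exercised.  Flanks and loops are redrawn (≤ 50 attempts)
if they would form a competing complementary run of ≥ 6 bp against the
stem.  `designRandomModified()` / `designFullyModified()` /
`designEvalRandom()` produce the uniform-random cohorts (150 nt with 8
modifications, fully modified variants, and 50-nt evaluation sets with
1/2/4/8 modifications).

What the generator does *not* emulate: real probing noise structure
(position-correlated, reactivity-dependent), naturally occurring sequence
composition, or modification context preferences.  Passing recovery tests
therefore demonstrates correctness of the inverse machinery under the
model's own forward process, not measurement realism.

The noise model multiplies each upper-triangle probability once per
unordered pair by `(1 + ξ)`, `ξ ~ N(0, σ²)`, clips at zero (no upper clip
— marginals may exceed 1, which the L1 loss tolerates) and re-marginalizes.

## Validation strategy and numerical choices

* **Enumeration oracle** (`enumerateStructures()`, N ≤ 18): a pure-R,
  structurally independent second implementation that lists every nested
  structure, scores it by loop decomposition, and yields Z, P, dZ/dtheta
  and the MFE by direct summation.  The dynamic programs agree with it to
  < 1e−9 relative (machine precision in practice) on random sequences with
  0–4 modifications, including multiloop-bearing cases with a nonzero
  `f4`, which pins down the multiloop conventions above.  The enumeration
  itself is cross-checked against a Nussinov-style counting DP.
* **Finite differences**: analytic `dP` and `dloss` match central
  differences (step 1e−4 kcal/mol) to < 1e−5 / 1e−4 relative wherever FD
  is numerically meaningful; entries with |dP/dtheta| < 1e−7 sit below the
  FD roundoff floor (probabilities carry ~1e−16 error, so a central
  difference over 2·10⁻⁴ resolves nothing smaller than ~1e−12) and are
  compared absolutely.  Loss-gradient checks skip sequence/parameter
  combinations within `10·h·|dMBPP|` of an L1 kink.
* **MFE**: Zuker recursions mirror the inside decomposition exactly;
  traceback ties prefer hairpin > two-loop > multiloop, then smallest
  (h, l), making structures deterministic.  Energies match the enumerated
  minimum to 1e−12 (addition order differs).
* **Problem sizes** in the shipped tests: 100 oracle sequences (N ≤ 16),
  50 FD sequences (N ≤ 30), the 27-sequence reduced recovery (3 classes ×
  9 positions, 150 epochs), the full 135 × 300-epoch protocol, a 5-point
  noise ladder on the reduced design, and 100–1000-sequence evaluation
  cohorts — all chosen so the whole suite runs in minutes on one core.

## Design choices where the ground was open

* **Temperature** is fixed at 37 °C (`RT = 0.6163`, β = 1.6225 mol/kcal),
  the Turner convention.
* **RMSD** between probability matrices averages over *all* upper-triangle
  entries (a `entries = "nonzero"` switch restricts to entries nonzero in
  either matrix); recall/precision of two empty structures is defined as
  (1, 1).
* **Reduced recovery classes** 6CUG, UA6U, U66U: one strongly stabilizing,
  one mid-range, one destabilizing doubly-modified stack, spanning the
  reference table's range.
* **Update granularity**: strictly one update per sequence (135 × 300 =
  40 500 updates), no mini-batching, no reshuffling by default.

## Known limitations

* The initiation-only loop tables make ensembles softer than a full Turner
  model: a handful of m6A-sensitive pair probabilities in the designed
  stem-loops stay mid-range, so near the optimum the per-sequence L1
  gradient does not vanish and constant-rate SGD settles into a
  steady-state oscillation of ~0.01–0.04 kcal/mol for the most exposed
  classes.  In the shipped full-protocol run the total absolute recovery error
  across the 15 classes is ~0.09 kcal/mol and is dominated by the worst
  class (6AUU), which oscillates ~0.04 around its reference value;
  10/15 classes land exactly on the reference at two decimals.  Noisy-data totals scale accordingly (they are
  ~1.3–1.5× the softest published values at σ = 0.2–0.3).
* Only stacking parameters are trainable; loop initiation energies for
  modified contexts are out of scope (the machinery would extend, since
  any energy term entering `f2` linearly differentiates the same way).
* No pseudoknots, no suboptimal-structure enumeration, no partition
  function rescaling (hence the 200-nt cap), single-threaded.
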