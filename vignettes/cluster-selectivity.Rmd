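---
title: "Modelling enzymatic enantioselectivity with cluster models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling enzymatic enantioselectivity with cluster models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmclust)
```

## The model and its assumptions

The cluster approach models an enzymatic reaction with a limited active-site
region — typically a few hundred atoms — treated quantum-mechanically, while
the rest of the protein enters only through two surrogates: a homogeneous
dielectric continuum for long-range electrostatics, and a *coordinate-locking
scheme* that fixes selected atoms (normally the truncation points where
covalent bonds to the protein backbone were severed) at their
crystallographic positions, preserving the pocket's shape during geometry
optimization.

For a desymmetrization reaction the substrate is *meso*: the two
enantiomer-forming pathways start from the same enzyme–substrate complex, so
differential substrate binding drops out and the enantiomeric excess is
governed by the two activation barriers alone. With attack at C1 giving the
*S,S* product and at C2 the *R,R* product, transition-state theory gives

$$\Delta\Delta G^\ddagger = RT\,\ln\frac{1+ee}{1-ee},
\qquad ee = \tanh\!\frac{\Delta\Delta G^\ddagger}{2RT},$$

with the package-wide sign convention *negative = R,R-favored* (matching
$\Delta\Delta E^\ddagger = E^\ddagger_{C2} - E^\ddagger_{C1}$). When several
transition-state conformers feed each product, `boltzmann_ee()` applies
Curtin–Hammett weighting, $ee = (W_{SS}-W_{RR})/(W_{SS}+W_{RR})$ with
$W = \sum_i e^{-E_i/RT}$; for one conformer per face this reduces exactly to
the two-state formula, which the test suite verifies to 1e-12.

Corrected total energies follow the usual two-level protocol: electronic
energy, solvation and dispersion from the large-basis single point, the
zero-point correction from the optimization-level frequency job. The
comparison against experiment is therefore enthalpic
($\Delta\Delta E^\ddagger$ vs $\Delta\Delta G^\ddagger_{expt}$) — a known
approximation of the approach, which the report's column names state
honestly.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| temperature | 298.15 K | reproduces the reference experiment-to-energy conversions at the printed 0.1 kcal/mol precision |
| cap C–H / N–H / O–H / S–H length | 1.10 / 1.01 / 0.97 / 1.34 Å | standard link-atom values; the cap sits on the severed bond vector |
| frozen set | caps + their attachment heavy atoms | the minimal locking scheme; an explicit selector list in the recipe overrides it (caps are always frozen) |
| clash threshold (mutation) | 1.0 Å | closer contacts warn but do not abort: mutants feed a downstream optimization that relieves clashes |
| conformer-consistency threshold | 0.3 Å heavy-atom per-residue RMSD | a quantified proxy for the visual "same local minimum" check; configurable |
| gas constant | 1.98720425e-3 kcal/(mol K) | all energies are kcal/mol internally; hartree-based engines convert at ingestion (627.509474) |

Protonation is deliberately **explicit user input**: every titratable
residue in a model (Asp/Glu/His/Tyr/Cys/Arg/Lys) must carry a declared state
before hydrogens are added. Automatic pKa guessing inside a truncated
cluster would be silently wrong more often than helpfully right.

## Design choices where the design was open

* **Alternate locations** resolve to the highest-occupancy conformer, ties
  to the first listed — standard practice.
* **Frozen-flag persistence.** PDB has no native locked-atom field, so the
  writer emits `REMARK 250 QMCLUST FROZEN/CAP` records listing serials and
  the reader recovers them; flags therefore survive a round trip and every
  downstream job spec copies them mechanically.
* **Mutations** keep the backbone and C$\beta$ bitwise and grow the new side
  chain from idealized internal coordinates, inheriting the parent's chi1
  where the target has the corresponding torsion. Inheriting chi1 best
  preserves the crystal-frame pocket shape without a rotamer search, which
  would be spurious precision before a QM re-optimization anyway. Mutations
  at different residues are strictly local, hence commute.
* **Truncation deletes a connected component**: the severed bond is removed
  from the residue's bond graph and everything reachable through the removed
  atom is discarded, so one rule cleanly removes a backbone or a side-chain
  tail; cutting inside a ring is refused.
* **Multiple TS conformers** per pathway: the lowest total energy defines
  the pathway barrier in `delta_delta_barrier()` (the Curtin–Hammett limit);
  the fully weighted alternative is `boltzmann_ee()`.
* **TS validation**: a saddle-search result with a known imaginary-mode
  count is accepted only when that count is exactly 1; an unknown count is
  accepted with a warning rather than rejected, since frequency data may
  legitimately be absent from an ingested table.

## The toy active site: what it does and does not establish

`generate_toy_site()` builds a deterministic, desk-scale stand-in for a
crystal structure: a cyclopentene-oxide analogue whose epoxide oxygen
bridges C1/C2, an acid aspartate with a carboxylate oxygen placed 2.7 Å
from the epoxide oxygen (the proton-donor contact), a base aspartate with a
water oxygen 2.9 Å from its carboxylate (the nucleophile being activated),
and hydrophobic pocket residues (Leu/Ile/Met/Val at analogue positions) on
a ring of radius 5.2 Å with ±2 Å axial offsets. A 0.02 Å Gaussian jitter
(seeded) is applied to the pocket residues only, so the catalytic contacts
stay exact; the layout was chosen once so that no spurious inter-residue
bonds appear at the bond-perception threshold.

This emulates the *topology and bookkeeping* of a real active site — residue
selection, truncation, capping, locking, mutation, hydrogen templates — not
its physics. A green builder test establishes that the construction rules
are honored on a well-posed input; it says nothing about real barriers,
optimized geometries, attack angles, or the 259-atom composition of a
crystal-derived model, all of which require actual DFT and are explicitly
out of scope. Energetic numbers in the end-to-end tests come from a bundled
lookup table constructed to reproduce the published barrier set, so those
tests verify the assembly arithmetic and the sign conventions, not the
quantum chemistry.

The toy engine (harmonic bonds from covalent radii plus soft exponential
repulsion, gradient descent on unfrozen atoms) exists to exercise the engine
contract: it is rotation/translation invariant, deterministic, honors frozen
atoms, and supports `minimize` and `single-point` only — a saddle search on
a two-term force field would be theatre, so the pipeline's toy mode degrades
to single points and says so.

## Numerical choices and degenerate inputs

* ee→ΔΔG errors outside (−1, 1) and warns beyond |ee| = 0.999 where the
  conversion diverges; the inverse clamps to the largest double below 1 so
  the round-trip identity holds on the full grid.
* `boltzmann_ee` shifts by the minimum energy before exponentiating
  (log-sum-exp), so absolute and relative energies give identical results.
* Superposition uses the Kabsch SVD with the determinant sign correction
  (proper rotations only) and refuses fewer than 3 pairs or a collinear
  subset; overlay comparisons superpose on the shared frozen subset — the
  crystallographic frame of the cluster — before per-residue RMSDs.
* Angles clamp the cosine into [−1, 1], so near-collinear probes return
  exactly 180° instead of NaN.
* Bond perception uses 1.25 × the sum of covalent radii with a 0.4 Å floor.
* The barrier table keeps full precision; rounding to the reporting
  precision of 0.1 kcal/mol happens only at display.

## Known limitations

* Enthalpy stands in for free energy beyond the ZPE correction.
* Side-chain templates cover the standard residues except tryptophan and
  use idealized geometry with a single inherited torsion — adequate as input
  to re-optimization, not as final geometry.
* Hydrogen placement is template-count-based; exotic ligands need entries
  in the template table (the toy epoxide ships one).
* The toy world's variant ladder reuses the published mutation compositions
  where they are printed; the third R-branch step is a synthetic stand-in
  because its composition is not machine-readable in the source material.
* No scheduler/queue integration: real engines plug in through the results
  table or the `run_engine` generic.
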