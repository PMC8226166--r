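---
title: "Methods: PTM-aware analysis of peptide dimer trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PTM-aware analysis of peptide dimer trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmdimer)
```

## The problem

The N-terminal tail of histone H3 is an intrinsically disordered region
whose post-translational modifications (PTMs) — phosphorylation of Ser/Thr,
methylation of Lys/Arg, acetylation of Lys — modulate chromatin structure.
Phosphorylation in particular acts as a charge rheostat: the unmodified
H3(1–12) tail is strongly basic, each phosphate removes two charge units,
and a sufficiently modified tail becomes an exactly neutral polyampholyte.
How two such tails associate with each other — which residue pairs stay in
contact, for what fraction of the time, and how much surface the dimer
buries — is typically studied with long molecular-dynamics simulations of
two-chain systems.

`ptmdimer` implements the *analysis* layer of such a study as reusable,
tested code: a formal-charge model for annotated, variably modified
peptides; heavy-atom close-contact detection and the time-averaged contact
count $N_{cc}$; residue-pair interaction-persistence maps with salt-bridge
typing; Shrake–Rupley solvent-accessible surface area (SASA) and the
buried-area statistic $\Delta A$; and a synthetic two-chain trajectory
generator that provides exact ground truth for every stage, because the
original MD trajectories of the motivating system are not publicly
deposited.

## The charge model

A peptide is an annotated string such as
`ART[ph]K[me3]QTAR[me2]KSTG-NME`: one-letter codes, bracketed PTM tags
(`ph`, `me1`, `me2`, `me3`, `ac`), an optional `ACE-` N-terminal acetyl
cap and `-NME` C-terminal N-methyl amide cap. The formal net charge at
pH ≈ 7 is a sum of independent group contributions:

| group | contribution |
|---|---|
| free N-terminal amine / acetyl cap | +1 / 0 |
| free C-terminal acid / N-methyl amide cap | −1 / 0 |
| Arg, Lys side chain (any methylation state) | +1 |
| acetyl-Lys | 0 |
| Asp, Glu | −1 |
| His | 0 |
| phospho-Ser/Thr/Tyr | −2 |
| all other side chains | 0 |

Assumptions: the phosphate is fully deprotonated (−2), the standard state
for a phosphomonoester dianion at neutral pH; histidine is treated as
neutral; no pK~a~ titration model is attempted. Methylation never changes
the formal charge of Lys or Arg — it redistributes, but does not remove,
the positive charge. Asp/Glu and acetyl-Lys do not occur in the four
built-in study peptides but are defined so the model is total over the 20
amino acids. With these rules the four built-in peptides
(`builtin_peptides()`) carry charges +5, +4, +3 and 0:

```{r charges}
vapply(builtin_peptides(), compute_formal_charge, integer(1))
```

## Trajectories

The native trajectory format is multi-model PDB: human-inspectable,
universally writable, and entirely adequate at the scale of a few hundred
analysed frames. The reader enforces the container invariants (at least
one model, exactly two chains, an identical atom roster in every model),
drops water and counter-ion records with a reported count, and takes the
element from columns 77–78 when present, otherwise from the first
alphabetic character of the atom name (sufficient for peptide chemistry,
which has no two-letter elements). Modified residues are written as
`TPO`, `SEP`, `PTR`, `M3L`, `MLY`, `MLZ`, `ALY`, `DA2`, `NMM`; a YAML
topology sidecar maps each chain to its annotation string, which is the
authoritative PTM record. Coordinates are Å throughout; chains are
reported in lexical order; no periodic-boundary handling is attempted
(the analysis assumes imaged, whole molecules).

## Close contacts and $N_{cc}$

A close contact is a pair of non-hydrogen atoms strictly closer than 4 Å.
All analyses run on the heavy-atom view of the trajectory. $N_{cc}$
counts *inter-chain atom pairs* (each unordered pair once) and is
averaged over frames; residue-pair incidence uses the any-atom criterion
(at least one heavy-atom pair within the cutoff). The neighbour search is
a cell list with cells of edge equal to the cutoff; the test suite checks
it against an $O(n^2)$ double-loop oracle on randomized frames, plus
symmetry under chain relabelling, monotonicity in the cutoff and
invariance under rigid motions.

A residue pair is typed as a salt bridge when one partner carries a
phosphate (phospho-Ser/Thr/Tyr) and the other a guanidinium (Arg, any
methylation state) or ammonium/methylammonium group (Lys, unless
acetylated); the four categories are `R_pS`, `R_pT`, `K_pS`, `K_pT`, and
everything else is `other_contact`. Classification is by residue identity
and PTM state, not by charged-group geometry — at 4 Å residue granularity
the distinction rarely matters, and the typing is meant as a label on the
persistence map, not a geometric definition of an ion pair.

## Persistence maps

The persistence of a residue pair is the fraction of frames in which it
is in contact — an exact rational (frame count over total frames), so
recovery of scheduled fractions can be tested for equality, not
approximate agreement. Reported maps keep pairs with persistence at or
above a threshold, 10% by default and *inclusive*, so a pair present in
exactly 10% of frames is reported. Intramolecular pairs separated by two
or fewer positions in sequence are excluded (bonded and near-bonded
neighbours are trivially in contact; the window is configurable), and
intermolecular pairs are never excluded. Entries are sorted by descending
persistence and exported as TSV and as JSON with a line width mapped
linearly from the threshold (thinnest) to 98% (thickest), ready for a
linear interaction diagram.

## SASA and $\Delta A$

SASA uses the Shrake–Rupley sphere-point method with test points on a
deterministic golden-section spiral — no random number generator, so
areas are bit-reproducible. Defaults: probe radius 1.4 Å (water), 960
points per atom, Bondi-derived radii C 1.70, N 1.55, O 1.52, S 1.80,
P 1.80 Å; hydrogens are excluded and no united-atom inflation is applied.
At 960 points an isolated atom's area is exact to well under 0.5%, and a
two-sphere configuration agrees with the closed-form spherical-cap
solution to within 2%; the lattice error shrinks monotonically with the
point count.

The buried area of a two-chain frame is $A_1 + A_2 - A_{12}$, where
$A_{12}$ is the SASA of the dimer frame and $A_1$, $A_2$ are the SASA of
each chain computed *on the in-complex coordinates with the partner
deleted*. $\Delta A = \langle A_1 + A_2 - A_{12}\rangle$ is the average
over frames. The in-complex convention (rather than independently
relaxed monomers) is deliberate: it makes the buried area a per-frame
observable of the same trajectory, which is what a time average requires,
and it guarantees $A_1 + A_2 \ge A_{12}$ per frame up to the lattice
resolution (0.1 Å² tolerance). Chains placed ≥ 20 Å apart give
$|\Delta A| < 0.1$ Å².

## The synthetic generator

The generator emulates the one thing the analysis needs from a
trajectory — two 12-residue chains whose inter-chain residue contacts
follow a known on/off schedule — and nothing else. Chains are rigid
copies of an ideal geometry built from internal coordinates
($\varphi,\psi$ = (−57°, −47°) helical or (−135°, 135°) extended; standard
bond lengths and angles), with a reduced side chain: CB plus a single tip
pseudo-atom whose element matches the interaction chemistry (N for
Arg/Lys, P for phospho-Ser/Thr, C otherwise). Charged tips are placed at
the reach of their charged group (4.0–4.3 Å beyond CB); neutral side
chains get a compact 1.2 Å stub. The tip lengths are interaction radii
for the reduced model, not calibrated side-chain geometry.

An `association_schedule` lists episodes (residue pair, target fraction,
contact distance ≤ 3.2 Å). Episode on-frames are nested prefixes of a
single seeded shuffle of the frame order: the most persistent episode is
on in the largest prefix, and so on. Nesting is what makes the problem
tractable — a frame's configuration is fully described by its engagement
depth, so only `n_episodes + 1` distinct rigid placements of chain B are
ever needed, and overlapping episodes are geometrically consistent by
construction. For each depth a placement is solved numerically
(Nelder–Mead over the 6 rigid degrees of freedom, seeded by an SVD fit of
the engaged tips onto displaced targets) and then *verified* against hard
margins; an unsatisfiable engagement set raises an infeasibility error
naming the episodes rather than emitting compromised geometry.

**Noise and provable exactness.** Positional noise is Gaussian with the
displacement norm of each atom clipped at 1.3σ. A residue-pair minimum
distance can therefore shift by at most 2.6σ between the rigid and the
noisy geometry. The generator verifies every engaged pair at distance
≤ 4 − 2.6σ and every other inter-chain pair at ≥ 4 + 2.6σ + 0.03, so no
pair can cross the 4 Å classification boundary in any frame: the analysis
pipeline recovers every scheduled fraction *exactly*, noise included.
Unclipped Gaussian noise cannot give this guarantee — with σ = 0.3 Å a
3.2 Å contact crosses 4 Å with a few-percent probability per frame, which
over hundreds of frames would corrupt the recovered fractions; clipping
is what turns the separation margin into a theorem. The schedule
validator enforces the corresponding inequalities up front.

**Default fixture.** The study-scale fixture
(`h3_dimer_fixture()`) is two chains carrying the mitotic
phospho-T3/trimethyl-K4/dimethyl-R8 mark set, 200 frames, and the
persistence ladder 19%, 64%, 94%, 98% — persistence values reported for
real inter-chain interactions in the motivating system. The four episodes
form one compact interface, the R2/T3 region of chain A against the
R8/K9 region of chain B, with the phospho-T3/dimethyl-R8 salt bridge as
the most persistent pair. A compact interface is a geometric necessity:
the off-pair margin must hold for every unscheduled residue pair, and any
residue adjacent to an engaged one sits only ~4.6 Å from the partner, so
widely separated simultaneous contacts are unsatisfiable for rigid
chains. For the same reason the default noise is σ = 0.05 Å (off-margin
≈ 4.2 Å, which the four-contact dock satisfies); single-episode schedules
support σ = 0.3 Å comfortably, and the test suite exercises that case.
The extended geometry admits up to the four simultaneous contacts of the
default ladder; the helical barrel, whose side chains radiate in all
directions, admits two.

**What the generator does not emulate** — and hence what passing tests do
and do not show about real data: there is no physics (no force field,
solvent, electrostatics or kinetics), chains do not deform, side chains
are reduced to tips, and contact schedules are imposed rather than
emergent. Exact recovery on generated data validates the *bookkeeping* of
the pipeline — contact detection, persistence arithmetic, thresholding,
typing, SASA accounting — not any claim about how real modified tails
associate. Values of $N_{cc}$ and $\Delta A$ from generated fixtures
reflect the reduced geometry and are not comparable to values computed
from real, full-atom trajectories.

## Numerical choices and degenerate inputs

* Strict `<` at the 4 Å contact cutoff; inclusive `≥` at the 10%
  persistence threshold (keeps threshold-exact pairs representable).
* Persistence fractions and $N_{cc}$ means are plain arithmetic on exact
  frame counts; no smoothing, no burn-in removal (callers trim frames or
  use `stride` instead).
* SASA lattice is deterministic; the only tolerance is the lattice
  resolution itself (tested at 0.1 Å² for buried-area non-negativity).
* Hydrogen-free frames are legitimate everywhere; an empty contact series
  is an error for `mean_ncc` (undefined) but an all-zero one yields an
  empty map.
* Report files round $N_{cc}$ to one decimal and $\Delta A$ to whole Å²
  (matching the display precision conventional for such tables); JSON
  outputs keep full precision. The analysis path uses no RNG, so reruns
  are byte-identical.

## Problem sizes

The test suite and the bundled analysis scripts run the pipeline at the
scale the package targets: 200-frame fixtures for study-scale checks,
100-frame fixtures where many pipeline runs are compared, 960 sphere
points for headline SASA numbers and 240 points (with strides) where many
frames are processed repeatedly. These sizes were chosen as realistic
desk-scale analysis volumes; all statistics are means over frames and are
insensitive to further enlargement beyond sampling noise, which the
generator eliminates by construction.

## Known limitations

* The PDB reader targets the fixed-column subset produced by common MD
  tooling; exotic records (insertion codes, altLocs) are not interpreted.
* Salt-bridge typing is identity-based; a geometric mode (requiring the
  minimal-distance atom pair to involve phosphate O and guanidinium or
  ammonium N) would be a natural extension.
* The generator's rigid-interface capacity caps simultaneous contacts at
  about four (extended) or two (helical); denser interaction networks
  cannot be scheduled as a single nested ladder.
* Contact kinetics (on/off rates, lifetimes) are out of scope; the
  persistence map is a time-fraction summary only.
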