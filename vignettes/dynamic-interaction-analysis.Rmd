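---
title: "Dynamic interaction fingerprints and activation-state analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic interaction fingerprints and activation-state analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynofp)
```

## Scope and model

`dynofp` re-implements, as a reusable and testable pipeline, the analysis
layer that sits on top of molecular-dynamics simulations of opioid
receptor–ligand complexes:

1. **Per-frame geometric interaction detection** — ionic contacts
   (salt bridges), hydrogen bonds, single-water-mediated hydrogen bonds,
   hydrophobic contacts, cation–π interactions, and steric clashes.
2. **Dynamic-pharmacophore occurrence statistics** — for each monitored
   interaction, the percentage of trajectory frames in which it occurs,
   per simulation replicate and averaged across replicates, plus
   interaction-distance profiles with quartile summaries.
3. **Docking-pose rescoring** — counting which entries of a reference
   interaction fingerprint a pose reproduces, enforcing a maximum
   distance between the ligand's protonated ring amine and the γ-carbon
   of the conserved pocket aspartate D3.32, and ranking by score with
   ties broken by that same distance.
4. **Activation-state classification** — the TM6 deflection, measured as
   the Cα–Cα distance between the intracellular anchors 6.31 (bottom of
   TM6) and 4.40 (bottom of TM4), classified against reference distances
   taken from active- and inactive-state crystal structures, plus the
   occupancy of the TM5–TM6 salt bridge (K5.39–E6.58) that is expected
   to hinder the activation-related TM6 outward movement.

Residues are addressed in Ballesteros–Weinstein (BW) notation `T.PP`:
helix `T`, position `PP` relative to the most conserved residue `T.50` of
that helix. BW labels are computed by a constant offset from per-helix
anchor residues inside user-supplied helix ranges; insertions or deletions
within a helix are deliberately unsupported, because the class-A receptors
this package targets do not need them. Residues outside the helix ranges
receive region tags (`N-term`, `ECL1`–`ECL3`, `ICL1`–`ICL3`, `C-term`).

The built-in tables for the µ-, δ-, κ-opioid and nociceptin receptors
place, for example, the conserved aspartate at MOR D149^3.32^, the TM5
lysine at MOR K235^5.39^, and the non-conserved position 6.58 at K305
(MOR), W284 (DOR) and E297 (KOR). For the NOP receptor the literature is
inconsistent about whether the pocket tyrosine 3.33 is residue 130 or
131; the generator takes this as a parameter (`nop_tyr333`, default 131,
with the aspartate at the preceding position) rather than hard-coding
either convention.

## Geometric criteria

The published occurrence statistics this package emulates were produced
by pharmacophore software whose internal geometric definitions are not
public. The defaults here are therefore explicit stand-ins chosen from
common pharmacophore-toolkit conventions, all exposed in
`interaction_criteria()`:

| parameter | default | meaning |
|---|---|---|
| `ionic_max_dist` | 4.5 Å | max heavy-atom distance between opposite charges |
| `hbond_max_dist` | 3.5 Å | donor–acceptor heavy-atom distance |
| `hbond_min_angle` | 130° | angle at the hydrogen, or at the donor heavy atom in surrogate mode |
| `hydrophobic_max_dist` | 4.5 Å | min C/S–C/S contact distance |
| `cationpi_max_dist` | 6.0 Å | cation to ring centroid |
| `cationpi_max_offset` | 30° | angle from the ring normal |
| `clash_overlap` | 0.4 Å | van der Waals overlap reported as a clash |

All distance boundaries are inclusive. Because MD trajectories are often
stored without hydrogens, hydrogen bonds default to a heavy-atom
surrogate: the angle is measured at the donor heavy atom against its
bonded antecedent; when no antecedent is known the angle criterion is
skipped (set `hbond_strict = TRUE` to make this an error instead).
Water-mediated bonds require a *single* water hydrogen-bonded to both
the ligand group and the receptor atom within the same frame; two-water
bridges are out of scope.

## Occurrence statistics

A frame counts as positive for a monitored interaction if at least one
positive event of that type occurs between the configured partners — no
multiplicity weighting, matching the percentage-of-trajectory semantics
of dynamic pharmacophores. Replicate percentages are combined as an
unweighted arithmetic mean (all replicates have equal length by default);
`pooled = TRUE` pools frames instead, for unequal replicate lengths.
Distance profiles report min, quartiles and max using linear
interpolation (type-7 quantiles); outputs round percentages to one
decimal place while full precision is kept internally.

## Pose rescoring

The score is an unweighted count of matched reference entries: the
published procedure rescored poses by the presence or absence of listed
interactions, not by magnitudes. Water-mediated entries match against
*any* retained water, because reference tables list waters without a
stable identity. The constraint (default 5.5 Å, inclusive) is measured
from the morphinan amine nitrogen to the D3.32 γ-carbon. Ranking is
descending score, then ascending constraint distance, then pose id — a
total, deterministic order. The antagonist-pocket pattern used for the
inactive-state NOP receptor is expressed as an ordinary reference
fingerprint (`builtin_reference_fingerprint("NOP_inactive")`), not a
special case.

## State classification

With active reference `A` and inactive reference `I` (user inputs,
normally measured on the corresponding crystal structures — the package
never downloads structures), a frame with deflection `d` is

* `active_like` if `d ≥ A − τ`,
* `inactive_like` if `d ≤ I + τ`,
* `intermediate` otherwise,

with tolerance `τ = 0` by default: the published reference distances are
drawn as lines, not bands, so the open interval between them is the
intermediate region and boundary values belong to the end states. The
text of the source material wavers between "alpha carbonyl" and "alpha
carbon" for the measured atoms; Cα is used, matching standard GPCR
activation metrics, with `use_carbonyl = TRUE` available as a switch.
Fractions are pooled over the frames of all replicates, matching the
single-percentage reporting style the package emulates.

## The synthetic generator

Study-scale MD (five 100-ns membrane simulations per receptor) is not
reproducible at desk scale, so every analysis stage is validated against
synthetic trajectories with known ground truth. `generate_template()`
builds a toy seven-helix scaffold (helices on a 12 Å circle, 1.5 Å rise
per residue) carrying all named key residues, a four-feature ligand
(protonated morphinan amine, protonated secondary amine, carboxylate,
phenol), and optionally a water placed to bridge the phenol to the
K5.39 backbone carbonyl. `render_trajectory()` then renders frames in
which:

* each scheduled contact is placed at `bound_dist` (default 3.0 Å) or
  `unbound_dist` (default 8.0 Å) along its own displacement axis, plus
  Gaussian noise on the placed distance (`noise_sd`, default 0.05 Å);
* the TM6 deflection is set per frame from the state schedule
  (defaults: 12.6 Å active, 10.0 Å intermediate, 7.4 Å inactive against
  toy references of 12.0 / 8.0 Å).

Scheduled pairs are geometrically independent — each mobile side chain
moves along its own axis from its own ligand anchor atom, with companion
atoms offset perpendicular to that axis — so scheduled occupancies never
interfere and are exactly recoverable. The spec validator enforces the
separation invariant `bound + 3σ < cutoff < unbound − 3σ` (and the
analogous margins for the deflection targets), so the default noise can
never flip a scheduled frame. Exact-mode schedules place exactly
`round(p·n)` positive frames (round half up, which makes occupancies
like 0.813 or 0.053 exact at n = 1000); Bernoulli mode draws i.i.d.
frames. Replicate `r` uses seed `seed + r`, and the ground-truth JSON
(masks, state labels, seeds) is sufficient to regenerate a trajectory
bit-for-bit.

The default schedules are the study conditions themselves: the
per-receptor ionic occupancy table (e.g. the morphinan-amine–D3.32 salt
bridge in 100 % of frames, the MOR carboxylate–K5.39 contact at 81.3 %),
the KOR K5.39–E6.58 bridge at 45.6 %, and the per-receptor
intermediate-state fractions (MOR 44.6 %, DOR 5.3 %, KOR 51.9 %). The
split of the non-intermediate mass between active- and inactive-like
frames is not reported anywhere; the defaults place most of it in the
active-like state, as expected for agonist-bound complexes, with a small
inactive tail.

What the generator does **not** emulate: force-field physics, membrane
and solvent environments, correlated side-chain motions, conformational
heterogeneity beyond the scheduled displacements, and real ligand
geometry. Passing the recovery tests therefore demonstrates that the
*statistics and classification logic* are correct, not that the
geometric criteria would reproduce published percentages on real
trajectories — the criteria behind those numbers are unpublished.

## Numerical choices and edge cases

* Exhaustive all-pairs distance evaluation everywhere; the atom groups
  involved are tiny, so no spatial indexing is needed, and the test
  suite checks each detector against an independent brute-force loop.
* Cation–π rings must contain ≥ 5 atoms with out-of-plane RMS below
  0.25 Å (plane fitted by SVD); non-planar rings are an error, not a
  silent miss. The ring normal is sign-free.
* `classify_frame()` auto-swaps inverted references with a warning.
* Empty pose lists: filtering an empty set returns an empty set;
  *ranking* an empty set is an error, since a ranking of nothing is
  meaningless.
* Sequence identity/similarity (`pairwise_identity()`) uses global
  Needleman–Wunsch alignment with BLOSUM62 (gap open 10, extend 4) and
  counts identical pairs over aligned columns excluding terminal gaps;
  "similar" means a positive substitution score. The alignment method
  behind published identity figures is typically unstated, so these
  values are method-dependent.

## Problem sizes used in validation

The packaged tests and the acceptance script use 5 replicates × 1000
frames for occurrence recovery and single 1000-frame trajectories for
occupancy and state recovery — the same frame counts as the study
systems they emulate (1000 stored conformations per 100 ns replicate at
a 100 ps interval) — plus smaller renders for property checks. A full
acceptance run completes in seconds on one CPU.

## A worked example

```{r example}
spec <- synthetic_spec("KOR", n_frames = 1000, n_replicates = 5, seed = 42)
res <- render_trajectory(generate_template(spec), spec)
occurrence_frequencies(res$replicates, schedule_definitions(spec))
tm5_tm6_bridge_occupancy(res$replicates[[1]])
state_fractions(res$replicates, schedule_state_reference(spec))
```

## Known limitations

* Geometric criteria are stand-ins, not reconstructions of the
  proprietary definitions behind the published tables.
* BW assignment assumes gap-free helices between the stated boundaries.
* The CSV frame dialect and PDB cover the fixture workflow; DCD input is
  supported for externally produced trajectories, but the package never
  writes binary formats itself.
* Pose *generation*, docking scores, force-field minimisation, energy-
  based interaction scoring, and microswitch/free-energy analyses are
  out of scope.
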